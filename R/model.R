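#' Train a phosphorylation-site classifier
#'
#' Fits either a random forest ([randomForest::randomForest()], 100 trees,
#' sqrt(p) features per split) or an RBF-kernel support vector machine
#' ([e1071::svm()], `C = 1`, `gamma = 1/p`, with Platt-style probability
#' calibration so ROC/AUC can be computed from graded scores).  For the SVM
#' the columns are standardised (centre/scale fitted on the training rows
#' only and stored in the model); the forest sees raw features.  A fixed
#' seed makes the forest (and the SVM's internal calibration
#' cross-validation) reproducible.
#'
#' @param x Numeric feature matrix (rows = instances, named columns).
#' @param labels 0/1 labels, at least 2 instances per class.
#' @param algorithm `"rf"` (default) or `"svm"`.
#' @param n_trees Forest size (default 100).
#' @param cost SVM cost parameter C (default 1).
#' @param gamma SVM RBF width (default `1/ncol(x)`).
#' @param standardize Standardise columns; defaults to `TRUE` for the SVM
#'   and `FALSE` for the forest.
#' @param class_weights Optional named weights `c("0" = , "1" = )`; default
#'   none (no resampling or reweighting).
#' @param seed Integer seed (default 1).
#' @return A list of class `"phos_classifier"` holding the fitted model, the
#'   recorded column names, and the standardisation parameters.
#' @export
phos_train <- function(x, labels, algorithm = c("rf", "svm"),
                       n_trees = 100L, cost = 1, gamma = NULL,
                       standardize = NULL, class_weights = NULL, seed = 1L) {
  algorithm <- match.arg(algorithm)
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  if (any(!is.finite(x))) {
    bad <- unique(colnames(x)[ceiling(which(!is.finite(x)) / nrow(x))])
    stop("non-finite values in column(s): ", paste(bad, collapse = ", "))
  }
  tab <- table(factor(labels, levels = c(0, 1)))
  if (any(tab < 2L)) {
    stop("need at least 2 instances per class (got ",
         paste(tab, collapse = "/"), ")")
  }
  if (is.null(standardize)) standardize <- algorithm == "svm"
  centre <- scl <- NULL
  if (standardize) {
    centre <- colMeans(x)
    scl <- apply(x, 2, sd)
    scl[scl == 0] <- 1
    x <- scale(x, center = centre, scale = scl)
  }
  y <- factor(labels, levels = c(0, 1))
  set.seed(seed)
  fit <- if (algorithm == "rf") {
    randomForest::randomForest(x, y, ntree = n_trees,
                               classwt = class_weights)
  } else {
    if (is.null(gamma)) gamma <- 1 / ncol(x)
    e1071::svm(x, y, kernel = "radial", cost = cost, gamma = gamma,
               probability = TRUE, scale = FALSE,
               class.weights = class_weights)
  }
  structure(list(algorithm = algorithm, fit = fit,
                 columns = colnames(x), centre = centre, scale = scl,
                 n_trees = if (algorithm == "rf") n_trees else NULL,
                 cost = if (algorithm == "svm") cost else NULL,
                 gamma = if (algorithm == "svm") gamma else NULL,
                 seed = as.integer(seed)),
            class = "phos_classifier")
}

#' Score new instances with a trained classifier
#'
#' @param object A `phos_classifier`.
#' @param x Feature matrix whose columns must match (by name and order) the
#'   columns the model was trained on; a mismatch is an error listing the
#'   missing/extra columns.
#' @param type `"prob"` for the positive-class score in [0, 1] (RF: vote
#'   fraction; SVM: calibrated probability) or `"label"` for the hard 0/1
#'   call at `score > 0.5` (a score of exactly 0.5 is called negative).
#' @param ... Unused.
#' @return Numeric vector of scores or integer 0/1 labels.
#' @export
predict.phos_classifier <- function(object, x, type = c("prob", "label"), ...) {
  type <- match.arg(type)
  stopifnot(is.matrix(x))
  if (!identical(colnames(x), object$columns)) {
    missing <- setdiff(object$columns, colnames(x))
    extra <- setdiff(colnames(x), object$columns)
    stop("feature columns do not match the trained model",
         if (length(missing)) paste0("; missing: ",
                                     paste(utils::head(missing, 5), collapse = ", ")),
         if (length(extra)) paste0("; extra: ",
                                   paste(utils::head(extra, 5), collapse = ", ")),
         if (!length(missing) && !length(extra)) "; column order differs")
  }
  if (!is.null(object$centre)) {
    x <- scale(x, center = object$centre, scale = object$scale)
  }
  score <- if (object$algorithm == "rf") {
    predict(object$fit, x, type = "prob")[, "1"]
  } else {
    p <- predict(object$fit, x, probability = TRUE)
    attr(p, "probabilities")[, "1"]
  }
  score <- unname(score)
  if (type == "prob") score else as.integer(score > 0.5)
}

#' @export
print.phos_classifier <- function(x, ...) {
  cat(sprintf("phos_classifier: %s on %d features (seed %d)\n",
              if (x$algorithm == "rf")
                sprintf("random forest, %d trees", x$n_trees)
              else sprintf("SVM-RBF, C = %g, gamma = %g", x$cost, x$gamma),
              length(x$columns), x$seed))
  invisible(x)
}

#' Stratified cross-validation fold assignment
#'
#' @param labels 0/1 labels; every class must have at least `n_folds`
#'   instances.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..n_folds`, one per instance;
#'   within each class the fold sizes differ by at most one.
#' @export
stratified_folds <- function(labels, n_folds = 5L, seed = 1L) {
  stopifnot(n_folds >= 2L)
  counts <- table(labels)
  if (any(counts < n_folds)) {
    stop("a class has fewer instances than folds (",
         paste(counts, collapse = "/"), " vs ", n_folds, ")")
  }
  folds <- integer(length(labels))
  set.seed(seed)
  for (lab in names(counts)) {
    idx <- which(labels == utils::type.convert(lab, as.is = TRUE))
    folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  folds
}

#' Cross-validate a classifier configuration
#'
#' Stratified k-fold (default 5) cross-validation: the model is refitted on
#' each training split and scored on the held-out fold; per-fold metrics and
#' a pooled report over the concatenated out-of-fold scores are returned.
#' When a `selector` is given, feature selection is likewise refitted inside
#' each training fold (nested cross-validation), so the out-of-fold scores
#' carry no selection leakage -- the protocol to use when the selection
#' itself is part of what is being evaluated (e.g. permutation-null checks).
#'
#' @inheritParams phos_train
#' @param n_folds Number of folds (default 5).
#' @param selector Optional `function(x_train, labels_train)` returning the
#'   column indices to keep; applied per fold.
#' @param ... Further arguments passed to [phos_train()].
#' @return A list of class `"phos_cv"`: `fold_metrics` (list of
#'   `phos_metrics`), `pooled` (`phos_metrics` over all out-of-fold scores),
#'   `scores` (out-of-fold score per instance), `folds`, `seed`.
#' @export
cross_validate <- function(x, labels, algorithm = c("rf", "svm"),
                           n_folds = 5L, seed = 1L, selector = NULL, ...) {
  algorithm <- match.arg(algorithm)
  folds <- stratified_folds(labels, n_folds = n_folds, seed = seed)
  scores <- numeric(length(labels))
  fold_metrics <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    hold <- folds == f
    keep <- if (is.null(selector)) seq_len(ncol(x)) else {
      selector(x[!hold, , drop = FALSE], labels[!hold])
    }
    model <- phos_train(x[!hold, keep, drop = FALSE], labels[!hold],
                        algorithm = algorithm, seed = seed + f, ...)
    scores[hold] <- predict(model, x[hold, keep, drop = FALSE], type = "prob")
    fold_metrics[[f]] <- evaluate_predictions(labels[hold], scores[hold])
  }
  structure(list(fold_metrics = fold_metrics,
                 pooled = evaluate_predictions(labels, scores),
                 scores = scores, folds = folds, seed = as.integer(seed)),
            class = "phos_cv")
}

#' @export
print.phos_cv <- function(x, ...) {
  cat(sprintf("phos_cv: %d folds, pooled out-of-fold performance:\n",
              length(x$fold_metrics)))
  print(x$pooled)
  invisible(x)
}
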