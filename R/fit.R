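#' Fit a phosphorylation-site predictor end to end
#'
#' The package's central fitting function.  Starting from sequences and site
#' annotations it (1) builds the labelled 21-mer fragment dataset for one
#' central-residue type, (2) draws a stratified 80/20 train/test split,
#' (3) encodes the requested feature schemes, (4) runs the two-stage
#' mRMR + symmetrical-uncertainty feature selection **on the training
#' partition only**, (5) trains the classifier on the selected training
#' columns, (6) cross-validates it (stratified 5-fold by default) and
#' (7) scores the held-out test partition.  Setting
#' `select_on = "all"` reproduces the stricter emulation in which selection
#' sees the full dataset before the split (leakage-prone; off by default).
#'
#' @param proteins Named character vector of sequences ([read_fasta()]).
#' @param sites Site-annotation data.frame ([read_site_table()]).
#' @param residue Central residue type: `"S"`, `"T"` or `"Y"`.
#' @param schemes Feature schemes to encode (subset of PP, BE, SS, FF, FA).
#' @param properties,profiles,vocab Encoder resources (see
#'   [assemble_features()]).
#' @param flank Window half-width (default 10).
#' @param negative_policy,drop_edge_sites Passed to [build_dataset()].
#' @param train_fraction Training fraction (default 0.8).
#' @param k mRMR retention per category (default 50).
#' @param su_threshold,bins,mrmr_variant Selection parameters
#'   ([two_stage_select()]).
#' @param algorithm `"rf"` or `"svm"`.
#' @param n_folds Cross-validation folds (default 5).
#' @param select_on `"train"` (default, leakage-safe) or `"all"`.
#' @param seed Integer seed driving the split, fold assignment and model.
#' @param ... Further arguments to [phos_train()] (`n_trees`, `cost`, ...).
#' @return An object of class `"phospho_fit"` with components `fragments`,
#'   `split`, `features` (column metadata only), `selection`, `model`, `cv`,
#'   `test` (a `phos_metrics` report), `config`.
#' @seealso [predict.phospho_fit()], [summary.phospho_fit()],
#'   [plot.phospho_fit()]
#' @export
phospho_fit <- function(proteins, sites, residue = c("S", "T", "Y"),
                        schemes = c("PP", "BE", "SS", "FF", "FA"),
                        properties = load_property_table(),
                        profiles = NULL, vocab = NULL,
                        flank = 10L, negative_policy = "unannotated",
                        drop_edge_sites = FALSE,
                        train_fraction = 0.8, k = 50L, su_threshold = 0,
                        bins = 3L, mrmr_variant = "MID",
                        algorithm = c("rf", "svm"), n_folds = 5L,
                        select_on = c("train", "all"), seed = 1L, ...) {
  residue <- match.arg(residue)
  algorithm <- match.arg(algorithm)
  select_on <- match.arg(select_on)

  fragments <- build_dataset(proteins, sites, residue = residue,
                             flank = flank,
                             negative_policy = negative_policy,
                             drop_edge_sites = drop_edge_sites)
  if (nrow(fragments) == 0L) stop("no ", residue, " fragments to fit on")
  split <- split_dataset(fragments, train_fraction = train_fraction,
                         seed = seed)
  feats <- assemble_features(fragments, schemes = schemes,
                             properties = properties, profiles = profiles,
                             vocab = vocab)
  frag_key <- paste0(fragments$protein_id, "#", fragments$position)
  in_train <- frag_key %in% paste0(split$train$protein_id, "#",
                                   split$train$position)
  sel_rows <- if (select_on == "train") in_train else rep(TRUE, nrow(feats$x))
  selection <- two_stage_select(feats$x[sel_rows, , drop = FALSE],
                                fragments$label[sel_rows],
                                k = k, su_threshold = su_threshold,
                                categories = feats$meta$category,
                                variant = mrmr_variant, bins = bins)
  x_sel <- feats$x[, selection$selected, drop = FALSE]
  model <- phos_train(x_sel[in_train, , drop = FALSE],
                      fragments$label[in_train],
                      algorithm = algorithm, seed = seed, ...)
  cv <- cross_validate(x_sel[in_train, , drop = FALSE],
                       fragments$label[in_train],
                       algorithm = algorithm, n_folds = n_folds,
                       seed = seed, ...)
  test_scores <- predict(model, x_sel[!in_train, , drop = FALSE])
  test <- evaluate_predictions(fragments$label[!in_train], test_scores)

  config <- list(residue = residue, schemes = schemes, flank = flank,
                 negative_policy = negative_policy,
                 drop_edge_sites = drop_edge_sites,
                 train_fraction = train_fraction, k = k,
                 su_threshold = su_threshold, bins = bins,
                 mrmr_variant = mrmr_variant, algorithm = algorithm,
                 n_folds = n_folds, select_on = select_on,
                 seed = as.integer(seed))
  structure(list(fragments = fragments, split = split,
                 meta = feats$meta, selection = selection, model = model,
                 cv = cv, test = test,
                 resources = list(properties = properties,
                                  profiles = profiles, vocab = vocab),
                 config = config,
                 config_hash = config_hash(config)),
            class = "phospho_fit")
}

#' @export
print.phospho_fit <- function(x, ...) {
  cat(sprintf("phospho_fit: p%s predictor (%s, schemes %s)\n",
              x$config$residue,
              toupper(x$config$algorithm),
              paste(x$config$schemes, collapse = "+")))
  cat(sprintf("  %d fragments (%d train / %d test), %d of %d features kept\n",
              nrow(x$fragments), nrow(x$split$train), nrow(x$split$test),
              length(x$selection$selected), nrow(x$meta)))
  cat("  held-out test: ")
  print(x$test)
  invisible(x)
}

#' Summarise a fitted phosphorylation-site predictor
#'
#' @param object A `phospho_fit`.
#' @param ... Unused.
#' @return A data.frame with one row per evaluation context
#'   (cross-validation pooled, held-out test) and columns n, ACC, SN, SP,
#'   PRE, F, MCC, AUC; printed as percentages to match common reporting.
#' @method summary phospho_fit
#' @export
summary.phospho_fit <- function(object, ...) {
  row <- function(m) {
    data.frame(n = m$n, acc = m$metrics[["acc"]], sn = m$metrics[["sn"]],
               sp = m$metrics[["sp"]], pre = m$metrics[["pre"]],
               f = m$metrics[["f"]], mcc = m$metrics[["mcc"]], auc = m$auc)
  }
  out <- rbind(cv_pooled = row(object$cv$pooled), test = row(object$test))
  class(out) <- c("summary.phospho_fit", "data.frame")
  out
}

#' @export
print.summary.phospho_fit <- function(x, ...) {
  shown <- x
  for (col in c("acc", "sn", "sp", "pre", "f")) {
    shown[[col]] <- sprintf("%.1f%%", 100 * shown[[col]])
  }
  shown$mcc <- sprintf("%.2f", x$mcc)
  shown$auc <- sprintf("%.3f", x$auc)
  print.data.frame(shown)
  invisible(x)
}

#' Score new candidate sites with a fitted predictor
#'
#' Re-encodes the given sites exactly as at fit time (same schemes,
#' resources and selected columns) and scores them with the trained
#' classifier.
#'
#' @param object A `phospho_fit`.
#' @param proteins Named character vector of sequences.
#' @param sites Data.frame with columns `protein_id`, `position` (and
#'   optionally `residue`); all central residues must match the model's
#'   residue type.
#' @param profiles,vocab Resources for the new proteins; default to the ones
#'   stored at fit time.
#' @param type `"prob"` or `"label"`.
#' @param ... Unused.
#' @return Input data.frame with `score` (and for `type = "label"` a
#'   `label`) column appended.
#' @export
predict.phospho_fit <- function(object, proteins, sites,
                                profiles = NULL, vocab = NULL,
                                type = c("prob", "label"), ...) {
  type <- match.arg(type)
  cfg <- object$config
  frags <- data.frame(protein_id = sites$protein_id,
                      position = as.integer(sites$position),
                      residue = cfg$residue,
                      label = NA_integer_,
                      stringsAsFactors = FALSE)
  frags$window <- mapply(function(pid, pos) {
    if (!pid %in% names(proteins)) stop("unknown protein id: ", pid)
    extract_fragment(proteins[[pid]], pos, cfg$flank)
  }, frags$protein_id, frags$position, USE.NAMES = FALSE)
  centres <- substr(frags$window, cfg$flank + 1L, cfg$flank + 1L)
  if (any(centres != cfg$residue)) {
    stop("model predicts p", cfg$residue, " sites only; found central ",
         paste(unique(centres[centres != cfg$residue]), collapse = ", "))
  }
  frags <- as_phos_fragments(frags, cfg$flank)
  feats <- assemble_features(frags, schemes = cfg$schemes,
                             properties = object$resources$properties,
                             profiles = profiles %||% object$resources$profiles,
                             vocab = vocab %||% object$resources$vocab)
  x <- feats$x[, object$selection$selected, drop = FALSE]
  out <- as.data.frame(sites)
  out$score <- predict(object$model, x, type = "prob")
  if (type == "label") out$label <- as.integer(out$score > 0.5)
  out
}

#' Plot the held-out ROC curve of a fitted predictor
#'
#' @param x A `phospho_fit`.
#' @param ... Passed to [graphics::plot()].
#' @return The ROC data.frame, invisibly.
#' @method plot phospho_fit
#' @export
plot.phospho_fit <- function(x, ...) {
  roc <- x$test$roc
  if (is.null(roc)) stop("no ROC available (single-class test set)")
  graphics::plot(roc$fpr, roc$tpr, type = "l",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("p%s %s: test AUC %.3f", x$config$residue,
                                toupper(x$config$algorithm), x$test$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(roc)
}

# Small stable djb2-style hash of a configuration's deparsed form; embedded in
# artifacts so outputs from different configurations refuse to be mixed up.
config_hash <- function(config) {
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Run the full pipeline from a configuration file or list
#'
#' Thin orchestration over [phospho_fit()]: reads the inputs named in the
#' configuration, fits the predictor, and writes the run artifacts (feature
#' column metadata, both selection rankings, metrics report, fitted model)
#' into an output directory.  Every artifact embeds the configuration hash,
#' so artifacts from different runs cannot silently be combined.
#'
#' Recognised configuration keys: `fasta`, `sites`, `profiles`, `vocab`,
#' `properties` (input paths; `profiles`/`vocab`/`properties` optional),
#' `out_dir`, and any argument of [phospho_fit()] (`residue`, `schemes`,
#' `k`, `algorithm`, `seed`, ...).
#'
#' @param config A named list or the path of a YAML file containing one.
#' @return The fitted `phospho_fit`, invisibly; artifacts under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$fasta), !is.null(config$sites),
            !is.null(config$out_dir))
  proteins <- read_fasta(config$fasta)
  sites <- read_site_table(config$sites, proteins)
  profiles <- if (!is.null(config$profiles))
    read_structural_profiles(config$profiles)
  vocab <- if (!is.null(config$vocab)) read_vocabulary(config$vocab)
  properties <- if (!is.null(config$properties))
    load_property_table(config$properties) else load_property_table()

  fit_args <- config[intersect(names(config), names(formals(phospho_fit)))]
  fit_args$proteins <- proteins
  fit_args$sites <- sites
  fit_args$profiles <- profiles
  fit_args$vocab <- vocab
  fit_args$properties <- properties
  if (!is.null(fit_args$schemes)) fit_args$schemes <- unlist(fit_args$schemes)
  fit <- do.call(phospho_fit, fit_args)

  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- fit$config_hash
  meta <- fit$meta
  meta$config_hash <- hash
  write.table(meta, file.path(out_dir, "feature_columns.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  rankings <- rbind(fit$selection$mrmr, fit$selection$su)
  rankings$config_hash <- hash
  write.table(rankings, file.path(out_dir, "rankings.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  report <- list(config = fit$config, config_hash = hash,
                 n_features_total = nrow(fit$meta),
                 n_features_selected = length(fit$selection$selected),
                 cv_pooled = as.list(c(fit$cv$pooled$metrics,
                                       auc = fit$cv$pooled$auc)),
                 test = as.list(c(fit$test$metrics, auc = fit$test$auc)),
                 test_counts = as.list(fit$test$counts))
  jsonlite::write_json(report, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  saveRDS(fit, file.path(out_dir, "model.rds"))
  invisible(fit)
}
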