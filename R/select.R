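#' Greedy mRMR ranking within each feature category
#'
#' Minimum-redundancy maximum-relevance filter: within each feature category
#' independently, the first pick maximises the mutual information
#' `I(feature; label)`; each subsequent pick maximises relevance minus the
#' mean mutual information with the already-selected features of that
#' category (the MID "difference" form; the MIQ quotient form divides
#' instead).  Selection stops at `min(k, category width)` features.  All
#' mutual information is computed on discretized columns
#' ([discretize_features()]).  Ties break to the lower column index, so the
#' ranking is deterministic.
#'
#' @param x Numeric feature matrix (or a `phos_features` object).
#' @param labels Binary class labels, one per row.
#' @param k Number of features to retain per category (default 50).
#' @param categories Character vector, one category per column; taken from
#'   the `phos_features` metadata when `x` is one, otherwise a single
#'   category is assumed.
#' @param variant `"MID"` (default) or `"MIQ"`.
#' @param bins Discretization bins for continuous columns.
#' @return A data.frame of class `"phos_ranking"` with columns `rank`
#'   (within category), `index` (column index in `x`), `name`, `category`,
#'   `score` (the greedy criterion value at selection time) and `stage`
#'   (`"mrmr"`).
#' @export
mrmr_rank <- function(x, labels, k = 50L, categories = NULL,
                      variant = c("MID", "MIQ"), bins = 3L) {
  variant <- match.arg(variant)
  if (inherits(x, "phos_features")) {
    categories <- categories %||% x$meta$category
    x <- x$x
  }
  stopifnot(is.matrix(x), nrow(x) == length(labels), k >= 1L)
  if (is.null(categories)) categories <- rep("all", ncol(x))
  stopifnot(length(categories) == ncol(x))

  d <- discretize_features(x, bins = bins)
  nlev <- attr(d, "n_levels")
  cy <- as_codes(labels)
  ky <- max(cy)

  res <- list()
  for (cat in unique(categories)) {
    cols <- which(categories == cat)
    rel <- vapply(cols, function(j) mi_codes(d[, j], nlev[j], cy, ky),
                  numeric(1))
    n_pick <- min(k, length(cols))
    picked <- integer(n_pick)
    scores <- numeric(n_pick)
    red_sum <- numeric(length(cols))
    active <- rep(TRUE, length(cols))
    for (t in seq_len(n_pick)) {
      crit <- if (t == 1L) {
        rel
      } else if (variant == "MID") {
        rel - red_sum / (t - 1L)
      } else {
        rel / pmax(red_sum / (t - 1L), .Machine$double.eps)
      }
      crit[!active] <- -Inf
      # ties (within floating-point noise) break to the lower column index
      best <- which(crit >= max(crit) - 1e-12)[1]
      picked[t] <- best
      scores[t] <- crit[best]
      active[best] <- FALSE
      if (t < n_pick) {
        jb <- cols[best]
        upd <- which(active)
        red_sum[upd] <- red_sum[upd] + vapply(cols[upd], function(j) {
          mi_codes(d[, j], nlev[j], d[, jb], nlev[jb])
        }, numeric(1))
      }
    }
    res[[cat]] <- data.frame(rank = seq_len(n_pick),
                             index = cols[picked],
                             name = colnames(x)[cols[picked]] %||%
                               as.character(cols[picked]),
                             category = cat,
                             score = scores,
                             stage = "mrmr",
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("phos_ranking", "data.frame")
  out
}

#' Symmetrical-uncertainty ranking of features against the label
#'
#' Orders features by `SU(feature, label)` descending (ties to the lower
#' column index).  Intended as the second selection stage, applied to the
#' pooled mRMR survivors; the full ranked list is returned so any cutoff is
#' recoverable.
#'
#' @inheritParams mrmr_rank
#' @param indices Column indices of `x` to rank (default: all columns).
#' @return A data.frame of class `"phos_ranking"` with columns `rank`,
#'   `index`, `name`, `category`, `score` (SU value) and `stage` (`"su"`).
#' @export
su_rank <- function(x, labels, indices = NULL, categories = NULL, bins = 3L) {
  if (inherits(x, "phos_features")) {
    categories <- categories %||% x$meta$category
    x <- x$x
  }
  if (is.null(indices)) indices <- seq_len(ncol(x))
  if (length(indices) == 0L) stop("no features to rank")
  if (is.null(categories)) categories <- rep("all", ncol(x))
  d <- discretize_features(x[, indices, drop = FALSE], bins = bins)
  su <- vapply(seq_along(indices), function(j) {
    suppressWarnings(symmetrical_uncertainty(d[, j], labels))
  }, numeric(1))
  ord <- order(-su, indices)
  out <- data.frame(rank = seq_along(indices),
                    index = indices[ord],
                    name = colnames(x)[indices[ord]] %||%
                      as.character(indices[ord]),
                    category = categories[indices[ord]],
                    score = su[ord],
                    stage = "su",
                    stringsAsFactors = FALSE)
  class(out) <- c("phos_ranking", "data.frame")
  out
}

#' Two-stage feature selection: per-category mRMR, then SU
#'
#' Runs [mrmr_rank()] within each feature category, pools the per-category
#' top-`k` survivors, ranks them by symmetrical uncertainty against the
#' label, and keeps those with `SU > su_threshold`.  The default threshold
#' of 0 only drops features carrying no empirical association at all
#' (constant or exactly independent columns); both rankings are returned so
#' any other cutoff (for example a top-n rule) can be applied afterwards.
#' The whole procedure is a pure function of its inputs and configuration.
#'
#' @inheritParams mrmr_rank
#' @param su_threshold Keep survivors with SU strictly above this value
#'   (default 0).
#' @return A list of class `"phos_selection"`: `selected` (column indices of
#'   the kept features, in SU-rank order), `mrmr` and `su` (the two
#'   `phos_ranking` tables) and `config`.
#' @export
two_stage_select <- function(x, labels, k = 50L, su_threshold = 0,
                             categories = NULL, variant = c("MID", "MIQ"),
                             bins = 3L) {
  variant <- match.arg(variant)
  feats <- NULL
  if (inherits(x, "phos_features")) {
    feats <- x
    categories <- categories %||% feats$meta$category
    x <- feats$x
  }
  mr <- mrmr_rank(x, labels, k = k, categories = categories,
                  variant = variant, bins = bins)
  su <- su_rank(x, labels, indices = sort(mr$index),
                categories = categories, bins = bins)
  keep <- su$index[su$score > su_threshold]
  if (length(keep) == 0L) {
    stop("no features survive SU > ", su_threshold,
         "; relax su_threshold (e.g. keep the full SU ranking)")
  }
  structure(list(selected = keep, mrmr = mr, su = su,
                 config = list(k = k, su_threshold = su_threshold,
                               variant = variant, bins = bins)),
            class = "phos_selection")
}

#' @export
print.phos_selection <- function(x, ...) {
  cat(sprintf(
    "phos_selection: %d features kept (mRMR top-%d per category, SU > %g)\n",
    length(x$selected), x$config$k, x$config$su_threshold))
  tab <- table(x$su$category[x$su$index %in% x$selected])
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = "   "),
      "\n", sep = "")
  invisible(x)
}
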