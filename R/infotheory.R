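# Plug-in information measures on categorical columns.  All entropies are in
# bits (log base 2); 0 * log(0) is treated as 0 throughout.

# Recode any vector to integer codes 1..K.
as_codes <- function(x) {
  if (is.factor(x)) return(as.integer(x))
  match(x, sort(unique(x)))
}

#' Shannon entropy of a categorical column (bits)
#'
#' Plug-in (maximum-likelihood) estimate from the empirical distribution.
#'
#' @param x A non-empty vector treated as categorical.
#' @return Entropy in bits.
#' @export
#' @examples
#' entropy_bits(c(0, 0, 1, 1))          # 1
#' entropy_bits(c("a", "a", "b", "c"))  # 1.5
entropy_bits <- function(x) {
  if (length(x) == 0L) stop("entropy of an empty column is undefined")
  p <- tabulate(as_codes(x))
  p <- p[p > 0] / length(x)
  -sum(p * log2(p))
}

#' Mutual information between two categorical columns (bits)
#'
#' Plug-in estimate `I(X;Y) = H(X) + H(Y) - H(X,Y)`; non-negative up to
#' floating-point rounding.
#'
#' @param x,y Equal-length vectors treated as categorical.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  cx <- as_codes(x)
  cy <- as_codes(y)
  joint <- (cx - 1L) * max(cy) + cy
  h <- entropy_bits(cx) + entropy_bits(cy) - entropy_bits(joint)
  max(h, 0)
}

# Fast path for pre-coded integer vectors with known alphabet sizes; used by
# the greedy mRMR loop.
mi_codes <- function(cx, kx, cy, ky) {
  n <- length(cx)
  pj <- tabulate((cx - 1L) * ky + cy, nbins = kx * ky)
  pj <- pj[pj > 0] / n
  px <- tabulate(cx, nbins = kx)
  px <- px[px > 0] / n
  py <- tabulate(cy, nbins = ky)
  py <- py[py > 0] / n
  max(-sum(px * log2(px)) - sum(py * log2(py)) + sum(pj * log2(pj)), 0)
}

#' Symmetrical uncertainty between two categorical columns
#'
#' `SU(X,Y) = 2 * I(X;Y) / (H(X) + H(Y))`, the information gain normalised
#' by the marginal entropies, in [0, 1].  The information-gain term is the
#' mutual information (the standard reading in attribute-evaluation work;
#' a conditional-entropy reading would break the [0, 1] range).  When both
#' columns are constant the denominator is 0 and SU is defined as 0 with a
#' warning.
#'
#' @param x,y Equal-length vectors treated as categorical.
#' @return SU value in [0, 1].
#' @export
symmetrical_uncertainty <- function(x, y) {
  hx <- entropy_bits(x)
  hy <- entropy_bits(y)
  if (hx + hy == 0) {
    warning("both columns constant: SU defined as 0")
    return(0)
  }
  min(2 * mutual_information(x, y) / (hx + hy), 1)
}

#' Discretize a feature matrix for information-theoretic scoring
#'
#' Columns with at most two distinct values (binary indicators, flags) pass
#' through untouched; continuous columns are cut into `bins` equal-frequency
#' intervals (quantile breaks, duplicates collapsed).  Every column ends up
#' as integer codes over a finite alphabet.
#'
#' @param x Numeric matrix.
#' @param bins Number of equal-frequency bins for continuous columns
#'   (default 3).
#' @return Integer matrix of codes (1..K per column), with attribute
#'   `"n_levels"` giving each column's alphabet size.
#' @export
discretize_features <- function(x, bins = 3L) {
  stopifnot(is.matrix(x), bins >= 2L)
  out <- matrix(1L, nrow(x), ncol(x), dimnames = dimnames(x))
  nlev <- integer(ncol(x))
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    u <- unique(v)
    if (length(u) <= 2L) {
      out[, j] <- match(v, sort(u))
      nlev[j] <- length(u)
    } else {
      br <- unique(quantile(v, probs = seq(0, 1, length.out = bins + 1),
                            names = FALSE, type = 7))
      if (length(br) < 3L) {
        # Quantiles collapsed (heavy ties): fall back to a midrange split so
        # the alphabet stays small.
        mid <- mean(range(v))
        out[, j] <- as.integer(v > mid) + 1L
        nlev[j] <- 2L
      } else {
        out[, j] <- cut(v, breaks = br, include.lowest = TRUE, labels = FALSE)
        nlev[j] <- length(br) - 1L
      }
    }
  }
  attr(out, "n_levels") <- stats::setNames(nlev, colnames(x))
  out
}
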