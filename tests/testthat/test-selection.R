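# A small labelled matrix with a mix of informative and noise columns.
noisy_matrix <- function(n = 120, p = 20, seed = 77) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("f%02d", seq_len(p))))
  x[, 1] <- x[, 1] + 2 * y          # strong continuous signal
  x[, 2] <- y + rnorm(n, sd = 0.4)  # medium
  list(x = x, y = y)
}

test_that("mRMR's first pick per category is the MI argmax, by oracle", {
  nm <- noisy_matrix()
  d <- discretize_features(nm$x)
  rel <- vapply(seq_len(ncol(d)), function(j) mi_oracle(table(d[, j], nm$y)),
                numeric(1))
  r <- mrmr_rank(nm$x, nm$y, k = 5)
  expect_identical(r$index[r$rank == 1], which.max(rel))
  # per-category independence: each category's first pick is its own argmax
  cats <- rep(c("A", "B"), each = 10)
  r2 <- mrmr_rank(nm$x, nm$y, k = 3, categories = cats)
  for (cat in c("A", "B")) {
    cols <- which(cats == cat)
    expect_identical(r2$index[r2$category == cat & r2$rank == 1],
                     cols[which.max(rel[cols])])
  }
})

test_that("redundant duplicates are deferred behind weaker independent signal", {
  y <- rep(c(0L, 1L), each = 6)
  f1 <- y; f1[1] <- 1L            # strong but imperfect label proxy
  f2 <- f1                        # exact duplicate
  f3 <- y; f3[c(2, 7, 8)] <- 1L - f3[c(2, 7, 8)]  # weaker, non-duplicated
  x <- cbind(f1 = f1, f2 = f2, f3 = f3)
  r <- mrmr_rank(x, y, k = 3)
  expect_identical(r$index, c(1L, 3L, 2L))
  # and the greedy path agrees with the step-by-step oracle
  expect_identical(r$index, mrmr_oracle(x, y, 3))
})

test_that("greedy selection agrees with the exhaustive oracle on random instances", {
  set.seed(91)
  for (i in 1:5) {
    n <- 40; p <- 6
    y <- rep(c(0L, 1L), length.out = n)
    x <- matrix(sample(0:1, n * p, replace = TRUE), n, p)
    x[, 3] <- ifelse(runif(n) < 0.8, y, 1L - y)
    expect_identical(mrmr_rank(x, y, k = p)$index, mrmr_oracle(x, y, p))
  }
})

test_that("mRMR retains top-k per category, bounded by category width", {
  set.seed(13)
  y <- rep(c(0L, 1L), each = 60)
  x <- matrix(rnorm(120 * 200), 120, 200)
  r <- mrmr_rank(x, y, k = 50)
  expect_identical(nrow(r), 50L)
  expect_identical(anyDuplicated(r$index), 0L)

  x30 <- x[, 1:30]
  expect_identical(nrow(mrmr_rank(x30, y, k = 50)), 30L)
})

test_that("SU ranking sorts by the oracle's scores with deterministic ties", {
  set.seed(41)
  n <- 60
  y <- rep(c(0L, 1L), each = n / 2)
  x <- cbind(exact = y,
             n1 = sample(0:1, n, TRUE), n2 = sample(0:1, n, TRUE),
             n3 = sample(0:1, n, TRUE), n4 = sample(0:1, n, TRUE))
  r <- su_rank(x, y)
  expect_identical(r$index[1], 1L)
  expect_equal(r$score[1], 1)
  # order matches sorting brute-force SU values (ties by lower index)
  d <- discretize_features(x)
  su <- vapply(seq_len(ncol(x)), function(j) su_oracle(table(d[, j], y)),
               numeric(1))
  expect_identical(r$index, order(-su, seq_len(ncol(x))))
  expect_equal(r$score, su[r$index])

  # invariant under relabelling of a feature's category codes
  x2 <- x
  x2[, 2] <- 1 - x2[, 2]
  expect_identical(su_rank(x2, y)$index, r$index)
})

test_that("two-stage selection pools mRMR survivors and applies the SU cutoff", {
  set.seed(55)
  y <- rep(c(0L, 1L), each = 60)
  x <- matrix(rnorm(120 * 200), 120, 200,
              dimnames = list(NULL, sprintf("c%03d", 1:200)))
  x[, 7] <- x[, 7] + 2.5 * y
  sel <- two_stage_select(x, y, k = 50)
  expect_lte(length(sel$selected), 50L)
  expect_true(7L %in% sel$selected)
  expect_identical(sel$su$stage[1], "su")
  expect_identical(sel$mrmr$stage[1], "mrmr")

  # threshold 0 keeps exactly the informative mRMR survivors
  expect_setequal(sel$selected,
                  sel$su$index[sel$su$score > 0])

  # determinism: identical config and inputs -> identical index lists
  sel2 <- two_stage_select(x, y, k = 50)
  expect_identical(sel$selected, sel2$selected)
  expect_identical(sel$mrmr, sel2$mrmr)

  # an impossible threshold is an actionable error
  expect_error(two_stage_select(x, y, k = 10, su_threshold = 1), "relax")
})

test_that("selection runs per category on feature objects and respects metadata", {
  b <- small_bundle()
  fr <- suppressWarnings(build_dataset(b$proteins, b$sites, "S"))
  fx <- suppressWarnings(
    assemble_features(fr, c("PP", "BE", "SS", "FF", "FA"),
                      profiles = b$profiles, vocab = b$vocab))
  sel <- two_stage_select(fx, fr$label, k = 20)
  by_cat <- table(sel$mrmr$category)
  expect_true(all(by_cat <= 20L))
  expect_identical(sort(unique(sel$mrmr$category)),
                   sort(unique(fx$meta$category)))
  # selected indices refer to existing, named columns
  expect_true(all(sel$selected %in% seq_len(ncol(fx$x))))
  expect_identical(
    sel$su$name[match(sel$selected, sel$su$index)],
    colnames(fx$x)[sel$selected])
})
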