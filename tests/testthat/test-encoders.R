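make_profile <- function(proteins) {
  do.call(rbind, lapply(names(proteins), function(pid) {
    n <- nchar(proteins[[pid]])
    data.frame(protein_id = pid, position = seq_len(n),
               ss_state = rep_len(c("C", "H", "E"), n),
               disorder_score = round(seq(0, 1, length.out = n), 4),
               stringsAsFactors = FALSE)
  }))
}

frags21 <- function() {
  b <- small_bundle()
  suppressWarnings(build_dataset(b$proteins, b$sites, "S"))[1:25, ]
}

test_that("scheme widths are 7/20/5 per window position", {
  b <- small_bundle()
  fr <- frags21()
  expect_identical(ncol(encode_physicochemical(fr)), 147L)
  expect_identical(ncol(encode_binary(fr)), 420L)
  expect_identical(ncol(encode_structural(fr, b$profiles)), 105L)
  # width scales with the flank
  for (flank in c(3L, 6L)) {
    fr_f <- suppressWarnings(build_dataset(b$proteins, b$sites, "S",
                                           flank = flank))[1:10, ]
    w <- 2L * flank + 1L
    expect_identical(ncol(encode_physicochemical(fr_f)), 7L * w)
    expect_identical(ncol(encode_binary(fr_f)), 20L * w)
    expect_identical(ncol(encode_structural(fr_f, b$profiles)), 5L * w)
  }
})

test_that("physicochemical values are direct table lookups; pads are zero", {
  props <- load_property_table()
  fr <- frags21()
  pp <- encode_physicochemical(fr, props)
  scales <- c("composition", "flexibility", "hydrophobicity", "net_charge",
              "partition", "volume", "mol_weight")
  chars <- matrix(unlist(strsplit(fr$window, "")), nrow = nrow(fr),
                  byrow = TRUE)
  for (row in c(1L, 7L)) {
    for (offset in c(-10L, 0L, 4L)) {
      res <- chars[row, offset + 11L]
      for (k in seq_along(scales)) {
        expect_identical(unname(pp[row, sprintf("PP.%+d.%s", offset, scales[k])]),
                         unname(props[res, scales[k]]))
      }
    }
  }
  # all-pad window except the centre: only the centre block can be nonzero
  lone <- manual_fragments(paste0(strrep("X", 10), "S", strrep("X", 10)))
  v <- encode_physicochemical(lone, props)
  expect_true(all(v[, -(71:77)] == 0))
})

test_that("one-hot encoding reproduces the canonical bit layout", {
  lone_a <- manual_fragments(paste0(strrep("X", 10), "S", "A", strrep("X", 9)))
  be <- encode_binary(lone_a)
  # the alanine at offset +1 is 1 followed by 19 zeros
  a_block <- be[1, sprintf("BE.%+d.%s", 1L, phosml:::AA_ALPHABET)]
  expect_identical(paste(a_block, collapse = ""), "10000000000000000000")
  # the serine centre has its single 1 at position 16
  s_block <- be[1, sprintf("BE.%+d.%s", 0L, phosml:::AA_ALPHABET)]
  expect_identical(paste(s_block, collapse = ""), "00000000000000010000")

  fr <- frags21()
  be_m <- encode_binary(fr)
  non_pad <- vapply(strsplit(fr$window, ""), function(ch) sum(ch != "X"),
                    integer(1))
  expect_identical(unname(rowSums(be_m)), as.numeric(non_pad))
  # every per-position block sums to exactly 1 (non-pad) or 0 (pad)
  for (offset in -10:10) {
    block <- be_m[, sprintf("BE.%+d.%s", offset, phosml:::AA_ALPHABET)]
    chars <- substr(fr$window, offset + 11L, offset + 11L)
    expect_identical(unname(rowSums(block)), as.numeric(chars != "X"))
  }
})

test_that("structural encoding: ASA lookup, SS one-hot, strict disorder cutoff", {
  proteins <- c(Q1 = "AAAAASAAAAA")
  prof <- data.frame(protein_id = "Q1", position = 1:11,
                     ss_state = c(rep("C", 4), "H", "E", rep("C", 5)),
                     disorder_score = c(0.5, 0.51, 0.49, rep(0.2, 8)),
                     stringsAsFactors = FALSE)
  fr <- manual_fragments("AAAAASAAAAA", protein_id = "Q1", position = 6L)
  ss <- encode_structural(fr, prof)
  expect_identical(ncol(ss), 55L)
  # disorder: strictly above 0.5 only
  expect_identical(unname(ss[1, c("SS.-5.disorder", "SS.-4.disorder",
                                  "SS.-3.disorder")]),
                   c(0, 1, 0))
  # SS one-hot sums to 1 per non-pad position, 0 per pad
  for (offset in -5:5) {
    blk <- ss[1, sprintf("SS.%+d.%s", offset, c("C", "H", "E"))]
    expect_identical(sum(blk), 1)
  }
  # ASA is the property-table lookup for the residue
  props <- load_property_table()
  expect_identical(unname(ss[1, "SS.+0.asa"]), unname(props["S", "asa"]))
  expect_identical(unname(ss[1, "SS.-1.asa"]), unname(props["A", "asa"]))

  # missing profile entry is an error naming protein and position
  expect_error(encode_structural(fr, prof[-3, ]), "Q1#3")

  # pad columns are all zero at window edges
  edge <- manual_fragments("XXXAASAAXXX", protein_id = "Q1", position = 4L)
  ss_edge <- encode_structural(edge, prof)
  expect_true(all(ss_edge[1, grepl("^SS\\.[-+]5\\.", colnames(ss_edge))] == 0))
})

test_that("membership encodings are protein-level and tolerate unannotated proteins", {
  vocab <- structure(list(
    terms = data.frame(term = sprintf("T%02d", 1:10),
                       category = rep(c("GO-BP", "KEGG", "domain",
                                        "UP_KEYWORDS", "UP_SEQ_FEATURE"), 2),
                       stringsAsFactors = FALSE),
    membership = stats::setNames(
      c(rep(list("PA"), 3), rep(list(c("PA", "PB")), 2), rep(list("PB"), 3),
        rep(list(character(0)), 2)),
      sprintf("T%02d", 1:10))), class = "phos_vocab")
  fr <- manual_fragments(rep("AAAAASAAAAA", 3),
                         protein_id = c("PA", "PA", "PB"),
                         position = rep(6L, 3))
  ff <- encode_functional(fr, vocab)   # GO-BP, KEGG, domain terms: 6 of them
  fa <- encode_annotations(fr, vocab)  # UP_* terms: 4 of them
  expect_identical(ncol(ff), 6L)
  expect_identical(ncol(fa), 4L)
  # two fragments of the same protein encode identically
  expect_identical(ff[1, ], ff[2, ])
  expect_identical(fa[1, ], fa[2, ])
  # membership sums: PA is in T1..T5, of which T1,T2,T3 are FF and T4,T5 FA;
  # PB is in T4..T8, of which T6,T7,T8 are FF
  expect_identical(sum(ff[1, ]), 3)
  expect_identical(sum(ff[3, ]), 3)
  expect_identical(sum(fa[1, ]), 2)
  expect_identical(sum(fa[3, ]), 2)
  # unannotated protein encodes all-zero with a warning
  fr_new <- manual_fragments("AAAAASAAAAA", protein_id = "PZ", position = 6L)
  expect_warning(z <- encode_functional(fr_new, vocab), "PZ")
  expect_true(all(z == 0))
})

test_that("vocabulary files round-trip with persisted term order", {
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("# comment", "TermB\tGO-MF\tP1\tP2", "TermA\tKEGG\tP2"), gmt)
  v <- read_vocabulary(gmt)
  expect_identical(v$terms$term, c("TermB", "TermA"))  # file order kept
  expect_identical(v$membership$TermA, "P2")
  writeLines(c("TermB\tBAD-CAT\tP1"), gmt)
  expect_error(read_vocabulary(gmt), "category")
})

test_that("assembled matrix concatenates schemes in fixed order with metadata", {
  b <- small_bundle()
  fr <- frags21()
  fx <- assemble_features(fr, c("PP", "BE", "SS"), profiles = b$profiles)
  expect_identical(ncol(fx$x), 672L)
  expect_identical(as.vector(table(fx$meta$category)[c("PP", "BE", "SS")]),
                   c(147L, 420L, 105L))
  expect_identical(unique(fx$meta$category), c("PP", "BE", "SS"))
  expect_identical(fx$meta$name, colnames(fx$x))
  expect_true(all(range(fx$meta$offset) == c(-10L, 10L)))
  expect_false(anyNA(fx$x))

  full <- suppressWarnings(
    assemble_features(fr, c("FF", "PP", "FA", "SS", "BE"),
                      profiles = b$profiles, vocab = b$vocab))
  n_terms <- nrow(b$vocab$terms)
  expect_identical(ncol(full$x), 672L + n_terms)
  expect_identical(unique(full$meta$category), c("PP", "BE", "SS", "FF", "FA"))

  # zero fragments: 0 rows, configured width
  none <- assemble_features(fr[0, ], c("PP", "BE"))
  expect_identical(dim(none$x), c(0L, 567L))

  # missing resources are configuration errors before encoding
  expect_error(assemble_features(fr, c("PP", "SS")), "profiles")
  expect_error(assemble_features(fr, c("PP", "FF")), "vocabulary")
})

test_that("encoding is deterministic and row order tracks fragment order", {
  b <- small_bundle()
  fr <- frags21()
  fx1 <- suppressWarnings(assemble_features(fr, c("PP", "BE", "SS", "FF", "FA"),
                                            profiles = b$profiles,
                                            vocab = b$vocab))
  fx2 <- suppressWarnings(assemble_features(fr, c("PP", "BE", "SS", "FF", "FA"),
                                            profiles = b$profiles,
                                            vocab = b$vocab))
  expect_identical(fx1$x, fx2$x)

  perm <- rev(seq_len(nrow(fr)))
  fx_rev <- suppressWarnings(assemble_features(fr[perm, ],
                                               c("PP", "BE", "SS", "FF", "FA"),
                                               profiles = b$profiles,
                                               vocab = b$vocab))
  expect_identical(fx_rev$x, fx1$x[perm, ])
})
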