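#' Load an amino-acid property table
#'
#' Reads a tab-separated table with one row per standard amino acid and the
#' eight scale columns `composition`, `flexibility`, `hydrophobicity`,
#' `net_charge`, `partition`, `volume`, `mol_weight` and `asa`.  The first
#' seven drive the physicochemical encoder; `asa` is the per-residue
#' solvent-accessibility lookup used by the structural encoder.  Each scale
#' is min-max normalised to [0, 1] over the 20 residues, so all encoded
#' values are commensurate (a requirement for RBF-kernel distances).
#'
#' @param path Path to a property TSV; `NULL` (default) loads the table
#'   bundled with the package (sources documented in its header comments).
#' @return A 21 x 8 numeric matrix (rows: 20 amino acids plus the all-zero
#'   pad row `X`) of class `"phos_properties"`; the raw table is kept in
#'   attribute `"raw"`.
#' @export
load_property_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "aa_properties.tsv", package = "phosml")
  }
  tab <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  scales <- c("composition", "flexibility", "hydrophobicity", "net_charge",
              "partition", "volume", "mol_weight", "asa")
  missing <- setdiff(c("aa", scales), names(tab))
  if (length(missing)) {
    stop("property table missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!setequal(tab$aa, AA_ALPHABET)) {
    stop("property table must have exactly one row per standard amino acid")
  }
  raw <- as.matrix(tab[scales])
  rownames(raw) <- tab$aa
  raw <- raw[AA_ALPHABET, , drop = FALSE]
  norm <- apply(raw, 2, function(v) {
    r <- range(v)
    if (diff(r) == 0) rep(0, length(v)) else (v - r[1]) / diff(r)
  })
  rownames(norm) <- AA_ALPHABET
  # Pad row: all-zero contribution in every scheme.
  norm <- rbind(norm, matrix(0, 1, ncol(norm), dimnames = list(PAD_CHAR)))
  structure(norm, raw = raw, class = c("phos_properties", class(norm)))
}

pp_scales <- function() {
  c("composition", "flexibility", "hydrophobicity", "net_charge",
    "partition", "volume", "mol_weight")
}

# Fragments -> n x (2f+1) character matrix of window residues.
window_chars <- function(fragments) {
  w <- fragments$window
  if (length(w) == 0L) {
    flank <- attr(fragments, "flank") %||% 10L
    return(matrix(character(0), 0L, 2L * flank + 1L))
  }
  wid <- unique(nchar(w))
  if (length(wid) != 1L) stop("fragments have inconsistent window lengths")
  matrix(unlist(strsplit(w, "")), nrow = length(w), ncol = wid, byrow = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

offset_labels <- function(flank) sprintf("%+d", seq(-flank, flank))

#' Encode fragments under the physicochemical-property scheme (PP)
#'
#' Each window position contributes the 7 normalised scale values of its
#' residue, concatenated position-by-position (offset order, then scale
#' order), giving `7 * (2 * flank + 1)` columns -- 147 for the default
#' 21-residue windows.  Pad positions contribute zeros.
#'
#' @param fragments A `phos_fragments` data.frame.
#' @param properties A `phos_properties` matrix from [load_property_table()].
#' @return Numeric matrix, one row per fragment; column names
#'   `PP.<offset>.<scale>`.
#' @export
encode_physicochemical <- function(fragments, properties = load_property_table()) {
  chars <- window_chars(fragments)
  flank <- (ncol(chars) - 1L) %/% 2L
  offs <- offset_labels(flank)
  scales <- pp_scales()
  blocks <- lapply(seq_len(ncol(chars)), function(i) {
    m <- properties[chars[, i], scales, drop = FALSE]
    colnames(m) <- sprintf("PP.%s.%s", offs[i], scales)
    m
  })
  out <- do.call(cbind, blocks)
  rownames(out) <- NULL
  out
}

#' Encode fragments under the one-hot sequence scheme (BE)
#'
#' Every window position becomes a 20-bit indicator over the amino acids in
#' alphabetical one-letter order (A, C, D, ..., Y): alanine is
#' `10000000000000000000`, serine `00000000000000010000`.  Pads contribute
#' 20 zeros.  Width is `20 * (2 * flank + 1)` -- 420 for 21-mers.
#'
#' @inheritParams encode_physicochemical
#' @return Numeric 0/1 matrix with column names `BE.<offset>.<aa>`.
#' @export
encode_binary <- function(fragments) {
  chars <- window_chars(fragments)
  flank <- (ncol(chars) - 1L) %/% 2L
  offs <- offset_labels(flank)
  blocks <- lapply(seq_len(ncol(chars)), function(i) {
    m <- outer(chars[, i], AA_ALPHABET, `==`) + 0
    colnames(m) <- sprintf("BE.%s.%s", offs[i], AA_ALPHABET)
    m
  })
  out <- do.call(cbind, blocks)
  rownames(out) <- NULL
  out
}

#' Read per-residue structural profiles
#'
#' Parses a tab-separated table with columns `protein_id`, `position`,
#' `ss_state` (C/H/E) and `disorder_score` in [0, 1], as produced by
#' secondary-structure and disorder predictors.  Lines starting with `#` are
#' skipped.
#'
#' @param path Path to the profile TSV.
#' @return A data.frame of class `"phos_profiles"`.
#' @export
read_structural_profiles <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    colClasses = c(protein_id = "character",
                                   ss_state = "character"),
                    stringsAsFactors = FALSE)
  required <- c("protein_id", "position", "ss_state", "disorder_score")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("profile table missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(!tab$ss_state %in% SS_STATES)) {
    stop("ss_state must be one of C, H, E")
  }
  if (any(tab$disorder_score < 0 | tab$disorder_score > 1)) {
    stop("disorder_score must lie in [0, 1]")
  }
  tab$position <- as.integer(tab$position)
  class(tab) <- c("phos_profiles", "data.frame")
  tab
}

#' Encode fragments under the structural scheme (SS)
#'
#' Each window position contributes 5 values: the residue's normalised
#' maximum accessible surface area (from the property table), a 3-bit
#' one-hot over the secondary-structure states coil/helix/strand, and a
#' disorder flag that is 1 iff the residue's disorder score exceeds
#' `disorder_cutoff` (strictly above; a score of exactly 0.5 counts as
#' ordered).  Pads contribute 5 zeros.  Width is `5 * (2 * flank + 1)` --
#' 105 for 21-mers.
#'
#' @inheritParams encode_physicochemical
#' @param profiles A `phos_profiles` data.frame covering every non-pad
#'   residue of every fragment; a missing residue is an error naming the
#'   protein and position.
#' @param disorder_cutoff Disorder threshold (default 0.5).
#' @return Numeric matrix with column names `SS.<offset>.<asa|C|H|E|disorder>`.
#' @export
encode_structural <- function(fragments, profiles,
                              properties = load_property_table(),
                              disorder_cutoff = 0.5) {
  chars <- window_chars(fragments)
  flank <- (ncol(chars) - 1L) %/% 2L
  offs <- offset_labels(flank)
  key <- paste0(profiles$protein_id, "#", profiles$position)
  ss_by_key <- stats::setNames(profiles$ss_state, key)
  dis_by_key <- stats::setNames(profiles$disorder_score, key)
  n <- nrow(chars)
  blocks <- vector("list", ncol(chars))
  for (i in seq_len(ncol(chars))) {
    off <- i - flank - 1L
    block <- matrix(0, n, 5L,
                    dimnames = list(NULL,
                                    sprintf("SS.%s.%s", offs[i],
                                            c("asa", SS_STATES, "disorder"))))
    live <- which(chars[, i] != PAD_CHAR)
    if (length(live)) {
      k <- paste0(fragments$protein_id[live], "#", fragments$position[live] + off)
      miss <- which(is.na(ss_by_key[k]))
      if (length(miss)) {
        stop("structural profile missing residue ", k[miss[1]],
             " (protein#position)")
      }
      block[live, 1L] <- properties[chars[live, i], "asa"]
      block[cbind(live, 1L + match(ss_by_key[k], SS_STATES))] <- 1
      block[live, 5L] <- as.numeric(dis_by_key[k] > disorder_cutoff)
    }
    blocks[[i]] <- block
  }
  do.call(cbind, blocks)
}

#' Read a term-membership vocabulary
#'
#' Parses GMT-style lines `term<TAB>category<TAB>protein_id...` into an
#' ordered vocabulary.  Term order is the file order and is part of the
#' encoding contract: feature-column identity depends on it.  Categories
#' GO-BP, GO-MF, GO-CC, domain and KEGG feed the functional-feature (FF)
#' scheme; UP_SEQ_FEATURE and UP_KEYWORDS feed the functional-annotation
#' (FA) scheme.
#'
#' @param path Path to the vocabulary file.
#' @return A list of class `"phos_vocab"` with `terms` (data.frame `term`,
#'   `category`) and `membership` (named list term -> character vector of
#'   protein ids).
#' @export
read_vocabulary <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 2L)
  if (length(short)) {
    stop("vocabulary line(s) with fewer than 2 fields: ",
         paste(utils::head(short, 5), collapse = ", "))
  }
  term <- vapply(parts, `[[`, character(1), 1L)
  category <- vapply(parts, `[[`, character(1), 2L)
  if (anyDuplicated(term)) stop("duplicate vocabulary term(s)")
  bad <- which(!category %in% c(FF_CATEGORIES, FA_CATEGORIES))
  if (length(bad)) {
    stop("unknown vocabulary category: ", category[bad[1]])
  }
  membership <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(membership) <- term
  structure(list(terms = data.frame(term = term, category = category,
                                    stringsAsFactors = FALSE),
                 membership = membership),
            class = "phos_vocab")
}

# Binary membership encoding over a subset of vocabulary categories.
# One column per term, fragment-level: every fragment of a protein gets that
# protein's membership vector.
encode_membership <- function(fragments, vocab, categories, prefix) {
  keep <- vocab$terms$category %in% categories
  terms <- vocab$terms$term[keep]
  n <- nrow(fragments)
  out <- matrix(0, n, length(terms),
                dimnames = list(NULL, if (length(terms))
                  sprintf("%s.%s", prefix, terms) else character(0)))
  if (n == 0L || length(terms) == 0L) return(out)
  all_members <- unique(unlist(vocab$membership[terms], use.names = FALSE))
  orphan <- setdiff(unique(fragments$protein_id), all_members)
  if (length(orphan)) {
    warning("protein(s) absent from all vocabulary terms (encoded all-zero): ",
            paste(utils::head(orphan, 5), collapse = ", "))
  }
  for (j in seq_along(terms)) {
    out[, j] <- as.numeric(fragments$protein_id %in% vocab$membership[[terms[j]]])
  }
  out
}

#' Encode fragments under the functional-feature scheme (FF)
#'
#' One binary column per GO-BP, GO-MF, GO-CC, domain and KEGG term, in the
#' vocabulary's persisted order: 1 iff the fragment's parent protein is a
#' member of the term.  Membership is protein-level, so all fragments of a
#' protein share the same vector; proteins absent from every term encode as
#' all-zero with a warning.
#'
#' @inheritParams encode_physicochemical
#' @param vocab A `phos_vocab` from [read_vocabulary()].
#' @return Numeric 0/1 matrix with column names `FF.<term>`.
#' @export
encode_functional <- function(fragments, vocab) {
  encode_membership(fragments, vocab, FF_CATEGORIES, "FF")
}

#' Encode fragments under the functional-annotation scheme (FA)
#'
#' As [encode_functional()], over the UP_SEQ_FEATURE and UP_KEYWORDS
#' categories.
#'
#' @inheritParams encode_functional
#' @return Numeric 0/1 matrix with column names `FA.<term>`.
#' @export
encode_annotations <- function(fragments, vocab) {
  encode_membership(fragments, vocab, FA_CATEGORIES, "FA")
}

#' Assemble the combined feature matrix
#'
#' Encodes fragments under the requested schemes and concatenates the
#' blocks in the fixed order PP, BE, SS, FF, FA.  With PP, BE and SS active
#' on 21-mers the width is 147 + 420 + 105 = 672; FF/FA widths equal the
#' vocabulary sizes.  Resources required by an active scheme are checked
#' before any encoding.
#'
#' @inheritParams encode_physicochemical
#' @param schemes Character subset of `c("PP","BE","SS","FF","FA")`.
#' @param profiles Structural profiles (required when `"SS"` is active).
#' @param vocab Vocabulary (required when `"FF"` or `"FA"` is active).
#' @param disorder_cutoff Passed to [encode_structural()].
#' @return A list of class `"phos_features"`: `x` (numeric matrix), `meta`
#'   (data.frame `name`, `category`, `offset`; offset `NA` for
#'   fragment-level columns) and `fragments`.
#' @export
assemble_features <- function(fragments, schemes = c("PP", "BE", "SS"),
                              properties = load_property_table(),
                              profiles = NULL, vocab = NULL,
                              disorder_cutoff = 0.5) {
  schemes <- match.arg(schemes, SCHEME_ORDER, several.ok = TRUE)
  schemes <- SCHEME_ORDER[SCHEME_ORDER %in% schemes]
  if ("SS" %in% schemes && is.null(profiles)) {
    stop("scheme SS is active but no structural profiles were supplied")
  }
  if (any(c("FF", "FA") %in% schemes) && is.null(vocab)) {
    stop("scheme FF/FA is active but no vocabulary was supplied")
  }
  blocks <- list()
  for (s in schemes) {
    blocks[[s]] <- switch(s,
      PP = encode_physicochemical(fragments, properties),
      BE = encode_binary(fragments),
      SS = encode_structural(fragments, profiles, properties, disorder_cutoff),
      FF = encode_functional(fragments, vocab),
      FA = encode_annotations(fragments, vocab))
  }
  x <- do.call(cbind, blocks)
  if (is.null(x)) x <- matrix(numeric(0), nrow(fragments), 0L)
  meta <- do.call(rbind, lapply(names(blocks), function(s) {
    nm <- colnames(blocks[[s]])
    parts <- strsplit(nm, ".", fixed = TRUE)
    offset <- if (s %in% c("PP", "BE", "SS")) {
      as.integer(vapply(parts, `[[`, character(1), 2L))
    } else rep(NA_integer_, length(nm))
    data.frame(name = nm, category = s, offset = offset,
               stringsAsFactors = FALSE)
  }))
  if (is.null(meta)) {
    meta <- data.frame(name = character(0), category = character(0),
                       offset = integer(0), stringsAsFactors = FALSE)
  }
  structure(list(x = x, meta = meta, fragments = fragments),
            class = "phos_features")
}

#' @export
print.phos_features <- function(x, ...) {
  cat(sprintf("phos_features: %d fragments x %d features\n",
              nrow(x$x), ncol(x$x)))
  if (nrow(x$meta)) {
    tab <- table(factor(x$meta$category, levels = SCHEME_ORDER))
    tab <- tab[tab > 0]
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = "   "),
        "\n", sep = "")
  }
  invisible(x)
}
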