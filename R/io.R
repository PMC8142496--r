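#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and the header token before the first whitespace
#' becomes the record id.  Parsing is delegated to
#' [Biostrings::readAAStringSet()] after a light structural check so that a
#' file whose first record lacks a `>` header line is rejected with the
#' offending line number.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences; names are protein ids.  An
#'   empty file yields an empty vector.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 description", "mksty", ">P2", "AAAA"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    return(stats::setNames(character(0), character(0)))
  }
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("malformed FASTA: expected '>' header at line ", first,
         " of ", path)
  }
  aas <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aas))
  ids <- vapply(strsplit(names(aas), "\\s+"), `[[`, character(1), 1L)
  if (any(!nzchar(ids))) {
    stop("malformed FASTA: empty record id in ", path)
  }
  stats::setNames(unname(seqs), ids)
}

#' Read a site-annotation table
#'
#' Expects a tab-separated file with header columns `protein_id`, `position`,
#' `residue` and `label` (1 = phosphorylated, 0 = not).  Positions are
#' 1-based.  Lines starting with `#` are ignored.  When `proteins` is
#' supplied, each row is validated against the sequence: out-of-range
#' positions and residue mismatches are errors naming the offending rows.
#'
#' @param path Path to the TSV file.
#' @param proteins Optional named character vector of sequences (as returned
#'   by [read_fasta()]) used for validation.
#' @return A data.frame with columns `protein_id`, `position`, `residue`,
#'   `label`.
#' @export
read_site_table <- function(path, proteins = NULL) {
  tab <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    colClasses = c(protein_id = "character",
                                   residue = "character"),
                    stringsAsFactors = FALSE)
  required <- c("protein_id", "position", "residue", "label")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("site table is missing column(s): ", paste(missing, collapse = ", "))
  }
  tab <- tab[required]
  tab$position <- as.integer(tab$position)
  validate_sites(tab, proteins)
  tab
}

# Shared row-level validation for site annotations.
validate_sites <- function(sites, proteins = NULL) {
  bad_res <- which(!sites$residue %in% c("S", "T", "Y"))
  if (length(bad_res)) {
    stop("residue must be one of S, T, Y; offending row(s): ",
         paste(utils::head(bad_res, 5), collapse = ", "))
  }
  bad_lab <- which(!sites$label %in% c(0L, 1L))
  if (length(bad_lab)) {
    stop("label must be 0 or 1; offending row(s): ",
         paste(utils::head(bad_lab, 5), collapse = ", "))
  }
  if (!is.null(proteins)) {
    unknown <- setdiff(unique(sites$protein_id), names(proteins))
    if (length(unknown)) {
      stop("annotation references unknown protein id(s): ",
           paste(unknown, collapse = ", "))
    }
    len <- nchar(proteins)[sites$protein_id]
    oob <- which(sites$position < 1L | sites$position > len)
    if (length(oob)) {
      stop("position out of range for row(s): ",
           paste(utils::head(oob, 5), collapse = ", "))
    }
    at <- substr(proteins[sites$protein_id], sites$position, sites$position)
    mism <- which(at != sites$residue)
    if (length(mism)) {
      stop("annotated residue disagrees with sequence for row(s): ",
           paste(utils::head(mism, 5), collapse = ", "))
    }
  }
  invisible(sites)
}

#' Enumerate candidate phospho-acceptor positions in a sequence
#'
#' @param sequence A single protein sequence string.
#' @param residues Subset of `c("S", "T", "Y")` to scan for.
#' @return Ascending 1-based integer positions whose residue is in
#'   `residues`.
#' @export
#' @examples
#' enumerate_candidate_sites("MKSTY")          # 3 4 5
#' enumerate_candidate_sites("MKSTY", "Y")     # 5
enumerate_candidate_sites <- function(sequence, residues = c("S", "T", "Y")) {
  stopifnot(length(sequence) == 1L, length(residues) >= 1L)
  residues <- match.arg(residues, c("S", "T", "Y"), several.ok = TRUE)
  chars <- strsplit(sequence, "")[[1]]
  which(chars %in% residues)
}

#' Extract a fixed-length window around a candidate site
#'
#' Returns the `2 * flank + 1` residues centred on `position`.  Positions
#' beyond either terminus are padded with `'X'`; non-standard residues inside
#' the window (U, B, Z, `*`, ...) are likewise replaced by `'X'` with a
#' warning, so the window alphabet is always the 20 standard codes plus the
#' pad.
#'
#' @param sequence A single protein sequence string.
#' @param position 1-based position of the central residue, which must be
#'   S, T or Y.
#' @param flank Number of residues on each side of the centre (default 10,
#'   i.e. 21-residue windows).
#' @return A character string of length `2 * flank + 1`.
#' @export
#' @examples
#' extract_fragment("MKSTY", 3, flank = 2)  # "MKSTY"
#' extract_fragment("MKSTY", 5, flank = 2)  # "STYXX"
extract_fragment <- function(sequence, position, flank = 10L) {
  stopifnot(length(sequence) == 1L, flank >= 1L)
  n <- nchar(sequence)
  if (position < 1L || position > n) {
    stop("position ", position, " outside sequence of length ", n)
  }
  centre <- substr(sequence, position, position)
  if (!centre %in% c("S", "T", "Y")) {
    stop("central residue at position ", position, " is '", centre,
         "', not one of S, T, Y")
  }
  lo <- position - flank
  hi <- position + flank
  left_pad <- max(0L, 1L - lo)
  right_pad <- max(0L, hi - n)
  core <- substr(sequence, max(1L, lo), min(n, hi))
  frag <- paste0(strrep(PAD_CHAR, left_pad), core, strrep(PAD_CHAR, right_pad))
  chars <- strsplit(frag, "")[[1]]
  odd <- !chars %in% c(AA_ALPHABET, PAD_CHAR)
  if (any(odd)) {
    warning("non-standard residue(s) ",
            paste(unique(chars[odd]), collapse = ", "),
            " in window at position ", position, " replaced by '", PAD_CHAR, "'")
    chars[odd] <- PAD_CHAR
    frag <- paste(chars, collapse = "")
  }
  frag
}

#' Build a labelled fragment dataset for one central-residue type
#'
#' Positives are the annotated (`label == 1`) sites of the requested residue
#' type.  Under the default `"unannotated"` policy, negatives are every other
#' enumerated site of that residue type in proteins that carry at least one
#' positive annotation (of any residue type); under `"annotated"` only
#' explicit `label == 0` rows become negatives.  Each residue type (S, T, Y)
#' yields its own dataset.
#'
#' @param proteins Named character vector of sequences.
#' @param sites Site-annotation data.frame (see [read_site_table()]).
#' @param residue Central residue type for this dataset: "S", "T" or "Y".
#' @param flank Window half-width (default 10).
#' @param negative_policy `"unannotated"` (default) or `"annotated"`.
#' @param drop_edge_sites If `TRUE`, discard sites whose window would need
#'   terminal padding instead of padding with `'X'`.
#' @return A data.frame of class `"phos_fragments"` with columns
#'   `protein_id`, `position`, `residue`, `label`, `window`; the flank is
#'   stored as an attribute.
#' @export
build_dataset <- function(proteins, sites, residue = c("S", "T", "Y"),
                          flank = 10L,
                          negative_policy = c("unannotated", "annotated"),
                          drop_edge_sites = FALSE) {
  residue <- match.arg(residue)
  negative_policy <- match.arg(negative_policy)
  validate_sites(sites, proteins)

  pos_rows <- sites[sites$label == 1L & sites$residue == residue, , drop = FALSE]
  # Proteins eligible to contribute negatives: those carrying >= 1 positive
  # annotation of any residue type.
  pos_proteins <- unique(sites$protein_id[sites$label == 1L])

  if (negative_policy == "unannotated") {
    neg <- lapply(pos_proteins, function(pid) {
      cand <- enumerate_candidate_sites(proteins[[pid]], residue)
      cand <- setdiff(cand, pos_rows$position[pos_rows$protein_id == pid])
      if (length(cand)) {
        data.frame(protein_id = pid, position = cand, residue = residue,
                   label = 0L, stringsAsFactors = FALSE)
      }
    })
    neg_rows <- do.call(rbind, neg)
  } else {
    neg_rows <- sites[sites$label == 0L & sites$residue == residue, , drop = FALSE]
  }
  out <- rbind(pos_rows[c("protein_id", "position", "residue", "label")],
               neg_rows[c("protein_id", "position", "residue", "label")])
  if (is.null(out) || nrow(out) == 0L) {
    out <- data.frame(protein_id = character(0), position = integer(0),
                      residue = character(0), label = integer(0),
                      window = character(0), stringsAsFactors = FALSE)
    return(as_phos_fragments(out, flank))
  }
  out <- out[order(out$protein_id, out$position), , drop = FALSE]
  rownames(out) <- NULL
  if (drop_edge_sites) {
    len <- nchar(proteins)[out$protein_id]
    keep <- out$position - flank >= 1L & out$position + flank <= len
    out <- out[keep, , drop = FALSE]
  }
  out$window <- mapply(function(pid, pos) {
    extract_fragment(proteins[[pid]], pos, flank)
  }, out$protein_id, out$position, USE.NAMES = FALSE)
  as_phos_fragments(out, flank)
}

as_phos_fragments <- function(df, flank) {
  attr(df, "flank") <- as.integer(flank)
  class(df) <- c("phos_fragments", "data.frame")
  df
}

#' @export
print.phos_fragments <- function(x, ...) {
  flank <- attr(x, "flank")
  cat(sprintf("phos_fragments: %d fragments (window %d, flank %d)\n",
              nrow(x), 2L * flank + 1L, flank))
  if (nrow(x)) {
    tab <- table(factor(x$label, levels = c(0L, 1L)))
    cat(sprintf("  positives: %d   negatives: %d\n", tab[["1"]], tab[["0"]]))
  }
  invisible(x)
}

#' Stratified train/test split
#'
#' Splits fragments into train and test partitions, stratified by label so
#' both sides preserve the class balance.  Within each class,
#' `round(train_fraction * n_class)` instances go to training.  Reproducible
#' under a fixed seed.
#'
#' @param fragments A `phos_fragments` data.frame (or any data.frame with a
#'   `label` column).
#' @param train_fraction Fraction assigned to training (default 0.8).
#' @param seed Integer RNG seed.
#' @param stratify Set `FALSE` to split without stratification (needed when
#'   a class has fewer than 2 instances).
#' @return A list of class `"phos_split"` with elements `train`, `test`
#'   (both subsets of `fragments`) and `seed`.
#' @export
split_dataset <- function(fragments, train_fraction = 0.8, seed = 1L,
                          stratify = TRUE) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  n <- nrow(fragments)
  target <- floor(train_fraction * n + 0.5)
  idx_train <- integer(0)
  if (stratify) {
    counts <- table(fragments$label)
    if (any(counts < 2L)) {
      stop("fewer than 2 instances in a class; rerun with stratify = FALSE")
    }
    # Largest-remainder allocation so the stratum sizes sum to the overall
    # round(train_fraction * n) target.
    base <- floor(train_fraction * counts)
    rem <- train_fraction * counts - base
    extra <- target - sum(base)
    take <- base
    if (extra > 0) {
      bump <- order(-rem)[seq_len(extra)]
      take[bump] <- take[bump] + 1L
    }
    set.seed(seed)
    for (i in seq_along(counts)) {
      idx <- which(fragments$label == as.integer(names(counts)[i]))
      idx_train <- c(idx_train, sample(idx, take[i]))
    }
  } else {
    set.seed(seed)
    idx_train <- sample(n, target)
  }
  idx_train <- sort(idx_train)
  structure(list(train = fragments[idx_train, , drop = FALSE],
                 test = fragments[setdiff(seq_len(n), idx_train), , drop = FALSE],
                 seed = as.integer(seed)),
            class = "phos_split")
}

#' @export
print.phos_split <- function(x, ...) {
  cat(sprintf("phos_split: %d train / %d test (seed %d)\n",
              nrow(x$train), nrow(x$test), x$seed))
  invisible(x)
}
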