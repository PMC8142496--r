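#' Configuration for the synthetic fixture generator
#'
#' Defines a self-contained synthetic study: random protein sequences
#' (uniform over the 20 residues by default), labelled S/T/Y sites, a
#' per-residue structural profile, annotation vocabularies and the bundled
#' property table.  Class-conditional signal is planted through four knobs
#' so every pipeline stage -- encoding, selection, modelling, evaluation --
#' has something real to find:
#'
#' * composition bias: near a positive site, flanking residues at
#'   `bias_offsets` are drawn from `motif_residues` with probability
#'   `composition_bias`;
#' * disorder enrichment: residues within `disorder_halfwidth` of a positive
#'   centre draw a high-disorder score (Beta(6, 2)) with probability
#'   `disorder_enrichment`, against a low-disorder background (Beta(2, 6));
#' * secondary-structure bias: residues within `coil_halfwidth` of a
#'   positive centre are coil with probability `coil_bias` (background
#'   C/H/E = 0.45/0.35/0.20);
#' * annotation enrichment: proteins are "positive-rich" with probability
#'   `enriched_fraction` (their candidate sites are positive with
#'   probability `p_pos_rich`, others `p_pos_poor`), and the
#'   `n_informative_terms` informative terms include positive-rich proteins
#'   with probability `term_prob_rich` versus `term_prob_poor`; decoy terms
#'   include every protein with probability `decoy_prob`.
#'
#' Setting `composition_bias`, `disorder_enrichment` and the term/coil
#' biases to their background values removes all signal (a null bundle).
#'
#' @param n_proteins Number of proteins (default 200, giving on the order
#'   of a thousand fragments per residue-type dataset -- enough that pooled
#'   out-of-fold AUC estimates have a standard error well under 0.025).
#' @param length_range Min/max protein length (default 60-140).
#' @param enriched_fraction Fraction of positive-rich proteins (0.5).
#' @param p_pos_rich,p_pos_poor Per-site positive probability by protein
#'   class (0.8 / 0.2; overall balance about 50/50).
#' @param composition_bias,motif_residues,bias_offsets Composition knob
#'   (0.6; P/R/D; offsets -3..-1, 1..3).
#' @param disorder_enrichment,disorder_halfwidth Disorder knob (0.8; 3).
#' @param coil_bias,coil_halfwidth Secondary-structure knob (0.75; 2).
#' @param n_informative_terms,n_decoy_terms Vocabulary sizes (6 / 14).
#' @param term_prob_rich,term_prob_poor,decoy_prob Membership odds
#'   (0.85 / 0.10 / 0.30).
#' @param seed Integer seed; recorded in every output file.
#' @return A list of class `"synth_config"`.
#' @export
synth_config <- function(n_proteins = 200L, length_range = c(60L, 140L),
                         enriched_fraction = 0.5,
                         p_pos_rich = 0.8, p_pos_poor = 0.2,
                         composition_bias = 0.6,
                         motif_residues = c("P", "R", "D"),
                         bias_offsets = c(-3L, -2L, -1L, 1L, 2L, 3L),
                         disorder_enrichment = 0.8, disorder_halfwidth = 3L,
                         coil_bias = 0.75, coil_halfwidth = 2L,
                         n_informative_terms = 6L, n_decoy_terms = 14L,
                         term_prob_rich = 0.85, term_prob_poor = 0.10,
                         decoy_prob = 0.30,
                         seed = 101L) {
  cfg <- as.list(environment())
  probs <- c(enriched_fraction, p_pos_rich, p_pos_poor, composition_bias,
             disorder_enrichment, coil_bias, term_prob_rich, term_prob_poor,
             decoy_prob)
  stopifnot(all(probs >= 0 & probs <= 1), n_proteins >= 1L,
            length_range[1] >= 21L, length_range[2] >= length_range[1])
  class(cfg) <- "synth_config"
  cfg
}

# Vocabulary categories cycled over informative then decoy terms.
synth_term_table <- function(cfg) {
  cats <- c("GO-BP", "GO-MF", "GO-CC", "KEGG", "domain",
            "UP_KEYWORDS", "UP_SEQ_FEATURE")
  n_inf <- cfg$n_informative_terms
  n_dec <- cfg$n_decoy_terms
  data.frame(
    term = c(if (n_inf) sprintf("T_INF%02d", seq_len(n_inf)),
             if (n_dec) sprintf("T_DEC%02d", seq_len(n_dec))),
    category = rep_len(cats, n_inf + n_dec),
    informative = rep(c(TRUE, FALSE), c(n_inf, n_dec)),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic study in memory
#'
#' Draws the full object bundle described by [synth_config()] without
#' touching disk.  Fully reproducible: the configured seed initialises the
#' RNG and identical configs give identical bundles.
#'
#' @param config A `synth_config`.
#' @return A list of class `"synth_bundle"`: `proteins` (named character
#'   vector), `sites` (annotation data.frame), `profiles`
#'   (`phos_profiles`), `vocab` (`phos_vocab`), `properties`, `truth` (list
#'   with the planted feature-column names per signal, protein classes and
#'   the config) .
#' @export
synth_bundle <- function(config = synth_config()) {
  cfg <- config
  set.seed(cfg$seed)
  ids <- sprintf("SP%04d", seq_len(cfg$n_proteins))
  lens <- sample(seq(cfg$length_range[1], cfg$length_range[2]),
                 cfg$n_proteins, replace = TRUE)
  rich <- runif(cfg$n_proteins) < cfg$enriched_fraction
  names(rich) <- ids

  seq_chars <- lapply(lens, function(n) sample(AA_ALPHABET, n, replace = TRUE))
  names(seq_chars) <- ids

  # Choose positive centres per protein, then implant the composition motif
  # around them (never overwriting a chosen centre), and only afterwards
  # re-enumerate candidates so negatives reflect the final sequences.
  sites <- vector("list", cfg$n_proteins)
  pos_centres <- vector("list", cfg$n_proteins)
  for (i in seq_along(ids)) {
    chars <- seq_chars[[i]]
    cand <- which(chars %in% c("S", "T", "Y"))
    p <- if (rich[i]) cfg$p_pos_rich else cfg$p_pos_poor
    pos <- cand[runif(length(cand)) < p]
    for (centre in pos) {
      for (off in cfg$bias_offsets) {
        at <- centre + off
        if (at >= 1L && at <= length(chars) && !(at %in% pos) &&
            runif(1) < cfg$composition_bias) {
          chars[at] <- sample(cfg$motif_residues, 1L)
        }
      }
    }
    seq_chars[[i]] <- chars
    pos_centres[[i]] <- pos
    cand <- which(chars %in% c("S", "T", "Y"))
    neg <- setdiff(cand, pos)
    sites[[i]] <- data.frame(
      protein_id = ids[i],
      position = c(pos, neg),
      residue = chars[c(pos, neg)],
      label = rep(c(1L, 0L), c(length(pos), length(neg))),
      stringsAsFactors = FALSE)
  }
  proteins <- vapply(seq_chars, paste, character(1), collapse = "")
  sites <- do.call(rbind, sites)
  sites <- sites[order(sites$protein_id, sites$position), , drop = FALSE]
  rownames(sites) <- NULL

  # Per-residue structural profile, independent across residues.
  profiles <- do.call(rbind, lapply(seq_along(ids), function(i) {
    n <- length(seq_chars[[i]])
    near <- rep(FALSE, n)
    near_c <- rep(FALSE, n)
    for (centre in pos_centres[[i]]) {
      lo <- max(1L, centre - cfg$disorder_halfwidth)
      hi <- min(n, centre + cfg$disorder_halfwidth)
      near[lo:hi] <- TRUE
      lo <- max(1L, centre - cfg$coil_halfwidth)
      hi <- min(n, centre + cfg$coil_halfwidth)
      near_c[lo:hi] <- TRUE
    }
    hi_dis <- near & runif(n) < cfg$disorder_enrichment
    dis <- ifelse(hi_dis, rbeta(n, 6, 2), rbeta(n, 2, 6))
    ss <- ifelse(near_c & runif(n) < cfg$coil_bias, "C",
                 sample(SS_STATES, n, replace = TRUE,
                        prob = c(0.45, 0.35, 0.20)))
    data.frame(protein_id = ids[i], position = seq_len(n), ss_state = ss,
               disorder_score = round(dis, 4), stringsAsFactors = FALSE)
  }))
  class(profiles) <- c("phos_profiles", "data.frame")

  # Vocabulary with enrichment for positive-rich proteins.
  tt <- synth_term_table(cfg)
  membership <- lapply(seq_len(nrow(tt)), function(j) {
    p <- if (tt$informative[j]) {
      ifelse(rich, cfg$term_prob_rich, cfg$term_prob_poor)
    } else rep(cfg$decoy_prob, length(ids))
    ids[runif(length(ids)) < p]
  })
  names(membership) <- tt$term
  vocab <- structure(list(terms = tt[c("term", "category")],
                          membership = membership),
                     class = "phos_vocab")

  truth <- list(
    seed = cfg$seed,
    planted = synth_planted_columns(cfg, tt),
    protein_class = ifelse(rich, "rich", "poor"),
    config = cfg)

  structure(list(proteins = proteins, sites = sites, profiles = profiles,
                 vocab = vocab, properties = load_property_table(),
                 truth = truth),
            class = "synth_bundle")
}

# Feature-column names the signal knobs make informative, in the naming
# scheme of the encoders.  Empty when all knobs sit at background levels.
synth_planted_columns <- function(cfg, tt = synth_term_table(cfg)) {
  planted <- character(0)
  if (cfg$composition_bias > 0) {
    planted <- c(planted, as.vector(outer(
      sprintf("%+d", cfg$bias_offsets), cfg$motif_residues,
      function(o, r) sprintf("BE.%s.%s", o, r))))
  }
  bg_dis <- 0  # background enrichment probability
  if (cfg$disorder_enrichment > bg_dis) {
    offs <- seq(-cfg$disorder_halfwidth, cfg$disorder_halfwidth)
    planted <- c(planted, sprintf("SS.%+d.disorder", offs))
  }
  if (cfg$coil_bias > 0.45) {
    offs <- seq(-cfg$coil_halfwidth, cfg$coil_halfwidth)
    planted <- c(planted, sprintf("SS.%+d.C", offs))
  }
  inf <- tt[tt$informative, , drop = FALSE]
  if (nrow(inf) && cfg$term_prob_rich != cfg$term_prob_poor) {
    prefix <- ifelse(inf$category %in% FA_CATEGORIES, "FA", "FF")
    planted <- c(planted, sprintf("%s.%s", prefix, inf$term))
  }
  planted
}

#' Write a synthetic fixture bundle to disk
#'
#' Materialises a [synth_bundle()] in the on-disk formats the pipeline
#' reads: `proteins.fasta`, `sites.tsv`, `profiles.tsv`, `vocab.gmt`,
#' `properties.tsv` and `truth.json` (seed, config and planted feature
#' columns).  Every table carries the seed in a `#` header line.
#' Byte-identical across runs with the same config.
#'
#' @param config A `synth_config`.
#' @param out_dir Output directory.
#' @param force Overwrite an existing non-empty directory (default FALSE:
#'   collision is an error).
#' @return The bundle (invisibly), with `out_dir` attached.
#' @export
generate_bundle <- function(config = synth_config(), out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force) {
    stop("output directory ", out_dir,
         " exists and is not empty; use force = TRUE to overwrite")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  bundle <- synth_bundle(config)
  hdr <- sprintf("# generated by phosml synth (seed: %d)", config$seed)

  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(bundle$proteins),
    file.path(out_dir, "proteins.fasta"))

  write_tsv_with_header <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_tsv_with_header(bundle$sites, file.path(out_dir, "sites.tsv"))
  write_tsv_with_header(as.data.frame(bundle$profiles),
                        file.path(out_dir, "profiles.tsv"))

  gmt <- vapply(seq_len(nrow(bundle$vocab$terms)), function(j) {
    paste(c(bundle$vocab$terms$term[j], bundle$vocab$terms$category[j],
            bundle$vocab$membership[[j]]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, gmt), file.path(out_dir, "vocab.gmt"))

  file.copy(system.file("extdata", "aa_properties.tsv", package = "phosml"),
            file.path(out_dir, "properties.tsv"), overwrite = TRUE)

  jsonlite::write_json(
    list(seed = config$seed,
         planted = bundle$truth$planted,
         protein_class = as.list(bundle$truth$protein_class),
         config = config[setdiff(names(config), character(0))]),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)

  attr(bundle, "out_dir") <- out_dir
  invisible(bundle)
}

#' Summarise a fixture bundle directory
#'
#' Re-reads the bundle files and reports site counts per residue type, class
#' balance and the planted signal columns.
#'
#' @param out_dir Directory written by [generate_bundle()].
#' @return A list: `n_proteins`, `sites` (per-residue positive/negative
#'   counts), `positive_fraction`, `planted`, `seed`.
#' @export
describe_bundle <- function(out_dir) {
  files <- c("proteins.fasta", "sites.tsv", "profiles.tsv", "vocab.gmt",
             "truth.json")
  missing <- files[!file.exists(file.path(out_dir, files))]
  if (length(missing)) {
    stop("bundle at ", out_dir, " is missing file(s): ",
         paste(missing, collapse = ", "))
  }
  proteins <- read_fasta(file.path(out_dir, "proteins.fasta"))
  sites <- read_site_table(file.path(out_dir, "sites.tsv"), proteins)
  truth <- jsonlite::read_json(file.path(out_dir, "truth.json"),
                               simplifyVector = TRUE)
  counts <- table(residue = sites$residue, label = sites$label)
  list(n_proteins = length(proteins),
       sites = counts,
       positive_fraction = mean(sites$label),
       planted = truth$planted,
       seed = truth$seed)
}
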