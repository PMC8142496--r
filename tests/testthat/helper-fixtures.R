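# Shared fixtures, built in code.  Bundles are cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

# A small synthetic study (fast; used by unit tests).
small_bundle <- function() {
  if (is.null(.fixture_cache$small)) {
    .fixture_cache$small <- suppressWarnings(
      synth_bundle(synth_config(n_proteins = 40L, seed = 424242L)))
  }
  .fixture_cache$small
}

# The generator's default study conditions (used by the acceptance checks).
default_bundle <- function() {
  if (is.null(.fixture_cache$default)) {
    .fixture_cache$default <- suppressWarnings(
      synth_bundle(synth_config(seed = 20260101L)))
  }
  .fixture_cache$default
}

toy_proteins <- function() {
  c(P1 = "MKSTY",
    P2 = "AAASAAATAAAYAAASAAAT",
    P3 = paste(rep("ASTYG", 10), collapse = ""))
}

# Fragments data.frame built by hand (windows given directly).
manual_fragments <- function(windows, flank = (nchar(windows[1]) - 1L) %/% 2L,
                             protein_id = sprintf("P%d", seq_along(windows)),
                             position = rep(flank + 1L, length(windows)),
                             label = rep(1L, length(windows))) {
  df <- data.frame(protein_id = protein_id, position = position,
                   residue = substr(windows, flank + 1L, flank + 1L),
                   label = label, window = windows, stringsAsFactors = FALSE)
  phosml:::as_phos_fragments(df, flank)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
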