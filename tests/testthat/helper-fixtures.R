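# Shared lazy fixture cache: the small and medium synthetic datasets are
# generated once per test run and reused across test files.
.fixture_cache <- new.env(parent = emptyenv())

get_fixture <- function(name) {
  if (is.null(.fixture_cache[[name]])) {
    .fixture_cache[[name]] <- make_fixture(name)
  }
  .fixture_cache[[name]]
}

# Annotated events of a fixture, cached alongside it.
get_events <- function(name, include_synonymous = TRUE) {
  key <- paste0(name, "_ev_", include_synonymous)
  if (is.null(.fixture_cache[[key]])) {
    ds <- get_fixture(name)
    .fixture_cache[[key]] <- expand_events(
      ds$residues, ds$mutations, include_synonymous = include_synonymous)
  }
  .fixture_cache[[key]]
}

# Independent brute-force enumeration of single-base substitutions,
# deliberately sharing no code with the package internals: it uses
# Biostrings' genetic code table and plain string surgery.
oracle_sbs <- function(codon, position) {
  code <- Biostrings::GENETIC_CODE
  names(code) <- gsub("U", "T", names(code))
  out <- list()
  for (b in c("A", "C", "G", "T")) {
    if (b == substr(codon, position, position)) next
    target <- codon
    substr(target, position, position) <- b
    out[[length(out) + 1L]] <- data.frame(
      source = codon, target = target,
      wt_aa = unname(code[codon]), mut_aa = unname(code[target]),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Ordered amino-acid pairs reachable by substituting one codon position,
# synonymous and stop-involving events excluded (independent oracle).
oracle_reachable <- function(position) {
  if (is.character(position)) position <- match(position, c("I", "II", "III"))
  code <- Biostrings::GENETIC_CODE
  names(code) <- gsub("U", "T", names(code))
  sense <- names(code)[code != "*"]
  ev <- do.call(rbind, lapply(sense, oracle_sbs, position = position))
  ev <- ev[ev$mut_aa != "*" & ev$wt_aa != ev$mut_aa, ]
  sort(unique(paste(ev$wt_aa, ev$mut_aa)))
}
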