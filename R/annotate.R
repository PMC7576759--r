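# Join residue-level annotations (wild-type codon, RSA) with per-mutation
# ddG tables and expand each residue into classified, ddG-bearing
# substitution events.

#' Core/surface classification from relative solvent accessibility
#'
#' Residues with RSA of at most the threshold (default 20%) belong to the
#' protein core, the rest to the surface. Values marginally above 100% (as
#' produced by some accessibility programs) are clamped to 100.
#'
#' @param rsa Numeric vector of RSA values in percent.
#' @param threshold Core/surface boundary in percent; the boundary itself is
#'   core.
#' @return Character vector, `"core"` or `"surface"`.
#' @export
#' @examples
#' rsa_class(c(20, 20.1))  # "core" "surface"
rsa_class <- function(rsa, threshold = 20) {
  if (!is.numeric(rsa) || any(!is.finite(rsa))) stop("rsa must be finite numeric")
  if (any(rsa < 0 | rsa > 100.5)) {
    stop("rsa out of range [0, 100]: ", paste(utils::head(rsa[rsa < 0 | rsa > 100.5]), collapse = ", "))
  }
  rsa <- pmin(rsa, 100)
  ifelse(rsa <= threshold, "core", "surface")
}

.check_residues <- function(residues) {
  need <- c("protein_id", "position", "wt_aa", "wt_codon", "rsa", "protein_length")
  miss <- setdiff(need, names(residues))
  if (length(miss)) stop("residue table lacks column(s): ", paste(miss, collapse = ", "))
  residues$wt_codon <- .check_codons(residues$wt_codon)
  residues$wt_aa <- .norm_aa(residues$wt_aa)
  tr <- translate(residues$wt_codon)
  bad <- tr != residues$wt_aa
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(
      "codon/amino-acid mismatch at %s position %d: codon %s encodes %s, table says %s (%d mismatching residue(s) in total)",
      residues$protein_id[i], residues$position[i], residues$wt_codon[i],
      tr[i], residues$wt_aa[i], sum(bad)))
  }
  residues
}

#' Expand residues into annotated substitution events
#'
#' Expands every residue into its 9 single-base substitution events,
#' excludes nonsense events, attaches the ddG of the corresponding
#' amino-acid mutation, and classifies each event. ddG is a property of the
#' amino-acid mutation, so all degenerate base-level paths to the same
#' mutant amino acid share one ddG value and the mutation contributes with
#' its path multiplicity. Synonymous events carry ddG = 0 exactly.
#'
#' Missense events whose (protein, position, mutant amino acid) has no row
#' in the mutation table are dropped and collected in the gap report
#' (attribute `"gaps"`); event-count bookkeeping is in attribute `"counts"`.
#'
#' @param residues Data frame with columns `protein_id`, `position`,
#'   `wt_aa`, `wt_codon`, `rsa` (percent), `protein_length`.
#' @param mutations Data frame with columns `protein_id`, `position`,
#'   `wt_aa`, `mut_aa`, `ddg` (kcal/mol, positive destabilizing).
#' @param include_synonymous Include synonymous events (at ddG = 0)?
#' @param rsa_threshold Core/surface RSA boundary in percent.
#' @return Data frame of annotated events with the residue columns plus
#'   `target`, `codon_position`, `wt_base`, `mut_base`, `mut_aa`, `class`,
#'   `titv`, `ddg`, `rsa_stratum`, `ddg_class`.
#' @export
expand_events <- function(residues, mutations, include_synonymous = TRUE,
                          rsa_threshold = 20) {
  residues <- .check_residues(residues)
  ev_lookup <- all_code_events(1L)

  idx <- match(residues$wt_codon, sense_codons())
  if (anyNA(idx)) {
    i <- which(is.na(idx))[1]
    stop(sprintf("stop codon %s at %s position %d cannot be a wild-type codon",
                 residues$wt_codon[i], residues$protein_id[i], residues$position[i]))
  }
  # each sense codon owns 9 consecutive rows of ev_lookup
  rows <- rep((idx - 1L) * 9L, each = 9L) + seq_len(9L)
  ev <- ev_lookup[rows, ]
  res <- residues[rep(seq_len(nrow(residues)), each = 9L), ]
  events <- data.frame(
    res,
    target = ev$target,
    codon_position = ev$positions,
    wt_base = ev$wt_base,
    mut_base = ev$mut_base,
    mut_aa = ev$mut_aa,
    class = ev$class,
    titv = ev$titv,
    row.names = NULL,
    stringsAsFactors = FALSE
  )

  n_total <- nrow(events)
  nonsense <- events$class == "nonsense"
  n_nonsense <- sum(nonsense)
  events <- events[!nonsense, ]

  # ddG lookup by amino-acid mutation
  key <- paste(events$protein_id, events$position, events$mut_aa, sep = "\r")
  mkey <- paste(mutations$protein_id, mutations$position, mutations$mut_aa, sep = "\r")
  if (anyDuplicated(mkey)) stop("duplicate rows in mutation table")
  events$ddg <- mutations$ddg[match(key, mkey)]
  events$ddg[events$class == "synonymous"] <- 0

  gaps <- events[events$class == "missense" & is.na(events$ddg),
                 c("protein_id", "position", "wt_aa", "mut_aa", "wt_codon", "target")]
  rownames(gaps) <- NULL
  events <- events[!is.na(events$ddg), ]

  n_syn <- sum(events$class == "synonymous")
  if (!include_synonymous) events <- events[events$class != "synonymous", ]

  events$rsa_stratum <- rsa_class(events$rsa, rsa_threshold)
  events$ddg_class <- classify_ddg(events$ddg)
  rownames(events) <- NULL

  attr(events, "gaps") <- gaps
  attr(events, "include_synonymous") <- include_synonymous
  attr(events, "counts") <- c(
    residues = nrow(residues),
    total = n_total,
    nonsense = n_nonsense,
    synonymous = n_syn,
    missense = n_total - n_nonsense - n_syn - nrow(gaps),
    gap_dropped = nrow(gaps)
  )
  events
}

#' Check a coding sequence against a protein sequence
#'
#' Gapless positional comparison: the CDS is split into codons, translated,
#' and compared residue by residue with the protein sequence. The mapping is
#' accepted when at least 95% of positions match (boundary inclusive); a
#' trailing stop codon on the CDS is tolerated and ignored. Mismatching
#' positions are flagged so that their residues carry no codon.
#'
#' @param protein_seq Amino-acid sequence: single string or character vector
#'   of one-letter codes.
#' @param cds Nucleobase sequence: single string or character vector; length
#'   must be 3x the protein length (plus an optional stop codon).
#' @param min_identity Acceptance threshold on the identity fraction.
#' @return List with `identity`, `accepted`, and `codon_map` (data frame:
#'   `position`, `codon`, `aa_protein`, `aa_cds`, `match`).
#' @export
validate_cds <- function(protein_seq, cds, min_identity = 0.95) {
  if (length(protein_seq) == 1L && nchar(protein_seq) > 1L) {
    protein_seq <- strsplit(protein_seq, "")[[1]]
  }
  protein_seq <- .norm_aa(protein_seq)
  if (length(cds) == 1L) cds <- strsplit(toupper(cds), "")[[1]] else cds <- toupper(cds)
  if (!all(cds %in% NUCLEOBASES)) stop("invalid nucleobase in CDS")
  np <- length(protein_seq)
  if (length(cds) == 3L * (np + 1L)) {
    tail_codon <- paste(cds[(3L * np + 1L):(3L * np + 3L)], collapse = "")
    if (translate(tail_codon) == "*") cds <- cds[seq_len(3L * np)]
  }
  if (length(cds) != 3L * np) {
    stop(sprintf("CDS length %d does not match 3 x %d residues", length(cds), np))
  }
  codons <- vapply(seq_len(np), function(i) {
    paste(cds[(3L * i - 2L):(3L * i)], collapse = "")
  }, character(1))
  aa_cds <- translate(codons)
  ok <- aa_cds == protein_seq
  identity <- mean(ok)
  list(
    identity = identity,
    accepted = identity >= min_identity,
    codon_map = data.frame(
      position = seq_len(np), codon = codons,
      aa_protein = protein_seq, aa_cds = aa_cds, match = ok,
      stringsAsFactors = FALSE
    )
  )
}
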