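# Combinatorics of the standard genetic code: translation, enumeration of
# single- and multiple-base substitutions, synonymy, degeneracy,
# transition/transversion labelling, and position-restricted reachability
# of amino-acid mutations.

NUCLEOBASES <- c("A", "C", "G", "T")
PURINES     <- c("A", "G")
PYRIMIDINES <- c("C", "T")

CODON_POSITIONS <- c("I", "II", "III")

# Standard genetic code, DNA alphabet, stop = "*".
.GENETIC_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

AMINO_ACIDS <- sort(unique(.GENETIC_CODE[.GENETIC_CODE != "*"]))

.AA3 <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val"
)

#' The standard genetic code table
#'
#' Returns the standard (nuclear) genetic code as a named character vector:
#' names are the 64 DNA codons, values are one-letter amino-acid codes with
#' `"*"` for the three stop codons.
#'
#' @return Named character vector of length 64.
#' @export
#' @examples
#' genetic_code()[c("ATG", "TAA")]
genetic_code <- function() .GENETIC_CODE

#' Sense codons of the standard genetic code
#'
#' @return Character vector of the 61 codons encoding an amino acid.
#' @export
sense_codons <- function() names(.GENETIC_CODE)[.GENETIC_CODE != "*"]

# Normalise amino-acid input: accepts one-letter or three-letter codes.
.norm_aa <- function(aa, allow_stop = FALSE) {
  aa <- as.character(aa)
  three <- match(tolower(aa), tolower(.AA3))
  out <- ifelse(is.na(three), toupper(aa), names(.AA3)[three])
  valid <- AMINO_ACIDS
  if (allow_stop) valid <- c(valid, "*")
  bad <- !(out %in% valid)
  if (any(bad)) {
    stop("invalid amino acid(s): ", paste(unique(aa[bad]), collapse = ", "))
  }
  out
}

.check_codons <- function(codons) {
  codons <- toupper(as.character(codons))
  bad <- !(codons %in% names(.GENETIC_CODE))
  if (any(bad)) {
    stop("invalid codon(s): ", paste(unique(codons[bad]), collapse = ", "))
  }
  codons
}

.pos_index <- function(position) {
  if (is.numeric(position)) {
    idx <- as.integer(position)
  } else {
    idx <- match(as.character(position), CODON_POSITIONS)
  }
  if (any(is.na(idx)) || any(idx < 1L) || any(idx > 3L)) {
    stop("codon positions must be in {I, II, III} (or 1:3)")
  }
  idx
}

#' Translate codons under the standard genetic code
#'
#' @param codons Character vector of DNA codons (e.g. `"ATG"`).
#' @return Character vector of one-letter amino acids, `"*"` for stops.
#' @export
#' @examples
#' translate(c("ATG", "GGG", "TAA"))
translate <- function(codons) {
  codons <- .check_codons(codons)
  unname(.GENETIC_CODE[codons])
}

#' Transition or transversion?
#'
#' A substitution is a transition when it interchanges two purines (A, G) or
#' two pyrimidines (C, T), and a transversion otherwise.
#'
#' @param b1,b2 Character vectors of nucleobases; pairwise distinct.
#' @return Logical vector, `TRUE` for transitions.
#' @export
#' @examples
#' is_transition("A", "G")  # TRUE
#' is_transition("C", "A")  # FALSE
is_transition <- function(b1, b2) {
  b1 <- toupper(as.character(b1)); b2 <- toupper(as.character(b2))
  if (any(!(c(b1, b2) %in% NUCLEOBASES))) stop("invalid nucleobase")
  if (any(b1 == b2)) stop("b1 and b2 must differ")
  (b1 %in% PURINES) == (b2 %in% PURINES)
}

.event_class <- function(wt_aa, mut_aa) {
  wt_aa <- rep_len(wt_aa, length(mut_aa))
  ifelse(wt_aa == "*", "from_stop",
    ifelse(mut_aa == "*", "nonsense",
      ifelse(wt_aa == mut_aa, "synonymous", "missense")))
}

# Enumerate substitutions of one codon at a fixed set of positions, every
# named position changing. 3^k events for k positions... minus none: each
# position takes one of its 3 alternative bases, so 3^k events.
.enumerate_events <- function(codon, idx) {
  b <- strsplit(codon, "")[[1]]
  alts <- lapply(idx, function(i) setdiff(NUCLEOBASES, b[i]))
  grid <- expand.grid(alts, stringsAsFactors = FALSE)
  targets <- apply(grid, 1, function(repl) {
    b2 <- b
    b2[idx] <- repl
    paste(b2, collapse = "")
  })
  ti <- vapply(seq_len(nrow(grid)), function(r) {
    flags <- is_transition(b[idx], unlist(grid[r, ]))
    if (all(flags)) "transition" else if (!any(flags)) "transversion" else "mixed"
  }, character(1))
  wt_aa <- .GENETIC_CODE[codon]
  mut_aa <- .GENETIC_CODE[targets]
  data.frame(
    source = codon,
    target = targets,
    positions = paste(CODON_POSITIONS[idx], collapse = "+"),
    order = length(idx),
    wt_base = paste(b[idx], collapse = ""),
    mut_base = apply(grid, 1, paste, collapse = ""),
    wt_aa = unname(wt_aa),
    mut_aa = unname(mut_aa),
    class = .event_class(unname(wt_aa), unname(mut_aa)),
    titv = ti,
    stringsAsFactors = FALSE
  )
}

#' Enumerate single-base substitutions of a codon
#'
#' Every codon admits exactly 9 single-base substitutions (3 positions times
#' 3 alternative bases). Each event is classified as synonymous, missense or
#' nonsense (or `from_stop` when the source is a stop codon, so that
#' downstream statistics can exclude it), and as transition or transversion.
#'
#' @param codon A single DNA codon.
#' @return A data frame with one row per event: `source`, `target`,
#'   `positions` (`"I"`, `"II"` or `"III"`), `order` (always 1), `wt_aa`,
#'   `mut_aa`, `class`, `titv`.
#' @export
#' @examples
#' sbs_events("TTA")
sbs_events <- function(codon) {
  codon <- .check_codons(codon)
  if (length(codon) != 1L) stop("sbs_events() takes a single codon")
  out <- do.call(rbind, lapply(1:3, function(i) .enumerate_events(codon, i)))
  rownames(out) <- NULL
  out
}

#' Enumerate multiple-base substitutions of a codon
#'
#' Enumerates the substitutions that change exactly the given set of codon
#' positions: every named position must take one of its 3 alternative bases,
#' giving 9 events for a two-position set and 27 for the full three-position
#' set. This keeps the seven position-set classes (I, II, III, I+II, I+III,
#' II+III, I+II+III) disjoint.
#'
#' @param codon A single DNA codon.
#' @param positions Character or integer vector of at least two distinct
#'   codon positions among `"I"`, `"II"`, `"III"`.
#' @return Data frame with the same columns as [sbs_events()]; `titv` is
#'   `"mixed"` when the changed bases mix transitions and transversions.
#' @export
#' @examples
#' mbs_events("ATG", c("I", "II"))
mbs_events <- function(codon, positions) {
  codon <- .check_codons(codon)
  idx <- sort(unique(.pos_index(positions)))
  if (length(idx) < 2L) stop("mbs_events() needs at least two positions")
  out <- .enumerate_events(codon, idx)
  rownames(out) <- NULL
  out
}

#' All substitution events of every sense codon, by position-set class
#'
#' @param orders Which substitution orders to include (subset of 1:3).
#' @return Data frame of events from all 61 sense codons; single-base events
#'   plus, for orders 2 and 3, every position-set class.
#' @export
all_code_events <- function(orders = 1L) {
  orders <- as.integer(orders)
  stopifnot(all(orders %in% 1:3))
  sets <- list()
  if (1L %in% orders) sets <- c(sets, list(1L, 2L, 3L))
  if (2L %in% orders) sets <- c(sets, list(c(1L, 2L), c(1L, 3L), c(2L, 3L)))
  if (3L %in% orders) sets <- c(sets, list(1:3))
  out <- do.call(rbind, lapply(sense_codons(), function(cd) {
    do.call(rbind, lapply(sets, function(s) .enumerate_events(cd, s)))
  }))
  rownames(out) <- NULL
  out
}

#' Minimal base distance between two amino acids
#'
#' The minimum Hamming distance over all pairs of codons encoding the two
#' amino acids. Mutations at distance 1 are reachable by a single base
#' substitution (the "SBS-reachable" subset of amino-acid mutations);
#' mutations at distance 2 or 3 require simultaneous multiple-base changes.
#'
#' @param wt,mut Amino acids (one- or three-letter codes), distinct.
#' @return A list with `wt`, `mut`, `min_distance` (1, 2 or 3) and
#'   `is_mu_sbs` (`TRUE` iff `min_distance == 1`).
#' @export
#' @examples
#' aa_mutation_distance("Phe", "Leu")$min_distance  # 1
#' aa_mutation_distance("Met", "Trp")$min_distance  # 2
aa_mutation_distance <- function(wt, mut) {
  wt <- .norm_aa(wt); mut <- .norm_aa(mut)
  if (wt == mut) stop("wt and mut must be different amino acids")
  cw <- names(.GENETIC_CODE)[.GENETIC_CODE == wt]
  cm <- names(.GENETIC_CODE)[.GENETIC_CODE == mut]
  d <- min(outer(cw, cm, Vectorize(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  })))
  list(wt = wt, mut = mut, min_distance = as.integer(d),
       is_mu_sbs = d == 1L)
}

#' Table of all 380 ordered amino-acid mutations
#'
#' @return Data frame with columns `wt_aa`, `mut_aa`, `min_distance`,
#'   `is_mu_sbs`, one row per ordered pair of distinct amino acids.
#' @export
aa_mutation_table <- function() {
  prs <- expand.grid(wt_aa = AMINO_ACIDS, mut_aa = AMINO_ACIDS,
                     stringsAsFactors = FALSE)
  prs <- prs[prs$wt_aa != prs$mut_aa, ]
  d <- mapply(function(w, m) aa_mutation_distance(w, m)$min_distance,
              prs$wt_aa, prs$mut_aa)
  prs$min_distance <- as.integer(d)
  prs$is_mu_sbs <- prs$min_distance == 1L
  rownames(prs) <- NULL
  prs
}

#' Amino-acid mutations reachable at one codon position
#'
#' Enumerates all single-base substitutions of the 61 sense codons restricted
#' to one codon position, drops synonymous and stop-involving events, and
#' returns the distinct ordered (wild-type, mutant) amino-acid pairs. Under
#' the standard code this gives 14 mutations for base III, 62 for base I and
#' 82 for base II.
#'
#' @param position One of `"I"`, `"II"`, `"III"` (or 1:3).
#' @return Data frame with columns `wt_aa`, `mut_aa`.
#' @export
#' @examples
#' nrow(reachable_aa_mutations("III"))  # 14
reachable_aa_mutations <- function(position) {
  idx <- .pos_index(position)
  if (length(idx) != 1L) stop("one position at a time")
  ev <- do.call(rbind, lapply(sense_codons(),
                              function(cd) .enumerate_events(cd, idx)))
  ev <- ev[ev$class == "missense", c("wt_aa", "mut_aa")]
  out <- unique(ev)
  rownames(out) <- NULL
  out[order(out$wt_aa, out$mut_aa), , drop = FALSE]
}

#' Degeneracy of an amino-acid mutation from a codon
#'
#' The number of distinct single-base substitutions of `codon` whose target
#' codon encodes `target_aa`. Zero when the mutation is not SBS-reachable
#' from this codon.
#'
#' @param codon A sense codon.
#' @param target_aa Target amino acid, different from `translate(codon)`.
#' @return Integer count.
#' @export
#' @examples
#' degeneracy("TTA", "Phe")  # 2 (TTT, TTC)
degeneracy <- function(codon, target_aa) {
  codon <- .check_codons(codon)
  if (.GENETIC_CODE[codon] == "*") stop("codon must be a sense codon")
  target_aa <- .norm_aa(target_aa)
  if (target_aa == .GENETIC_CODE[codon]) {
    stop("target equals the wild-type amino acid; use synonymous_count()")
  }
  ev <- sbs_events(codon)
  sum(ev$mut_aa == target_aa)
}

#' Number of synonymous single-base substitutions of a codon
#'
#' @param codon A sense codon.
#' @return Integer count of SBS events leaving the amino acid unchanged.
#' @export
synonymous_count <- function(codon) {
  codon <- .check_codons(codon)
  if (.GENETIC_CODE[codon] == "*") stop("codon must be a sense codon")
  sum(sbs_events(codon)$class == "synonymous")
}

#' Write the genetic code table as TSV
#'
#' @param path Output file path.
#' @return The table, invisibly: codon, three- and one-letter amino acid,
#'   stop flag.
#' @export
export_code_table <- function(path) {
  aa1 <- unname(.GENETIC_CODE)
  tab <- data.frame(
    codon = names(.GENETIC_CODE),
    aa3 = ifelse(aa1 == "*", "Stp", unname(.AA3[aa1])),
    aa1 = aa1,
    is_stop = aa1 == "*",
    stringsAsFactors = FALSE
  )
  write_tsv(tab, path)
  invisible(tab)
}
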