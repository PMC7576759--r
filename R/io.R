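# Readers and writers: TSV tables, FASTA sequences, Kazusa-style codon
# usage, JSON reports and run configuration. All tabular output is
# UTF-8 TSV with a header row, '.' decimal separator and no quoting, so
# files are bit-exact across platforms.

#' Write a data frame as TSV
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV file
#'
#' @param path Input path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Read a residue annotation table
#'
#' Expects columns `protein_id`, `position`, `wt_aa`, `wt_codon`, `rsa`
#' (percent), `protein_length`; validates codon/amino-acid consistency.
#'
#' @param path TSV path.
#' @return Validated residue data frame.
#' @export
read_residues <- function(path) {
  .check_residues(read_tsv(path))
}

#' Read a per-mutation ddG table
#'
#' Expects columns `protein_id`, `position`, `wt_aa`, `mut_aa`, `ddg`
#' (kcal/mol). The package convention is positive = destabilizing; set
#' `negate_ddg = TRUE` for inputs using the opposite sign.
#'
#' @param path TSV path.
#' @param negate_ddg Flip the sign of the ddG column on read?
#' @return Data frame.
#' @export
read_mutations <- function(path, negate_ddg = FALSE) {
  m <- read_tsv(path)
  need <- c("protein_id", "position", "wt_aa", "mut_aa", "ddg")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("mutation table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(m$ddg))) stop("non-finite ddg in ", path)
  m$wt_aa <- .norm_aa(m$wt_aa)
  m$mut_aa <- .norm_aa(m$mut_aa)
  if (any(m$wt_aa == m$mut_aa)) stop("wt_aa equal to mut_aa in ", path)
  if (negate_ddg) m$ddg <- -m$ddg
  m
}

#' Read a fitness table
#'
#' Expects columns `protein_id`, `position`, `wt_aa`, `mut_aa`, `fitness`,
#' `wt_score`, `lof_score`.
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_fitness <- function(path) {
  f <- read_tsv(path)
  need <- c("fitness", "wt_score", "lof_score")
  miss <- setdiff(need, names(f))
  if (length(miss)) stop("fitness table lacks column(s): ", paste(miss, collapse = ", "))
  f
}

#' Read a codon usage table
#'
#' Two dialects: plain TSV with columns `codon` and `fraction`
#' (within-family fractions), or Kazusa-style whitespace text in which each
#' entry is a codon followed by its frequency per thousand and a count in
#' parentheses, e.g. `UUU 17.6( 714298)`. RNA codons (U) are accepted and
#' converted to DNA (T). Fractions are renormalized within each synonymous
#' family; the organism nucleotide frequencies implied by the per-thousand
#' usage are stored in attribute `"nt_freq"` when available.
#'
#' @param path Input path.
#' @param format `"auto"`, `"tsv"` or `"kazusa"`.
#' @return Data frame with columns `codon`, `aa`, `fraction`.
#' @export
read_codon_usage <- function(path, format = c("auto", "tsv", "kazusa")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("\\bcodon\\b", first, ignore.case = TRUE)) "tsv" else "kazusa"
  }
  if (format == "tsv") {
    u <- read_tsv(path)
    if (!all(c("codon", "fraction") %in% names(u))) {
      stop("usage TSV needs columns 'codon' and 'fraction'")
    }
    u$codon <- gsub("U", "T", toupper(u$codon))
    per1000 <- NULL
  } else {
    txt <- paste(readLines(path), collapse = " ")
    # tokens: CODON number ( count )
    m <- gregexpr("[ACGTUacgtu]{3}\\s+[0-9.]+\\s*\\(\\s*[0-9]+\\s*\\)", txt)[[1]]
    if (m[1] == -1) stop("no Kazusa-style entries found in ", path)
    entries <- regmatches(txt, gregexpr(
      "[ACGTUacgtu]{3}\\s+[0-9.]+\\s*\\(\\s*[0-9]+\\s*\\)", txt))[[1]]
    codon <- gsub("U", "T", toupper(substr(entries, 1, 3)))
    per1000 <- as.numeric(sub("^.{3}\\s+([0-9.]+).*$", "\\1", entries))
    u <- data.frame(codon = codon, fraction = per1000, stringsAsFactors = FALSE)
  }
  u$codon <- .check_codons(u$codon)
  if (anyDuplicated(u$codon)) stop("duplicate codons in usage table")
  u$aa <- translate(u$codon)
  nt <- vapply(NUCLEOBASES, function(b) {
    sum(vapply(strsplit(u$codon, ""), function(x) sum(x == b), numeric(1)) *
          u$fraction)
  }, numeric(1))
  u <- u[u$aa != "*", ]
  # renormalize within synonymous families
  fam_tot <- stats::ave(u$fraction, u$aa, FUN = sum)
  bad <- fam_tot <= 0
  if (any(bad)) stop("zero total usage for family of ", u$codon[bad][1])
  u$fraction <- u$fraction / fam_tot
  rownames(u) <- NULL
  if (sum(nt) > 0) attr(u, "nt_freq") <- nt / sum(nt)
  u
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA path.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  seqs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                             seqtype = "AA")
  out <- toupper(vapply(seqs, function(s) as.character(s)[1], character(1)))
  names(out) <- vapply(seqs, function(s) attr(s, "name"), character(1))
  out
}

#' Write a synthetic structurome dataset to a directory
#'
#' Writes `residues.tsv`, `mutations.tsv`, `fitness.tsv`,
#' `codon_usage.tsv` and a `provenance.json` recording the generator
#' configuration, seed and checksum.
#'
#' @param ds A `synthetic_structurome`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(ds$residues, file.path(dir, "residues.tsv"))
  write_tsv(ds$mutations, file.path(dir, "mutations.tsv"))
  write_tsv(ds$fitness, file.path(dir, "fitness.tsv"))
  write_tsv(ds$codon_usage, file.path(dir, "codon_usage.tsv"))
  prov <- list(config = unclass(ds$config),
               checksum = dataset_checksum(ds))
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Default run configuration
#'
#' Houses the analysis constants: the RSA core/surface threshold (20%), the
#' ddG neutrality thresholds (+/- 0.5 kcal/mol) and the per-position
#' translation-error frequencies (0.313, 0.062, 0.625).
#'
#' @param ... Overrides of the default fields.
#' @return Named list.
#' @export
run_config <- function(...) {
  cfg <- list(
    rsa_threshold = 20,
    ddg_thresholds = c(-0.5, 0.5),
    translation_errors = unname(translation_error_model()),
    include_synonymous = TRUE,
    bias_mode = "equiprobability",
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg
}

#' Write a JSON results report
#'
#' @param results Named list of result tables/values.
#' @param path Output path.
#' @param config Optional resolved configuration to embed as provenance.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, config = NULL) {
  if (!is.null(config)) results <- c(list(config = config), results)
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}
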