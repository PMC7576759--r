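# Bundled whole-dataset analysis mirroring the layout of the robustness
# tables: BLOSUM classes, core/surface, codon positions, wild-type base,
# ti/tv, used-vs-synonymous codon deltas and bias stratification.

#' Used-vs-synonymous codon deltas across positions and strata
#'
#' Evaluates the normalized used-vs-synonymous difference
#' (see [codon_usage_delta()]) for substitutions at each codon position and
#' for the pooled random- and translation-weighted models, in the whole
#' dataset and in the core and surface strata.
#'
#' @inheritParams codon_usage_delta
#' @return Data frame with columns `row` (I, II, III, random, translation),
#'   `all`, `core`, `surface` (percent).
#' @export
usage_delta_table <- function(residues, mutations, rsa_threshold = 20,
                              sets = NULL) {
  if (is.null(sets)) sets <- .usage_event_sets(residues, mutations, rsa_threshold)
  cell <- function(weighting, stratum, position) {
    codon_usage_delta(weighting = weighting, stratum = stratum,
                      position = position, rsa_threshold = rsa_threshold,
                      sets = sets)$delta_percent
  }
  rows <- list(
    I = list("random", "I"), II = list("random", "II"),
    III = list("random", "III"),
    random = list("random", NULL), translation = list("translation", NULL)
  )
  out <- do.call(rbind, lapply(names(rows), function(nm) {
    w <- rows[[nm]][[1]]; p <- rows[[nm]][[2]]
    data.frame(row = nm,
               all = cell(w, "all", p),
               core = cell(w, "core", p),
               surface = cell(w, "surface", p),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Used-vs-synonymous codon deltas for biased and unbiased codons
#'
#' Splits residues according to whether their used codon is biased in the
#' organism's codon-usage table, then evaluates the used-vs-synonymous
#' delta in each subset under the random and translation weightings.
#'
#' @inheritParams codon_usage_delta
#' @param usage Codon-usage table (see [read_codon_usage()]).
#' @param mode Bias expectation model, passed to [bias_classify()].
#' @return Data frame with columns `row` (random, translation), `biased`,
#'   `unbiased` (percent).
#' @export
bias_delta_table <- function(residues, mutations, usage,
                             mode = "equiprobability", rsa_threshold = 20,
                             sets = NULL) {
  residues <- .check_residues(residues)
  fam_size <- table(.GENETIC_CODE[.GENETIC_CODE != "*"])
  multi <- residues$wt_aa %in% names(fam_size)[fam_size >= 2]
  residues <- residues[multi, ]
  lab <- bias_classify(residues$wt_codon, usage, mode = mode)
  if (is.null(sets)) sets <- .usage_event_sets(residues, mutations, rsa_threshold)
  res_lab <- stats::setNames(lab, paste(residues$protein_id, residues$position,
                                        sep = "\r"))
  subset_sets <- function(subset) {
    keep <- function(ev) {
      ev[res_lab[paste(ev$protein_id, ev$position, sep = "\r")] == subset, ]
    }
    list(used = keep(sets$used), syn = keep(sets$syn),
         n_excluded = sets$n_excluded)
  }
  ss <- list(biased = subset_sets("biased"), unbiased = subset_sets("unbiased"))
  cell <- function(subset, weighting) {
    s <- ss[[subset]]
    if (!nrow(s$used) || !nrow(s$syn)) return(NA_real_)
    codon_usage_delta(weighting = weighting, rsa_threshold = rsa_threshold,
                      sets = s)$delta_percent
  }
  data.frame(
    row = c("random", "translation"),
    biased = c(cell("biased", "random"), cell("biased", "translation")),
    unbiased = c(cell("unbiased", "random"), cell("unbiased", "translation")),
    stringsAsFactors = FALSE
  )
}

#' Full robustness analysis of one dataset
#'
#' Runs the single-base-substitution analysis end to end on a residue/ddG
#' dataset: core/surface and RSA-bin summaries, per-codon-position means
#' with and without synonymous-and-degeneracy weighting, BLOSUM62,
#' wild-type-base and ti/tv stratification, class fractions under the
#' random and translation-error models, used-vs-synonymous codon deltas,
#' GC delta, codon-base/hydropathy correlations, per-protein summaries and
#' core composition, and (when tables are supplied) the fitness and
#' codon-usage-bias analyses.
#'
#' @param residues,mutations Residue and ddG tables (see [expand_events()]).
#' @param usage Optional codon-usage table for the bias stratification.
#' @param fitness Optional fitness table (see [read_fitness()]).
#' @param config A [run_config()].
#' @return Named list of result tables, of class `"structurome_report"`.
#' @export
structurome_report <- function(residues, mutations, usage = NULL,
                               fitness = NULL, config = run_config()) {
  thr <- config$rsa_threshold
  ev_syn <- expand_events(residues, mutations, include_synonymous = TRUE,
                          rsa_threshold = thr)
  ev <- ev_syn[ev_syn$class != "synonymous", ]
  attr(ev, "include_synonymous") <- FALSE

  usets <- .usage_event_sets(residues, mutations, thr)
  pm_with <- position_means(ev_syn, "with_syn_and_degeneracy")
  pm_without <- position_means(ev_syn, "without")
  te <- config$translation_errors
  out <- list(
    counts = as.list(attr(ev_syn, "counts")),
    rsa_summary = summarize_events(ev, by = "rsa_stratum"),
    overall = summarize_events(cbind(ev, all = "all"), by = "all"),
    blosum_summary = summarize_events(ev, by = "blosum"),
    position_means_with_syn = as.list(pm_with),
    position_means_without_syn = as.list(pm_without),
    position_error_correlation = pearson(100 * te, pm_with),
    base_summary = summarize_events(ev, by = "wt_base"),
    titv_with_syn = titv_means(ev_syn, include_synonymous = TRUE),
    titv_without_syn = titv_means(ev_syn, include_synonymous = FALSE),
    class_fractions_random = as.list(
      weighted_class_fractions(ev_syn, rep(1 / 3, 3))),
    class_fractions_translation = as.list(
      weighted_class_fractions(ev_syn, te)),
    usage_delta = usage_delta_table(residues, mutations, rsa_threshold = thr,
                                    sets = usets),
    gc_delta = gc_delta(residues),
    hydropathy_correlation_T = hydrophobicity_correlation("T"),
    hydropathy_correlation_A = hydrophobicity_correlation("A"),
    protein_summary = protein_summary(ev, rsa_threshold = thr),
    composition = composition_profile(residues, rsa_threshold = thr),
    rsa_profile = rsa_profile(ev, bin_width = 1, threshold = thr)[c("bins")]
  )
  if (!is.null(usage)) {
    out$bias_delta <- bias_delta_table(residues, mutations, usage,
                                       mode = config$bias_mode,
                                       rsa_threshold = thr, sets = usets)
  }
  if (!is.null(fitness)) {
    cls <- fitness_classify(fitness$fitness, fitness$wt_score, fitness$lof_score)
    tab <- table(factor(cls, levels = c("deleterious", "neutral", "advantageous")))
    out$fitness_fractions <- as.list(as.numeric(tab) / sum(tab))
    names(out$fitness_fractions) <- names(tab)
  }
  out$config <- config
  class(out) <- c("structurome_report", "list")
  out
}

#' @export
print.structurome_report <- function(x, ...) {
  cat("Structurome robustness report\n")
  cat("  residues:", x$counts$residues,
      " events (non-nonsense, ddG-covered):",
      x$counts$synonymous + x$counts$missense, "\n")
  cat("  core/surface mean ddG:",
      sprintf("%.3f / %.3f kcal/mol\n",
              x$rsa_summary$mean_ddg[x$rsa_summary$stratum == "core"],
              x$rsa_summary$mean_ddg[x$rsa_summary$stratum == "surface"]))
  cat("  position means (with synonymous + degeneracy): ",
      paste(sprintf("%s=%.3f", names(x$position_means_with_syn),
                    unlist(x$position_means_with_syn)), collapse = ", "), "\n")
  cat("  r(position means, translation-error freq):",
      sprintf("%.4f\n", x$position_error_correlation$r))
  invisible(x)
}
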