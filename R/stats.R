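# Stratified robustness statistics: ddG class fractions, per-position and
# per-base means under synonymous/degeneracy weighting, translation-error
# weighting, BLOSUM and ti/tv stratification, used-vs-synonymous codon
# comparisons, bias stratification, RSA/length profiles, and fitness
# classification.

#' Classify a stability change as stabilizing, neutral or destabilizing
#'
#' Mutations with ddG below -0.5 kcal/mol are stabilizing, those above
#' +0.5 kcal/mol destabilizing; the closed interval between the thresholds
#' (boundaries included) is neutral.
#'
#' @param ddg Numeric vector of folding free-energy changes (kcal/mol,
#'   positive = destabilizing).
#' @param thresholds Lower/upper neutrality bounds (kcal/mol).
#' @return Character vector in `{"stabilizing", "neutral", "destabilizing"}`.
#' @export
#' @examples
#' classify_ddg(c(-0.7, 0.5, 0.51))
classify_ddg <- function(ddg, thresholds = c(-0.5, 0.5)) {
  if (!is.numeric(ddg) || any(!is.finite(ddg))) stop("ddg must be finite numeric")
  stopifnot(length(thresholds) == 2L, thresholds[1] <= thresholds[2])
  ifelse(ddg < thresholds[1], "stabilizing",
         ifelse(ddg > thresholds[2], "destabilizing", "neutral"))
}

DDG_CLASSES <- c("stabilizing", "neutral", "destabilizing")

.class_fractions <- function(cls) {
  tab <- table(factor(cls, levels = DDG_CLASSES))
  as.numeric(tab) / max(sum(tab), 1L)
}

#' Protein length bins
#'
#' @param length Numeric vector of protein lengths (residues).
#' @return Factor with levels `"L<=200"`, `"200<L<=400"`, `"L>400"`
#'   (boundaries 200 and 400 belong to the lower bin).
#' @export
length_bin <- function(length) {
  cut(length, breaks = c(0, 200, 400, Inf),
      labels = c("L<=200", "200<L<=400", "L>400"), right = TRUE)
}

# RSA bins [k, k+w) with the last bin closed at 100.
.rsa_bin <- function(rsa, bin_width = 1) {
  pmin(floor(rsa / bin_width), floor((100 - 1e-9) / bin_width)) * bin_width
}

# Derive a stratum column from a named scheme or take an existing column.
.stratify <- function(events, by, bin_width = 1) {
  lv <- NULL
  x <- switch(by,
    rsa_bin = .rsa_bin(events$rsa, bin_width),
    blosum = blosum_score(events$wt_aa, events$mut_aa),
    length_bin = length_bin(events$protein_length),
    protein = events$protein_id,
    position_set = ,
    codon_position = {
      col <- if ("codon_position" %in% names(events)) events$codon_position else events$positions
      lv <- intersect(c("I", "II", "III", "I+II", "I+III", "II+III", "I+II+III"),
                      unique(col))
      col
    },
    rsa_stratum = { lv <- c("core", "surface"); events$rsa_stratum },
    titv = { lv <- c("transition", "transversion", "mixed")
             lv <- intersect(lv, c("transition", "transversion", unique(events$titv)))
             events$titv },
    {
      if (!by %in% names(events)) stop("unknown stratifier: ", by)
      events[[by]]
    }
  )
  if (is.null(lv)) factor(x) else factor(x, levels = lv)
}

#' Per-stratum robustness summary
#'
#' Groups annotated events by a stratifier and reports, per stratum, the
#' event count, mean and standard deviation of ddG, and the fractions of
#' stabilizing, neutral and destabilizing events. Empty strata are kept as
#' n = 0 rows with `NA` statistics rather than silently dropped.
#'
#' Built-in stratifiers: `"rsa_stratum"` (core/surface), `"rsa_bin"`,
#' `"codon_position"`, `"position_set"`, `"wt_base"`, `"titv"`, `"blosum"`
#' (BLOSUM62 score of the amino-acid pair), `"order"`, `"protein"`,
#' `"length_bin"`; any other value is looked up as a column of `events`.
#'
#' @param events Annotated event data frame (see [expand_events()]).
#' @param by Stratifier name.
#' @param bin_width RSA bin width in percent (for `by = "rsa_bin"`).
#' @return Data frame of class `"stratum_summary"`: `stratum`, `n`,
#'   `mean_ddg`, `sd_ddg`, `frac_stabilizing`, `frac_neutral`,
#'   `frac_destabilizing`.
#' @export
summarize_events <- function(events, by = "rsa_stratum", bin_width = 1) {
  if (nrow(events) == 0L) stop("empty event table")
  g <- .stratify(events, by, bin_width)
  out <- do.call(rbind, lapply(levels(g), function(lev) {
    d <- events$ddg[which(g == lev)]
    n <- length(d)
    data.frame(
      stratum = lev,
      n = n,
      mean_ddg = if (n) mean(d) else NA_real_,
      sd_ddg = if (n > 1) stats::sd(d) else NA_real_,
      frac_stabilizing = if (n) mean(d < -0.5) else NA_real_,
      frac_neutral = if (n) mean(d >= -0.5 & d <= 0.5) else NA_real_,
      frac_destabilizing = if (n) mean(d > 0.5) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  class(out) <- c("stratum_summary", "data.frame")
  attr(out, "by") <- by
  out
}

#' @export
print.stratum_summary <- function(x, digits = 3, ...) {
  cat("Robustness summary by", attr(x, "by"), "\n")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Mean ddG per codon position
#'
#' In mode `"with_syn_and_degeneracy"` the mean at each codon position is
#' taken over all non-nonsense single-base events: synonymous events
#' contribute ddG = 0 and an amino-acid mutation reachable through k base
#' substitutions contributes k times. In mode `"without"` synonymous events
#' are excluded and degenerate paths are collapsed, averaging over distinct
#' (residue, amino-acid mutation, codon position) triples.
#'
#' @param events Annotated events expanded with the matching
#'   `include_synonymous` flag.
#' @param mode `"with_syn_and_degeneracy"` or `"without"`.
#' @return Named numeric vector of means for positions I, II, III (`NA` for
#'   an empty position stratum).
#' @export
position_means <- function(events, mode = c("with_syn_and_degeneracy", "without")) {
  mode <- match.arg(mode)
  inc <- attr(events, "include_synonymous")
  if (mode == "with_syn_and_degeneracy") {
    if (isFALSE(inc) || (is.null(inc) && !any(events$class == "synonymous"))) {
      stop("mode 'with_syn_and_degeneracy' needs events expanded with include_synonymous = TRUE")
    }
  } else {
    events <- events[events$class != "synonymous", ]
    keep <- !duplicated(events[, c("protein_id", "position", "mut_aa", "codon_position")])
    events <- events[keep, ]
  }
  vapply(CODON_POSITIONS, function(p) {
    d <- events$ddg[events$codon_position == p]
    if (length(d)) mean(d) else NA_real_
  }, numeric(1))
}

#' Class fractions under per-position mutation weights
#'
#' Computes the fraction of stabilizing, neutral and destabilizing events
#' when codon positions are hit with unequal frequencies, as in translation
#' errors: the fraction of class c is the weight-averaged per-position
#' fraction, sum_p w_p (class-c events at p / events at p). With equal
#' weights (the random-mutation model) this is the plain average of the
#' per-position fractions. Synonymous events (ddG = 0) count as neutral.
#'
#' If a position with nonzero weight has no events, the weights are
#' renormalized over the populated positions, with a warning.
#'
#' @param events Annotated single-base events (synonymous included and
#'   degeneracy counted, for the translation-error reading).
#' @param weights Per-position weights for I, II, III, summing to 1;
#'   defaults to the translation-error frequencies.
#' @return Named numeric vector `(stabilizing, neutral, destabilizing)`.
#' @export
weighted_class_fractions <- function(events, weights = translation_error_model()) {
  if (length(weights) != 3L) stop("weights must have length 3 (positions I, II, III)")
  if (abs(sum(weights) - 1) > 1e-6) stop("weights must sum to 1")
  w <- as.numeric(weights)
  frac <- sapply(CODON_POSITIONS, function(p) {
    d <- events$ddg[events$codon_position == p]
    if (!length(d)) return(c(NA_real_, NA_real_, NA_real_))
    .class_fractions(classify_ddg(d))
  })
  empty <- apply(is.na(frac), 2, any)
  if (any(empty & w > 0)) {
    warning("no events at position(s) ", paste(CODON_POSITIONS[empty & w > 0], collapse = ", "),
            "; renormalizing weights over populated positions")
  }
  w[empty] <- 0
  if (sum(w) == 0) stop("no populated position with nonzero weight")
  w <- w / sum(w)
  out <- drop(frac[, !empty, drop = FALSE] %*% w[!empty])
  names(out) <- DDG_CLASSES
  out
}

#' Pearson product-moment correlation
#'
#' Direct implementation of the product-moment formula, with the two-sided
#' p-value from the t transformation.
#'
#' @param x,y Numeric vectors of equal length (at least 3), with nonzero
#'   variance.
#' @return List with `r`, `n` and `p`.
#' @export
#' @examples
#' pearson(c(31.3, 6.2, 62.5), c(0.64, 0.91, 0.16))$r
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite input")
  dx <- x - mean(x); dy <- y - mean(y)
  sx <- sum(dx^2); sy <- sum(dy^2)
  if (sx == 0 || sy == 0) stop("zero variance: correlation undefined")
  r <- sum(dx * dy) / sqrt(sx * sy)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  list(r = r, n = n, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

#' Mean ddG of transitions and transversions
#'
#' @param events Annotated single-base events.
#' @param include_synonymous Keep synonymous events (contributing ddG = 0)?
#' @return `stratum_summary` data frame with transition and transversion
#'   rows (degeneracy counted through event multiplicity).
#' @export
titv_means <- function(events, include_synonymous = TRUE) {
  if (any(events$order != 1L)) stop("titv_means() takes order-1 events only")
  if (!include_synonymous) events <- events[events$class != "synonymous", ]
  out <- summarize_events(events, by = "titv")
  if (any(out$n == 0)) {
    warning("empty stratum: ", paste(out$stratum[out$n == 0], collapse = ", "))
  }
  out
}

.wmean <- function(x, w) sum(w * x) / sum(w)
.wvar <- function(x, w) {
  m <- .wmean(x, w)
  sum(w * (x - m)^2) / sum(w)  # population variance
}

# Expand events from each residue's used codon and from its other
# synonymous codons; attach per-event weights making residues (and, on the
# synonymous side, codons within a residue) equiponderant.
.usage_event_sets <- function(residues, mutations, rsa_threshold = 20) {
  residues <- .check_residues(residues)
  fam_size <- table(.GENETIC_CODE[.GENETIC_CODE != "*"])
  multi <- residues$wt_aa %in% names(fam_size)[fam_size >= 2]
  n_excluded <- sum(!multi)
  residues <- residues[multi, ]
  if (!nrow(residues)) stop("no residues with a multi-codon amino acid")

  used <- expand_events(residues, mutations, include_synonymous = TRUE,
                        rsa_threshold = rsa_threshold)
  used$codon_role <- "used"

  # per-codon list of the other codons of its family, precomputed once
  sense <- names(.GENETIC_CODE)[.GENETIC_CODE != "*"]
  alt_list <- lapply(stats::setNames(sense, sense), function(cd) {
    setdiff(sense[.GENETIC_CODE[sense] == .GENETIC_CODE[cd]], cd)
  })
  alts <- alt_list[residues$wt_codon]
  syn_res <- residues[rep(seq_len(nrow(residues)), lengths(alts)), ]
  syn_res$wt_codon <- unlist(alts, use.names = FALSE)
  syn <- expand_events(syn_res, mutations, include_synonymous = TRUE,
                       rsa_threshold = rsa_threshold)
  syn$codon_role <- "synonymous"
  list(used = used, syn = syn, n_excluded = n_excluded)
}

.usage_weights <- function(ev) {
  res_key <- paste(ev$protein_id, ev$position, sep = "\r")
  cod_key <- paste(res_key, ev$wt_codon, sep = "\r")
  cid <- match(cod_key, unique(cod_key))
  rid <- match(res_key, unique(res_key))
  n_ev_codon <- tabulate(cid)[cid]
  first <- !duplicated(cid)
  n_codons <- tabulate(rid[first])[rid]
  1 / (n_ev_codon * n_codons)
}

#' Used-codon versus synonymous-codon robustness difference
#'
#' Compares the mean ddG of single-base substitution events reached from
#' each residue's actual (used) codon with those reached from its other
#' synonymous codons, reported as the normalized difference
#' (<ddG_syn> - <ddG_used>) / sigma in percent, where
#' sigma^2 = sigma^2(ddG_used) + sigma^2(ddG_syn) (population variances).
#' A positive value means the used codons are the more robust ones.
#'
#' Each residue contributes with equal weight; on the synonymous side each
#' codon of a residue is weighted equally (mean of per-codon means), since
#' synonymous codons are compared as codon-level counterfactuals. Synonymous
#' events enter at ddG = 0; residues of single-codon amino acids (Met, Trp)
#' are excluded and counted.
#'
#' @param residues,mutations Residue and ddG tables (see [expand_events()]).
#' @param weighting `"random"` (positions equiprobable) or `"translation"`
#'   (positions weighted by the translation-error frequencies).
#' @param stratum Restrict to `"core"` or `"surface"` residues, or `"all"`.
#' @param position Optional single codon position (`"I"`, `"II"`, `"III"`)
#'   to restrict the substituted site.
#' @param rsa_threshold Core/surface RSA boundary (percent).
#' @param sets Precomputed event sets (internal; lets callers that evaluate
#'   several strata reuse one expansion).
#' @return List with `delta_percent`, the weighted means/SDs, event counts
#'   and `n_excluded` (residues of single-codon amino acids).
#' @export
codon_usage_delta <- function(residues, mutations,
                              weighting = c("random", "translation"),
                              stratum = c("all", "core", "surface"),
                              position = NULL, rsa_threshold = 20,
                              sets = NULL) {
  weighting <- match.arg(weighting)
  stratum <- match.arg(stratum)
  if (is.null(sets)) sets <- .usage_event_sets(residues, mutations, rsa_threshold)

  filter_ev <- function(ev) {
    if (stratum != "all") ev <- ev[ev$rsa_stratum == stratum, ]
    if (!is.null(position)) {
      p <- CODON_POSITIONS[.pos_index(position)]
      ev <- ev[ev$codon_position == p, ]
    }
    ev
  }
  used <- filter_ev(sets$used)
  syn <- filter_ev(sets$syn)
  if (!nrow(used) || !nrow(syn)) stop("empty used or synonymous event set after filtering")

  add_w <- function(ev) {
    w <- .usage_weights(ev)
    if (weighting == "translation") {
      w <- w * translation_error_model()[ev$codon_position]
    }
    w
  }
  wu <- add_w(used); ws <- add_w(syn)
  mu <- .wmean(used$ddg, wu); ms <- .wmean(syn$ddg, ws)
  vu <- .wvar(used$ddg, wu); vs <- .wvar(syn$ddg, ws)
  sigma <- sqrt(vu + vs)
  list(
    delta_percent = 100 * (ms - mu) / sigma,
    mean_used = mu, mean_syn = ms,
    sd_used = sqrt(vu), sd_syn = sqrt(vs),
    n_used_events = nrow(used), n_syn_events = nrow(syn),
    n_excluded = sets$n_excluded
  )
}

#' Classify a codon as biased or unbiased in an organism
#'
#' A codon is biased when its usage frequency within its synonymous family
#' deviates by more than 12.5% (relative) from the expected frequency. Under
#' `mode = "equiprobability"` the expectation is 1/k for a family of k
#' codons; under `mode = "nucleotide_freq"` it is proportional to the
#' product of the organism's nucleotide frequencies over the codon's bases,
#' normalized within the family.
#'
#' @param codon Character vector of sense codons.
#' @param usage Codon-usage table (see [read_codon_usage()]): data frame
#'   with columns `codon` and `fraction` (within-family fractions).
#' @param mode Expectation model.
#' @param nt_freq Named numeric frequencies of A, C, G, T (required for
#'   `mode = "nucleotide_freq"`; taken from `attr(usage, "nt_freq")` if
#'   present).
#' @param threshold Relative-deviation cutoff.
#' @return Character vector, `"biased"` or `"unbiased"`.
#' @export
bias_classify <- function(codon, usage,
                          mode = c("equiprobability", "nucleotide_freq"),
                          nt_freq = attr(usage, "nt_freq"), threshold = 0.125) {
  mode <- match.arg(mode)
  codon <- .check_codons(codon)
  if (any(.GENETIC_CODE[codon] == "*")) stop("stop codons have no usage family")
  vapply(codon, function(cd) {
    aa <- .GENETIC_CODE[cd]
    fam <- names(.GENETIC_CODE)[.GENETIC_CODE == aa]
    # single-codon families (Met, Trp) cannot deviate from uniform
    if (length(fam) < 2L) return("unbiased")
    obs <- usage$fraction[match(fam, usage$codon)]
    if (anyNA(obs)) stop("usage table does not cover the family of ", cd)
    obs <- obs / sum(obs)
    if (mode == "equiprobability") {
      expd <- rep(1 / length(fam), length(fam))
    } else {
      if (is.null(nt_freq)) stop("nucleotide_freq mode needs nt_freq")
      nt_freq <- nt_freq[NUCLEOBASES] / sum(nt_freq[NUCLEOBASES])
      expd <- vapply(fam, function(f) {
        prod(nt_freq[strsplit(f, "")[[1]]])
      }, numeric(1))
      expd <- expd / sum(expd)
    }
    i <- match(cd, fam)
    if (abs(obs[i] - expd[i]) / expd[i] > threshold) "biased" else "unbiased"
  }, character(1))
}

#' Classify a mutation's fitness effect
#'
#' A mutation is deleterious when its fitness is below the mean of the
#' loss-of-function and wild-type scores, advantageous when above 1.25 times
#' the wild-type score, and neutral in between (boundaries neutral).
#'
#' @param fitness,wt_score,lof_score Numeric vectors (recycled).
#' @return Character vector in `{"deleterious", "neutral", "advantageous"}`.
#' @export
#' @examples
#' fitness_classify(c(0.4, 1.0, 1.3), 1.0, 0.0)
fitness_classify <- function(fitness, wt_score, lof_score) {
  if (any(!is.finite(c(fitness, wt_score, lof_score)))) stop("non-finite score")
  lo <- (lof_score + wt_score) / 2
  hi <- 1.25 * wt_score
  if (any(lo > hi)) stop("degenerate thresholds: (lof + wt)/2 exceeds 1.25 * wt")
  ifelse(fitness < lo, "deleterious",
         ifelse(fitness > hi, "advantageous", "neutral"))
}

#' Mean ddG versus RSA, with the core/surface piecewise fit
#'
#' Bins events by RSA (half-open bins `[k, k+w)`, the last closed at 100),
#' reports the per-bin mean ddG, and fits the two regimes of the RSA-ddG
#' relation: a least-squares line on the bins above 20% RSA and a
#' second-degree polynomial on the bins at or below 20%.
#'
#' @param events Annotated events carrying `rsa` and `ddg`.
#' @param bin_width Bin width in percent.
#' @param threshold Boundary between the non-linear (core) and linear
#'   (surface) regimes.
#' @return List with `bins` (data frame: `bin_lo`, `bin_mid`, `n`,
#'   `mean_ddg`), `linear_fit` and `quadratic_fit` (each a list of
#'   `coefficients` and `r_squared`, or `NULL` with a warning when too few
#'   populated bins).
#' @export
rsa_profile <- function(events, bin_width = 1, threshold = 20) {
  b <- .rsa_bin(events$rsa, bin_width)
  agg <- stats::aggregate(events$ddg, by = list(bin_lo = b),
                          FUN = function(d) c(n = length(d), m = mean(d)))
  bins <- data.frame(
    bin_lo = agg$bin_lo,
    bin_mid = agg$bin_lo + bin_width / 2,
    n = agg$x[, "n"],
    mean_ddg = agg$x[, "m"]
  )
  bins <- bins[order(bins$bin_lo), ]
  rownames(bins) <- NULL

  fit_stats <- function(fit) {
    list(coefficients = stats::coef(fit),
         r_squared = summary(fit)$r.squared)
  }
  hi <- bins[bins$bin_mid > threshold, ]
  lo <- bins[bins$bin_mid <= threshold, ]
  linear_fit <- if (nrow(hi) >= 3) {
    fit_stats(stats::lm(mean_ddg ~ bin_mid, data = hi))
  } else {
    warning("too few populated bins above ", threshold, "% for a linear fit")
    NULL
  }
  quadratic_fit <- if (nrow(lo) >= 4) {
    fit_stats(stats::lm(mean_ddg ~ bin_mid + I(bin_mid^2), data = lo))
  } else {
    warning("too few populated bins at or below ", threshold, "% for a quadratic fit")
    NULL
  }
  list(bins = bins, linear_fit = linear_fit, quadratic_fit = quadratic_fit)
}

#' Per-protein robustness summary
#'
#' One row per protein: mean ddG over its events, mean over surface events,
#' the core-to-length ratio (number of distinct core residues over protein
#' length) and the protein-length bin.
#'
#' @param events Annotated events with `protein_id` and `protein_length`.
#' @param rsa_threshold Core/surface RSA boundary (percent).
#' @return Data frame: `protein_id`, `protein_length`, `length_bin`,
#'   `n_events`, `mean_ddg`, `mean_ddg_surface`, `n_core_residues`,
#'   `core_to_length`.
#' @export
protein_summary <- function(events, rsa_threshold = 20) {
  out <- do.call(rbind, lapply(split(events, events$protein_id), function(ev) {
    res <- ev[!duplicated(ev$position), ]
    ncore <- sum(res$rsa <= rsa_threshold)
    surf <- ev$ddg[ev$rsa_stratum == "surface"]
    data.frame(
      protein_id = ev$protein_id[1],
      protein_length = ev$protein_length[1],
      length_bin = length_bin(ev$protein_length[1]),
      n_events = nrow(ev),
      mean_ddg = mean(ev$ddg),
      mean_ddg_surface = if (length(surf)) mean(surf) else NA_real_,
      n_core_residues = ncore,
      core_to_length = ncore / ev$protein_length[1],
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Hydrophobic composition of the core per protein-length bin
#'
#' Fraction of core residues (RSA at or below the threshold) that are Val,
#' Ile, Leu or Phe, per protein-length bin. Bins without core residues get
#' `NA` with a warning.
#'
#' @param residues Residue table with `wt_aa`, `rsa`, `protein_length`.
#' @param rsa_threshold Core/surface RSA boundary (percent).
#' @return Data frame: `length_bin`, `n_core`, `hydrophobic_fraction`.
#' @export
composition_profile <- function(residues, rsa_threshold = 20) {
  residues$wt_aa <- .norm_aa(residues$wt_aa)
  core <- residues[residues$rsa <= rsa_threshold, ]
  lb <- length_bin(core$protein_length)
  out <- do.call(rbind, lapply(levels(lb), function(lev) {
    aa <- core$wt_aa[which(lb == lev)]
    data.frame(
      length_bin = lev,
      n_core = length(aa),
      hydrophobic_fraction = if (length(aa)) mean(aa %in% HYDROPHOBIC_AAS) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  if (any(out$n_core == 0)) {
    warning("no core residues in bin(s): ",
            paste(out$length_bin[out$n_core == 0], collapse = ", "))
  }
  rownames(out) <- NULL
  out
}

.gc_content <- function(codon) {
  vapply(strsplit(codon, ""), function(b) mean(b %in% c("G", "C")), numeric(1))
}

#' GC-content difference between synonymous and used codons
#'
#' For every residue of a multi-codon amino acid, the mean GC fraction of
#' its other synonymous codons minus the GC fraction of the used codon;
#' averaged over residues and reported in percent. A negative value means
#' the used codons are GC-richer than their synonymous alternatives.
#'
#' @param residues Residue table with `wt_aa` and `wt_codon`.
#' @return List with `mean_percent`, `n_residues` and `n_excluded`
#'   (residues of single-codon amino acids).
#' @export
gc_delta <- function(residues) {
  residues$wt_codon <- .check_codons(residues$wt_codon)
  aa <- translate(residues$wt_codon)
  fam_size <- table(.GENETIC_CODE[.GENETIC_CODE != "*"])
  multi <- aa %in% names(fam_size)[fam_size >= 2]
  res <- residues[multi, , drop = FALSE]
  if (!nrow(res)) stop("no residues with a multi-codon amino acid")
  syn_gc <- vapply(unique(res$wt_codon), function(cd) {
    alt <- setdiff(names(.GENETIC_CODE)[.GENETIC_CODE == .GENETIC_CODE[cd]], cd)
    mean(.gc_content(alt))
  }, numeric(1))
  delta <- syn_gc[res$wt_codon] - .gc_content(res$wt_codon)
  list(mean_percent = 100 * mean(delta),
       n_residues = nrow(res), n_excluded = sum(!multi))
}

#' Correlation between codon base content and amino-acid hydropathy
#'
#' Pearson correlation, over the 61 sense codons, between the number of
#' occurrences of a nucleobase in the codon and the Kyte-Doolittle
#' hydropathy of the encoded amino acid.
#'
#' @param base One of `"A"`, `"C"`, `"G"`, `"T"`.
#' @return List with `r`, `n` and `p` (see [pearson()]).
#' @export
#' @examples
#' hydrophobicity_correlation("T")$r  # positive
hydrophobicity_correlation <- function(base = "T") {
  base <- match.arg(toupper(base), NUCLEOBASES)
  cods <- sense_codons()
  counts <- vapply(strsplit(cods, ""), function(b) sum(b == base), numeric(1))
  pearson(counts, unname(.KYTE_DOOLITTLE[.GENETIC_CODE[cods]]))
}
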