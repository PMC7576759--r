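# Seedable synthetic structurome generator. Emulates the statistical
# structure the analysis assumes: a log-normal protein length distribution,
# a core/surface RSA mixture whose core fraction rises with protein length,
# RSA- and length-dependent hydrophobic composition, biased codon usage,
# and an RSA/hydropathy/dissimilarity-dependent ddG model whose defaults
# are calibrated so that the core and surface missense means land on the
# 1.09 and 0.49 kcal/mol anchors.

# Dissimilarity of an amino-acid mutation: negated BLOSUM62 score rescaled
# to [0, 1] over the off-diagonal score range.
.dissimilarity <- function(wt, mut) {
  s <- blosum_score(wt, mut)
  off <- .BLOSUM62[row(.BLOSUM62) != col(.BLOSUM62)]
  (max(off) - s) / (max(off) - min(off))
}

#' Configuration of the synthetic structurome generator
#'
#' All parameters of the generator, with defaults emulating a curated
#' globular-protein structurome. `ddg_beta0` and `ddg_beta1` default to the
#' values that calibrate the expected core and surface missense means onto
#' `ddg_anchor_core` / `ddg_anchor_surface` (solved exactly from the other
#' parameters by [calibrate_ddg_model()]).
#'
#' @param n_proteins Number of proteins.
#' @param length_meanlog,length_sdlog Log-normal protein-length model.
#' @param core_fraction Probability that a residue is buried, per protein
#'   length bin (rises with length, matching the core-to-length trend).
#' @param rsa_core_shape Beta shape parameters of the buried RSA component
#'   (scaled to 0-20%).
#' @param rsa_surface_shape Beta shape parameters of the exposed RSA
#'   component (scaled to 20-100%).
#' @param core_hydrophobic Probability that a buried residue is Val, Ile,
#'   Leu or Phe, per length bin.
#' @param surface_hydrophobic Same for exposed residues (all bins).
#' @param codon_bias Codon-model bias strength in \[0, 1\]: the preferred
#'   (GC-richest) codon of each family receives this extra mass on top of
#'   the uniform share. A scalar applies to every amino acid; a vector named
#'   by amino acids sets per-family strengths (unnamed families get 0). The
#'   default gives half of the amino-acid families a strong bias (0.5) and
#'   leaves the other half uniform, so that biased and unbiased codons
#'   coexist as they do in real organisms.
#' @param ddg_beta0,ddg_beta1,ddg_beta2,ddg_beta3 ddG model coefficients:
#'   mean ddG = beta0 + beta1 (1 - RSA/100) + beta2 KD(wt) +
#'   beta3 dissimilarity(wt, mut), kcal/mol.
#' @param ddg_noise_sd Gaussian noise SD on ddG (kcal/mol).
#' @param ddg_anchor_core,ddg_anchor_surface Calibration anchors for the
#'   stratum means of missense events (kcal/mol).
#' @param fitness_alpha,fitness_gamma,fitness_noise_sd,fitness_scale Fitness
#'   model: fitness = fitness_scale * wt_score *
#'   logistic(alpha - gamma ddG + noise). The scale lets strongly
#'   stabilizing mutations exceed the wild-type score (a bare logistic would
#'   saturate at wt_score and make advantageous calls impossible); the
#'   defaults put the fitness midpoint at the destabilizing boundary
#'   (ddG = 0.5 kcal/mol).
#' @param wt_score,lof_score Wild-type and loss-of-function fitness scores.
#' @param seed Master seed; independent substreams are derived from it for
#'   each table.
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(n_proteins = 200,
                             length_meanlog = log(250), length_sdlog = 0.45,
                             core_fraction = c(0.24, 0.30, 0.34),
                             rsa_core_shape = c(1.0, 2.5),
                             rsa_surface_shape = c(1.2, 1.4),
                             core_hydrophobic = c(0.45, 0.41, 0.37),
                             surface_hydrophobic = 0.15,
                             codon_bias = stats::setNames(
                               rep(c(0.5, 0), 10), AMINO_ACIDS),
                             ddg_beta0 = NULL, ddg_beta1 = NULL,
                             ddg_beta2 = 0.05, ddg_beta3 = 1.0,
                             ddg_noise_sd = 0.9,
                             ddg_anchor_core = 1.09, ddg_anchor_surface = 0.49,
                             fitness_alpha = 1.0, fitness_gamma = 3.0,
                             fitness_noise_sd = 0.7, fitness_scale = 1.3,
                             wt_score = 1.0, lof_score = 0.0,
                             seed = 1L) {
  codon_bias <- .aa_bias(codon_bias)
  probs <- c(core_fraction, core_hydrophobic, surface_hydrophobic, codon_bias)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (length(core_fraction) != 3L || length(core_hydrophobic) != 3L) {
    stop("core_fraction and core_hydrophobic need one value per length bin")
  }
  cfg <- list(
    n_proteins = as.integer(n_proteins),
    length_meanlog = length_meanlog, length_sdlog = length_sdlog,
    core_fraction = core_fraction,
    rsa_core_shape = rsa_core_shape, rsa_surface_shape = rsa_surface_shape,
    core_hydrophobic = core_hydrophobic,
    surface_hydrophobic = surface_hydrophobic,
    codon_bias = codon_bias,
    ddg_beta0 = ddg_beta0, ddg_beta1 = ddg_beta1,
    ddg_beta2 = ddg_beta2, ddg_beta3 = ddg_beta3,
    ddg_noise_sd = ddg_noise_sd,
    ddg_anchor_core = ddg_anchor_core, ddg_anchor_surface = ddg_anchor_surface,
    fitness_alpha = fitness_alpha, fitness_gamma = fitness_gamma,
    fitness_noise_sd = fitness_noise_sd, fitness_scale = fitness_scale,
    wt_score = wt_score, lof_score = lof_score,
    seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  if (is.null(cfg$ddg_beta0) || is.null(cfg$ddg_beta1)) {
    b <- calibrate_ddg_model(cfg)
    cfg$ddg_beta0 <- b[["beta0"]]
    cfg$ddg_beta1 <- b[["beta1"]]
  }
  cfg
}

.LENGTH_BIN_BREAKS <- c(0, 200, 400, Inf)

# Per-amino-acid bias strengths from a scalar or (partially) named vector.
.aa_bias <- function(codon_bias) {
  if (length(codon_bias) == 1L && is.null(names(codon_bias))) {
    return(stats::setNames(rep(codon_bias, 20), AMINO_ACIDS))
  }
  if (is.null(names(codon_bias)) || !all(names(codon_bias) %in% AMINO_ACIDS)) {
    stop("codon_bias must be a scalar or a vector named by amino acids")
  }
  b <- stats::setNames(rep(0, 20), AMINO_ACIDS)
  b[names(codon_bias)] <- codon_bias
  b
}

# Expected codon distribution within a family under the codon model.
.codon_probs <- function(aa, bias) {
  fam <- names(.GENETIC_CODE)[.GENETIC_CODE == aa]
  gc <- .gc_content(fam)
  pref <- fam[order(-gc, fam)][1]
  p <- rep((1 - bias) / length(fam), length(fam))
  names(p) <- fam
  p[pref] <- p[pref] + bias
  p
}

# Amino-acid distribution of a stratum in a length bin.
.aa_probs <- function(p_hydrophobic) {
  p <- stats::setNames(rep((1 - p_hydrophobic) / 16, 20), AMINO_ACIDS)
  p[HYDROPHOBIC_AAS] <- p_hydrophobic / 4
  p
}

#' Calibrate the intercept and RSA slope of the ddG model
#'
#' Solves for `ddg_beta0` and `ddg_beta1` so that the expected mean ddG of
#' missense single-base events (degeneracy counted) equals the configured
#' core and surface anchors. The expectation is computed exactly from the
#' generator's own distributions: Beta moments for RSA, log-normal partial
#' expectations for the length-bin weights, and the genetic-code
#' combinatorics for the event-level hydropathy and dissimilarity terms.
#'
#' @param config A [generator_config()] (its `ddg_beta0`/`ddg_beta1` are
#'   ignored).
#' @return Named numeric vector `c(beta0, beta1)`.
#' @export
calibrate_ddg_model <- function(config) {
  cfg <- config
  # per-codon event-level sufficient statistics
  cods <- sense_codons()
  ev <- all_code_events(1L)
  ev <- ev[ev$class == "missense", ]
  n_mis <- vapply(cods, function(cd) sum(ev$source == cd), numeric(1))
  d_sum <- vapply(cods, function(cd) {
    e <- ev[ev$source == cd, ]
    if (!nrow(e)) 0 else sum(.dissimilarity(e$wt_aa, e$mut_aa))
  }, numeric(1))

  # per-amino-acid event statistics under the codon model
  aa_nmis <- aa_dsum <- stats::setNames(numeric(20), AMINO_ACIDS)
  for (aa in AMINO_ACIDS) {
    q <- .codon_probs(aa, cfg$codon_bias[[aa]])
    aa_nmis[aa] <- sum(q * n_mis[names(q)])
    aa_dsum[aa] <- sum(q * d_sum[names(q)])
  }

  # length-bin weights: expected residue mass per bin
  mu <- cfg$length_meanlog; s <- cfg$length_sdlog
  partial <- function(lo, hi) {
    exp(mu + s^2 / 2) * (stats::pnorm((log(hi) - mu - s^2) / s) -
                         stats::pnorm((log(lo) - mu - s^2) / s))
  }
  mass <- c(partial(1e-12, 200), partial(200, 400), partial(400, Inf))

  stratum_terms <- function(stratum) {
    w_bin <- if (stratum == "core") mass * cfg$core_fraction else mass * (1 - cfg$core_fraction)
    p_h <- if (stratum == "core") cfg$core_hydrophobic else rep(cfg$surface_hydrophobic, 3)
    num_h <- num_d <- den <- 0
    for (b in 1:3) {
      p <- .aa_probs(p_h[b])
      den <- den + w_bin[b] * sum(p * aa_nmis)
      num_h <- num_h + w_bin[b] * sum(p * aa_nmis * .KYTE_DOOLITTLE[AMINO_ACIDS])
      num_d <- num_d + w_bin[b] * sum(p * aa_dsum)
    }
    sh <- if (stratum == "core") cfg$rsa_core_shape else cfg$rsa_surface_shape
    mean_rsa <- if (stratum == "core") 20 * sh[1] / sum(sh) else 20 + 80 * sh[1] / sum(sh)
    c(x = 1 - mean_rsa / 100, h = num_h / den, d = num_d / den)
  }
  tc <- stratum_terms("core"); ts <- stratum_terms("surface")
  rhs <- c(cfg$ddg_anchor_core - cfg$ddg_beta2 * tc[["h"]] - cfg$ddg_beta3 * tc[["d"]],
           cfg$ddg_anchor_surface - cfg$ddg_beta2 * ts[["h"]] - cfg$ddg_beta3 * ts[["d"]])
  A <- rbind(c(1, tc[["x"]]), c(1, ts[["x"]]))
  b <- solve(A, rhs)
  c(beta0 = b[1], beta1 = b[2])
}

.substream_seeds <- function(seed, n = 4L) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Generate a synthetic structurome dataset
#'
#' Draws a residue table (protein, position, wild-type amino acid and codon,
#' RSA, protein length), a ddG table covering every missense single-base
#' substitution target of every residue, a fitness table for those
#' mutations, and the codon-usage table implied by the codon model.
#' Identical configurations (including the seed) give identical output.
#'
#' @param config A [generator_config()].
#' @return List of class `"synthetic_structurome"` with elements
#'   `residues`, `mutations`, `fitness`, `codon_usage` and `config`.
#' @export
#' @examples
#' ds <- generate_structurome(generator_config(n_proteins = 3, seed = 7))
#' head(ds$residues)
generate_structurome <- function(config) {
  cfg <- config
  stopifnot(inherits(cfg, "generator_config"))
  seeds <- .substream_seeds(cfg$seed, 4L)

  ## --- residues -----------------------------------------------------------
  set.seed(seeds[1])
  L <- pmax(30L, as.integer(round(stats::rlnorm(cfg$n_proteins,
                                                cfg$length_meanlog,
                                                cfg$length_sdlog))))
  pid <- sprintf("P%04d", seq_len(cfg$n_proteins))
  n_res <- sum(L)
  res <- data.frame(
    protein_id = rep(pid, L),
    position = unlist(lapply(L, seq_len)),
    protein_length = rep(L, L),
    stringsAsFactors = FALSE
  )
  bin <- as.integer(length_bin(res$protein_length))
  buried <- stats::runif(n_res) < cfg$core_fraction[bin]
  rsa <- numeric(n_res)
  rsa[buried] <- 20 * stats::rbeta(sum(buried), cfg$rsa_core_shape[1],
                                   cfg$rsa_core_shape[2])
  rsa[!buried] <- 20 + 80 * stats::rbeta(sum(!buried), cfg$rsa_surface_shape[1],
                                         cfg$rsa_surface_shape[2])
  rsa[!buried & rsa <= 20] <- 20.0001
  res$rsa <- round(rsa, 4)

  p_h <- ifelse(buried, cfg$core_hydrophobic[bin], cfg$surface_hydrophobic)
  # residue-wise amino-acid draw: hydrophobic (V/I/L/F) with prob p_h,
  # otherwise uniform over the remaining 16
  hydro <- stats::runif(n_res) < p_h
  aa <- character(n_res)
  aa[hydro] <- sample(HYDROPHOBIC_AAS, sum(hydro), replace = TRUE)
  aa[!hydro] <- sample(setdiff(AMINO_ACIDS, HYDROPHOBIC_AAS), sum(!hydro),
                       replace = TRUE)
  res$wt_aa <- aa

  # codon draw: uniform within family, then switched to the preferred codon
  # with probability codon_bias
  fam_list <- split(names(.GENETIC_CODE)[.GENETIC_CODE != "*"],
                    .GENETIC_CODE[.GENETIC_CODE != "*"])
  pref <- vapply(AMINO_ACIDS, function(a) names(.codon_probs(a, 1))[
    which.max(.codon_probs(a, 1))], character(1))
  fam_size <- lengths(fam_list)[aa]
  pick <- ceiling(stats::runif(n_res) * fam_size)
  codon <- mapply(function(a, k) fam_list[[a]][k], aa, pick, USE.NAMES = FALSE)
  use_pref <- stats::runif(n_res) < unname(cfg$codon_bias[aa])
  codon[use_pref] <- pref[aa[use_pref]]
  res$wt_codon <- codon
  res <- res[, c("protein_id", "position", "wt_aa", "wt_codon", "rsa",
                 "protein_length")]

  ## --- ddG table ----------------------------------------------------------
  set.seed(seeds[2])
  targets <- lapply(sense_codons(), function(cd) {
    ev <- sbs_events(cd)
    sort(unique(ev$mut_aa[ev$class == "missense"]))
  })
  names(targets) <- sense_codons()
  n_t <- lengths(targets)[res$wt_codon]
  mut <- data.frame(
    protein_id = rep(res$protein_id, n_t),
    position = rep(res$position, n_t),
    wt_aa = rep(res$wt_aa, n_t),
    mut_aa = unlist(targets[res$wt_codon], use.names = FALSE),
    stringsAsFactors = FALSE
  )
  rsa_rep <- rep(res$rsa, n_t)
  mut$ddg <- round(
    cfg$ddg_beta0 +
      cfg$ddg_beta1 * (1 - rsa_rep / 100) +
      cfg$ddg_beta2 * .KYTE_DOOLITTLE[mut$wt_aa] +
      cfg$ddg_beta3 * .dissimilarity(mut$wt_aa, mut$mut_aa) +
      stats::rnorm(nrow(mut), 0, cfg$ddg_noise_sd),
    4)
  rownames(mut) <- NULL

  ## --- fitness table ------------------------------------------------------
  set.seed(seeds[3])
  fit <- mut[, c("protein_id", "position", "wt_aa", "mut_aa")]
  lin <- cfg$fitness_alpha - cfg$fitness_gamma * mut$ddg +
    stats::rnorm(nrow(mut), 0, cfg$fitness_noise_sd)
  fit$fitness <- round(cfg$fitness_scale * cfg$wt_score * stats::plogis(lin), 4)
  fit$wt_score <- cfg$wt_score
  fit$lof_score <- cfg$lof_score

  ## --- codon usage table --------------------------------------------------
  usage <- do.call(rbind, lapply(AMINO_ACIDS, function(a) {
    p <- .codon_probs(a, cfg$codon_bias[[a]])
    data.frame(codon = names(p), aa = a, fraction = unname(p),
               stringsAsFactors = FALSE)
  }))
  rownames(usage) <- NULL
  nt <- vapply(NUCLEOBASES, function(b) {
    sum(vapply(strsplit(usage$codon, ""), function(x) sum(x == b), numeric(1)) *
          usage$fraction)
  }, numeric(1))
  attr(usage, "nt_freq") <- nt / sum(nt)

  out <- list(residues = res, mutations = mut, fitness = fit,
              codon_usage = usage, config = cfg)
  class(out) <- "synthetic_structurome"
  out
}

#' @export
print.synthetic_structurome <- function(x, ...) {
  cat("Synthetic structurome:",
      x$config$n_proteins, "proteins,",
      nrow(x$residues), "residues,",
      nrow(x$mutations), "ddG rows (seed", paste0(x$config$seed, ")"), "\n")
  invisible(x)
}

#' Packaged deterministic fixtures
#'
#' Two fixed generator configurations used throughout the test suite:
#' `"small"` (6 short proteins, about 500 residues, for unit tests) and
#' `"medium"` (200 proteins, about 50,000 residues, for statistical
#' parameter-recovery tests).
#'
#' @param name `"small"` or `"medium"`.
#' @return A `synthetic_structurome` (see [generate_structurome()]), with a
#'   checksum in attribute `"checksum"`.
#' @export
make_fixture <- function(name = c("small", "medium")) {
  name <- match.arg(name)
  cfg <- switch(name,
    small = generator_config(n_proteins = 6, length_meanlog = log(85),
                             length_sdlog = 0.3, seed = 101L),
    medium = generator_config(n_proteins = 200, seed = 202L)
  )
  ds <- generate_structurome(cfg)
  attr(ds, "checksum") <- dataset_checksum(ds)
  ds
}

#' Cheap deterministic checksum of a synthetic dataset
#'
#' Row counts and rounded column sums of the four tables, folded into one
#' string; regeneration under the same configuration must reproduce it.
#'
#' @param ds A `synthetic_structurome`.
#' @return Character scalar.
#' @export
dataset_checksum <- function(ds) {
  part <- function(df) {
    nums <- vapply(df[vapply(df, is.numeric, logical(1))], function(x) {
      sum(x)
    }, numeric(1))
    paste(nrow(df), paste(sprintf("%.4f", nums), collapse = ","), sep = ":")
  }
  paste(part(ds$residues), part(ds$mutations), part(ds$fitness),
        part(ds$codon_usage), sep = "|")
}
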