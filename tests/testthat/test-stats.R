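test_that("classify_ddg keeps the boundaries neutral", {
  expect_identical(classify_ddg(c(-0.51, -0.5, 0, 0.5, 0.51)),
                   c("stabilizing", "neutral", "neutral", "neutral",
                     "destabilizing"))
  expect_identical(classify_ddg(0.3, thresholds = c(-0.1, 0.2)),
                   "destabilizing")
  expect_error(classify_ddg(NA_real_), "finite")
  expect_error(classify_ddg(1, thresholds = c(1, -1)))
})

test_that("fitness_classify uses (lof+wt)/2 and 1.25*wt with neutral boundaries", {
  expect_identical(fitness_classify(c(0.4999, 0.5, 1.25, 1.2501), 1, 0),
                   c("deleterious", "neutral", "neutral", "advantageous"))
  # non-default scores: lo = 1.25, hi = 2.5
  expect_identical(fitness_classify(c(1.24, 1.25, 2.5, 2.51), 2, 0.5),
                   c("deleterious", "neutral", "neutral", "advantageous"))
  expect_error(fitness_classify(1, 1, 2), "degenerate")
  expect_error(fitness_classify(NA_real_, 1, 0), "non-finite")
})

test_that("length bins close at 200 and 400", {
  expect_identical(as.character(length_bin(c(1, 200, 201, 400, 401))),
                   c("L<=200", "L<=200", "200<L<=400", "200<L<=400", "L>400"))
})

# One Gly residue with codon GGG: position I gives Arg (twice) and Trp,
# position II gives Glu, Ala, Val, position III is fully synonymous.
ggg_residue <- data.frame(
  protein_id = "P1", position = 1L, wt_aa = "G", wt_codon = "GGG",
  rsa = 50, protein_length = 100L, stringsAsFactors = FALSE)
ggg_mutations <- data.frame(
  protein_id = "P1", position = 1L, wt_aa = "G",
  mut_aa = c("R", "W", "E", "A", "V"),
  ddg = c(1.0, 2.0, 0.5, -0.2, 0.1), stringsAsFactors = FALSE)

test_that("position means with and without synonymous/degeneracy (GGG example)", {
  ev <- expand_events(ggg_residue, ggg_mutations)
  pm <- position_means(ev, "with_syn_and_degeneracy")
  expect_equal(unname(pm), c((1 + 1 + 2) / 3, (0.5 - 0.2 + 0.1) / 3, 0))

  pm2 <- position_means(ev, "without")
  expect_equal(unname(pm2[c("I", "II")]), c((1 + 2) / 2, 0.4 / 3))
  expect_true(is.na(pm2[["III"]]))  # no missense at base III of GGG

  ev_nosyn <- expand_events(ggg_residue, ggg_mutations,
                            include_synonymous = FALSE)
  expect_error(position_means(ev_nosyn, "with_syn_and_degeneracy"),
               "include_synonymous")
})

test_that("summarize_events partitions events and keeps empty strata", {
  ev <- get_events("small")
  s <- summarize_events(ev[ev$class == "missense", ], by = "rsa_stratum")
  expect_identical(s$stratum, c("core", "surface"))
  expect_identical(sum(s$n), sum(ev$class == "missense"))
  core <- ev$ddg[ev$class == "missense" & ev$rsa_stratum == "core"]
  expect_equal(s$mean_ddg[1], mean(core))
  expect_equal(s$sd_ddg[1], stats::sd(core))
  expect_equal(s$frac_stabilizing + s$frac_neutral + s$frac_destabilizing,
               c(1, 1))

  only_core <- ev[ev$rsa_stratum == "core", ]
  s2 <- summarize_events(only_core, by = "rsa_stratum")
  expect_identical(s2$n[s2$stratum == "surface"], 0L)
  expect_true(is.na(s2$mean_ddg[s2$stratum == "surface"]))

  expect_error(summarize_events(ev[0, ]), "empty")
  expect_error(summarize_events(ev, by = "nonexistent"), "unknown stratifier")
})

test_that("pearson agrees with stats::cor and stats::cor.test", {
  x <- c(1.2, 3.4, 2.2, 5.5, 4.1, 0.3)
  y <- c(2.0, 1.1, 4.4, 3.3, 5.5, 1.0)
  p <- pearson(x, y)
  expect_equal(p$r, stats::cor(x, y), tolerance = 1e-12)
  ct <- stats::cor.test(x, y)
  expect_equal(p$p, unname(ct$p.value), tolerance = 1e-9)
  expect_identical(p$n, 6L)

  perfect <- pearson(1:5, 2 * (1:5) + 3)
  expect_equal(perfect$r, 1)
  expect_true(is.finite(perfect$p) && perfect$p < 1e-10)

  expect_error(pearson(1:3, 1:4), "equal length")
  expect_error(pearson(1:2, 1:2), "at least 3")
  expect_error(pearson(c(1, 1, 1), 1:3), "zero variance")
})

test_that("weighted class fractions reproduce the hand-built toy case", {
  ev <- data.frame(
    codon_position = c("I", "I", "II", "II", "III"),
    ddg = c(1, 1, 0, 0, -1), stringsAsFactors = FALSE)
  out <- weighted_class_fractions(ev, weights = c(0.2, 0.3, 0.5))
  expect_equal(unname(out), c(0.5, 0.3, 0.2))
  expect_identical(names(out), c("stabilizing", "neutral", "destabilizing"))
  expect_error(weighted_class_fractions(ev, weights = c(0.5, 0.5)), "length 3")
  expect_error(weighted_class_fractions(ev, weights = c(0.5, 0.4, 0.2)),
               "sum to 1")
})

test_that("equal position weights average the per-position class fractions", {
  ev <- get_events("small")
  frac_at <- function(p) {
    cls <- classify_ddg(ev$ddg[ev$codon_position == p])
    as.numeric(table(factor(cls, levels = c("stabilizing", "neutral",
                                            "destabilizing"))) / length(cls))
  }
  manual <- (frac_at("I") + frac_at("II") + frac_at("III")) / 3
  eq <- weighted_class_fractions(ev, weights = rep(1 / 3, 3))
  expect_equal(unname(eq), manual, tolerance = 1e-12)
  # and the translation weighting is the same average under unequal weights
  te <- translation_error_model()
  manual_te <- te[["I"]] * frac_at("I") + te[["II"]] * frac_at("II") +
    te[["III"]] * frac_at("III")
  expect_equal(unname(weighted_class_fractions(ev, te)), manual_te,
               tolerance = 1e-12)
})

test_that("missing positions trigger weight renormalization with a warning", {
  ev <- data.frame(codon_position = c("I", "I", "II"),
                   ddg = c(1, 1, 0), stringsAsFactors = FALSE)
  expect_warning(out <- weighted_class_fractions(ev), "renormalizing")
  w <- translation_error_model()[1:2] / sum(translation_error_model()[1:2])
  expect_equal(unname(out), c(0, unname(w[2]), unname(w[1])))
})

test_that("titv means match manual stratified means", {
  ev <- get_events("small")
  tm <- titv_means(ev, include_synonymous = TRUE)
  expect_identical(tm$stratum[1:2], c("transition", "transversion"))
  expect_equal(tm$mean_ddg[tm$stratum == "transition"],
               mean(ev$ddg[ev$titv == "transition"]))
  tm2 <- titv_means(ev, include_synonymous = FALSE)
  expect_equal(tm2$mean_ddg[tm2$stratum == "transversion"],
               mean(ev$ddg[ev$titv == "transversion" & ev$class != "synonymous"]))
})

test_that("codon_usage_delta is zero when ddG depends only on the amino acids", {
  res <- data.frame(protein_id = "P1", position = 1L, wt_aa = "D",
                    wt_codon = "GAT", rsa = 30, protein_length = 100L,
                    stringsAsFactors = FALSE)
  mut <- data.frame(protein_id = "P1", position = 1L, wt_aa = "D",
                    mut_aa = c("N", "H", "Y", "A", "G", "V", "E"),
                    ddg = c(0.2, 0.9, 1.4, 0.5, 1.1, 0.7, 0.1),
                    stringsAsFactors = FALSE)
  d <- codon_usage_delta(res, mut)
  # GAT and GAC reach identical amino-acid multisets at every position
  expect_equal(d$delta_percent, 0, tolerance = 1e-12)
  expect_equal(d$mean_used, d$mean_syn, tolerance = 1e-12)
})

test_that("codon_usage_delta matches the hand formula and is antisymmetric", {
  # Lys codons: AAA reaches Ile at base II where AAG reaches Met
  mut <- data.frame(protein_id = "P1", position = 1L, wt_aa = "K",
                    mut_aa = c("Q", "E", "T", "R", "I", "N", "M"),
                    ddg = c(0.4, 0.6, 1.0, 0.8, 2.0, 0.3, 0.5),
                    stringsAsFactors = FALSE)
  res_a <- data.frame(protein_id = "P1", position = 1L, wt_aa = "K",
                      wt_codon = "AAA", rsa = 30, protein_length = 100L,
                      stringsAsFactors = FALSE)
  res_g <- res_a; res_g$wt_codon <- "AAG"

  d_a <- codon_usage_delta(res_a, mut)
  d_g <- codon_usage_delta(res_g, mut)

  # hand computation: both codons yield 8 non-nonsense events with equal
  # weights; the sets differ only in Ile (used AAA) versus Met (used AAG)
  ev_used <- c(0.4, 0.6, 1.0, 0.8, 2.0, 0.3, 0.3, 0)  # Q E T R I N N syn
  ev_syn  <- c(0.4, 0.6, 1.0, 0.8, 0.5, 0.3, 0.3, 0)  # Q E T R M N N syn
  popvar <- function(x) mean((x - mean(x))^2)
  sigma <- sqrt(popvar(ev_used) + popvar(ev_syn))
  expect_equal(d_a$delta_percent,
               100 * (mean(ev_syn) - mean(ev_used)) / sigma, tolerance = 1e-12)
  expect_identical(d_a$n_used_events, 8L)
  expect_identical(d_a$n_syn_events, 8L)

  # swapping which codon is used flips the sign exactly
  expect_equal(d_a$delta_percent, -d_g$delta_percent, tolerance = 1e-12)
  d_at <- codon_usage_delta(res_a, mut, weighting = "translation")
  d_gt <- codon_usage_delta(res_g, mut, weighting = "translation")
  expect_equal(d_at$delta_percent, -d_gt$delta_percent, tolerance = 1e-12)
})

test_that("single-codon amino acids are excluded from usage deltas", {
  res <- data.frame(protein_id = "P1", position = 1:2, wt_aa = c("K", "M"),
                    wt_codon = c("AAA", "ATG"), rsa = 30,
                    protein_length = 100L, stringsAsFactors = FALSE)
  mut <- data.frame(protein_id = "P1", position = 1L, wt_aa = "K",
                    mut_aa = c("Q", "E", "T", "R", "I", "N", "M"),
                    ddg = 0.5, stringsAsFactors = FALSE)
  d <- codon_usage_delta(res, mut)
  expect_identical(d$n_excluded, 1L)

  only_met <- res[2, ]
  expect_error(codon_usage_delta(only_met, mut), "multi-codon")
})

test_that("bias_classify applies the 12.5% relative-deviation rule", {
  usage <- data.frame(codon = c("GAT", "GAC"), fraction = c(0.6, 0.4),
                      stringsAsFactors = FALSE)
  expect_identical(unname(bias_classify(c("GAT", "GAC"), usage)),
                   c("biased", "biased"))

  usage$fraction <- c(0.55, 0.45)  # deviation 0.10 < 0.125
  expect_identical(unname(bias_classify("GAT", usage)), "unbiased")

  usage$fraction <- c(0.5625, 0.4375)  # deviation exactly 0.125: unbiased
  expect_identical(unname(bias_classify("GAT", usage)), "unbiased")

  usage$fraction <- c(0.5, 0.5)
  # nucleotide-frequency expectation: T four times likelier than C at the
  # third base makes the uniform observation strongly biased
  nt <- c(A = 0.25, C = 0.1, G = 0.25, T = 0.4)
  expect_identical(unname(bias_classify("GAT", usage,
                                        mode = "nucleotide_freq",
                                        nt_freq = nt)), "biased")
  expect_error(bias_classify("GAT", usage, mode = "nucleotide_freq"),
               "nt_freq")

  # single-codon families cannot deviate
  expect_identical(unname(bias_classify("ATG", usage)), "unbiased")
  expect_error(bias_classify("TAA", usage), "stop codon")
  expect_error(bias_classify("AAA", usage), "does not cover")
})

test_that("gc_delta reproduces the Lys hand computation", {
  expect_equal(gc_delta(data.frame(wt_codon = "AAA"))$mean_percent,
               100 / 3, tolerance = 1e-12)
  expect_equal(gc_delta(data.frame(wt_codon = "AAG"))$mean_percent,
               -100 / 3, tolerance = 1e-12)
  mixed <- gc_delta(data.frame(wt_codon = c("AAA", "ATG")))
  expect_identical(mixed$n_excluded, 1L)
  expect_identical(mixed$n_residues, 1L)
  expect_error(gc_delta(data.frame(wt_codon = "ATG")), "multi-codon")
})

test_that("hydropathy correlations match a direct recomputation", {
  for (b in c("T", "A")) {
    h <- hydrophobicity_correlation(b)
    counts <- vapply(strsplit(sense_codons(), ""),
                     function(x) sum(x == b), numeric(1))
    kd <- unname(kyte_doolittle(translate(sense_codons())))
    expect_equal(h$r, stats::cor(counts, kd), tolerance = 1e-12)
    expect_identical(h$n, 61L)
  }
  expect_gt(hydrophobicity_correlation("T")$r, 0)
  expect_lt(hydrophobicity_correlation("A")$r, 0)
})

test_that("rsa_profile recovers exact piecewise relations", {
  rsa <- seq(0.5, 99.5, by = 1)
  ddg <- ifelse(rsa <= 20, 3 - 0.1 * rsa + 0.002 * rsa^2, 2 - 0.01 * rsa)
  ev <- data.frame(rsa = rsa, ddg = ddg)
  # exact data makes summary.lm warn about a perfect fit; that is the point
  prof <- suppressWarnings(rsa_profile(ev, bin_width = 1))
  expect_identical(nrow(prof$bins), 100L)
  expect_equal(unname(prof$linear_fit$coefficients), c(2, -0.01),
               tolerance = 1e-8)
  expect_equal(prof$linear_fit$r_squared, 1, tolerance = 1e-8)
  expect_equal(unname(prof$quadratic_fit$coefficients), c(3, -0.1, 0.002),
               tolerance = 1e-8)

  # RSA = 100 falls into the last bin rather than opening a new one
  ev2 <- data.frame(rsa = c(99.2, 100), ddg = c(1, 2))
  # both fits are impossible here: two warnings, one per regime
  w <- testthat::capture_warnings(prof2 <- rsa_profile(ev2))
  expect_length(w, 2)
  expect_match(w, "too few", all = TRUE)
  expect_equal(prof2$bins$bin_lo, 99)
  expect_equal(prof2$bins$n, 2)
})

test_that("protein_summary computes core-to-length ratios", {
  ev <- get_events("small")
  ps <- protein_summary(ev[ev$class == "missense", ])
  expect_identical(nrow(ps), length(unique(ev$protein_id)))
  ds <- get_fixture("small")
  p1 <- ds$residues[ds$residues$protein_id == ps$protein_id[1], ]
  expect_identical(ps$n_core_residues[1], sum(p1$rsa <= 20))
  expect_equal(ps$core_to_length[1], sum(p1$rsa <= 20) / p1$protein_length[1])
  expect_equal(ps$mean_ddg[1],
               mean(ev$ddg[ev$class == "missense" &
                             ev$protein_id == ps$protein_id[1]]))
})

test_that("composition_profile reports core hydrophobic fractions per bin", {
  res <- data.frame(wt_aa = c("V", "G", "K", "L"),
                    rsa = c(10, 10, 15, 50),
                    protein_length = 100L, stringsAsFactors = FALSE)
  expect_warning(cp <- composition_profile(res), "no core residues")
  expect_identical(cp$n_core, c(3L, 0L, 0L))
  expect_equal(cp$hydrophobic_fraction[1], 1 / 3)
  expect_true(all(is.na(cp$hydrophobic_fraction[2:3])))
})
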