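# mutrobust

Protein mutational robustness at the genetic-code and codon level.

`mutrobust` analyses how single- and multiple-base substitutions of codons
affect protein stability, at the scale of whole structuromes. It provides:

* **Genetic-code combinatorics** — exhaustive enumeration of the 549
  single-base substitution events of the 61 sense codons (and all
  multiple-base position-set classes), with synonymy, degeneracy,
  transition/transversion labels, minimal codon distances between amino
  acids, and per-position reachability of amino-acid mutations.
* **Annotation** — expansion of residue tables (wild-type codon + relative
  solvent accessibility) into classified substitution events joined with
  per-mutation folding free-energy changes (ddG, kcal/mol, positive =
  destabilizing), with strict validation, gap reports and conservation
  bookkeeping; CDS-to-protein mapping checks.
* **Stratified statistics** — stabilizing/neutral/destabilizing fractions
  (neutral-inclusive ±0.5 kcal/mol thresholds), core/surface (RSA ≤ 20%)
  and RSA-profile summaries, per-codon-position means with and without
  synonymous events and degeneracy, translation-error weighting
  (0.313/0.062/0.625 per position), BLOSUM62 and ti/tv stratification,
  used-versus-synonymous codon deltas, codon-usage-bias classification
  (12.5% relative deviation rule), GC deltas, and fitness-effect
  classification.
* **A seedable synthetic structurome generator** — emulates the statistical
  structure of curated X-ray structuromes (log-normal lengths, core/surface
  RSA mixture, length-dependent hydrophobic core composition, biased codon
  usage, an RSA/hydropathy/dissimilarity ddG model calibrated exactly onto
  core/surface anchors of 1.09/0.49 kcal/mol) so the entire pipeline is
  testable offline, with parameter recovery as the acceptance surface.
* **IO and a CLI** — TSV/FASTA/Kazusa-style codon-usage readers, JSON
  reports with config provenance, and a `simulate` / `annotate` / `stats` /
  `code-analysis` / `report` command-line interface (`inst/cli/mutrobust`).

See the vignette (`vignettes/mutational-robustness-methods.Rmd`) for the
model, the conventions, and the generator calibration.

## Worked example

```r
library(mutrobust)

ds <- generate_structurome(generator_config(n_proteins = 20, seed = 7))
ds
#> Synthetic structurome: 20 proteins, 5578 residues, 33269 ddG rows (seed 7)

ev <- expand_events(ds$residues, ds$mutations)
attr(ev, "counts")
#>    residues       total    nonsense  synonymous    missense gap_dropped
#>        5578       50202        2495        9678       38029           0

summarize_events(ev[ev$class == "missense", ], by = "rsa_stratum")
#> Robustness summary by rsa_stratum
#>  stratum     n mean_ddg sd_ddg frac_stabilizing frac_neutral frac_destabilizing
#>     core 11325    1.078  0.956            0.050        0.219              0.730
#>  surface 26704    0.492  0.964            0.151        0.352              0.496

# buried mutations are about twice as destabilizing as surface ones

pm <- position_means(ev, "with_syn_and_degeneracy")
round(pm, 3)
#>     I    II   III
#> 0.602 0.775 0.208

# position III, the position translation errors hit most often, is by far
# the least destabilizing:
round(pearson(100 * translation_error_model(), pm)$r, 4)
#> [1] -0.9875

codon_usage_delta(ds$residues, ds$mutations,
                  weighting = "translation")$delta_percent
#> [1] -3.090216   # used-vs-synonymous delta, percent of combined SD

nrow(reachable_aa_mutations("III"))
#> [1] 14
```

The full analysis bundle — core/surface, BLOSUM, per-base, ti/tv,
usage-delta and bias tables, GC delta, per-protein summaries, fitness
fractions — is one call: `structurome_report(ds$residues, ds$mutations,
usage = ds$codon_usage, fitness = ds$fitness)`, or from the shell:

```sh
Rscript inst/cli/mutrobust simulate --out data --n-proteins 50 --seed 1
Rscript inst/cli/mutrobust report --residues data/residues.tsv \
    --mutations data/mutations.tsv --usage data/codon_usage.tsv \
    --fitness data/fitness.tsv --out report.json
```

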