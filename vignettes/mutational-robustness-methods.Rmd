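---
title: "Methods: mutational robustness at the genetic-code and codon level"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutational robustness at the genetic-code and codon level}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutrobust)
```

This vignette documents the analysis model implemented by `mutrobust`, the
conventions and constants it is built on, the design of the synthetic
structurome generator used for testing, and the numerical choices that are
not obvious from the function reference.

## The analysis model

The unit of analysis is the *substitution event*: a codon together with one
of its base substitutions. Every sense codon admits exactly nine single-base
substitutions (SBS; three positions times three alternative bases), so a
protein of $L$ residues contributes $9L$ events. Each event is classified by
comparing the translations of the source and target codons:

* **synonymous** — same amino acid; by convention the folding free-energy
  change is exactly $\Delta\Delta G = 0$;
* **missense** — a different amino acid; the event inherits the
  $\Delta\Delta G$ of the amino-acid mutation;
* **nonsense** — the target is a stop codon; nonsense events are excluded
  from all stability statistics (a truncated protein has no meaningful
  folding free energy).

$\Delta\Delta G$ (kcal/mol, positive = destabilizing) is a property of the
*amino-acid* mutation, not of the base-level path. When several distinct
substitutions of one codon reach the same amino acid (e.g. `TTA` reaches Phe
through both `TTT` and `TTC`), all of them carry the same $\Delta\Delta G$
and the mutation contributes with its path multiplicity. We call this
multiplicity the *degeneracy* of the mutation from that codon. Statistics
are therefore computed in two modes: *with synonymous events and
degeneracy* (the natural weighting when base substitutions, not amino-acid
mutations, are the random objects — e.g. under a translation-error model)
and *without* (each distinct amino-acid mutation counted once, synonymous
events dropped).

Residues are stratified by relative solvent accessibility (RSA, percent):
RSA $\le 20\%$ is *core*, RSA $> 20\%$ is *surface*, with the boundary in
the core. Values marginally above 100% (an artifact of some accessibility
programs) are clamped to 100. Stability classes use the neutral-inclusive
thresholds: stabilizing below $-0.5$, destabilizing above $+0.5$, neutral on
and between the boundaries. Fitness effects of mutations are classified as
deleterious below $(\mathrm{lof}+\mathrm{wt})/2$, advantageous above
$1.25\,\mathrm{wt}$, neutral in between (boundaries neutral).

The translation-error model assigns codon positions I, II, III the
mispairing frequencies $(0.313,\; 0.062,\; 0.625)$: position II is read the
most accurately and position III the least. Under a *weighting* over
positions $w_p$, the fraction of class $c$ is the weight-averaged
per-position fraction $\sum_p w_p \, f_c(p)$, not the pooled fraction; the
two differ because nonsense exclusion leaves unequal event counts per
position. The *random-mutation* model is the special case $w_p = 1/3$.

## Genetic-code combinatorics and a note on reachability counts

`all_code_events()` enumerates all $61 \times 9 = 549$ single-base events:
392 missense, 134 synonymous, and 23 nonsense. Multiple-base substitutions
are enumerated per *position set* (I+II, I+III, II+III, I+II+III), with
every named position changing, which keeps the seven position-set classes
disjoint. Of the 380 ordered amino-acid mutations, those at minimal codon
Hamming distance 1 are reachable by some SBS; the rest require simultaneous
multiple-base changes.

`reachable_aa_mutations(p)` restricts the enumeration to a single codon
position and returns the distinct ordered (wild-type, mutant) amino-acid
pairs, synonymous and stop-involving events excluded. Exhaustive
enumeration gives **14** pairs for base III, **62** for base I and **82**
for base II (total 158). Reference figures of 64 (base I) and 80 (base II)
with the same total of 158 are in circulation; we were unable to reproduce
them under any counting convention we tried (per-codon-context counting,
splitting the serine/leucine/arginine codon blocks, counting stop-involving
events, assigning each pair to a unique position), and the discrepancy is
exactly what a hand tally of *unordered* pairs (31/41, miscounted as 32/40
and then doubled) would produce. The package reports the enumerated values;
the acceptance suite keeps the reference values as stated and the two
corresponding assertions fail, documenting the disagreement rather than
hiding it. The qualitative conclusion is unaffected: base III reaches by
far the fewest amino-acid mutations and base II the most.

```{r reachability}
vapply(c("I", "II", "III"),
       function(p) nrow(reachable_aa_mutations(p)), integer(1))
```

## Used versus synonymous codons

For each residue of a multi-codon amino acid we compare the mean
$\Delta\Delta G$ of the SBS events reachable from its *used* codon with the
events reachable from its *other synonymous* codons, summarized as the
normalized difference

$$\delta = 100 \cdot
  \frac{\langle\Delta\Delta G\rangle_{syn} - \langle\Delta\Delta G\rangle_{used}}
       {\sqrt{\sigma^2_{used} + \sigma^2_{syn}}} \; [\%],$$

with population variances; positive $\delta$ means the used codons are the
more robust ones. Three conventions required a decision and are fixed as
follows:

* **Per-residue equal weight.** Every residue contributes equally to each
  side, regardless of its amino acid's family size or event count.
* **Per-codon weighting on the synonymous side.** The synonymous side of a
  residue is the *mean of per-codon means* over its alternative codons
  (weight $1/(n_{\text{events in codon}} \cdot n_{\text{codons}})$), since
  synonymous codons enter as codon-level counterfactuals, not as a pooled
  event bag. For the used side the two readings coincide (one codon).
* **Synonymous events at $\Delta\Delta G = 0$ are included on both sides;**
  residues of single-codon amino acids (Met, Trp) are excluded and counted,
  as no counterfactual exists.

Under the translation weighting, each event's weight is additionally
multiplied by its position's mispairing frequency. Two exact identities
serve as self-tests: $\delta = 0$ whenever $\Delta\Delta G$ depends only on
the amino-acid pair and the used and synonymous codons reach the same
amino-acid multisets (e.g. the Asp pair `GAT`/`GAC`), and $\delta$ flips
sign exactly when the roles of the two codons of a two-codon family are
swapped.

A codon is *biased* in an organism when its within-family usage deviates
from expectation by more than 12.5% in **relative** terms,
$|f_{obs} - f_{exp}|/f_{exp} > 0.125$. The expectation is either
equiprobability ($1/k$ for a $k$-codon family) or, in
`mode = "nucleotide_freq"`, proportional to the product of the organism's
nucleotide frequencies over the codon's bases, renormalized within the
family. A relative rather than absolute deviation makes the rule comparable
across family sizes ($f_{exp}$ ranges from $1/6$ to $1/2$). Single-codon
families cannot deviate and are classified unbiased.

The correlation between codon base content and residue hydropathy
(`hydrophobicity_correlation()`) is computed *per codon* over the 61 sense
codons — the count of the base in the codon against the Kyte–Doolittle
hydropathy of the encoded amino acid — rather than per amino acid, so that
codon multiplicity weights the relation the same way it weights the
structurome statistics.

## The synthetic structurome generator

Structurome-scale inputs (thousands of X-ray structures with per-mutation
$\Delta\Delta G$ predictions) cannot be shipped or recomputed here, so the
package generates synthetic datasets that emulate the *statistical
structure the analysis assumes*, and uses parameter recovery on them as its
principal acceptance surface. The generator is seedable and fully
deterministic: independent substreams are derived from one master seed for
the residue, $\Delta\Delta G$ and fitness tables, so regenerating with the
same configuration is byte-identical.

The default configuration *is* the study condition of the test suite; its
components, with rationale:

* **Protein lengths** — log-normal, `meanlog = log(250)`, `sdlog = 0.45`
  (lengths in residues, minimum 30): right-skewed with a median of ~250,
  the familiar shape of globular-protein length distributions.
* **RSA** — a two-component mixture with disjoint supports: buried residues
  draw $20 \cdot \mathrm{Beta}(1.0, 2.5)$ (RSA 0–20%), exposed residues
  $20 + 80 \cdot \mathrm{Beta}(1.2, 1.4)$ (20–100%). The buried probability
  rises with the protein-length bin, `core_fraction = (0.24, 0.30, 0.34)`
  for $L \le 200$, $200 < L \le 400$, $L > 400$ — longer chains bury
  proportionally more residues.
* **Composition** — buried residues are Val/Ile/Leu/Phe with probability
  `core_hydrophobic = (0.45, 0.41, 0.37)` per length bin (the hydrophobic
  core dilutes slightly in larger proteins), exposed residues with
  probability 0.15; the remaining mass is uniform over the other 16 amino
  acids.
* **Codon model** — within each family, frequency $(1-b)/k$ plus $b$ on one
  *preferred* codon (the GC-richest, ties broken alphabetically), with bias
  strength $b$ per amino acid. Because the 12.5% relative rule classifies a
  whole family one way for any single $b$ (all biased for $b > 0.125$), the
  default gives alternate amino-acid families $b = 0.5$ and $b = 0$, so
  biased and unbiased codons coexist as they do in real organisms; a scalar
  `codon_bias` is accepted and applied to all families, and $b = 0$ yields
  an exactly uniform, all-unbiased table.
* **$\Delta\Delta G$ model** (kcal/mol) — for each missense amino-acid
  mutation of each residue,
  $$\Delta\Delta G = \beta_0 + \beta_1\,(1 - \mathrm{RSA}/100)
    + \beta_2\,\mathrm{KD}(wt) + \beta_3\,d(wt, mut) + \varepsilon,$$
  with $d$ the BLOSUM62 score negated and rescaled to $[0,1]$ over the
  off-diagonal range, $\mathrm{KD}$ the Kyte–Doolittle hydropathy,
  $\beta_2 = 0.05$, $\beta_3 = 1$, and $\varepsilon \sim N(0, 0.9^2)$.
  Burial, wild-type hydrophobicity and physicochemical dissimilarity are
  the three strongest determinants of mutational destabilization, and a
  linear model with Gaussian noise is the simplest form whose stratified
  *means* — the only quantities the analysis tests — can be calibrated
  exactly. Skewness of real $\Delta\Delta G$ distributions is deliberately
  not emulated.
* **Fitness model** — $\mathrm{fitness} = s \cdot \mathrm{wt} \cdot
  \mathrm{logistic}(\alpha - \gamma\,\Delta\Delta G + \eta)$ with
  $s = 1.3$, $\alpha = 1$, $\gamma = 3$, $\eta \sim N(0, 0.7^2)$. The
  saturation scale $s$ matters: a bare logistic never exceeds the wild-type
  score, which would make the advantageous class unreachable by
  construction. With these defaults the fitness midpoint sits at the
  destabilizing boundary ($\Delta\Delta G = 0.5$) and strongly stabilizing
  mutations occasionally exceed $1.25\,\mathrm{wt}$, giving roughly
  57% deleterious / 34% neutral / 8% advantageous calls at scale.

### Exact calibration of the ddG intercept and RSA slope

`ddg_beta0` and `ddg_beta1` are not hand-tuned. `calibrate_ddg_model()`
solves the $2\times2$ linear system that makes the *expected* mean
$\Delta\Delta G$ of missense SBS events (degeneracy counted) equal the
anchors `ddg_anchor_core = 1.09` and `ddg_anchor_surface = 0.49` kcal/mol.
The expectation is assembled analytically, with no Monte Carlo step, from

* per-codon missense event counts and dissimilarity sums from the code
  table, averaged over the codon model;
* the amino-acid distribution of each stratum and length bin;
* length-bin residue masses from log-normal partial expectations,
  $E[L\,\mathbf{1}\{a < L \le b\}] =
  e^{\mu + \sigma^2/2}\,[\Phi(\tfrac{\ln b - \mu - \sigma^2}{\sigma}) -
  \Phi(\tfrac{\ln a - \mu - \sigma^2}{\sigma})]$;
* Beta means for the stratum RSA terms.

Because every term is an exact expectation of the sampling process, the
realized stratum means converge to the anchors as the dataset grows, which
is what the parameter-recovery acceptance tests assert (within three
cluster-robust standard errors, clustering events within residues — events
of one residue share its RSA and amino acid, so event-level standard errors
would be anti-conservative).

### Fixtures and problem sizes

Two frozen configurations are packaged (`make_fixture()`): **small** — 6
proteins of median length 85, seed 101, 476 residues — for fast unit tests
and examples; **medium** — 200 proteins under the default configuration,
seed 202, ~55,000 residues and ~325,000 $\Delta\Delta G$ rows — for
statistical recovery tests. The sizes are the package's own choice: small
enough that the full suite runs in well under five minutes on one CPU,
large enough that the 3-SE recovery bands are a few thousandths of a
kcal/mol wide and would detect real calibration errors. Fixtures are always
generated in code, never stored.

## Numerical and formatting choices

* Tabular IO is UTF-8 TSV with a header, `.` decimal separator and no
  quoting; JSON is written with full precision (`digits = NA`). Outputs are
  deterministic given inputs and configuration.
* Variances in the usage delta are population variances (the event sets
  are the full populations for the residue, not samples).
* `pearson()` implements the product-moment formula directly with the
  two-sided $t$ p-value; the test suite cross-checks it against
  `stats::cor` / `stats::cor.test`. The $|r| = 1$ edge case is guarded with
  a machine-epsilon floor rather than returning `NaN`.
* RSA bins are half-open $[k, k+w)$ with the last bin closed at 100; the
  two regimes of the RSA–$\Delta\Delta G$ profile are fitted separately
  (least-squares line above 20%, second-degree polynomial at or below 20%),
  as the relation visibly changes character at the core boundary.
* Empty strata are reported as $n = 0$ rows with `NA` statistics rather
  than dropped; weightings over positions renormalize over populated
  positions with a warning rather than failing.
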