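---
title: "Methods: compensated pathogenic deviations, their molecular impact, and genetic background"
author: "cpdtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compensated pathogenic deviations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpdtools)
```

## The problem

A compensated pathogenic deviation (CPD) is a missense variant that is
pathogenic in humans although the mutant residue is the native one in an
ortholog of another species; the damaging effect is suppressed there,
most plausibly by compensatory substitutions in the sequence
neighborhood. Hemophilia A and B — caused by missense variants in the
coagulation factors FVIII (gene *F8*) and FIX (*F9*) — make an unusually
good model system: curated variant databases attach a clinical severity
label to each variant, and the hemostasis pathway whose genetic state
modulates the bleeding phenotype is well characterized. `cpdtools`
implements the resulting analysis chain: CPD classification from ortholog
alignments, molecular-impact characterization, severity-association
statistics, and per-individual genetic-background accounting, plus a
synthetic-data generator that makes every stage testable without any
external database.

## CPD classification

Given an ortholog multiple sequence alignment with one designated human
row, a variant `wt`→`mut` at human position $p$ (1-based in the ungapped
human sequence) maps to the alignment column holding the $p$-th non-gap
human character. The variant is a CPD **iff at least one non-human row
carries `mut` at that column** — an existential criterion, so a single
supporting species suffices. Matching is exact, case-insensitive,
single-letter equality; gaps (`-`, `.`) and ambiguity codes never match;
the human row itself never counts as support. The procedure has no
thresholds, which is why the package can demand *exact* recovery of
planted compensations in its tests.

Two deliberate robustness decisions:

* **Wild-type mismatches.** Variant databases and the canonical sequence
  underlying an alignment occasionally disagree on the wild-type residue.
  A mismatch between the annotated `wt` and the human row does not abort
  the run; the call is emitted, flagged (`wt_check = "mismatch"`), and
  excluded from severity statistics by default (overridable).
* **Curation flag.** Manual causality curation of variants is outside the
  package's scope, but a logical `curated` column is carried through and
  `severity_contingency(..., curated_only = TRUE)` restricts analyses to
  curated rows.

All column indices exposed by the package are 1-based, matching R's
indexing convention; the CLI output states this in a header comment.

## Molecular impact measures

Four complementary quantities are attached to each call:

* **ΔΔG** (kcal/mol, destabilizing positive): folding free-energy change
  upon mutation, supplied as an external table (e.g. FoldX output). The
  package ingests, never computes, it.
* **RSA** (%): relative solvent accessibility of the mutated residue in
  an experimental structure, also an external table (e.g. NACCESS
  output). Values are validated to lie in $[0, 100]$.
* **BLOSUM62 element**: the published log-odds substitution score between
  `wt` and `mut`, embedded as a constant and checksum-tested against a
  vendored plain-text copy.
* **Shannon entropy** (bits) of the variant's alignment column:
  $H = -\sum_i p_i \log_2 p_i$ over the amino-acid frequencies at the
  column, ranging from 0 (fully conserved) to $\log_2 20 \approx 4.322$.
  Base 2 is forced by that stated ceiling. The human row *is* included in
  the counts (the sum runs over all amino acids at the column), while
  gaps and ambiguity codes are excluded from both the counts and the
  normalizing total.

Missing ΔΔG/RSA values (positions not resolved in any structure) are
handled *pairwise per property*: a variant missing ΔΔG still contributes
to the BLOSUM62 and entropy comparisons.

## Statistics

**Fisher's exact test** (`fisher_exact_2x2`) is implemented in-package as
conditional hypergeometric enumeration: given fixed margins, the p-value
sums the probabilities of all tables whose point probability is at most
that of the observed table, with a relative tie tolerance of $10^{-7}$.
Degenerate margins return $p = 1$ with a warning. The test suite checks
this implementation two independent ways — exhaustively against a
log-binomial-coefficient enumeration for every 2×2 table with total
$\le 60$, and against `stats::fisher.test` on random tables.

**Mood's median test** (`moods_median_test`) pools both samples, computes
the grand median, dichotomizes each observation into above versus
not-above it, and tests the resulting 2×2. Two conventions are explicit:

* *Tie rule*: values equal to the grand median count as "≤ median". A
  consequence worth knowing: the p-value is invariant under strictly
  *increasing* transforms of the data, but not in general under
  order-reversing ones, because the grand median point itself switches
  sides of the dichotomy.
* *Backend*: the default is the exact Fisher test, which stays honest for
  the small curated severity subsets this analysis meets (down to 12 vs
  13 values); a Pearson chi-square without continuity correction is
  available via `backend = "chisq"`.

No multiple-testing correction is applied anywhere — the analysis reports
each comparison's p-value as is.

**Overlap** (`overlap_fraction`) reports the percentage of one sample
lying strictly below the median of another, the descriptive statistic
used to express how much the CPD and noCPD impact distributions overlap.

**Severe fractions** are reported as integer percentages with half-up
rounding (`floor(x + 0.5)`), the convention that reproduces the published
group percentages from their printed counts.

One reproduction caveat: the published FIX severity table (CPD 25
mild/22 severe; noCPD 93/251) yields $p = 5.5\times10^{-4}$ under the
standard two-sided test implemented here (and under every common
alternative convention we examined), while the printed value is
$4.0\times10^{-4}$; the FVIII and pooled other-disease tables reproduce
exactly. The package reports what the counts imply.

## Genetic background

Background is counted over a fixed panel of hemostasis genes; the bundled
default is a representative 19-gene list (coagulation cascade factors,
fibrinogen chains, von Willebrand factor, kininogen, GP1BB, and the main
natural anticoagulants) with *F8* and *F9* focal — any panel file can be
substituted. Conventions:

* A protein is "mutated" for an individual when it carries ≥ 1 missense
  variant in that gene; burden counts variants, prevalence counts
  individuals.
* Zygosity is ignored — any non-reference genotype counts once per
  (individual, variant). The emulated cohort is male, so the X-linked
  focal genes are effectively hemizygous anyway.
* Both burden totals are emitted: including the focal genes and excluding
  them, so either reading of "background size" is recomputable. Per-variant
  background ranges exclude the focal variant itself but keep other
  same-gene (cis) variants.
* Unknown-pathogenicity variants count as neutral in the composition
  summary by default (a pathogenicity annotation database marks
  pathogenic variants; absence means "not annotated"), with
  `unknown_as_neutral = FALSE` keeping them separate.
* Variants carried by ≥ 2 individuals are flagged `multi_carrier`; only
  those exhibit between-carrier background variability.

## The synthetic-data generator

The generator exists so that every pipeline stage can be tested against
recorded ground truth. Its defaults mirror the scale of the real study
system: 971 pathogenic variants with 122 compensated, protein length
2332, a cohort of 1233 males over five superpopulations, and a 19-gene
panel.

* **Alignments.** Each site draws ortholog residues from a two-state
  mixture — the human residue with frequency $q$, the remainder spread
  over $k$ alternatives — with $q$ solved so the mixture's entropy matches
  a per-site target. This is deliberately approximate entropy *targeting*
  (realized column entropies are noisy and biased low at small species
  counts), not phylogenetic simulation: there is no tree, no substitution
  model, and no linkage. Default site targets follow a right-skewed Beta
  profile (most sites conserved). Ortholog-only insertion columns and
  scattered deletion gaps exercise the position-to-column mapping.
* **Planting.** CPD-true variants get the mutant residue written into 1–3
  non-human rows at their column; CPD-false variants have it scrubbed
  from all non-human rows. Classifier recall and precision must therefore
  both be exactly 1.
* **Impact and severity.** ΔΔG is Gaussian per group — defaults
  $\mathcal{N}(0.8, 1.0)$ for CPDs vs $\mathcal{N}(1.8, 1.2)$ for noCPDs,
  a 1.0 kcal/mol shift in the direction "compensated variants are
  milder"; RSA is uniform per group (noCPDs more buried). Severity is
  coupled to ΔΔG alone through a logistic model
  $P(\text{severe}) = \text{logit}^{-1}(-1.6 + 1.0\,\Delta\Delta G)$ —
  the minimal structure needed to exercise the mild-vs-severe
  comparisons; the intercept puts the overall severe fraction near the
  study's observed one.
* **Cohort.** Each panel gene carries 6 segregating sites whose common
  frequency is calibrated so that $P(\ge 1\ \text{variant in gene}) $
  matches a per-gene prevalence target; defaults span near-universal
  (VWF 0.99, F12 0.97) to rare (KNG1 0.03, GP1BB 0.02) with the rest
  spread over 0.15–0.55. This lands the modal mutated-protein count at
  6–8 and per-individual burdens mainly in 5–20, the shape reported for
  the real population. Sites are pathogenic with probability 0.25,
  making ~97% of individuals carry at least one pathogenic variant.
  Superpopulation weights approximate the male composition of the
  population panel (AFR 0.27, AMR 0.14, EAS 0.20, EUR 0.19, SAS 0.20).
  Sites are independent: no linkage, no population-specific site
  frequencies unless a per-population multiplier is supplied.

Everything is deterministic given `seed` (the three generators use fixed
offsets of it), and `simulate_study()` writes the full bundle — FASTA,
TSVs, panel, `truth.json` — reloadable by the package's own readers.

What passing tests on this generator do **not** show: real alignments
have phylogenetic correlation between species, real variant databases
have curation noise and non-binary severities, and real cohorts have
linkage and population structure. The generator validates the *machinery*
(mapping, classification, counting, test calibration), not the biological
conclusions.

## Numerical choices and test scale

* Fisher tie comparisons use relative tolerance $10^{-7}$; p-values are
  clipped to $[0,1]$. Human-readable output rounds p-values to 2
  significant figures; machine output keeps full precision.
* Entropy uses `log2`; $0 \le H \le \log_2 20$ is asserted in tests.
* The exhaustive Fisher validation covers all ~6×10⁵ tables with total
  ≤ 60; the Mood's oracle uses 10⁵ label permutations at $n = 60 + 60$;
  type-I calibration uses 200 null simulations at $n = 150$ per group
  (sizes chosen so the exact test's discreteness is mild); end-to-end
  shift detection runs at the default study scale (122/849). The whole
  suite runs in about a minute on one core.

## Known limitations

* Positions are taken as 1-based indices into the supplied human
  sequence; no HGVS/mature-peptide renumbering is attempted — align your
  variant table to your alignment's sequence before calling.
* The default hemostasis panel is representative, not a canonical list;
  supply your own for real analyses.
* The VCF reader is minimal (GT presence plus two INFO tags); richly
  annotated VCFs should be pre-processed to the long TSV dialect.
* Mood's median test discards within-group ordering beyond the
  dichotomy; with heavy ties at the grand median its power drops, and
  the package warns when no dichotomy exists at all.
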