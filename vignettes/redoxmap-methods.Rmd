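---
title: "Methods: site-level cysteine redoxome profiling with redoxmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: site-level cysteine redoxome profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redoxmap)
```

## The measurement model

redoxmap analyses bottom-up proteomics experiments that use differential
alkylation to encode the redox state of every cysteine in the mass tag it
carries. Free thiols are first blocked with N-ethylmaleimide (NEM, adduct
C~6~H~7~NO~2~, +125.05 Da monoisotopic); reversibly oxidized thiols
(disulfide, S-sulfenylation, S-nitrosylation, S-glutathionylation) are then
reduced with TCEP and labeled with biotin-PEAC5-maleimide (BPM,
+548.28 Da). After tryptic digestion and LC-MS/MS identification with both
adducts as variable modifications, the tag observed on a cysteine reports
its original state: NEM means it was reduced, BPM means it was reversibly
oxidized, and an untagged cysteine is recorded as unlabeled. The unit of
analysis is the *site observation*: a distinct (protein accession, 1-based
cysteine position, label, condition, replicate) tuple, obtained by exact
substring mapping of each peptide onto its stated protein.

Two deliberate choices at this level:

* A site seen with both labels through *different* PSMs of the same
  replicate keeps both observations. Mixed within-condition states are real
  (partial oxidation across molecules) and are exactly what the mixed Venn
  patterns below describe. A single residue carrying both tags in *one* PSM
  is chemically contradictory and is dropped with a log entry.
* Peptides that match their protein at several offsets are flagged
  ambiguous and excluded by default (configurable); the coordinate of such
  a site is not identifiable from the peptide alone.

## Percentages and tests

Per replicate, the percentage of oxidized / reduced / unlabeled sites is
computed over that replicate's distinct observations, so the three numbers
sum to 100. Group summaries are mean ± SEM over replicates, compared
between conditions with an equal-variance two-tailed Student's t test. The
degenerate case of two identical constant groups is defined as t = 0,
p = 1 (the generic t test refuses constant input, but this case arises in
small planted examples).

## Reproducibility filter and the 15-region Venn algebra

A (site, condition, label) is *reproducible* when it is detected under the
same label in at least `minReplicates` of the condition's replicates
(default 2 of 3). Each reproducible site then carries a pair of label
subsets (RT set, Cold set), each a subset of {oxidized, reduced}, not both
empty: 4 × 4 − 1 = 15 realizable patterns, lettered A–O.

The scientifically meaningful grouping is by *class*:

* **dynamic** — both conditions non-empty and different label sets
  (6 patterns): the redox state moved with temperature.
* **reactive** — the dynamic patterns shifted toward oxidation under cold:
  reduced→oxidized (L), reduced&oxidized→oxidized (M),
  reduced→reduced&oxidized (N).
* **rt_exclusive / cold_exclusive** — detected in one condition only
  (3 + 3 patterns).
* **stable** — identical non-empty label sets (3 patterns).

L, M and N are fixed by their published definitions. The remaining twelve
letters are presentation labels only; we assign them in a documented
canonical order (A–C the RT-only patterns ordered ox, ox+red, red; I–K the
Cold analogues; D, F, H the stable patterns; E, G, O the
reduction-direction dynamic patterns). Tests assert class semantics, not
letter identity, for those twelve.

Site-level Venn counts partition the reproducible site keys (they always
sum to the number of sites); protein-level counts deduplicate per
(protein, region), so a protein with several sites in one category counts
once there.

## Motif enrichment (pLogo-style exact binomial)

For any set of sites, 15-mer windows are extracted with the cysteine at
the center and flanks −7..+7; termini are padded with `-`, and pads are
excluded from every count and denominator. For residue r at flank
position j, with k of the N non-pad foreground windows carrying r at j and
background probability p:

* enrichment (k/N ≥ p): score = −log~10~ P(X ≥ k), X ~ Binomial(N, p)
* depletion (k/N < p): score = log~10~ P(X ≤ k) (reported negative)

Tails are exact binomial sums (computed in log space for numerical
stability at extreme scores; no normal approximation). The "PWM score" of
the heatmaps is this signed score; an alternative log-odds-of-binomial
statistic exists in the pLogo literature, so the statistic is isolated in
`plogoScore()` where it can be swapped.

The significance threshold is Bonferroni over the 20 × 14 cells of a logo:
−log~10~(α / 280) = 3.7477 at α = 0.05, matching the printed cutoff of
3.75; an explicit threshold can also be supplied. By construction the
per-logo family-wise error under the null is at most α, which
`simulateNullLogos()` verifies by simulation.

The default background is the set of *all* cysteine-centered windows of
the supplied proteome, with per-position frequencies and without
subtracting the foreground; a pooled (position-independent) composition is
available as an option, since published logo runs do not always state
which was used.

## Subcellular summaries

Sites are joined to a UniProt-derived accession→compartments table over a
seven-term controlled vocabulary (nucleus, mitochondrion, cytosol,
endoplasmic reticulum, Golgi apparatus, plasma membrane, extracellular
space) with a small alias map for common term variants. A site on a
protein annotated to m compartments counts in all m. Percent oxidized per
compartment uses labeled sites only, n~ox~ / (n~ox~ + n~red~) × 100,
computed per replicate and then summarised as mean ± SEM with a Student's
t test (matching mean-±-SEM reporting); a pooled mode, which takes the
union of distinct sites across replicates before dividing, is provided
because the replicate-versus-pooled denominator convention is not fixed in
the field.

## Label-free abundance

Total-sum normalization rescales every sample so all column totals equal
the mean raw total. Per protein, log2FC = log2(mean~Cold~ / mean~RT~) on
normalized intensities, and an equal-variance two-tailed t test is run on
log2-transformed intensities (the raw scale is available as an option;
log-scale Student's t is the standard surrogate when the upstream
software's internal test is unspecified). Significance is p < 0.05 with
|log2FC| > 0 and no multiple-testing correction, mirroring the volcano
convention this pipeline reproduces. Proteins with a zero group mean (or
any non-positive intensity under the log option) are flagged and excluded
from testing. Note that total-sum normalization couples proteins: a large
unbalanced mass of true changes biases fold-change recovery, which is why
the generator plants balanced up/down effects.

## What the synthetic generator emulates

`simulateRedoxData()` produces a complete, truth-annotated input bundle:
a proteome FASTA drawn i.i.d. from a mammalian-like residue composition,
2 conditions × 3 replicates of PSM tables, a localization table, an
abundance matrix, and a machine-readable truth file. Default settings are
fixed once to mirror the study design at roughly one-fifth scale:

* 300 proteins of 120–400 residues; 273 labeled sites distributed over
  the 15 patterns so that the oxidized fraction of reproducible sites is
  ≈15% in both conditions with fewer total Cold sites, 12 dynamic and 7
  reactive sites; plus 20 unlabeled sites (≈7% of observations).
* Per-replicate detection probability 0.9 for each planted (site, label).
* Lysine planted at −1 of 60% of reactive sites; aspartate/glutamate
  planted at −2/+2 of 50% of RT-exclusively-reduced sites — the two motif
  signals this analysis is designed to recover.
* Abundance: log2 intensities uniform on (18, 24) with noise σ = 0.2,
  30 differential proteins at |log2FC| = 1 (balanced up/down), and
  per-sample loading factors so normalization has real work to do.

Sites are emitted on tryptic-like peptides (cut after K/R). To keep the
mapping exercise honest the generator guarantees peptides of length ≥ 8
that occur exactly once in the proteome, which requires removing K/R and
stray cysteines from the immediate (±6) sequence context of planted sites.
Two consequences are worth knowing: flank positions within ±6 of planted
sites are slightly depleted of K/R/C relative to the background windows,
and unlabeled observations arise only where planted. Real data differ in
further ways the generator does not model: missed cleavages, shared
peptides between paralogues, intensity-dependent detection, and
correlated replicate structure. Passing tests therefore demonstrate
correctness of the computations under the stated statistical model, not
robustness to every artefact of instrument data.

Determinism: a fixed seed yields byte-identical output files, and the
bundled audit (`auditSimulation()`) re-reads every emitted file through
the package's own I/O layer and cross-checks it against the truth table.

## Numerical and design choices

* Coordinates are 1-based and inclusive throughout, matching residue
  numbering conventions in curated tables (e.g. Mic19 Cys183).
* Modification tokens match by name (case-insensitive) or by delta mass
  within ±0.02 Da.
* Peptides shared between proteins are used under the accession stated in
  the PSM row; no razor-protein inference is attempted.
* `-` padding at protein termini; pads never enter numerators or
  denominators.
* Degenerate background cells (p = 0 or 1) cannot be scored by a binomial
  tail; a never-seen background residue scores Inf when observed and 0
  when absent.
* Problem sizes in the test-suite simulations (300 sites for the
  reproducibility recovery, 200 null logos of 100 windows, 500 proteins
  for the abundance null) were chosen so each Monte-Carlo check has a
  ≥3-standard-deviation margin around its expected value while a full run
  stays comfortably interactive.

## Known limitations

* No stoichiometry: the method classifies sites as oxidized/reduced per
  replicate; it does not estimate percent oxidation of a residue.
* NEM can react with persulfidated cysteines, so S-persulfidation sites
  may be misclassified as reduced — a limitation of the labeling
  chemistry itself, inherited by any analysis of it.
* The nine unnamed Venn letters are canonical but arbitrary; only class
  membership should be interpreted.
* No FDR modeling of the upstream search, no GO/KEGG enrichment, and no
  structural analyses; those stages sit outside this package's scope.
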