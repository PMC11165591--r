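---
title: "Evaluating MS/MS fragment intensity predictions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating MS/MS fragment intensity predictions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectrangle)
```

## The problem

Deep-learning predictors of peptide MS/MS fragment intensities are now
routine inputs to spectral-library searching and rescoring, but their
accuracy claims are hard to compare: each method is trained and reported on
different data, different fragment annotations, and different similarity
conventions. `spectrangle` implements one fixed, auditable assessment
pipeline:

1. annotate experimental spectra with singly- and doubly-charged b/y
   fragment intensities from theoretical m/z values;
2. score every precursor-spectrum match (PSM) against a method's predicted
   intensity vector with scale-free similarity metrics;
3. aggregate scores into precursor-weighted binned distributions;
4. compare each method's distribution to an *experimental reproducibility*
   reference distribution via quantiles and the Wasserstein distance, and
   rank methods by median.

A "precursor" throughout is a modified peptide sequence plus its charge;
the same sequence at two charges is two precursors, and an oxidized peptide
is a different precursor from its unmodified form (they fragment
differently).

## Fragment annotation

Theoretical m/z values use standard monoisotopic residue masses, proton
1.007276 Da, water 18.010565 Da, oxidation +15.994915 Da and
carbamidomethyl +57.021464 Da. The b ion at ordinal $i$ has neutral mass
equal to the sum of the first $i$ (modified) residue masses; the y ion adds
one water to the last $i$ residues; $m/z = (M + z \cdot m_p)/z$. Only b/y
ions at fragment charges 1-2 are considered — that is the intersection of
what the evaluated predictor families emit — and every intensity vector
uses one canonical slot order (charge 1 then 2; within a charge b$_1$..b$_{N-1}$
then y$_1$..y$_{N-1}$) so experimental and predicted vectors always align.

Peak matching uses 20 ppm for FTMS fragment spectra and 0.5 Da for ITMS by
default (the common search-engine settings). A theoretical fragment with no
peak inside tolerance gets intensity zero. Two deliberate tie-break rules,
configurable nowhere because determinism matters more than the choice:
when several peaks fall inside the window the closest m/z wins, with exact
distance ties going to the higher intensity; and when one peak sits inside
the window of two theoretical fragments (possible for short peptides at
0.5 Da) it is assigned to both slots, because each theoretical fragment is
looked up independently.

Exclusion rules, applied in order with per-PSM reasons: peptides with
modifications other than methionine oxidation / cysteine carbamidomethyl,
or containing U/O residues, are dropped at table reading; PSMs whose
annotated vector is all zero are dropped; in singly-charged-only scoring
mode, PSMs with an all-zero charge-1 block are dropped; and the
*comparability filter* (on by default) keeps only peptide length $\le 30$
and precursor charge $\le 6$, the subset every mainstream predictor can
process. Every filter conserves its input: kept plus excluded equals what
went in, and the counts are logged.

## Similarity and distributions

Two scale-free metrics are computed per PSM between the experimental
vector $u$ and predicted vector $v$:

* normalized spectral angle
  $\alpha = 1 - \frac{2}{\pi}\arccos\frac{\langle u,v\rangle}{\|u\|\,\|v\|}$,
  which lies in $[0,1]$ for non-negative vectors. Its advantage over
  correlation is linear (rather than saturating) behaviour near perfect
  agreement, so it separates good methods better; the package's test suite
  checks this as a simulation property (median $\alpha$ < median $r$ on
  near-identical pairs) rather than as a fixed number.
* Pearson's $r$. Zero-variance vectors have no defined $r$ and are
  excluded with a distinct condition class instead of being scored 0.

The arccos argument is clamped to $[-1, 1]$ (dot products exceed 1 by
ulps) and $\theta$ to $[0, \pi/2]$.

Scores are binned at width 0.001 into half-open bins, top edge closed.
Each PSM contributes weight $1/m_p$ where $m_p$ is the number of PSMs of
its precursor within the dataset, so **each precursor has equal impact**
and the total mass of a distribution equals its number of distinct
precursors. The phrasing "weighted by the number of PSMs" admits a literal
multiplicative reading that contradicts the equal-impact goal; the package
implements the goal and keeps the literal reading behind
`weighting = "psm_count"`. A *dataset* is the set of PSMs sharing an exact
(NCE, dissociation, instrument, mass-analyzer) combination; distributions
from different datasets are combined by adding corresponding bins, and
datasets whose nonredundant precursor count falls below a configurable
minimum are flagged and dropped before evaluation.

Reported quantiles (10/25/50/75/90%) are the centers of the bins where the
cumulative normalized mass crosses the probability — quantization error at
most half a bin width. The Wasserstein distance between two distributions
normalized to unit mass is $W_1 = w\sum_k |\mathrm{CDF}_1(k) -
\mathrm{CDF}_2(k)|$ with $w$ the bin width; normalization happens inside
the computation because combined multi-dataset histograms are not
probability distributions.

**Experimental reference.** Prediction quality has a ceiling: replicate
spectra of the same precursor differ. For every precursor with $\ge 2$
usable PSMs the package builds a reference profile — the element-wise mean
of the L2-normalized replicate vectors — and scores each replicate against
it with the same metric and weighting. The resulting "experimental"
distribution is the reproducibility yardstick; each method's report row
carries its $W_1$ distance to it, and methods are ranked by descending
median (ties broken by the 75% quantile, then name, and flagged).

Stratified reports rebuild distributions within strata of precursor
charge, peptide length, NCE, or methionine-oxidation status, recomputing
multiplicities within each stratum. Length intervals default to the six
bins 7-10, 11-14, 15-18, 19-22, 23-26, 27-30 — the boundaries are not
fixed by any convention, so they are configurable and always declared in
the report output.

## The synthetic world

The simulator exists because the real assessment inputs (tens of millions
of spectra plus six trained predictors) cannot ship with a package. It is
first-class, seeded, and generates:

* **truth**: distinct peptides of length 7-30 (uniform residues, tryptic
  C-terminus by default, each methionine oxidized with probability 0.2),
  precursor charges drawn from {2: 0.6, 3: 0.3, 4: 0.1}, and a true
  relative intensity profile per precursor drawn from a symmetric
  Dirichlet($\alpha = 0.5$) over the canonical layout and L2-normalized —
  small $\alpha$ gives the peaky profiles typical of HCD spectra;
* **replicates**: 1-3 spectra per precursor (probabilities 0.3/0.4/0.3),
  each the true profile under multiplicative lognormal noise with CV 0.10,
  independent 5% peak dropout, and uniform m/z jitter of 5 ppm — kept
  below the 20 ppm matching tolerance *by construction* so that matching
  failures come only from dropout and tests stay interpretable;
* **predictors**: one per configured method, the true profile times
  lognormal noise of that method's CV, re-normalized.

One deliberate idealization: by default the generator resamples any
peptide whose theoretical fragment m/z values are not mutually resolvable
at the matching tolerance plus jitter. Such degeneracies are real — b$_1^+$
coincides *exactly* with b$_2^{2+}$ whenever the first two residues are
identical, so roughly one peptide in ten carries a fragment its spectrum
cannot disambiguate — and the annotation module handles them by its
documented nearest/tie rules. But inside the simulation they would make
"perfect input" unrecoverable by any matcher, so excluding them keeps the
zero-noise pipeline-identity test exact (`avoid_mz_collisions = FALSE`
restores the realistic world).

Defaults were chosen once as a plausible tryptic HCD/QE/FTMS world and are
not tuned to any test outcome. Lognormal noise and Dirichlet truth are
modeling conveniences with controllable CV, not fragmentation physics: the
simulator has no mobile-proton or proline effects, no correlated noise
across fragments, no retention-time dimension, and decoy noise peaks are
off by default. A green pipeline test therefore establishes that the
*measurement machinery* (annotation, metrics, weighting, distances,
ranking) is correct and that the pipeline recovers known orderings of
predictor quality — not that any real predictor is good.

Two simulation paths exist: the file-based path (MGF + TSV round trip
through annotation) proves the I/O and matching layers, and an in-memory
path (`simulate_scores()`/`run_benchmark()`) skips serialization and peak
matching for the large seeded studies. The two are exactly equivalent when
jitter stays below tolerance and no decoys are added, which the zero-noise
identity test verifies end to end through the files.

## Numerical and design choices

* Monoisotopic masses throughout (consistent with ppm-level tolerances);
  carbamidomethyl is a fixed modification on every cysteine, with an
  option to disable.
* Bin edges half-open with the top edge closed so a perfect score of 1.0
  is counted; $\alpha$ is binned on $[0,1]$, $r$ on $[-1,1]$.
* All-zero vectors are *rejected* by the metrics (callers must filter);
  this surfaces pipeline bugs instead of silently scoring 0.
* Whether $\theta$ is computed on raw or normalized vectors is immaterial
  ($\alpha$ is scale-invariant); the explicit L2 normalization appears
  only where it changes the answer, in the reference-profile mean.
* PSMs with all-zero doubly-charged-inclusive vectors are excluded under
  the same rule as the singly-charged mode (the symmetric reading).
* Reports print statistics to 3 decimals; equality of re-runs is exact
  because the pipeline is deterministic given its inputs.

## Limitations

The package evaluates annotated b/y intensities only — no neutral losses,
no a/c/x/z ions, no full-spectrum comparison including unannotated peaks.
It does not search spectra, convert vendor raw files, run or fine-tune any
predictor, or estimate FDR. The synthetic generator's independence
assumptions (per-slot noise, per-peak dropout) are stronger than real
replicate variation, so absolute similarity values from simulations should
never be quoted as expected real-data performance; only relative
comparisons within a simulated world are meaningful.
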