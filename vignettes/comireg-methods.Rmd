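---
title: "Context-specific miRNA regulation: model, screening statistic, and design notes"
author: "comireg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-specific miRNA regulation: model, screening statistic, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comireg)
```

## The CoMi model

A miRNA that represses its targets inside a functional gene set leaves a
signed, localized footprint in expression data. `comireg` makes that footprint
the unit of analysis.

**Patterns.** For miRNA $i$ with target set $M_i$ and gene set $j$ with
members $G_j$, both restricted to a declared gene universe $U$, the pair is a
*CoMi pattern* when the overlap $|M_i \cap G_j|$ is significant by an
upper-tail hypergeometric test, $P(X \ge |M_i \cap G_j|)$ with
$X \sim \mathrm{Hypergeom}(|U|, |M_i|, |G_j|)$. A pattern freezes the
partition of $G_j$ into $n_T \ge 1$ targets and $n_{NT} \ge 1$ non-targets;
expression data never changes the partition, only the statistic computed on
it. Pairs where the miRNA covers the whole set (or none of it) are excluded
because no two-sample contrast exists.

**Indices.** The *CoMi index* of a pattern under a condition is the Welch
two-sample statistic

$$t = \frac{\overline{\Delta T} - \overline{\Delta NT}}
           {\sqrt{s^2_T/n_T + s^2_{NT}/n_{NT}}}$$

with Welch–Satterthwaite degrees of freedom and a two-sided p-value. For a
*differential* index, $\Delta T$ and $\Delta NT$ are per-gene log2 fold
changes (case vs control; the mean paired difference for paired designs,
difference of group means otherwise). For a *per-sample* index they are one
sample's raw expression values, which yields a per-patient feature matrix.
Positive $t$ means the targets sit above the non-targets; the sign is carried
as a direction label (`target_up` / `target_down`).

**Networks.** The indices of a profile with $p < \alpha$ (strict, default
$\alpha = 0.05$) become directed miRNA $\to$ term edges, weighted
$-\log_{10} p$. miRNAs carry out-degrees, terms in-degrees; degree tables and
distributions are computed; fitting the distributions (e.g. power-law
exponents) is left to the caller.

**Screening.** A condition profile's $k$ largest and $k$ smallest statistics
form the up-tag and down-tag of a query signature, with
$5 \le k \le \lfloor n/3 \rfloor$ for a profile of $n$ indices. Each library
instance is scored by the Spearman correlation between the disease and drug
statistics over the signature patterns shared by both profiles (at least 3
required; unscorable instances are excluded, not imputed). Instances are
ranked ascending, so the strongest reversal is rank 1. Enrichment of the
$t$ known-positive instances at positions $V(1) < \dots < V(t)$ of the
$N$-long list is the signed two-sided KS statistic

$$a = \max_j\left(\frac{j}{t} - \frac{V(j)}{N}\right),\qquad
  b = \max_j\left(\frac{V(j)}{N} - \frac{j-1}{t}\right),\qquad
  \mathrm{KS} = \begin{cases} a & a \ge b\\ -b & \text{otherwise,}\end{cases}$$

the connectivity-map form of the statistic. Its *drug screening performance*
(DSP) p-value re-places the positive ranks uniformly at random without
replacement $n_\mathrm{perm}$ times (default 1000) and uses the add-one
estimate $p = (\#\{|KS_\mathrm{perm}| \ge |KS_\mathrm{obs}|\} + 1) /
(n_\mathrm{perm} + 1)$, which is floored at $1/(n_\mathrm{perm}+1)$ and never
exactly zero.

**Response prediction.** Per-sample CoMi statistics are features in a
repeated, stratified 5-fold cross-validation (each held-out fold is 20% of
the cohort, reconciling an 80/20 split with 5-fold CV). Within every training
portion, in order: the majority class is under-sampled to the minority size
(every minority sample kept), features are ranked by ascending two-sided
Welch p-value between outcome classes with lexicographic tie-breaks, and the
chosen classifier — logistic regression, Gaussian naive Bayes, or a
linear-kernel SVM scored by its decision values — is fit on the top
`nFeatures`. Held-out scores are pooled per repeat into one AUC and the
report averages over repeats. Feature selection never sees held-out samples.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` (discovery) | 0.05 | hypergeometric gate for patterns |
| `alpha` (network) | 0.05 | strict index p-value cutoff for edges |
| `k` | 5 … $\lfloor n/3\rfloor$ | signature window size |
| `nPerm` | 1000 | DSP permutations; p floor 1/1001 |
| `nFeatures` | 27 | features per training fold (the marker-panel size this workflow was designed around; searchable) |
| `nFolds`, `nRepeats` | 5, 100 | cross-validation layout |
| `noiseSd` | 1 | generator noise SD, log2 units |

No multiple-testing correction is applied anywhere by default: the method's
protocol thresholds raw p-values at 0.05 throughout, and the pattern /
network stages are used as a ranked discovery device rather than an
inferential endpoint. The hypergeometric universe is a deliberate input: the
command-line `patterns` stage declares it as the intersection of the
expression matrix's genes with the gene-set collection's genes and logs the
size, so p-values are reproducible from the inputs alone.

## The synthetic study design

`simulationSpec()` encodes the study the method presumes, at desk scale:

* **Annotation.** A universe of 500 genes, 15 miRNAs with random target sets
  (density 0.08), and 40 terms of 40–100 genes. Real gene sets are not
  random draws — their members share regulators — so every term is built
  around a *focal* miRNA whose targets are seeded into the term (a fifth of
  the term, grown until the overlap clears the discovery gate). This yields
  a pattern collection of realistic size from annotation alone. Terms named
  in planted effects use the planted miRNA as focal.
* **Disease cohort.** 43 tumor/normal pairs (the size of the paired cohort
  the method was developed on). Each pair shares a Gaussian baseline (SD 1)
  and each measurement adds independent Gaussian noise (SD 1), both on the
  log2 scale; planted disease effects add a location shift (default
  −1 noise-SD) to the case values of the planted pattern's target genes
  only. Pairing is therefore informative (the shared baseline cancels in
  paired differences). Location shifts in log-scale Gaussians are the
  minimal model the Welch contrast assumes; the generator deliberately omits
  probe-level artifacts, batch effects, heavy tails and correlated noise, so
  passing tests demonstrate correctness of the machinery, not robustness to
  microarray pathology.
* **Drug library.** 5 true drugs whose fold-change effects are the exact
  negation of the planted disease effects, among 50 decoys that perturb 1–3
  random patterns with random shifts; all instances carry per-gene sampling
  noise matched to the disease fold changes, $\sigma\sqrt{2/n}$.
* **Patient cohort.** 178 patients with exactly
  $\mathrm{round}(178 \times 26/178) = 26$ responders (the imbalance of the
  clinical cohort the protocol describes); responders additionally carry the
  planted response shifts on the predictive patterns' target genes.

All generators are pure functions of `(spec, seed)`: same seed, byte-identical
output, and the caller's RNG stream is untouched.

## Numerical conventions and degenerate inputs

* **Welch edge cases.** Both subsets constant and equal: statistic 0, p 1,
  direction `null`. Both constant and unequal: the statistic is capped at
  $\pm 10^6$ and p floored at the smallest positive double — an infinity is
  never returned — and the index is flagged degenerate. A singleton subset
  has no Welch df; the statistic is computed with that subset's variance
  taken as zero and p forced to 1, flagged.
* **Ties and ordering.** Every ordering the package promises is
  deterministic: radix (byte-order) sorts, ties broken lexicographically by
  pattern key or instance id. Spearman uses average ranks (`stats::cor`).
* **Profile coverage.** Patterns whose genes are missing from an expression
  input are dropped with a counted warning; an input covering no pattern is
  an error. Library instances sharing fewer than 3 signature patterns with
  the disease profile are excluded from ranking with a warning.
* **Serialization.** Profiles and patterns round-trip through versioned TSVs
  written at 15 significant digits (≥ 12 digits on re-read); a bad version
  tag or truncated body is an error, never a silent partial load.

## Design choices that were genuinely open

* **Which t-test.** The denominator $\sqrt{s^2_T/n_T + s^2_{NT}/n_{NT}}$ is
  the unequal-variance form, so Welch with two-sided p-values was adopted;
  direction travels separately as the statistic's sign. This is also robust
  to the very unequal subset sizes patterns produce.
* **KS variant.** The screening statistic follows the connectivity-map
  two-sided enrichment form (the $a$/$b$ maxima above), which matches the
  screen's design — signed scores in $[-1, 1]$, positive when true drugs
  lead the reversal ranking. The statistic is isolated behind `ksScore()` so
  an alternative running-sum variant can be substituted in one place. Note
  the two-sided form is *not* antisymmetric under rank reversal in general;
  reversal flips the sign whenever the positives are concentrated in one
  half of the list.
* **Spearman domain.** Connectivity is correlated over the signature's
  patterns only (up-tag ∪ down-tag), not the full profile: the signature is
  the query object, and restricting to it keeps the score comparable across
  window sizes.
* **80/20 vs 5-fold.** Read as the same statement: repeats of stratified
  5-fold cross-validation, each fold ≈ 20% held out. The repeat count
  defaults to 100 and is configurable.
* **AUC aggregation.** Held-out scores are pooled within a repeat (one AUC
  per repeat, averaged across repeats); pooling across folds first avoids
  the instability of per-fold AUCs on 26-positive cohorts.
* **Duplicate expression rows** collapse by arithmetic mean with a warning —
  a neutral choice for log-scale intensities; platform-specific probe
  summarization belongs upstream of this tool.

## Problem sizes used in the checks

The test-suite and `scripts/acceptance.R` run everything at sizes a laptop
handles in minutes, chosen to keep Monte-Carlo error well inside the asserted
bands: 1000 null index evaluations for type-I error; 200 screens × 1000
permutations for DSP-p uniformity (checked at the deciles); 100 seeded
screen runs of 5 true drugs vs 50 decoys; 500 runs for the power of a −1 SD
repression on a 20/80 partition; 100 CV repeats on a 200-patient, 1:6
imbalanced cohort for planted-AUC and feature recovery; the null AUC is
estimated over 10 independent null cohorts × 10 repeats, since a single
small cohort's conditional AUC varies more than the null expectation itself.
Exhaustive oracles (subset enumeration for the hypergeometric tail, all
position sets for the KS score) run at universe/list sizes ≤ 12 where
enumeration is exact.

## Known limitations

* Target maps and gene set collections are inputs; the package neither
  consolidates target predictions nor models the GO DAG (terms are flat
  sets). Noise in either propagates directly into pattern discovery.
* The hypergeometric universe choice materially changes overlap p-values;
  comparisons across runs require the same declared universe.
* Per-sample indices contrast raw expression levels within one sample, so
  they inherit any within-sample normalization problems; inputs are assumed
  normalized, log-scale.
* The permutation null for the DSP p-value treats instances as
  exchangeable; correlated instances of the same drug make it liberal.
* The generator's Gaussian, uncorrelated noise is a floor for difficulty:
  real cohorts are harder, and planted-recovery rates here are upper bounds
  on what identical settings achieve on real data.
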