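---
title: "Methods: the Iam/hiQ accuracy indices and their implementation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Iam/hiQ accuracy indices and their implementation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iamhiq)
```

## The problem

Genotype imputation fills in untyped variants from a reference panel and
reports, for each marker and individual, a triplet of a-posteriori
genotype probabilities $(p_0, p_1, p_2)$ with $\sum_g p_g = 1$ — the
*dosages*. Association analysis downstream is only as good as these
probabilities, and the accuracy scores bundled with imputation software
differ across platforms. This package implements a platform-independent
pair of per-marker indices computable from any dosage file, together
with the machinery to turn them into filtering decisions: data-driven
thresholds, a genome scan for low-accuracy regions, and diagnostics.

## Per-marker model

Three marginal situations anchor the construction. A triplet can be

1. one-hot — the genotype is unambiguous, fully individual-specific
   information;
2. uniform $(\tfrac13,\tfrac13,\tfrac13)$ — a best guess would be pure
   chance;
3. the Hardy–Weinberg triplet
   $\big((1-f)^2,\,2f(1-f),\,f^2\big)$ at allele frequency $f$ — the
   imputation used only the population allele frequency.

The anti-concentration $Q_{i,m} = \sum_g p_g(1-p_g)$ (complement of the
Herfindahl–Hirschman concentration index) is 0 in situation 1 and
$2/3$ in situation 2. With the marker mean
$\bar Q_m = \tfrac1N \sum_i Q_{i,m}$,

$$Iam_{chance,m} = 1 - \frac{\bar Q_m}{2/3}, \qquad
  Iam_{HWE,m} = 1 - \frac{\bar Q_m}{Q_{HWE}(\hat f_m)},$$

where $Q_{HWE}(f) = (-2f)(f-1)(3f^2-3f+2)$ is $Q$ evaluated at the HWE
triplet and $\hat f_m = \sum_i d_{i,m} / 2N$, $d_{i,m} = p_1 + 2p_2$, is
the dosage-implied allele frequency. $Iam_{HWE}$ is 1 in situation 1,
0 in situation 3, and can go negative when triplets sit between the
uniform and the HWE triplet — such values are reported unmodified, as
clipping would hide genotyping artefacts; small negative values are
chance-level noise. When $\hat f \in \{0, 1\}$ the HWE anchor vanishes
and $Iam_{HWE}$ is undefined (`NA` plus the `IAM_HWE_UNDEFINED` flag),
not an error: monomorphic dosage columns are a real occurrence.

$Q_{HWE}$ shrinks rapidly with MAF (0.625 at $f=0.5$, 0.039 at
$f=0.01$), which is why $Iam_{chance}$ alone misleads for rare markers
and both rescalings are kept.

The heterogeneity index compares the average-dosage distribution
$f_{ad}$ (component-wise mean triplet) with the average best-guess
distribution $f_{bg}$ (mean of one-hot vectors at each individual's
maximal probability):

$$hiQ = 1 - \sqrt{1 - \textstyle\sum_g \sqrt{f_{ad}(g)\, f_{bg}(g)}},$$

i.e. one minus the Hellinger distance between the two trinomial
distributions. A marker whose individuals all carry the same fuzzy
triplet has $f_{bg}$ concentrated on one genotype while $f_{ad}$ is
spread out, and hiQ drops (ten copies of $(0.6, 0.3, 0.1)$ give
$1-\sqrt{1-\sqrt{0.6}} \approx 0.53$) — there is no inter-individual
variation for a statistical test to use, however confident each triplet
looks. Note the formula's value for a perfectly homogeneous marker is
this 0.53, not 0; the index is anchored at coincidence
($f_{ad} = f_{bg} \Rightarrow hiQ = 1$), and we implement the formula
rather than any looser verbal gloss of it.

Two symmetries are load-bearing and property-tested: all indices are
invariant under permuting individuals, and under reversing every
triplet $(p_0,p_1,p_2) \to (p_2,p_1,p_0)$ — the latter maps
$\hat f \to 1-\hat f$ and leaves $Q_{HWE}$ (symmetric in
$f \leftrightarrow 1-f$) and the Hellinger sum (invariant under a
simultaneous component permutation) unchanged. Consequently the package
never folds $\hat f$ to a minor-allele frequency and reports it
unfolded.

## Reader policy and degenerate inputs

GEN files carry rounded probabilities, so triplet sums rarely equal 1
exactly. The reader's policy:

* $|{\sum p - 1}| \le 10^{-9}$: left untouched. This keeps the
  write-then-read cycle of the synthetic generator bit-exact; a
  renormalization at this magnitude would be numerical noise.
* $10^{-9} < |{\sum p - 1}| \le 10^{-3}$: renormalized to sum 1, marker
  flagged `RENORMALIZED`.
* larger deviations, or probabilities outside $[0,1]$: an error under
  the default `strict` policy (naming marker and individual); under
  `lenient` the individual is excluded and counted.
* all-zero triplets (the IMPUTE2 missing-genotype convention) are
  always excluded; `n_used` records the individuals actually averaged.

Multi-allelic markers must be pre-split into pseudo-biallelic variants
upstream; the reader does not attempt a splitting rule of its own.
Sex chromosomes are out of scope (the HWE anchor would need sex-aware
genotype frequencies); autosomes are assumed.

In `hiq()` the Bhattacharyya sum is clipped to $\le 1$ before the outer
square root to absorb rounding at the $10^{-15}$ level; best-guess ties
split their unit mass equally among the tied genotypes, keeping
$f_{bg}$ a deterministic proper distribution with no dose-direction
bias.

## Thresholds from a robust bivariate normal

Fixed universal cutoffs for accuracy scores are hard to justify; the
package instead fits the bulk of the $(Iam_{HWE}, hiQ)$ cloud and lets
the data set its own lower bounds. A hidden bivariate normal is assumed
(ignoring the indices' upper bounds) and fitted by iterative trimming:

1. initialize location with coordinate-wise medians, scatter with a
   MAD-based diagonal;
2. trim all points whose squared Mahalanobis distance exceeds the
   $\chi^2_2$ quantile at $1 - \alpha$ (default $\alpha = 10^{-6}$);
3. re-estimate mean and covariance from the retained set; repeat until
   the retained set stabilizes (membership is a hard threshold, so the
   iteration cannot cycle through ties) or 50 iterations.

The random region at coverage $1 - 10^{-9}$ then gives per-index lower
bounds as the coordinate-wise extremes of the coverage ellipse,
$\mu_j - \sqrt{\chi^2_{2,\,cov}\,\Sigma_{jj}}$ — deliberately
conservative, so that false exclusion of a well-imputed marker is
negligible even across millions of markers. Markers with undefined
$Iam_{HWE}$ are excluded from the fit but classified conservatively as
below-threshold. For general use without a fit, thresholds of 0.5 for
$Iam_{HWE}$ (≈ half the genotype information individual-specific) and
0.9 for $hiQ$ are the defaults throughout.

This trimming scheme is the package's own design choice: classical
robust-regression procedures in commercial suites do not document a
reproducible algorithm, and an explicitly specified iteration was
preferred over a black box. For the same reason the additional
"outlier multiplier" knob such suites expose has no counterpart here —
only the $\alpha$-quantile trim is implemented.

## The EWMA region scan

Single-marker filters miss *regions* of mediocre accuracy. Each
chromosome's index series is smoothed in ascending position order with
the one-sided recursion $s_1 = x_1$,
$s_t = \alpha x_t + (1-\alpha) s_{t-1}$ (default $\alpha = 0.1$);
maximal runs with $s_t <$ threshold become **hot** regions and,
independently, runs with $s_t <$ threshold/2 become **very hot**
regions (they may nest inside hot ones). Comparison is strict, bounds
are the first/last member positions (1-based closed; a true BED export
is available), and singleton regions are legitimate calls.

Choices a user should know about:

* smoothing restarts at every chromosome — carrying state across a
  chromosome boundary has no biological meaning;
* undefined index values are transparent: the state is carried past
  them and they cannot belong to a region;
* the very-hot cutoff is computed as exactly half the threshold;
* a causal EWMA necessarily *lags*: entering a dip from a high
  background takes $\lceil \log(\text{thr}/b)/\log(1-\alpha)\rceil$
  markers, and leaving it again takes symmetric time, so a called
  region is shifted/stretched relative to the underlying true run for
  interior dips. An optional reverse pass
  (`find_accuracy_regions(..., reverse = TRUE)`) takes the
  coordinate-wise minimum of the forward and backward smooths for
  sensitivity analysis. The suite's exact-recovery test therefore
  plants its low-accuracy run at the chromosome start (where $s_1 =
  x_1$ makes entry immediate) and uses a threshold low enough that the
  first background marker clears it in one step — the one configuration
  where exact recovery is analytically forced rather than approximate.

## The synthetic generator

`simulate_marker(f, n, lambda, blur_mode)` draws each individual's true
genotype $G$ from HWE at frequency $f$ and emits
$\lambda\,\text{onehot}(G) + (1-\lambda)\,B$, where $B$ is the HWE
triplet at $f$, the uniform triplet, or one fixed random triplet shared
by all individuals (`homogeneous`). The three marginal situations above
are thus *exact endpoints* of the mixture ($\lambda = 1$;
$\lambda = 0$ with uniform blur; $\lambda = 0$ with HWE blur), so the
endpoint assertions in the test suite are analytically forced, not
calibrated. Useful consequences, all property-tested:

* expected $Iam$ is monotone in $\lambda$ (Q is concave quadratic in
  each $p_g$; the mixture moves linearly toward a one-hot vertex);
* under HWE blur with $\lambda > 2/3$ the best guess equals the true
  genotype for every individual, so $hiQ \to 1$ as $n$ grows;
* $\hat f$ concentrates on $f$ at the usual $1/\sqrt{n}$ rate.

Dataset-level defaults are one synthetic chromosome of 200 markers by
1000 individuals at $\lambda = 0.95$ with HWE blur, and a
low-MAF-enriched frequency law (50% of markers with $f \in
[10^{-4}, 0.01)$, 15% in $[0.01, 0.05)$, 35% in $[0.05, 0.5]$) — the
composition of a modern imputation backbone, where roughly half the
variants are rare. Test and acceptance runs use between $5\times10^2$
and $10^4$ individuals and up to a few hundred markers, sizes at which
the Monte-Carlo noise of every asserted quantity is comfortably inside
its tolerance.

What the generator does **not** emulate: linkage disequilibrium and
haplotype structure (markers are independent), reference-panel errors,
batch effects, or any actual imputation engine. Passing tests therefore
demonstrate that the indices measure what they claim on dosages with
known information content — not that any particular imputation pipeline
is well calibrated. The generator seeds a single RNG from its `seed`
field (restoring the caller's RNG state afterwards), making every
dataset a pure function of its configuration.

## Numerical and interface choices

* All indices are computed in double precision with no rounding;
  the metrics TSV stores 12 significant digits.
* $Q$ is computed as $\sum p(1-p)$; the identity with $1-\sum p^2$ on
  normalized triplets is verified to $10^{-12}$ in the suite.
* `iam_chance()` clamps results into $[0,1]$ after validating its input
  to a $10^{-9}$ tolerance, so fp noise at the anchors cannot leak out
  of range; `iam_hwe()` is never clamped (negative values are
  information).
* The streaming GEN reader holds one chunk of lines at a time and
  applies a per-record function, so whole-file materialization is never
  required; per-file dialect (5 vs 6 identity columns) is fixed by the
  first line.
* CLI subcommands write outputs to a `.tmp` path and rename on success,
  and drop a `<out>.log` with every parameter, so interrupted runs
  leave no plausible-looking partial files and any run is reproducible
  from its log.

## Known limitations

* $Iam_{HWE}$ inherits the HWE assumption of its anchor: under strong
  local inbreeding or in family data the anchor is biased. For family
  samples, estimate $\hat f$ on founders only (pass the founder subset
  of rows), or fall back to $Iam_{chance}$.
* The bivariate-normal threshold model ignores the hard upper bounds of
  both indices; with very tight clouds the fitted ellipse can extend
  past 1. Only the *lower* bounds are used, where the approximation is
  harmless.
* The EWMA lag described above means region boundaries are approximate
  by construction for interior dips; treat called bounds as
  neighbourhoods, not base-pair-exact intervals.
* Sex chromosomes, BGEN/PLINK binary dosage formats and multi-allelic
  splitting are not implemented.
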