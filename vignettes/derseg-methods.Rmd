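---
title: "Base-resolution differential expression: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Base-resolution differential expression: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(derseg)
```

## The identify-then-annotate model

derseg detects differential expression from RNA-seq without committing to a
gene model in advance. The data object is the *coverage matrix* \(Y\): rows
are genomic bases, columns are samples, entries are the number of aligned
reads overlapping that base in that sample (junction reads count toward
every base they overlap; alignment itself is upstream of this package).
The analysis proceeds in four modular stages, and only afterward —
optionally — consults gene annotation.

### 1. Per-base linear model and moderated statistics

For each base \(l_j\) we fit, by ordinary least squares,

\[
g(Y_{ij}) \;=\; \alpha(l_j) + \sum_{p=2}^{P}\beta_p(l_j)\,X_{pi}
           + \sum_{k=1}^{K}\gamma_k(l_j)\,W_{ik} + \varepsilon_{ij},
\]

where \(g(y) = \log_2(y + c_0)\) with offset \(c_0 > 0\), \(X_{pi}\) are
group indicators against a reference category, and \(W_{ik}\) are optional
per-sample confounders (library size, GC content, demographics). Under the
log2 transform, \(\beta_2\) for a two-group design is the log2 fold change.
Because per-base sample sizes are small, the residual variances
\(s_j^2\) (with \(d\) degrees of freedom each) are shrunk toward a prior
variance shared across bases. The prior \((d_0, s_0^2)\) is estimated by
moment matching on \(\log s_j^2\) over expressed bases, inverting the
trigamma function for \(d_0\) — the standard empirical-Bayes treatment of
regularized linear contrasts. The moderated statistic at each base is

\[
s(l_j) \;=\; \frac{\hat\beta_2(l_j)}{\sqrt{\tilde s_j^2\, v_j}},\qquad
\tilde s_j^2 = \frac{d_0 s_0^2 + d\, s_j^2}{d_0 + d},
\]

with \(v_j\) the contrast's unscaled variance (constant across complete
bases). For more than two groups a moderated F replaces the signed t and
region directions are reported "mixed"; the documented, tested path is the
two-group design. Bases whose average raw coverage falls below the
expression cutoff \(c\) get \(s(l_j) = 0\) exactly: the segmentation's
null state must see them at its emission mode and the genome track must
remain contiguous. We deliberately do not smooth \(s(l)\) along the
genome — expression has sharp starts and ends, and the segmentation model
below is responsible for spatial structure.

### 2. Three-state segmentation

A first-order hidden Markov chain \(D(l)\) runs along the genome with
states 0 (not expressed), 1 (expressed, not differential), and 2
(differentially expressed). Emissions are normal:
state 0 \(\sim N(0, \delta)\) with \(\delta\) a very small variance, and
states 1 and 2 \(\sim N(\mu_d, \sigma_d^2)\) estimated from a two-groups
normal mixture \(f(s) = \pi_1^* f_1(s) + \pi_2^* f_2(s)\) fitted by EM to
the statistics of expressed bases. The unexpressed prior \(\pi_0\) is the
fraction of bases with average coverage below \(c\); the mixture weights
are scaled so \(\pi = (\pi_0, (1-\pi_0)\pi_1^*, (1-\pi_0)\pi_2^*)\) sums
to one. The transition matrix is fixed — high retention on the diagonal,
the remainder split evenly — rather than estimated: genes are sparse and
segment lengths are a design assumption, not a quantity the statistic
track identifies well. The decoded path is the joint maximum a posteriori
(Viterbi) sequence, with ties broken toward the lower-numbered state (the
conservative direction). Maximal runs of equal state become regions; runs
of state 2 are the *candidate differentially expressed regions* (DERs).

Three estimation details matter in practice, all of which this package
resolved deliberately:

* **Empirical-null anchoring.** Free two-component EM can mislabel a track
  whose signal mass sits in separated clusters on both sides of zero (half
  the expressed bases up at \(+6\), say, and a quarter down at \(-5\)):
  the "null" component then locks onto one signal cluster. Since the
  statistic is a moderated t, its null component must lie near zero with
  scale near one, drifting only modestly on real data. The package
  estimates that empirical null by truncated-normal maximum likelihood on
  the central window \(|s| \le 2.5\); if the free EM fit's null mean lands
  more than one null SD from that center, the fit is redone with the null
  component held at the empirical null and EM updating only the
  alternative component (initialized on the moments of the out-of-window
  points, so it spans both tails instead of locking onto one). On an
  all-signal track (nothing central) the theoretical null \(N(0,1)\) is
  used.
* **Boundary collapse on pure-null tracks.** When two components fail to
  beat a single normal by a BIC-sized margin, the likelihood surface is an
  unidentifiable manifold and EM stalls at an arbitrary split; the package
  then returns the boundary fit — everything null, the mixing proportion
  at its floor (\(10^{-4}\)), a vestigial wide alternative. This keeps
  global-null analyses from manufacturing a differential state.
* **Label constraint.** After a free fit the narrower component is the
  null; the alternative is allowed to be wide and roughly centered so one
  state-2 class carries both over- and under-expression, with the region
  direction read afterwards from the sign of the region statistic.

### 3. Permutation significance

Each candidate DER \(r\) is summarized by \(\bar s_r\), the mean of its
base statistics (a "sum" mode is available for strict fidelity to the
historical region statistic, but the mean makes regions of different
lengths comparable, and is the default). Group labels are permuted \(B\)
times — uniformly, with replacement over labelings, confounders staying
attached to their samples — and the entire statistic-mixture-HMM pipeline
is re-run per permutation (\(\pi_0\) and the expressed mask depend only on
coverage and are not recomputed). State-2 regions of the permuted passes
contribute their statistics to a pooled null, and

\[
p_r = \frac{1 + \#\{\rho : |\bar s^0_\rho| \ge |\bar s_r|\}}
           {1 + \sum_b P_b}
\]

by default: two-sided, with a pseudocount so the p-value is a valid,
strictly positive permutation p-value. The historical one-sided,
pseudocount-free form \(\#\{\bar s^0_\rho > \bar s_r\} / \sum_b P_b\) is
available as `p_mode = "paper-exact"`, `sided = "one"`; it can return
exactly zero and is blind to under-expression. Benjamini–Hochberg
adjustment produces the reported q-values; regions with \(q < 0.05\) are
called significant by convention. Designs with confounders beyond library
size would need a bootstrap rather than this simple permutation and are
not supported in the significance step.

### 4. Annotation

A GTF (converted to 0-based half-open on read) or BED reference supplies
exons and derived gene spans. A region is *exonic* if it overlaps any
exon, *intronic* if it is exon-free but inside a gene span, *intergenic*
otherwise; the best exon is the one with the most overlapping bases (ties
to the smaller start), strand is ignored for overlap and carried for
reporting. An exon is called differentially expressed when a single
significant region covers at least a configurable fraction of it (default
0.2 at \(q < 0.05\)); genes are the distinct identifiers of called exons.
The exon-calling thresholds are exposed rather than fixed because
exon-level criteria legitimately vary between references and studies.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `offset` | 0.5 | \(c_0\) in \(\log_2(y + c_0)\); half a read keeps zeros finite |
| `cutoff` | 5 | average-coverage threshold \(c\) separating expressed from unexpressed bases |
| `delta` | 1e-4 | variance of the state-0 emission; "very small" on the t scale |
| `retain_prob` | 0.999 | diagonal of the fixed transition matrix; expected segment length \(\sim 1000\) bases, gene-scale |
| `libsize` | "median" | per-sample summary added (log2, centered) as a confounder; `"q75"` or `"none"` |
| `B` | 50 | permutations for the null pool |
| `p_mode`, `sided` | pseudocount, two | empirical p-value form |
| `stat_mode` | mean | region statistic: mean or sum of base statistics |

Results are robust to moderate changes in the prior state probabilities;
`retain_prob` is the one segmentation knob with visible effect (it trades
fragmentation against boundary precision, and more smoothing never
increases the region count). The library-size summary is computed across
*all* analyzed bases, zeros included; on sparse spans every sample's
median can be zero, in which case the substituted values are constant
across samples, carry no information, and the column is dropped with a
message rather than fitted (a constant column would be collinear with the
intercept). Percentiles use the linear-interpolation definition
(`quantile` type 7) so the summary is reproducible across tools.

## The simulator and what it does (not) emulate

`simulate_experiment()` draws per-base counts negative-binomially
(dispersion \(\phi\), default 0.1; \(\phi = 0\) gives Poisson) around
region means that ramp linearly over a fixed 20-base window at region
edges, multiplied by per-sample library factors (default
Uniform(0.85, 1.15)) and by \(2^{\mathrm{FC}}\) in the non-reference
group; `log2fc = -Inf` zeroes a region in that group. Bases outside
expressed regions are exactly zero. It writes standard bedGraph, a sample
sheet and truth tables, so the full pipeline including file input is
exercised end-to-end.

This emulates overdispersed coverage with blurred region boundaries and
depth variation. It does **not** emulate junction/splice structure,
read-level autocorrelation of coverage (neighboring bases share reads and
are strongly dependent in real data; simulated bases are independent given
the mean), GC or mappability artifacts, or annotation-scale genome
complexity. Passing tests on these simulations therefore demonstrates the
statistical machinery — estimation, segmentation, calibration — not
robustness to alignment artifacts.

Three canonical scenarios (`scenario_planted()`, `scenario_null()`,
`scenario_group_specific()`) pin down the validation conditions:

* planted: 100 kb, twenty expressed 500-bp regions (\(\mu = 30\),
  \(n = 5+5\)), ten of them DE at \(|\log_2 \mathrm{FC}| = 2\), five up
  and five down; the ten non-DE expressed regions are there so the mixture
  has a genuine expressed-null component. Validation asks for sensitivity
  and precision \(\ge 0.8\) at \(q < 0.05\) with 1-bp matching, B = 50.
* null: 20 kb, eight expressed non-DE regions, ten replicates at B = 20;
  candidate p-values should be uniform and on average at most 5% of
  candidates reach \(q < 0.05\). With the boundary-collapse rule the
  global null typically produces almost no candidates at all — the
  stronger form of the same property — so the uniformity check frequently
  has (nearly) nothing to test.
* group-specific: 20 kb, six regions expressed only in group 1 plus three
  shared regions (a pseudoautosomal analogue), n = 9 expressing vs 6
  non-expressing samples with the control comparison re-splitting the
  expressing group 5-vs-4 — the classic sex-chromosome design at its
  published sample sizes, which also keeps the permutation space large
  (5005 labelings) so uniform label resampling rarely re-draws the
  observed split. Analysis sets the non-expressing group as the reference
  level, so group-specific regions are reported "up" (overexpressed in
  the expressing group).

Problem sizes (20–100 kb, \(B \le 50\), 10 replicates) were chosen as the
smallest at which the region-level asymptotics visibly hold; they run in
minutes on one core.

## Numerical choices and degenerate inputs

* Viterbi runs in log space; priors and transitions are floored at
  \(10^{-300}\) before logging; a non-finite statistic is an error naming
  the position.
* EM convergence is relative log-likelihood change below `tol` (1e-8);
  component variances are floored at \(10^{-8}\), mixing proportions at
  \(10^{-4}\); non-convergence returns the best fit with a warning and
  `converged = FALSE`.
* If trigamma inversion for \(d_0\) is infeasible (no excess spread in
  the log residual variances), \(d_0 = \infty\): fully pooled variance.
* All-zero coverage (possible in principle on degenerate permutation
  resamples) short-circuits to an all-state-0 path with zero candidate
  and zero null regions rather than erroring.
* An all-zero sample's library summary is replaced by the smallest
  positive summary across samples, with a warning.
* Ties in the best-exon choice go to the smaller exon start; ties in
  Viterbi go to the lower state.

## Known limitations

Single-normal alternatives cannot represent strongly asymmetric two-sided
signal perfectly — the wide component is a compromise density, and the
direction of each region comes from its own statistic's sign, not from
the mixture. Permutation granularity bounds attainable p-values at small
n (with replacement over labelings, the observed labeling can be
re-drawn; the pool records whatever was drawn). The bootstrap extension
needed for confounded designs, read-level simulation, and estimating the
transition matrix from data are out of scope.
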