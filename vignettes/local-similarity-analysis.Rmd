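---
title: "Local similarity analysis: statistic, p-value bound, and network screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local similarity analysis: statistic, p-value bound, and network screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsanet)
```

## The statistic

Local similarity analysis (LSA) asks, for two time series of common
length $n$: over all contiguous windows and all time shifts $d$ with
$|d| \le D$, how strong is the strongest aligned association, positive
or negative? Both series are first standardized to mean 0 and
*population* variance 1 (divisor $n$), so products behave like
correlations. For a fixed shift $d$ the pairwise products
$x_i\,y_{i-d}$ are accumulated along the diagonal with the running sum
floored at zero — once for the products (positive direction, array
$P$) and once for their negations (array $N$). With
$\hat P = \max P$ and $\hat N = \max N$ over all admissible positions,

$$\mathrm{LSA} = \operatorname{sign}(\hat P - \hat N)\,
  \frac{\max(\hat P, \hat N)}{n}.$$

Flooring a running sum at zero makes its maximum equal to the maximum
contiguous-window sum (the classic maximum-subarray identity), which is
why `lsa_pair()` — the dynamic program, implemented per diagonal in
compiled code with $O((2D+1)\,n)$ work and $O(1)$ extra memory per
diagonal — can be cross-checked against `lsa_pair_oracle()`, a
quadratic brute force that sums every window explicitly. The two share
no code path; the test suite holds them to $10^{-12}$ agreement on a
thousand random instances.

Consequences of the standardization, each property-tested: a
self-comparison gives exactly 1; $|\mathrm{LSA}| \le 1$
(Cauchy–Schwarz on any window); $|\mathrm{LSA}| \ge |\mathrm{PCC}|$
because the full-length zero-shift window is one candidate; and the
magnitude is non-decreasing in $D$ because larger lag bounds only
enlarge the search space.

Two reporting choices are deliberately ours. First, the tie
$\hat P = \hat N$ is resolved to the positive sign: a literal
$\operatorname{sign}(0)$ would zero out the statistic and discard the
magnitude, contradicting the intent that the strongest association be
reported. Second, the classical formulation does not say *where* the
similarity occurs; `lsa_pair()` reports `best_lag` and `best_window`
(0-based, half-open, on the first series) as an extension, defined as
the first maximizing segment in scan order — lags $-D..D$, then window
ends ascending, with strictly-greater updates so exact float ties keep
the earliest candidate. No epsilon is used in these comparisons: the
DP and the oracle accumulate each window's products in the same
left-to-right order, so agreement is a matter of identical arithmetic,
not tolerance.

## Significance without permutation

Under the null of independent series, the tail of the statistic can be
bounded in closed form. The distribution of a zero-floored running sum
coincides with that of the running maximum of the plain partial sums,
and the maximum of $k$ scaled partial sums of iid zero-mean variables
converges to the one-sided normal law
$G(t) = 2\Phi(t) - 1$ ($t \ge 0$). A union bound over all admissible
array positions then gives, for the literal count of positions with lag
bound $D$,

$$P(|\mathrm{LSA}| > x) \;\le\;
  2\left(n^2 - (n-D-1)(n-D)\right)
  \left(1 - G\!\left(x\sqrt{n/\operatorname{Var}(X_1Y_1)}\right)\right),$$

with $\operatorname{Var}(X_1Y_1) = 1$ after standardization. This is
`pvalue_bound(variant = "theorem")`.

Published reference tables of this bound, however, are matched not by
that expression but by the tighter

$$p(x, n) = \min\!\left(1,\; 2n\,\bigl(1 - \Phi(x\sqrt{n})\bigr)\right),$$

i.e. the same bound evaluated with the lag terms collapsed ($D = 0$)
and a single one-sided tail factor. We implemented both candidates and
evaluated them against every printed reference cell before freezing
`variant = "table"` as the default: the table variant reproduces each
cell to the printed 3 decimals, while the literal theorem form is
uniformly more conservative (the test suite asserts
`theorem >= table` pointwise). One printed cell ($x = 0.99$,
$n = 100$) is excluded from exact reproduction: it prints 0.001 where
every cell from $x = 0.79$ in the same column prints "< 0.001",
contradicting the bound's strict monotone decrease in $x$; we read it
as a typographic artifact and hold it to "< 0.001".

Numerics: the deep tail is computed via
`pnorm(t, lower.tail = FALSE)` rather than $1 - G(t)$, whose
cancellation rounds to zero past $t \approx 8$ and would invert the
variant ordering at machine precision.

The bound is asymptotic in $n$. Below roughly 30 time points it is
loose — `pvalue_bound()` warns but still returns the value, since
looseness here errs conservative: short series do not gain false
positives, they lose power. The permutation comparator
(`permutation_pvalue()`, add-one estimator $(1+k)/(1+p)$, default
shuffling one series — shuffling the second as well does not change the
null but doubles the cost) remains available; on null data its average
p-value sits below the bound's, the conservativeness the bound trades
for its $O(m^2 n)$ total cost against the permutation test's
$O(p\,m^2 n)$.

## Preprocessing

The pipeline order is fixed: interpolate → zero-filter → standardize.

* **Interpolation.** Missing entries are filled from the nearest
  observed temporal neighbours. For a single-point gap this is exactly
  the average of the two nearest observations; we extend to multi-point
  gaps by linear interpolation between the nearest observed point on
  each side, which agrees with the averaging rule wherever that rule is
  determined and is the standard completion elsewhere. A missing run at
  either boundary has only one side to draw on and takes the nearest
  observed value. The operation is idempotent.
* **Zero filter.** A series whose fraction of *exactly zero* raw
  values exceeds 0.25 (strict) is dropped. The rule targets sparse
  count data (e.g. taxon abundances); zeros are counted in the raw,
  interpolated values — standardization would destroy them — which is
  why the order above is not negotiable.
* **Standardization.** Population variance (divisor $n$) rather than
  sample variance: it is the normalization under which
  $\sum x_i^2 = n$, making the self-comparison exactly 1 and the
  Cauchy–Schwarz bound exactly $|\mathrm{LSA}| \le 1$. The statistic is
  invariant to affine rescaling of the raw series, so units never
  matter downstream.

## The all-pairs screen and its defaults

`all_pairs_lsa()` scores each of the $\binom{m}{2}$ unordered pairs
once, in a canonical order (labels sorted bytewise), and flags an edge
significant when **both** its p-value bound is at or below the
corrected level **and** its $|\mathrm{LSA}|$ reaches `lsa_threshold` —
the dual filter used in practice when drawing co-occurrence networks
(a magnitude threshold of 0.85 or higher is common for dense
expression data; the default 0 imposes no magnitude filter). The
Bonferroni divisor is $\binom{m}{2}$, the number of tests actually
performed, not $m^2$. Defaults elsewhere: $D = 3$ time steps (a small
multiple of typical response delays at daily-to-weekly sampling;
remember $D \le n - 2$) and $\alpha = 0.001$ in `run_pipeline()`,
reflecting the strict levels used for large screens.

Determinism: the scan runs serially in compiled code over the
canonical pair order, so output is identical no matter how the
`workers` argument is set; the argument is accepted for call-site
compatibility. We chose not to fork worker processes at all — gathering
and re-sorting chunks would buy nothing at the problem sizes the
package targets on one machine, and observational purity comes free
with a serial kernel. Exports: SIF (`label_a +ls/-ls label_b`,
sign-coded), a full edge-attribute TSV, and GraphML with every series
as a node (written through igraph), all restricted to significant
edges unless `all_edges = TRUE`.

## What the synthetic generators emulate — and what they do not

`null_matrix()` draws iid entries, uniform on $[0,1)$ by default —
matching large simulated null studies; the support is immaterial
because standardization removes location and scale — or standard
normal. Optional fractions of exact zeros and missing entries exercise
the filter and the interpolator. `lagged_pair()` plants the textbook
lead-lag signal: $b_t = c\,a_{t-\ell} + \sigma\,\varepsilon_t$ on the
overlap, iid noise outside it. `empirical_null_tail()` simulates
standardized normal pairs and returns the empirical exceedance of
$|\mathrm{LSA}|$; the normal (rather than uniform) default matches the
asymptotic regime in which the bound is derived, and the
conservativeness assertions hold for both distributions.

These generators produce *iid, uncorrelated-in-time* data. Real
abundance or expression series are autocorrelated, often compositional,
and unevenly sampled; the package neither simulates nor corrects for
any of that (no detrending, no rarefaction, equal spacing assumed).
Passing the null-calibration tests therefore shows the bound is valid
under the independence null it was derived for — not that it is
calibrated under temporal autocorrelation, which inflates local
similarity and makes p-values anti-conservative. That caveat is
inherent to the method, not to this implementation.

## Validation scales

The test suite validates at sizes chosen to exercise each claim
meaningfully on a single desktop core: a thousand random
oracle-equivalence instances ($n \le 12$, $D \le 3$); 10,000 simulated
null pairs per series length for bound conservativeness at
$n \in \{50, 100\}$, checked within three binomial standard errors; a
$1000 \times 30$ uniform null matrix screened at Bonferroni-corrected
$\alpha = 0.05$ (zero significant edges expected — indeed at $n = 30$
the corrected threshold of $\sim 10^{-7}$ is unreachable by the bound
for any $x \le 1$, mirroring the zero false positives reported for
million-series runs); and ten seeded $1000 \times 100$ permissive
screens ($\alpha = 0.05$, uncorrected) in which the significant-edge
graph may form chains but no 4-clique in at least nine of ten runs.
The million-series scale of the original null experiments is not
reproduced — the point of these runs is behavioral, not throughput.

## Known limitations

* Only one maximizing (lag, window) is reported even when several
  windows attain the maximum; inspection of the traces is still the
  honest way to see *how* two series are similar.
* LSA is asymmetric under time reversal; no symmetry across reversal
  is asserted or exploited.
* The bound needs $n \gtrsim 30$ for sharpness and assumes finite
  variance and independence across time; autocorrelated data violate
  the latter.
* Missing data are handled by imputation, not by a continuous-time
  statistic; heavy missingness should be treated with suspicion.
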