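---
title: "Wasserstein Boltzmann entropy of landscape mosaics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wasserstein Boltzmann entropy of landscape mosaics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicentropy)
```

## The quantity being computed

A landscape mosaic is a categorical raster: every cell carries one of $m$
class labels, and $N$ is the number of valid cells. Classical Boltzmann
entropy of the composition alone, $\ln N! - \sum_i \ln N_i!$, ignores the
fact that same-class cells often clump into *patches* ("continuous
spaces"): maximal groups of same-class cells mutually connected under a
neighbor rule (4-neighbor: shared edges; 8-neighbor: edges plus
diagonals). Cells inside a patch carry repeated information, and the
extended (absolute) Boltzmann entropy removes it:

$$S \;=\; \ln N! \;-\; \sum_{i=1}^{m} \ln N_i! \;-\;
  \sum_{i=1}^{m}\sum_{j=1}^{n_i} \ln r_{ij}!$$

with $k_B = 1$ (a physical scaling constant has no role for spatial
data), $N_i$ the cell count of class $i$, and $r_{ij}$ the size of the
$j$-th patch of class $i$. Note $S$ can be negative — a one-class,
one-patch mosaic gives $S = -\ln N!$ — and `absolute_entropy()` reports
it as defined, without clamping.

Computing $\ln(\cdot!)$ by forming factorials overflows quickly, so every
log-factorial in the package goes through `lgamma(n + 1)`.

## The Wasserstein construction

Each term $\ln s!$ expands by the identity
$\ln s! = \ln 1 + \ln 2 + \dots + \ln s$. Collecting those terms over a
multiset of sizes (the $N_i$, or the $r_{ij}$) gives the
*extended-logarithmic distribution*: bin $k$ holds mass
$a_k = \#\{s : s \ge k\}$ (`log_term_histogram()`). Its disorder is
scored as the 1-D Wasserstein (earth-mover) cost of producing it from the
Dirac reference that has all mass at $\ln 1 = 0$. Because the reference
is a point mass at the origin, no transport solver is needed: the cost is
transported mass times transported distance summed over bins,

$$W = \sum_k \frac{a_k}{\sum_k a_k}\,\ln k
  \;=\; \frac{\sum_s \ln s!}{\sum_s s},$$

and the closed form on the right is the independent oracle the test suite
checks the histogram route against. The normalizer is the cost of the
*most uniform state distribution* — mass $1/N$ on each bin
$\ln 1 \dots \ln N$ — which is $\ln(N!)/N$ (`max_transport_cost()`).
Dividing gives the normalized costs

$$W_c = \frac{\sum_i \ln N_i!}{\ln N!}, \qquad
  W_s = \frac{\sum_{ij} \ln r_{ij}!}{\ln N!},$$

both in $[0,1]$: 0 when every size is 1 (maximal fragmentation), 1 for a
single block of size $N$. This is the only reading of the "most uniform
state" normalization under which both terms are bounded by 1 and the
normalization step of the original recipe (divide the Dirac cost by the
theoretical maximum) goes through; it is documented here because the
prose definition alone is ambiguous. Higher $W_c$/$W_s$ mean more
*aggregation*, so the relative entropy flips them:

$$W_{dist} = (1 - W_c)(1 - W_s) \in [0, 1],$$

0 for a one-class one-patch mosaic, 1 when every cell is its own class.
`wdist()` computes all of this and returns a classed result:

```{r}
r <- categorical_raster(matrix(c(1L, 1L, 2L, 2L), 2, byrow = TRUE))
wdist(r, connectivity = 4)
```

For this two-block square, $W_c = W_s = 2\ln 2/\ln 24 \approx 0.436209$
and $W_{dist} = (1 - W_c)^2 \approx 0.317861$ — exact values the
acceptance suite freezes from an exact-factorial oracle.

## Patch labeling

`component_inventory()` conceptually binarizes the mosaic once per class
and labels connected components, the classical per-class procedure. The
implementation does all classes in one pass: it builds the graph whose
edges join adjacent *same-class* cells (4 or 8 neighborhood) and takes
`igraph::components()`. The two are equivalent because patches of
different classes can never share a cell, and the single pass keeps the
cost at $O(N)$ edges. Patches never span nodata cells, and nodata cells
are excluded from $N$ and from all counts. The test suite checks the
graph route against an explicit flood-fill oracle on random mosaics.

Connectivity 8 can only merge patches relative to connectivity 4, and
merging sizes $a + b$ replaces $\ln a! + \ln b!$ by the larger
$\ln(a+b)!$, so $W_s^{(8)} \ge W_s^{(4)}$ and
$W_{dist}^{(8)} \le W_{dist}^{(4)}$ always — a property test, and the
reason the two connectivities bracket each other in applications. The
default connectivity everywhere is 4, the traditional rule.

## Raster input and quantization

Text grids are whitespace-delimited integers, one line per raster row
(line 1 = top row); a `nodata` label may be excluded. Grayscale images
(PNG/JPEG/TIFF) map each distinct 8-bit level to a class; RGB input is
reduced by Rec. 601 luminance ($0.2989R + 0.5870G + 0.1140B$), the
convention of MATLAB's `rgb2gray`, then rounded to 0–255. BMP has no
installed R decoder and is not supported.

Continuous surfaces (a DEM, say) become mosaics via `quantize()`:

* `distinct` — one class per distinct value;
* `equal` — equal-width intervals over the observed range (the default
  recommendation for elevation data; the class count is the user's
  choice, as no canonical value exists);
* `edges` — explicit breakpoints; the interior edges delimit the bins, so
  out-of-range values fall into the unbounded end bins;
* `quantile` — rank-based assignment to requested proportions, each class
  count within one cell of its target share, ties broken by row-major
  scan order (a deterministic choice that makes reruns byte-identical).

Intervals are half-open $[lo, hi)$ with the last bin closed: a value
equal to an interior edge goes to the upper bin.

## The synthetic-landscape generator

The case-study designs need (a) mosaics with fixed composition but
controlled spatial aggregation and (b) progressively scrambled copies of
a seed raster. Both are provided as first-class, seeded functions.

`generate_fractal_surface()` uses spectral synthesis: Gaussian white
noise filtered in the Fourier domain with amplitude $f^{-(H+1)}$, i.e. a
power-law spectrum $f^{-(2H+2)}$, the fractional-Brownian-surface
exponent. The Hurst exponent $H \in (0,1)$ controls roughness: the
empirical variogram $\gamma(h)$ at small lags has log-log slope near
$2H$, and lag-1 autocorrelation increases with $H$. On a periodic
$128\times128$ domain the realized slope is biased toward the middle of
its range (discretization and periodicity compress the extremes), so the
generator's contract — tested over 20 seeds — is slope within $\pm 0.5$
of $2H$ plus strict monotonicity of smoothness in $H$, not an exact
exponent. `classify_by_quantile()` then carves the surface into classes
of fixed proportions by rank, giving the neutral-landscape mosaic;
`simulate_landscape()` composes the two. Defaults mirror the study
conditions: 6 equal classes at $128\times128$ for the Hurst study.

`randomize_rows()` permutes the cells of the first $k$ rows jointly (a
cell may move anywhere within the randomized block, not merely within
its own row — the stricter reading, chosen because it preserves exact
composition while destroying all structure in the block). Composition
invariance under this operation is what makes $W_c$ constant across the
scrambled copies while $W_s$ decays, isolating configuration as the
source of dissimilarity.

What the generator does *not* emulate: real landscapes have anisotropy,
nonstationary composition, and patch-shape regularities that a stationary
isotropic fractal lacks; real remote-sensing images have sensor noise and
many more gray levels than the 6–8 classes used here. Passing the trend
tests therefore shows the *metric* ranks aggregation correctly under
controlled conditions, not that any particular field dataset will
reproduce a printed table.

## Determinism and numerical choices

* Every stochastic function takes an explicit `seed` and restores the
  global RNG state afterward; fixed seed means bit-identical output.
* `run_batch()` parallelizes one task per input file
  (`parallel::mclapply`) and reassembles results in input order, so the
  CSV is byte-identical for any worker count; a failing input is
  recorded and the rest still compute. CSV floats are written at 6
  significant digits.
* Log-factorials via `lgamma` everywhere; exact digit-vector factorials
  exist only as a test oracle. Agreement tolerance in the invariant
  tests is $10^{-10}$ relative — sums of up to $10^6$ log terms stay far
  below it.
* $N = 1$ rasters are rejected ($\ln(1!)/1 = 0$ makes the normalizer
  degenerate) rather than assigned a value.
* Test and acceptance problem sizes — 200 random mosaics up to
  $12\times12$ for oracle equivalence, 20 seeds at $128\times128$ for
  the Hurst trend, 10 seeds at $256\times256$ for the row-randomization
  trend — were chosen as the smallest designs at which the trends are
  stable across seeds.

## Known limitations

* The fractal generator approximates fractional Brownian statistics on a
  periodic domain; its variogram slope is biased for extreme $H$.
* Quantile classification makes class proportions exact to one cell, but
  any other classing rule (e.g. natural breaks) will shift $W_c$.
* Only single-band input is analyzed; no CRS/projection handling.
* $W_{dist}$ compares mosaics of similar $N$ best: both terms are
  normalized by $\ln N!$, so absolute cross-size comparisons mix
  normalizers.
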