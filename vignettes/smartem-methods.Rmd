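---
title: "Runtime models, simulation and synthetic quality curves in smartem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Runtime models, simulation and synthetic quality curves in smartem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smartem)
```

# The acquisition model and its assumptions

`smartem` models a serial-section imaging workflow with nine parameters
(see `acquisition_params()`): the quality standard $Q$, tiling counts
$N_s$ and $N_t$, per-tile imaging times $T_{trad}$, $T_f$, $T_s$, per-tile
compute time $T_c$, and transition overheads $T_t$, $T_t'$. The model
assumes:

* **Proportional rescan time.** Re-imaging a fraction $\alpha$ of a tile
  takes $\alpha T_s$. Real scan controllers add per-region overheads (beam
  deflection, pattern loading), so $\alpha T_s$ is a lower bound on
  hardware rescan time; those overheads can be folded into $T_t$ if they
  are per-tile.
* **Homogeneous tiles.** One global $\alpha$ for every tile, and identical
  times across tiles. Per-tile rescan fractions are out of scope.
* **Transitions are charged per visit.** The parallel modes' rescan pass
  pays a full $T_t$ per tile and $T_t'$ per section even when a tile's
  rescan area is zero, exactly as the closed form is written. An optimizer
  that skips empty tiles would do better; modelling that is a non-goal.
* **No parallelization bottlenecks.** The two threads share an unbounded
  FIFO buffer and never contend for the GPU or I/O. Bottleneck-adjusted
  effective parameters are an extension hook, not implemented.

All times are kept in seconds internally; dwell times enter in ns/pixel at
the boundary (`derive_tile_time()` = width × height × dwell × 10⁻⁹), which
matches how per-tile times are usually derived in practice.

# Choosing the rescan fraction

Given a continuous non-decreasing quality curve $q:[0,1]\to[0,1]$ and a
standard $Q$ with $q(0)\le Q\le q(1)$, the planner uses
$\alpha=\inf\{x: q(x)\ge Q\}$. Because $q$ is continuous and monotone this
infimum is attained; `invert_for_alpha()` locates it by bisection to an
interval width of $10^{-9}$ (capped at 200 halvings) and returns exactly 0
when $Q\le q(0)$. Plateaus in user-supplied curves are allowed; the left
edge of a plateau is returned. Standards above $q(1)$ raise an
"unreachable quality standard" error naming the curve's span.

The packaged curve is the logistic
$q(x) = 1/(1+e^{-kx}) + e^{-k}/(1+e^{-k})$ with steepness $k$ exposed
(default 4). The second term makes $q(1)=1$ exactly; the implementation
computes it as `plogis(k*x) + (1 - plogis(k))`, which is algebraically
identical and — because $1-\mathrm{plogis}(k)$ is exact by Sterbenz's
lemma — returns floating-point 1.0 exactly at $x=1$. Note $q(0)$ is
$\approx 0.518$, not 0.5: the value 0.5 sometimes quoted for
fast-imaging-only quality is an approximation of this curve at 0, and the
package follows the formula literally.

# The discrete-event simulator

`simulate_acquisition()` schedules two resources — the imaging thread and
the computation thread — under three policies: `serial` (per-tile
fast-scan → compute → rescan), `parallel_global` (all fast scans first,
computes consumed FIFO in parallel, then one full rescan pass) and
`parallel_per_section` (per-section rescan passes; fast scanning of the
next section waits, because one physical beam serves both passes — the
alternative overlapping reading is plausible but not adopted). Time is
continuous floating point with no rounding; when a scan ends exactly as
the computation thread frees, compute starts at that instant, and
same-timestamp events are logged imaging-thread first.

The serial simulation reproduces the serial closed form exactly by
construction, which is a structural check that the simulator's bookkeeping
is right. The parallel closed form is provably a *lower bound* on the
simulated makespan: it assumes the computation thread finishes at
$\max\{A_n + T_c,\ a_1 + nT_c\}$ (where $a_1$ is the first tile's arrival
and $A_n$ the fast-pass span), which is exact when compute never backlogs
($T_c \le T_t+T_f$) or never idles after the first arrival
($T_c \ge T_t'+T_t+T_f$), but underestimates when compute idles at a
section boundary and then backlogs. The test suite pins a four-tile
instance where the simulated makespan is 530 s against the formula's
510 s, and property-tests both equality regimes on random draws.

Two simulator extensions suggested by the model's framing — a bounded
buffer between the threads, and stochastic per-tile rescan fractions —
are deliberately not implemented: every planner path uses the unbounded
deterministic contract, an untested configuration knob is a liability, and
both can be added behind the same `simulate_acquisition()` interface if a
use case appears. This keeps the event-log invariants (exact event counts,
policy-independent imaging busy time) unconditional.

# Sensitivity sweeps

`sweep_parameter()` varies one parameter over a grid while holding the
rest at their base values, re-deriving $\alpha$ from the quality standard
at every row. Since $\alpha$ depends only on $Q$ and the curve, it is
constant across non-$Q$ sweeps — recomputing it anyway keeps row semantics
uniform and makes $Q$ sweeps and non-$Q$ sweeps the same code path.
$T_{trad}$ is not sweepable, mirroring the model's sensitivity analysis.
Default grids are 25 evenly spaced points over 0.1×–10× the base value
(integer counts rounded and de-duplicated, $Q$ swept over $[0,1]$); the
span is a toolkit choice made to show both regimes of each tradeoff, not a
claim about any particular instrument. Rows with unreachable $Q$ are
marked, not fatal. The headline trends — savings grow with $N_s$, $N_t$
and shrink with $T_f$, $T_c$, $Q$, while $T_t'$ cancels exactly between
traditional and serial smart — are asserted as tests.

# The synthetic quality pipeline

`estimate_quality_curve()` emulates estimating $q$ empirically when no
annotated micrographs are at hand. What it emulates, and what it does not:

* **Specimens** (`generate_specimen()`): boundaries of a seeded random
  Voronoi partition, thickened to ~3 px — thin closed membranes enclosing
  convex-ish cells, with membrane fraction typically 15–30% of pixels
  (the generator errors only if a single class results). Default density:
  ~40 cells on 256×256 px. Real electron micrographs have texture,
  organelles and annotation noise; none of that is modelled, so a green
  test here establishes the *pipeline's* correctness and monotonicity, not
  segmentation performance on tissue.
* **Scans** (`simulate_scan()`): Poisson electron counting with per-pixel
  mean `base_rate × dwell_ns × contrast` (defaults 0.01 counts/ns and
  contrasts 0.3/1.0 for background/membrane), normalized by the maximum
  expected count. SNR grows as $\sqrt{\text{dwell}}$, the physical basis
  of the fast/slow tradeoff. The default dwell pair (25, 1200) ns is a
  realistic fast/slow EM pairing.
* **Masks** (`rescan_mask()`): random 32 px blocks by default (spatially
  coherent, like real rescan regions), or uniform random pixels. Both are
  content-blind; a learned predictor would target membranes and achieve
  more quality per unit $\alpha$, so the synthetic curve is conservative.
  How real mixed-dwell evaluations place their regions is generally not
  reported; random blocks are this package's choice.
* **Segmenter** (`segment_and_score()`): Gaussian smoothing (σ = 2 px)
  then Otsu's threshold, scored as orientation-corrected pixelwise
  accuracy (class polarity is arbitrary, so the better of the two
  assignments is reported; consequently scores are ≥ 0.5). The smoothing
  and threshold primitives are implemented in-package (no image-processing
  package is assumed) and are pinned against independently computed
  reference values in the tests. On a noise-free two-level image with
  smoothing disabled the score is exactly 1; with σ = 2 the blur of thin
  membranes costs a few percent even without noise — the default favors
  noise robustness at realistic dwell times.
* **Replication**: per rescan fraction, the mean accuracy across seeds is
  reported with a normal-approximation 95% CI (the CI method for such
  curves is typically unstated; the normal approximation is standard at
  ~20 replicates). The monotone fit is isotonic regression
  (`stats::isoreg`) with linear interpolation, clamped to [0, 1] and
  extended flat outside the sampled range.

All randomness flows through explicit integer seeds; sub-streams for
specimen, scans and masks are derived deterministically from the replicate
seed, so results are independent of evaluation order. Images are exchanged
as ASCII PGM (`write_pgm()`/`read_pgm()`) rather than PNG/TIFF: base R has
no raster codec, the format is human-inspectable, and 16-bit quantization
is far below the pipeline's noise floor.

# Numerical choices and degenerate inputs

* Runtimes are evaluated in double precision exactly as the formulas are
  written; with a single tile the parallel form's max-operands vanish via
  the $(N_sN_t-1)$ factors and the formula is still evaluated as written.
* `compare_modes()` breaks ties by the fixed order traditional <
  smart_serial < smart_parallel_global, so verdicts are deterministic.
* `breakeven_alpha()` solves the affine crossing in closed form; a zero
  slope ($T_s=0$) with unequal endpoints yields a "no crossing" status
  rather than an error.
* $T_{trad}$ is a free parameter: the defaults happen to set
  $T_{trad}=T_s$, but nothing ties them.
* The default compute time 28.8 s is used as printed in the default table;
  re-deriving it from the underlying inference-time extrapolation gives
  ≈28.6 s, and the package does not assert that arithmetic.
* Simulation comparisons use a relative tolerance of $10^{-9}$; the
  parallel bound check allows the same tolerance below zero for float
  round-off.

# Known limitations

The model ignores per-region rescan overheads, autofocus variability,
image-transfer bandwidth and GPU contention; the parallel formula can
underestimate makespan between the two tightness regimes (use the
simulator when in doubt); the synthetic quality curve transfers to real
data only in shape, not in level; and quality-maximization under a fixed
time budget (the dual problem) is not implemented.
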