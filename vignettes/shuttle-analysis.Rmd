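---
title: "Quantifying correlated shuttle motion of cytochrome domains"
author: "corrshuttle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying correlated shuttle motion of cytochrome domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corrshuttle)
```

## The system and the question

The type-I reaction center of green sulfur bacteria couples a homodimeric
PscA core — which holds the P840 special pair of bacteriochlorophylls — to
two copies of the membrane-anchored cytochrome PscC. Each PscC carries a
soluble heme domain that can reduce P840⁺. In MD sampling of the
PscA–2xPscC super-complex, the two heme domains are asymmetric (one
"docked" near P840, one "distant") and their positions alternate: frames in
which the two hemes approach each other tend to be frames in which the
docked heme has backed away from the special pair, and vice versa. This
package quantifies that mutually exclusive alternation and the residue-level
correlations that could carry it.

Two marker distances define the analysis plane:

* **Fe–Fe**: between the heme irons of the two PscC domains (PscC–PscC),
* **Fe–Mg**: between the docked heme iron and the Mg of the P840
  bacteriochlorophyll (PscA–PscC).

All coordinates are nanometres and all times nanoseconds internally; PDB
files on disk are in ångström as the format requires.

## The occupancy statistic

For a threshold $d$ (nm) and contraction factor $C \in (0,1]$, a frame $t$
is *mutually exclusive* when one distance is small while the other is
simultaneously large, in either assignment:

$$f(C,d) = \frac{1}{n}\left|\{\,t : (D_1(t) < Cd \wedge D_2(t) > d)\ \vee\
(D_1(t) > d \wedge D_2(t) < Cd)\,\}\right|$$

with $D_1$ the Fe–Fe and $D_2$ the Fe–Mg trace. Sweeping $d$ at fixed $C$
yields an occupancy curve whose peaks locate the alternating regimes; the
family of curves over a grid of $C$ values summarises how tightly the
"small" side must contract before occupancy collapses.

Choices a user should know about:

* **Strict inequalities.** A frame exactly at a threshold counts for
  neither branch. Under continuous noise this is a measure-zero event; it
  makes the statistic unambiguous on discrete fixtures.
* **Grids.** Defaults are $C \in \{0.67, 0.68, \ldots, 1.00\}$ (34 curves)
  and $d \in [1.5, 4.5]$ nm in 0.01 nm steps. Peak positions worth
  reporting are quoted at 0.1 nm granularity, so a 0.01 nm grid resolves
  them with an order of magnitude of margin.
* **Pooling.** "Percentage of simulation time" is the unweighted fraction
  of pooled frames across concatenated trajectories. Concatenation keeps
  segment boundaries (`distance_series$boundaries`) so that
  autocorrelation-aware analyses *could* exclude cross-boundary pairs, but
  the frame-wise statistic ignores them by design: the concatenated axis is
  an arbitrary reaction coordinate, not physical time.
* **Peaks.** Local maxima on the $d$ grid with topographic prominence at
  least 0.02 (two percentage points) are reported, sorted by occupancy,
  ties toward smaller $d$. The prominence floor sits below the coarsest
  differences a summary table would print, so no reported peak is an
  artifact of grid jitter.

Useful analytic anchors, both verified by the test suite: on *coupled*
two-state data with well-separated means and vanishing noise, the $C = 1$
curve peaks at 1.0 for any $d$ between the two regime means; on
*independent* switching with symmetric rates the same peak drops to
$2p(1-p) = 0.5$ — the null value against which observed occupancies should
be read.

## Distance distributions and modes

`summarize_distances()` builds a fixed-width histogram (default bin 0.05 nm)
and a Gaussian-kernel density on a regular grid spanning
$[\min - 3h, \max + 3h]$ for bandwidth $h$. The default bandwidth is
Silverman's rule; a constant sample falls back to a quarter of the bin
width so the density stays defined. Modes are KDE local maxima with
prominence at least a *fraction* of the tallest peak (default 0.05). The
relative threshold is this package's operational proxy for "values of
statistical significance" seen as widened violin sections: a mode must rise
by at least 5% of the main peak above its connecting saddle. With the
default fluctuation amplitude (see below) the Fe–Fe regime means 0.5 nm
apart are cleanly recovered; regimes 0.3 nm apart produce a shoulder whose
prominence sits near the threshold — exactly the regime where claiming a
"mode" becomes a judgement call.

`compare_models()` contrasts the docked-PscC–P840 distance between the
2xPscC and 1xPscC structural models: difference of means, difference of
primary modes, the two-sample Kolmogorov–Smirnov statistic, and the overlap
coefficient $\int \min(f, g)$ of the two densities. Signed statistics are
oriented first-minus-second and negate under argument swap.

## Flexibility profiling

`superpose()` implements the SVD-based Kabsch fit with a determinant guard
(proper rotations only; reflections are never returned). Degenerate
selections — fewer than three sites, or collinear sites — are refused.
`rmsd_series()` fits every frame onto a reference (default: the first
analyzed frame, selectable) over the same selection being measured;
cross-fitting (fit on one selection, measure another) is possible by
passing an explicit reference matrix. `rmsf_profile()` iteratively
superposes all frames onto their running mean structure until the mean
moves by less than $10^{-6}$ nm (50 iterations cap, always reached far
earlier on test fixtures), then reports
$\mathrm{RMSF}_i = \sqrt{\langle|r_i - \langle r_i\rangle|^2\rangle}$.

One property worth keeping in mind: the superposition fit itself absorbs
roughly $1/n_\text{beads}$ of a single bead's independent motion into the
rigid-body transform (the centroid chases the moving bead). On fixtures
built without rigid-body motion the closed form
$\mathrm{RMSF} = \sigma\sqrt{3}$ for isotropic per-axis jitter $\sigma$
holds exactly with `fit = FALSE`, and to within a few percent with the fit
enabled on frames of many beads. Real trajectories, of course, need the
fit.

## Dynamical network analysis

`displacement_correlation()` computes the standard normalised dot-product
covariance
$C_{ij} = \langle \Delta r_i \cdot \Delta r_j\rangle /
\sqrt{\langle|\Delta r_i|^2\rangle\langle|\Delta r_j|^2\rangle}$
of per-residue displacement vectors about their mean positions, pooling
frames over trajectories. `build_graph()` admits an edge only between
residues whose representative beads sit within 0.5 nm in at least 75% of
frames (both configurable; no published values exist for this system, so
these follow common dynamical-network practice), weighted
$w_{ij} = -\log|C_{ij}|$ so that a shortest path maximises the product of
correlation magnitudes along the route. `shortest_pathway()` runs Dijkstra
(via igraph) and breaks ties deterministically by the lexicographically
smallest node-name sequence; `betweenness_centrality()` is normalised
weighted betweenness. The trajectory subset the correlations are computed
from is explicit — pass a trimmed or subset ensemble — because pooling
choices change correlation estimates and no single convention is canonical.

`aromatic_hop_pathway()` is a declared *geometric surrogate* for an
electronic-coupling pathway calculation: a graph over aromatic side-chain
sites and cofactor endpoints, edges below a hop cutoff (default 0.8 nm)
weighted by distance, shortest route reported. It computes no electronic
structure; short hops are simply treated as good hops, which reproduces the
qualitative Trp/Tyr/Phe relay picture without claiming couplings or rates.

## The synthetic generators: what they emulate, and what not

The MD trajectories behind the original analysis are not deposited, so the
package generates data with the same statistical skeleton and known ground
truth.

**Two-state switching distances.** A hidden two-state continuous-time
Markov chain selects, per frame, one of two mean pairs; independent
Ornstein–Uhlenbeck fluctuations ride on each distance. Defaults define the
study conditions and are fixed once:

| parameter | default | why |
|---|---|---|
| state A means (Fe–Fe, Fe–Mg) | 3.2, 2.5 nm | the observed distance modes: hemes apart, docked heme close to P840 |
| state B means | 2.7, 2.8 nm | hemes together, docked heme backed away |
| OU stationary σ | 0.1 nm | sub-nm fluctuations; no amplitude is published, so this is regime-matching, not fitted |
| OU relaxation θ | 1 ns⁻¹ | nanosecond-scale local relaxation, fast against state dwells |
| switching rates k_AB, k_BA | 0.01 ns⁻¹ | ~100 ns dwells: several alternations per 0.8 µs analyzed segment |
| dt, n_frames | 0.1 ns, 48 000 | six 0.8 µs segments at 0.1 ns/frame |

The OU update uses the exact discrete solution
$x_{t+1} = \mu + (x_t-\mu)e^{-\theta\Delta t} + \sigma\sqrt{1 -
e^{-2\theta\Delta t}}Z_t$, so stationary moments are exact at any frame
interval. The hidden chain is discretised with the exact two-state CTMC
transition matrix over one frame interval,
$p_{A\to B} = (k_{AB}/\lambda)(1-e^{-\lambda\Delta t})$ with
$\lambda = k_{AB}+k_{BA}$: the naive per-rate rule $1-e^{-k\Delta t}$
ignores back-transitions within a frame and biases the stationary occupancy
away from $k_{BA}/\lambda$ at finite $\Delta t$, whereas the matrix
exponential keeps $k_{BA}/\lambda$ exact for every frame interval — which
is what makes the generator's occupancy a usable ground truth. Distances
are floored at 0.1 nm after noise addition for physical positivity. The
hidden-state sequence is returned (and exportable via
`write_sim_sidecar()`) so tests can condition on the truth.

**Planted correlation networks.** Beads sit on a ring (adjacent spacing
0.38 nm, a typical Cα virtual bond, inside the 0.5 nm contact cutoff), so a
planted arc between two endpoints competes against a genuine alternative
route around the other side. Displacements are drawn along the ring normal
from a zero-mean Gaussian whose correlation matrix carries the planted
structure — drawing along a single axis makes the displacement-vector
correlation equal the scalar matrix exactly, removing one estimation layer
from the ground truth. A subtlety dictated the correlation design: a matrix
with high correlation $\rho$ *only* between consecutive path beads is not
positive semidefinite once the path has three or more beads
($\mathrm{corr}(A,C) \ge 2\rho^2 - 1$ is forced), so consecutive planted
pairs get exactly `on_path_correlation` and planted pairs $k$ steps apart
get its $k$-th power (AR-style geometric decay), with `off_path_correlation`
everywhere else. Requests are still eigenvalue-checked and refused with the
offending eigenvalue if invalid.

**What the generators do not emulate:** no membrane or solvent, no
force-field energetics, no replica exchange, no slow conformational drift
within a state, no coupling between the distance process and the bead
network. Passing tests on synthetic data therefore demonstrate that the
*estimators* are correct and well-calibrated under known truth — not that
real trajectories satisfy the two-state model.

## Bookkeeping

`sampling_plan_summary()` does exact arithmetic over a block-structured
plan (count × duration, minus per-run discard). `gsb_rc_sampling_plan()`
encodes the published plan for this system: 2 models × 1 µs classical
equilibration (fully discarded), 2 × 20 REST2 replicas × 200 ns (first
50 ns discarded), and 2 models × 3 conformations × 2 runs × 1 µs production
(first 200 ns discarded) — totalling 22 µs scheduled, 9.6 µs analyzed
classical (4.8 µs per model), 6 µs analyzed REST2. Trimming composes
exactly (`trim(t1)` then `trim(t2)` equals `trim(t1+t2)`) because the
nominal start time advances with the trim rather than snapping to the next
surviving frame.

## Numerical choices and problem sizes

* Occupancy peak prominence 0.02; KDE mode prominence 5% of the peak
  density; both overridable.
* Kabsch uses base `svd()`; the determinant guard flips the smallest
  singular direction, never returning a reflection.
* Pathway tie-breaks are lexicographic on node names, so repeated runs and
  platforms agree.
* The test suite exercises long-run statistics at the sizes where their
  stated tolerances are comfortably powered: 2×10⁵ frames for OU moments
  (2% on σ), 10⁵ for hidden-chain occupancy and the occupancy nulls (3
  autocorrelation-corrected standard errors), 10⁵ samples for mode recovery
  (0.05 nm), 2×10⁴ frames × 20 seeds for planted-pathway recovery (observed
  rate 100%, required ≥ 95%). Correlation-matrix recovery uses 5×10⁴
  frames for the 0.03 absolute check.
* End-to-end pipeline runs are bit-reproducible for a fixed seed; the run
  manifest records the seed and an MD5 of the canonical configuration
  (excluding the output directory, which is location metadata).

## Known limitations

* The two-state generator is Markovian with OU noise; real domain motion
  has fat-tailed dwell distributions and state-dependent fluctuation
  amplitudes that the defaults do not attempt to capture.
* The aromatic-hop pathway is geometry only — no orbital overlap, no
  through-bond contributions.
* DCD trajectories are not read; convert to multi-model PDB or XYZ first.
* Mode detection near the prominence threshold is sensitive to bandwidth;
  report the bandwidth alongside any mode count.
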