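# corrshuttle

Trajectory analysis of correlated "shuttle" motion in the type-I reaction
center of green sulfur bacteria.

## The scientific problem

The reaction center of *Chlorobaculum tepidum* carries two copies of the
membrane-anchored cytochrome subunit PscC (cyt *c*~z~), each with a soluble
heme-bearing domain that can donate electrons to the P840 special pair held by
the PscA core. Molecular-dynamics sampling of the PscA–2xPscC super-complex
shows the two PscC domains alternating between mutually exclusive
configurations: when the two hemes approach each other, the "docked" PscC
backs away from P840, and vice versa — a candidate mechanism for electron
transfer *in series* (distant PscC → docked PscC → P840⁺).

`corrshuttle` re-implements the computations with which such shuttle motion
is quantified, as a reusable, tested R package:

- **Occupancy statistic.** For a threshold *d* (nm) and contraction factor
  *C* ∈ (0, 1], the fraction of frames in the mutually exclusive regime

  *f*(*C*, *d*) = |{*t* : (D₁(*t*) < *Cd* ∧ D₂(*t*) > *d*) ∨
  (D₁(*t*) > *d* ∧ D₂(*t*) < *Cd*)}| / *n*,

  where D₁ is the PscC–PscC (Fe²⁺…Fe²⁺) and D₂ the PscA–PscC (Fe²⁺…Mg)
  distance. The statistic is swept over a (*C*, *d*) grid; peaks of the
  resulting curves locate the alternating distance regimes
  (`occupancy_scan()`, `peaks()`, `peak_table()`).
- **Distance distributions.** Histogram/KDE summaries, prominence-based mode
  detection, and two-sample comparison of the docked-PscC–P840 distance
  between the 2xPscC and 1xPscC models (`summarize_distances()`,
  `find_modes()`, `compare_models()`).
- **Flexibility.** SVD-based Kabsch superposition, per-frame RMSD and
  per-residue RMSF for named selections such as the transmembrane helices,
  residues 1–100, of each PscC (`superpose()`, `rmsd_series()`,
  `rmsf_profile()`).
- **Dynamical network analysis.** Residue-displacement correlation matrices,
  contact-filtered graphs with −log|C_ij| edge weights, shortest allosteric
  pathways, betweenness centrality, and a geometric aromatic-hop pathway
  surrogate (`displacement_correlation()`, `build_graph()`,
  `shortest_pathway()`).
- **Trajectory handling.** Multi-model PDB and XYZ I/O (nm internally, Å on
  disk), site selection, distance extraction, equilibration trimming,
  concatenation and exact sampling-time accounting (`read_ensemble()`,
  `extract_distance()`, `trim_equilibration()`, `sampling_plan_summary()`).
- **Synthetic data with known ground truth.** The original MD trajectories
  are not publicly deposited, so the package ships a generator that emulates
  their statistical structure: Ornstein–Uhlenbeck distance fluctuations on a
  hidden two-state Markov chain (the coupled shuttle and its
  independent-switching null), three-bead marker embeddings, and bead
  networks with a planted correlation pathway
  (`simulate_switching_distances()`,
  `generate_planted_network_trajectory()`). Every downstream stage is tested
  against the analytic properties of these generators.

## Worked example

```r
library(corrshuttle)

## synthetic shuttle: state A (Fe-Fe 3.2, Fe-Mg 2.5) nm,
## state B (Fe-Fe 2.7, Fe-Mg 2.8) nm, OU noise sigma = 0.1 nm
sim <- simulate_switching_distances(switching_params(n_frames = 20000,
                                                     seed = 7))
sim
#> switching_sim: 20000 frames, coupled, fraction in state A 0.291

scan <- occupancy_scan(sim$fefe, sim$femg, C = c(0.8, 0.9, 1.0),
                       d_grid = seq(2.0, 4.0, by = 0.01))
scan
#> occupancy_scan: 3 curves (C 0.80..1.00), d 2.00..4.00 nm (201 points), 20000 frames
#>   max occupancy 0.681 at C=1.00, d=2.75 nm

peak_table(scan, C_subset = c(1.0, 0.9))
#>     C d_peak_nm low_threshold_nm percent
#> 1 0.9      2.98            2.682  28.370
#> 2 1.0      2.75            2.750  68.065

find_modes(summarize_distances(sim$fefe, bandwidth = 0.03))
#>   location  density prominence
#> 1 2.698063 2.657950  2.6579340
#> 2 3.214159 1.086984  0.8853293
```

The occupancy peak at *d* = 2.75 nm with *C* = 1 says that 68% of frames sit
in one of the two mutually exclusive regimes — the threshold falls between
the state-B Fe–Fe mean (2.7 nm) and the state-B Fe–Mg mean (2.8 nm), so each
hidden state satisfies exactly one branch of the predicate. The Fe–Fe mode
analysis recovers the two planted regime means (2.7 and 3.2 nm) from the
pooled density. On uncoupled (null) data the same peak drops to ≈ 0.5, the
analytic value 2·p·(1−p) with p = 0.5.

The full pipeline (simulate → extract → trim → occupancy / distributions /
flexibility / network, with TSV/JSON outputs and a provenance manifest) runs
from one configuration:

```r
bundle <- run_pipeline(list(
  generator = list(switching = list(n_frames = 20000),
                   planted_network = list(n_frames = 20000)),
  network = list(source = "NET:1:CA", sink = "NET:8:CA"),
  outdir = "run1", seed = 1))
render_report(bundle)   # figures regenerated purely from the exported TSVs
```

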