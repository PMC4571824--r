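# tunnelfold

Tools for studying whether and where a small protein domain folds while
still inside the ribosome exit tunnel. The package is aimed at people
working on cotranslational folding who want a self-contained, fully
seeded implementation of the three standard readouts:

* **Arrest-peptide force profiles.** A stalling arrest peptide (e.g.
  SecM) releases its arrest under tension on the nascent chain. With a
  folding domain tethered `L` residues upstream of the critical proline,
  the fraction of full-length product
  `f_FL = I_FL / (I_FL + I_A)` peaks sharply at the `L` where the domain
  folds as the arrest codon is decoded. The package turns gel-band
  intensity tables into profiles with replicate SEMs, locates the peak
  `L_max` (reporting tied intervals), and fits ligand titrations with a
  Hill isotherm `f(c) = f_min + (f_max - f_min) c^h / (K_half^h + c^h)`.

* **Coarse-grained tethered-folding simulation.** A structure-based
  (Gō-type) C-alpha bead model — 12-10 Lennard-Jones native contacts
  `λ ε_ij [5(σ_ij/r)^12 − 6(σ_ij/r)^10]`, harmonic bonds/angles, 1+3-fold
  torsions, r^-12 excluded volume — tethered at the P-site inside a
  repulsive tunnel scaffold. BAOAB Langevin dynamics with temperature
  replica exchange (8 rungs, 290–370 K, 310 K exact) give the folding
  probability `P_fold(L)` at 37 °C, its midpoint, and probe–anchor
  distance histograms (2 Å bins). The structural ligand is implicit: the
  global well-depth scale λ is calibrated by bisection plus
  thermodynamic perturbation so the isolated domain has
  `ΔG = −kB T ln(P_fold/(1−P_fold)) = −2.0 kcal/mol` at 310 K.

* **Single-ribosome FRET dwell analysis.** Two-state segmentation
  (Gaussian-mixture levels, hysteresis thresholds, photobleach
  truncation) of inter-subunit FRET traces, codon assignment (one
  rotated→non-rotated cycle per codon), dead-time-corrected
  single-exponential lifetime fits, survival curves and stall detection.

Every input has a seeded synthetic generator (toy native domain, toy
tunnel, gel lanes, fluorescence traces), so the whole pipeline runs and
is tested without external data. Real structures are supported through
`read_pdb()` / `build_scaffold()` (bio3d under the hood).

## Worked example

```r
library(tunnelfold)

# force profile from synthetic gel lanes
lanes <- gen_gel_lanes(L_list = 17:41, seed = 5)
prof <- assemble_profile(lanes)
head(prof, 3)
#>    L condition mean_fFL     SEM n
#> 1 17       +Zn   0.0997 0.00231 3
#> 2 18       +Zn   0.0981 0.00106 3
#> 3 19       +Zn   0.0984 0.00247 3
find_lmax(prof)
#> [1] 25
fit <- fit_titration(gen_titration_points(seed = 9))
fit$K_half
#> [1] 0.9639    # uM; 95% CI 0.70-1.23
```

The profile baseline sits at the no-folding level (~0.1), the peak at
`L_max = 25` marks the tether length where folding pulls the chain, and
the titration recovers the half-maximal ligand concentration (~1 uM)
from noisy points.

```r
# dwell-time pipeline on 150 synthetic single-ribosome traces
ts <- gen_fret_traces(n_traces = 150, seed = 42)
res <- fret_pipeline(ts)
res$lifetimes
#>   codon      state  tau     se    n
#> 1    NA nonrotated 2.62 0.0377 4816
#> 2    NA    rotated 2.59 0.0368 4959
res$mean_cycle
#> [1] 5.21      # s per codon
```

The two fitted state lifetimes sum to the mean elongation cycle, ~5 s
per codon at the generator's default kinetics.

```r
# the simulation side: calibrate stability, then fold in the tunnel
dom <- make_toy_domain()          # 29-residue hairpin+helix toy domain
build_native_topology(dom)
#> Go-model topology: 28 bonds, 27 angles, 26 torsions, 130 native
#> contacts (lambda = 1)
make_toy_tunnel()
#> Ribosome scaffold: 1024 static repulsive beads
#> Anchor-to-exit distance: 100 A

cal <- calibrate_stability(dom, seed = 1)   # lambda* with dG = -2.0
ch <- attach_linker(dom, 25)
tun <- make_toy_tunnel()
topo <- set_lambda(build_native_topology(ch), cal$lambda)
conf <- conformation(ch, topo, xyz = initial_tethered_xyz(ch, tun),
                     scaffold = tun, tether = TRUE)
ens <- replica_exchange_run(conf, steps = 600000, swap_interval = 500,
                            seed = 7, save_rungs = 3)
traj <- ens$trajectories[[rung_index(ens, 310)]]
distance_histogram(traj, class_filter = "folded")
```

At tether length 25 the folded domain sits deep in the tunnel vestibule,
roughly 65–85 Å from the P-site anchor; scanning `L` from 20 to 34 and
fitting `pfold_curve()` + `midpoint()` locates the folding transition
near `L ≈ 28`. The methods vignette (`vignettes/tunnelfold.Rmd`)
documents the model, the calibration scheme and all numerical choices.

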