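---
title: "Simulating and measuring cotranslational folding in the ribosome exit tunnel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and measuring cotranslational folding in the ribosome exit tunnel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Small protein domains can begin to fold before the ribosome has finished
synthesizing them. Whether a domain can fold while still *inside* the
~100 Å exit tunnel of the large ribosomal subunit is measurable by three
complementary readouts, all implemented in this package:

1. **Arrest-peptide force profiles.** A stalling arrest peptide (AP) such
   as SecM halts its own ribosome unless tension on the nascent chain
   releases the arrest. Placing a folding domain at a tether length $L$
   upstream of the AP's critical proline converts folding into a pulling
   force: the fraction of full-length product,
   $f_{FL} = I_{FL}/(I_{FL}+I_A)$, peaks sharply at the $L$ where folding
   occurs just as the arrest codon is decoded.
2. **Coarse-grained tethered-folding simulation.** A structure-based
   (Gō-type) model of the domain plus linker, tethered at the P-site
   inside a repulsive tunnel scaffold, yields the equilibrium folding
   probability $P_{fold}(L)$ at 37 °C and the location of the folded
   domain in the tunnel.
3. **Single-ribosome FRET dwell analysis.** Inter-subunit FRET reports
   the rotated/non-rotated cycle of an elongating ribosome; one
   high-to-low-to-high intensity cycle corresponds to one codon. Dwell
   times, survival curves and long terminal dwells (stalls) quantify
   where and how often ribosomes arrest.

Every input has a seeded synthetic generator, so the full pipeline runs
and is tested without any external data.

## The coarse-grained model

The chain is one bead per residue at the C$_\alpha$ position (a two-bead
mode with side-chain centroid beads exists for visualization; all
analyses use C$_\alpha$ beads). The potential is a standard Gō-type
energy:

* bonds $\tfrac12 k_b (r - r_0)^2$ with $k_b = 50$ kcal/mol/Å$^2$ and
  native equilibrium lengths;
* angles $\tfrac12 k_\theta (\theta - \theta_0)^2$,
  $k_\theta = 20$ kcal/mol/rad$^2$;
* backbone torsions $k_1[1-\cos(\phi-\phi_0)] + k_2[1-\cos 3(\phi-\phi_0)]$,
  $k_1 = 0.5$, $k_2 = 0.25$ kcal/mol;
* native contacts (domain pairs $|i-j|\ge 3$ within 8 Å in the native
  structure) with a 12-10 Lennard-Jones well
  $\lambda\,\varepsilon_{ij}\,[5(\sigma_{ij}/r)^{12} - 6(\sigma_{ij}/r)^{10}]$,
  minimum at the native distance $\sigma_{ij}$, base depth
  $\varepsilon_{ij} = 1$ kcal/mol;
* excluded volume $\varepsilon_{rep}(\sigma/r)^{12}$ between all other
  bead pairs and against every scaffold bead, $\sigma$ = sum of bead
  radii (2 Å per chain bead);
* a harmonic tether ($k_t = 10$ kcal/mol/Å$^2$) of the C-terminal bead
  to the P-site anchor.

The structural ligand (Zn$^{2+}$ in a zinc finger) is *implicit*: its
only effect is the global well-depth scale $\lambda$, calibrated so the
isolated domain has a chosen folding free energy (see below). Linker
residues get generic bonded terms ($r_0 = 3.8$ Å, $\theta_0 = 110^\circ$,
no torsion) and no native contacts.

Numerical choices worth knowing:

* Repulsion is cut off at twice the pair diameter sum (tail
  $< 2.5\times10^{-4}$ kcal/mol); native contacts at 12 Å. With the 8 Å
  contact-build cutoff this makes the native structure exactly
  force-free.
* The harmonic angle force carries an intrinsic $1/\sin\theta$ factor
  that diverges at collinear geometries. Outside [29°, 160°] the angle
  potential is therefore continued as a linear function of
  $\cos\theta$, matched in value and slope, which keeps the force
  bounded *and* exactly conservative (a bare force clamp pumps energy
  and destabilizes hot replicas). Torsions are skipped within ~0.6° of
  collinearity. Correspondingly, the synthetic domain builds its ideal
  β-strands as 130° zigzags (real C$_\alpha$ geometry), never straight
  lines.

## Sampling

Dynamics are BAOAB-discretized Langevin with a self-contained seeded
noise stream (bit-reproducible trajectories). Defaults: time step 8 fs,
friction 1 ps$^{-1}$, uniform 110 Da beads. We originally ran 10 fs with
0.5 ps$^{-1}$; a six-seed stability screen at the hottest rung showed
rare blow-ups at that setting, and 8 fs with friction 1 ps$^{-1}$ was the
fastest setting with zero failures and the highest folding/unfolding
transition count at 310 K, so those are the defaults.

Replica exchange uses 8 rungs spaced approximately geometrically over
290-370 K, with the rung nearest 310 K pinned to exactly 310 K (37 °C is
the analysis temperature). Neighbour swaps alternate even/odd pairs
every 1000 steps (500 in the bundled analyses) with Metropolis
acceptance $\min(1, e^{(\beta_i-\beta_j)(E_i-E_j)})$ and velocity
rescaling by $\sqrt{T_{new}/T_{old}}$. Statistics are taken directly
from the 310 K rung after discarding the first 20% of each trajectory;
no multi-state reweighting across temperatures is used.

```{r}
library(tunnelfold)
dom <- make_toy_domain()         # 29-residue hairpin+helix, probe at 21
topo <- build_native_topology(dom)
conf <- conformation(dom, topo)
ens <- replica_exchange_run(conf, steps = 200000, seed = 1)
```

## Stability calibration

`calibrate_stability()` finds the $\lambda$ at which the isolated domain
has a two-state folding free energy
$\Delta G = -k_B T \ln(P_{fold}/(1-P_{fold})) = -2.0$ kcal/mol at 310 K
(the implicit-ligand condition). The landscape is cooperative: the
slope $d\Delta G/d\lambda$ is of the order of the native-contact
energy gap between the states (tens of kcal/mol per unit $\lambda$ for
the default domain), so $\lambda^*$ must be located to a few parts in
a thousand. Plain bisection with stochastic $\Delta G$
evaluations cannot do that in reasonable time, so the search has two
stages:

1. bisection on $\lambda$ (initial bracket [0.5, 3], expanded ×2 up to
   twice if it fails to bracket) down to an interval of 0.02, with
   moderate-length replica-exchange runs per evaluation;
2. refinement by thermodynamic perturbation: the contact energy is
   exactly linear in $\lambda$, so the folded/unfolded populations of a
   long run at $\lambda_0$ can be reweighted by
   $\exp[-\beta(\lambda'/\lambda_0 - 1)E_{contact}]$ to nearby
   $\lambda'$ and the root of the reweighted $\Delta G(\lambda')$
   polished without new simulations. Several long runs iterate this,
   and the final $\lambda^*$ is the root of the inverse-variance-pooled
   reweighted curve over all refinement runs.

Three practical details matter for convergence. Trial runs at large
$\lambda$ shrink the time step by $1/\sqrt{\lambda}$ (deeper wells are
stiffer). The cold half of the ladder starts from the native structure
and the hot half from an extended chain, so the ensemble approaches the
folded/unfolded balance from both sides instead of relaxing a
one-sided transient down the ladder; refinement runs still discard a
deeper 30-35% equilibration share. And the reported $\Delta G$ carries
a block-bootstrap standard error (20 contiguous blocks of the
analysis-rung trajectory), which should be read as a lower bound: at
the default stability the unfolded state is rare (about 4% occupancy),
so run-to-run scatter of $\Delta G$ is roughly 0.3 kcal/mol per
$10^6$-step run and is dominated by slow replica-flow modes that one
long run averages out poorly. Replicate independent runs (pooled
folded/unfolded counts; `measure_dG(n_runs = ...)`) decorrelate those
modes, so the bundled analyses use several pooled $10^6$-step runs for
both refinement and the independent confirmation.

## The toy system

`make_toy_domain()` builds a deterministic compact native structure —
an ideal β-hairpin packed against an ideal α-helix, C$_\alpha$ virtual
bonds of 3.8 Å, bounded by a 12 Å sphere — emulating a minimal
zinc-finger-sized domain (29 residues, distance probe at position 21,
the position homologous to the His21 probe of the experimental domain).

`make_toy_tunnel()` builds the scaffold: a 100 Å tube of static
repulsive wall beads along $-z$ from the P-site anchor at the origin,
with a 10 Å entrance (0 to $-25$ Å), a linear taper to a 6 Å
constriction at $-40$ Å, and a linear widening to a 22 Å vestibule at
the open exit. A bead disk 4 Å above the anchor closes the entrance.
The design intent is twofold: geometrically, the folded domain
(cross-section circumradius ≈ 5 Å plus a ≈ 3.5 Å wall-exclusion layer)
must fit the distal vestibule but never the constriction; and
behaviourally, tethered simulations must actually reach the folded
state at long tethers within desk-scale sampling, so the folding onset
is reproduced qualitatively (P_fold low at short tethers, above one
half at long ones). The radii are tunable; the defaults were set by
those criteria — with a 14 Å vestibule and 2 Å wall beads the folded
domain did not fit anywhere inside the tunnel, and at 16–20 Å the
folded state remained so marginal that the transition never crossed
one half at the bundled run lengths; 22 Å with 1.5 Å wall beads (a 3 Å
bead lattice, still impermeable to the chain) satisfies both. Wall
rings are always placed at the profile breakpoints and the exit.

Folding analysis classifies frames by C$_\alpha$ RMSD to the native
domain after Kabsch superposition (linker excluded): folded below
3.5 Å, unfolded above 5.5 Å, intermediate otherwise. Intermediates count
in the $P_{fold}$ denominator but in neither class of the probe-anchor
distance histograms (2 Å bins aligned to zero, distances measured from
the probe bead to the P-site anchor, which stands in for the 3'-terminal
phosphorus of the P-site tRNA). The folding midpoint comes from a
least-squares logistic fit of $P_{fold}(L)$ with linear interpolation of
the 0.5 crossing as fallback. `glass_run()` continues a randomly chosen
(seeded) folded 310 K frame at 140 K, just above the water glass
transition, where the folded domain is kinetically trapped and samples a
narrow slice of the tunnel.

Typical products, at the problem sizes used by the bundled tests
(8 replicas; 3.5 × 10^5 steps per replica and per tether length for the
length scan, 6 × 10^5 for the L = 25 distance analysis, 10^6-scale runs
for the stability calibration — roughly 20 CPU-minutes end to end):

```{r}
cal <- calibrate_stability(dom, seed = 1)      # lambda*, dG, history
tun <- make_toy_tunnel()
ch <- attach_linker(dom, 25)
topo25 <- set_lambda(build_native_topology(ch), cal$lambda)
conf25 <- conformation(ch, topo25, xyz = initial_tethered_xyz(ch, tun),
                       scaffold = tun, tether = TRUE)
ens25 <- replica_exchange_run(conf25, steps = 600000, swap_interval = 500,
                              seed = 7, save_rungs = 3)
traj <- ens25$trajectories[[rung_index(ens25, 310)]]
distance_histogram(traj, class_filter = "folded")
```

## Force profiles

`gen_gel_lanes()` draws synthetic band intensities around a true
profile $f(L) = b + (A-b)\exp[-(L-L_0)^2/(2w^2)]$ (defaults: baseline
0.1, peak 0.8 at $L_0 = 25$, width 1.5, three replicates, 5%
multiplicative band noise, LogNormal(0, 0.1) lane loading). The analysis
side is deliberately simple and exact: per-lane
$f_{FL} = I_{FL}/(I_{FL}+I_A)$, group means with SEM = sd/$\sqrt n$
($n-1$ denominator; single replicates report SEM as `NA`), peak location
with exact-tie intervals (experimental profiles report interval peaks
like 24-26), and a Hill fit
$f(c) = f_{min} + (f_{max}-f_{min})\,c^h/(K_{1/2}^h + c^h)$ with $h$
fixed at 1 unless requested, via Levenberg-Marquardt least squares.
Band-intensity background subtraction is assumed done upstream; lanes
with both bands below a detection floor are dropped with a warning.

## FRET dwell analysis

`gen_fret_traces()` emulates inter-subunit FRET at 10 Hz for 10 min:
per codon one rotated dwell (high donor intensity, low FRET) and one
non-rotated dwell (low intensity), each exponential with mean 2.5 s, so
a 5 s elongation cycle; optional terminal stalls at an arrest codon
(the stalled ribosome ceases cycling and its non-rotated dwell ends
only by photobleaching — no arrest-release kinetics); Gaussian noise
(s.d. 0.07 on levels 0.3/1.0); single-step photobleaching
(Exp(300 s)) to zero. The rotated/non-rotated lifetime split of the 5 s
cycle is not separately known for this system, so the defaults split it
evenly; both are tunable.

Segmentation fits a Gaussian mixture (deterministic EM, variance floor)
to the raw intensity histogram — up to three components so a
photobleached level below both states is recognized — truncates the
trace at a terminal fall below both state levels, and calls states by
hysteresis at $\mu_{high}-\sigma_{high}$ / $\mu_{low}+\sigma_{low}$ on
the raw series (the 3-sample median filter is used for bleach detection;
state calling on the filtered series would delay threshold crossings and
swallow sub-0.5 s dwells). Segments shorter than 2 samples merge into
their neighbours. The k-th completed rotated-to-non-rotated cycle is
codon k; terminal (truncated) segments are flagged and never counted.

Lifetimes are single-exponential MLE fits, $\hat\tau$ = sample mean with
SE $\hat\tau/\sqrt n$. The pipeline applies a detection dead-time
correction: dwells shorter than 2 samples are unobservable and the
exponential is memoryless, so observed dwells distribute as
$c + \mathrm{Exp}(\tau)$ with $c = 2/\mathrm{rate}$, and
$\hat\tau = \mathrm{mean} - c$. Without it the recovered cycle is biased
upward by ~0.5 s at 10 Hz.

```{r}
ts <- gen_fret_traces(n_traces = 150, seed = 1)
res <- fret_pipeline(ts)
res$mean_cycle          # ~5 s per codon
head(res$survival)
detect_stalls(res$tables, max_codon = 50)
```

Known limitation: missed sub-sample dwells occasionally merge two
cycles, so codon numbers can slip downward by 1-2 over a long trace —
the same codon-assignment uncertainty real traces have. Survival drops
and stall codons are therefore smeared by a codon or two, and tests
compare cumulative drops rather than single-codon differences.
`detect_stalls()` takes a `max_codon` bound so the post-termination rest
of a completed ribosome is not misread as an arrest.

## What the synthetic data do and do not show

The generators reproduce the *structure* of the real data — two-state
dwell kinetics with bleaching, replicate gel intensities with loading
noise, a compact domain in a constricted tube — under exactly known
ground truth, which is what the tests exercise. They do not emulate
fluorophore blinking, gel background or densitometry artifacts, tRNA
half-steps or non-exponential dwell mixtures, the bumpy chemical
surface of the real exit tunnel (attractive chain-wall interactions are
deliberately absent: the scaffold is purely repulsive), or
sequence-specific linker effects. Passing tests therefore demonstrate
correctness of the algorithms under the stated model, not robustness to
every artifact of real data.

A further known limitation of the toy geometry: the real vestibule is a
pocket that localizes the folded domain tightly (the experimental
probe-anchor band at tether length 25 is 65-75 Å), while a smooth cone
of the same nominal radii lets the folded domain slide a little deeper,
so the simulated distance distribution reproduces the lower edge of
that band but extends its upper tail by ~10 Å.

Tethered folding is also a much slower two-state process than folding
in isolation: fold/unfold cycles inside the tube are rare events, and
at the bundled run lengths (4 × 10^5 steps per replica per tether
length) the P_fold(L) points carry substantial run-to-run scatter. The
folding-onset location is reproducible to roughly ±2 residues at this
scale; equilibrium-quality curves would need runs an order of magnitude
longer. Two-sided initial conformations for tethered ensembles
([initial_tethered_folded_xyz()] for the cold rungs) are provided for
convergence diagnostics: agreement between extended-start and
folded-start estimates indicates an equilibrated ensemble.

## Reproducibility

All generators and both samplers are pure functions of (parameters,
seed); trajectories are bit-identical across runs on the same build.
The `scripts/acceptance.R` entry point re-derives the pipeline's
headline numbers from scratch for any seed.
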