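---
title: "Modelling skin growth under tissue expansion and inverting elastic-wave probes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling skin growth under tissue expansion and inverting elastic-wave probes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(expansim)
```

## The problem

Tissue expanders trigger growth of new skin by holding it stretched beyond
its physiological state. Clinically, neither the in vivo tension of a
patient's skin nor its growth response can be measured non-invasively, which
makes expansion protocols heuristic. `expansim` implements a fully simulated
version of a proposed measurement pipeline:

1. a forward model of a skin patch stretched over an inflated expander, with
   a stretch-driven growth law converting elastic deformation into permanent
   area gain over days;
2. a non-invasive probe: a short pressure impulse excites a transverse
   elastic wave whose local speed $\sqrt{\sigma/\rho}$ encodes the in-plane
   tension $\sigma$, probed before inflation, immediately after, and after
   3.5 days of growth;
3. a virtual population of subjects with Latin-hypercube-sampled material
   parameters, from which waveform datasets are built;
4. a neural-network surrogate that inverts the three waveforms into the
   subject's shear modulus $\mu$, growth rate $k$, natural pre-stretch
   $\theta_\mathrm{nat}$, and the predicted 7-day spatial growth field.

## Growth mechanics

The kinematics use a multiplicative split of the deformation gradient,
$\mathbf{F} = \mathbf{F}^e \mathbf{F}^g$, into a reversible elastic part and
an irreversible growth part. Growth is transversely isotropic: equal
in-plane growth, none through the thickness, so
$\mathbf{F}^g = \sqrt{\theta_g}\,(\mathbf{I} - \mathbf{N}\otimes\mathbf{N}) +
\mathbf{N}\otimes\mathbf{N}$ for growth area stretch $\theta_g$ and surface
normal $\mathbf{N}$. Area changes follow the cofactor transport rule:
the total, growth, and elastic area stretches are
$\|\mathrm{cof}(\mathbf{F})\mathbf{N}\|$ and likewise for
$\mathbf{F}^g, \mathbf{F}^e$, with the exact identity
$\Theta = \theta_g\,\theta_e$ (tested to machine precision).

The material is compressible neo-Hookean, with energy
$\Psi = \tfrac{\mu}{2}(I_1^e - 3) + \tfrac{\lambda}{2}\ln^2 J^e$ and
$\lambda = 40\mu$ (near-incompressible). The Cauchy stress implemented is
$\sigma = [\mu(\mathbf{b}^e - \mathbf{I}) + \lambda \ln J^e\,\mathbf{I}]/J^e$,
i.e. the stress of the standard neo-Hookean potential that is stress-free in
the rest state; the energy above differs from that potential only by the
volumetric coupling term $-\mu \ln J^e$, which vanishes at $J^e = 1$, the
operating regime here. The consistency test differentiates the stress
potential numerically and checks the first-Piola transform.

Growth evolves as
$\dot{\theta}_g = k\,\max(0,\; \theta_e - \theta_\mathrm{nat})$:
any elastic area stretch beyond the natural pre-stretch drives growth at a
subject-specific rate $k$ (per day). The rate is rectified at zero so that
under-stretched skin does not shrink. Under a held total stretch $\Theta$,
$\theta_e = \Theta/\theta_g$ relaxes monotonically towards
$\theta_\mathrm{nat}$ and $\theta_g \to \Theta/\theta_\mathrm{nat}$.
Integration uses an explicit midpoint scheme with `dt = 0.01` day; tests
check agreement with an adaptive ODE solution to $10^{-6}$ and step-halving
stability to $10^{-4}$ at day 7.

## The reduced expansion model

One quarter of a 100 mm x 75 mm x 3 mm skin block is modelled (the
rectangular expander has two mirror planes), on a regular grid with symmetry
edges at $x=0$, $y=0$. Two deliberate reductions keep the forward model
desk-scale and deterministic:

* **Geometric expander.** The inflated expander is a smooth dome
  $z(x,y) = h\cos(\pi x/2a)\cos(\pi y/2b)$ imposed on top of the isotropic
  natural pre-stretch. Mapping the flat plane onto the dome multiplies local
  area by $\sqrt{1+|\nabla z|^2}$, so the held total stretch is
  $\Theta(x,y) = \theta_\mathrm{nat}\sqrt{1+|\nabla z|^2}$. The in-plane
  equilibrium redistribution that a full 3D contact simulation would perform
  is deliberately omitted; in exchange, every constitutive and growth
  equation is exact point-wise and the growth ODE applies cell by cell.
* **Dome defaults.** The dome spans the quarter domain
  ($a = 50$, $b = 37.5$ mm) so that every region of the 5x5 prediction grid
  experiences stretch and growth — with a small dome confined to a corner,
  most of the 25 growth targets would be constant across all subjects and
  the inverse problem would degenerate. The apex height (23.4 mm) is set by
  `calibrate_apex()` so the peak area-stretch factor is 1.4, keeping peak
  elastic stretches safely below reported skin failure strains. The
  resulting full-block dome volume, $16abh/\pi^2 \approx 71$ cc, is
  consistent with a nominal 60 cc rectangular expander inflated to the
  clinically common 110–120%.
* **Locally equi-biaxial stress.** Each point carries elastic stretch
  $\sqrt{\theta_e}$ in both in-plane directions; the thickness stretch
  solves the plane-stress condition $\sigma_{33}=0$ (a strictly monotone 1-D
  root, solved by safeguarded Newton to $|\sigma_{33}|<10^{-10}$ MPa). The
  in-plane stress is isotropic, and relaxes as growth proceeds — the
  mechanism the wave probe measures.

## The wave probe

The probe solves the transverse membrane equation
$\rho h\, \ddot w = \nabla\!\cdot(\sigma h \nabla w) + p(t)$ on the flat
reference plane, with the heterogeneous tension $\sigma h$ of the current
protocol stage (current thickness $h\lambda_3$). Units: lengths mm, stress
MPa, density kg m$^{-3}$, wave time s; the single conversion constant is
1 MPa/(kg m$^{-3}$) = $10^{12}$ mm$^2$ s$^{-2}$. The solver is an explicit
central-difference scheme with lumped mass, symmetry (mirror) conditions on
the two symmetry edges, clamped outer edges, and time step
$\mathrm{CFL}\cdot\min(\Delta x,\Delta y)/c_\max$ with CFL 0.5. Its discrete
mixed-product energy is conserved to round-off after the pulse ends (tested
to $10^{-6}$ relative drift per step).

The impulse (0.5 MPa for $2\times10^{-5}$ s on a 1 mm disc) is shorter than
one stable time step and smaller than one cell, so both its temporal and
spatial discretisation conserve the delivered impulse: the source is
weighted by the overlap of the pulse with each step, and the disc pressure
is distributed over nodes by the covered fraction of each dual cell.
Without this, waveform amplitude would scale with the subject-dependent
time step — an unphysical cue for the surrogate.

The protocol probes the receiver 5 mm from the impact at three stages:
baseline (natural pre-stretch only), day 0 (expander inflated, held
$10^{-5}$ day), and day 3.5; the day-7 growth field is stored as the
prediction target. The default probe pair, impact (20, 15) mm and receiver
(15, 15) mm, sits on the dome flank where the stage-to-stage tension
contrast is strong. Because tension is highest at day 0 and relaxes towards
baseline as growth consumes elastic stretch, first arrivals order as
day 0 < day 3.5 $\le$ baseline; this holds in tests at all corners of the
sampled parameter box and across random subjects. Arrival comparisons
across stages use a threshold shared between the three waveforms (a
fraction of the baseline peak), which is insensitive to stage-to-stage
amplitude differences.

**Known limitation.** The near-impulsive source excites grid-scale
wavelengths, and the scheme's numerical dispersion makes the late coda
converge slowly under grid refinement: at the desk grid
($\Delta x = 1.25$ mm) halving the spacing still changes the interpolated
waveform by tens of percent RMS, contracting by roughly 0.7 per refinement
level (tested). The surrogate is unaffected in-distribution because every
waveform in a study is produced on one fixed grid, but waveforms should not
be compared across grids. There is no through-thickness (Rayleigh) wave
physics; only the tension-to-speed mechanism and qualitative stage
orderings are claimed, not the 3D solid's quantitative arrival times.

## Virtual population

Subjects are drawn by Latin hypercube sampling over
$\mu \in [0.01667, 0.1]$ MPa, $k \in [0.2, 1.92]$ day$^{-1}$,
$\theta_\mathrm{nat} \in [1.05, 1.2]$, $\rho \in [1060.2, 1171.8]$
kg m$^{-3}$, with $\lambda = 40\mu$. Each parameter's range is split into
$n$ equal bins, one sample per bin, uniform within the bin, paired by
independent permutations; a fixed seed makes the draw bit-reproducible.
Density varies by $\pm 5\%$ around a nominal 1116 kg m$^{-3}$ as a hydration
nuisance parameter — it affects wave speed but is not a prediction target.

## Dataset assembly

Each recorded waveform is interpolated by a degree-4 (order-5 B-spline)
interpolating spline onto 1001 equally spaced times in [0, 0.0125] s. The
spline passes through every sample and reproduces quartic polynomials
exactly (tested); interior knots sit at data midpoints, which satisfies the
Schoenberg–Whitney conditions, and no extrapolation is permitted. The three
blocks are concatenated in the fixed order baseline, day 0, day 3.5 into a
3003-dimensional feature vector.

The day-7 growth field is coarsened to 5x5 by partitioning the quarter
domain into equal rectangles (10 mm x 7.5 mm) and taking the cell-centre
value nearest each rectangle centre (ties toward the origin), stored
row-major from the symmetry corner. Targets are these 25 values followed by
$\mu$, $k$, $\theta_\mathrm{nat}$ (28 in total). The extra-area metric
$\sum (\theta_g - 1)\,A_\mathrm{cell}$ summarises a growth field in mm$^2$.

Datasets are stored in a portable directory container: Feather files for
features ($n\times3003$) and targets ($n\times28$) — exact IEEE doubles, so
read-after-write is bit-identical (tested) — plus the subjects CSV manifest
and a JSON config snapshot.

## The surrogate and its training

The inverse model is a fully connected network
$3003 \to 32 \to 64 \to 32 \to 28$ with linear outputs, trained on
z-scored features and targets with minibatch Adam (batch 32, learning rate
$10^{-3}$) under the mean-squared-error loss. Scalers are fitted on training
rows only; predictions are returned in original units. Per-target accuracy
is the coefficient of determination $R^2$ on held-out subjects, identical
in scaled and original units for per-target z-scoring.

Training a ~100k-parameter first layer on a few hundred noiseless rows
overfits badly if done naively, so the default training scheme adds three
standard small-sample measures, each exposed in `arch_spec()`:

* **Smooth-basis first layer (`dct_k`).** The first dense layer is
  optimised in a fixed orthonormal DCT-II basis per 1001-sample block (450
  modes), with the projected coordinates re-standardized. Projection and
  scaling are linear, so after training they are folded back into the first
  weight matrix and bias: the stored model is exactly the declared dense
  architecture. The basis acts as a time-smoothness prior and conditions
  the optimisation of waveform inputs dramatically better than raw
  per-sample coordinates.
* **Augmentation and decay.** Gaussian input noise (sd 0.05 on standardized
  features, fresh each minibatch) and decoupled weight decay ($10^{-3}$).
  Optional variants (mixup blending, extra loss weight on the growth
  targets, log-space field targets) are exposed in `arch_spec()` but
  disabled by default; under cross-validation none improved on the
  defaults.
* **Averaged endpoint (SWA).** Training runs a fixed 500 epochs under a
  deterministic schedule (learning rate halved every 100 epochs from
  $10^{-3}$); the returned weights are the average over the final 150
  epochs at a constant learning rate $3\times10^{-4}$. A 5% inner
  validation split monitors the run; with SWA disabled (`swa_epochs = 0`)
  classic early stopping (patience 100, best-weight restoration) applies,
  and a reduce-on-plateau schedule is available when the validation split
  is large enough to drive it reliably. A hidden-layer `tanh` nonlinearity
  outperformed the rectifier for these smooth waveform inputs and is the
  default.

Everything is deterministic given the seed, including shuffling, the inner
split, initialisation and augmentation draws.

**Evaluation protocol.** Repeated k-fold cross-validation: per repeat a
fresh partition into near-equal folds and fresh initialisation; scalers and
the DCT re-standardization are fitted inside each training split (a canary
test checks that information available only on test rows cannot leak in).
The report collects per-target $R^2$ for all 28 targets plus the derived
`avg_growth` column (mean over the 25 growth targets per evaluation), with
medians and standard deviations, the fraction of held-out subjects whose 25
growth values are all predicted within 0.01, and supports an architecture
search ranked by the mean of the growth-field and shear-modulus medians
(ties broken by the growth-field median).

## Problem sizes and profiles

Two built-in configurations: the `desk` profile (300 subjects, 40x30 grid,
10-fold cross-validation with 2 repeats) — the package's standard
single-CPU evaluation, used by the test suite and the acceptance script —
and the `full` profile (1000 subjects, 100x76 grid, 5 repeats) for
full-scale runs. On the desk profile, dataset generation takes well under a
minute and the cross-validation about ten minutes on one CPU.

## What the simulation does and does not emulate

The generator produces noiseless, smooth waveforms from a reduced membrane
model on a fixed grid. Passing tests therefore demonstrate that the
pipeline's inverse problem is well-posed and that the surrogate recovers
material parameters and growth fields from simulator output — they do not
demonstrate robustness to measurement noise, device response, skin-layer
structure, anisotropy, viscoelasticity, 3D wave physics, or contact
mechanics between expander and skin, none of which are modelled. The growth
rate $k$ is intrinsically the hardest target: for fast-growing subjects the
day-3.5 state has nearly relaxed to baseline, so the waveform shift that
encodes $k$ saturates — mirrored in the lower held-out $R^2$ for $k$ than
for $\mu$ and $\theta_\mathrm{nat}$ (asserted as an identifiability
ordering in the acceptance tests). The 25-value growth field is the
tightest performance check at the desk scale: its day-7 values for
slow-growing subjects ($k \lesssim 0.4$/day) are still far from steady
state and depend sharply on $k$, so with ~30 held-out subjects per fold
the per-fold field accuracy is sensitive to how many slow growers the fold
contains, and the cross-validated median varies noticeably with the
population draw. Larger populations tighten this; the desk profile keeps
$n = 300$ for single-CPU runtimes.

## Reproducing a run

```{r, eval = FALSE}
cfg <- default_config("desk")
out <- "runs/demo"
cmd_sample(cfg, out)      # subjects.csv + manifest
cmd_simulate(cfg, out)    # dataset container (feather + csv + json)
report <- cmd_cv(cfg, out)    # repeated k-fold CV of the surrogate
print(report)
cmd_report(cfg, out)      # medians, scatter data, extra-area comparison
```

The same pipeline is scriptable from a shell via the thin wrapper in
`inst/cli/expansim`, and `scripts/acceptance.R` reruns the desk-profile
evaluation end to end from a single seed.
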