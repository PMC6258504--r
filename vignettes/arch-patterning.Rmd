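---
title: "Modelling dorso-ventral patterning of the zebrafish mandibular arch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dorso-ventral patterning of the zebrafish mandibular arch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(archpattern)
```

## The biological problem

Between roughly 14 and 36 hours post-fertilisation (hpf) the neural-crest
cells of the zebrafish first pharyngeal (mandibular) arch are partitioned
along the dorso-ventral (D-V) axis into three domains — ventral (V,
*hand2*-like genes), intermediate (I, *dlx3b/5a*-like) and dorsal (D,
*jag1b/hey1*-like) — that later form the lower jaw, the jaw joint and the
upper jaw skeleton. Two ventrally secreted morphogens convey position: Bmp
(short range, instructive) and Edn1 (long range, permissive). Patterning is
remarkably reproducible even though the tissue doubles in length and cell
number during the process and every signalling step is noisy.

`archpattern` implements a compact dynamical model of this system and the
analyses around it: how the *temporal order* in which the three gene groups
switch on shapes the robustness of the final pattern, and how precision
(run-to-run reproducibility) trades off against accuracy (closeness of the
simulated domain boundaries to reference wild-type boundaries).

## The gene-regulatory network

Each cell (or 1D node) carries three lumped concentrations $V, I, D$,
normalised so that the maximal steady state is about 1, driven by local
morphogen levels $A_1$ (Bmp) and $A_2$ (Edn1):

$$\dot V = -d_{ve} V + b_{ve} + v_{ve}\, h^+(A_1, p_1)$$
$$\dot I = -d_{in} I + b_{in} + v_{in}\, h^+(A_2, p_2)\, h^-(V, p_3)\,
  h^-(D, p_4)\, h^+(A_1, p_5)$$
$$\dot D = -d_{do} D + b_{do} + v_{do}\, h^-(I, p_6)\, h^-(A_2, p_7)$$

with Hill terms $h^+(s,p) = s^2/(p^2+s^2)$ and $h^-(s,p) = p^2/(p^2+s^2)$
(coefficient 2 throughout). Bmp activates V directly and gates I; Edn1 is
required by I and represses D; V and D both repress I; I represses D. The
basal production $b$ is a standalone additive term in all three equations.

### Parameter defaults and their calibration

No published table of the seven dissociation constants was available to this
implementation, so the defaults are the package's own calibration,
dimensionless, chosen once against four qualitative anchors and then frozen:

* three contiguous V/I/D bands at 35 hpf with a narrow ventral V band
  (about two cell rows in 2D);
* the same final 35 hpf label pattern for all six temporal orders;
* the six canonical perturbation outcomes (below);
* per-gene noise robustness increasing with earlier expression onset.

The shipped values are `p = (0.6, 0.2, 0.45, 0.45, 0.1, 0.5, 0.25)` with
gradient amplitudes 1 and decay lengths $\lambda_1 = 15$ µm (Bmp),
$\lambda_2 = 45$ µm (Edn1). The comparatively soft repression constants
(`p3`, `p4`, `p6`) matter: the I gene is the network hub, and steeper
repression gains would transmit V- and D-fluctuations into I strongly
enough to mask the temporal-order effects the model is meant to expose, and
would prevent the dorsal take-over of the I region under dorsal-factor
overexpression.

### Temporal order

Two mechanisms are implemented:

* **intrinsic** (default): the fast/medium/slow rate pairs
  $(v, d) = (3, 1.5, 0.75)\,\mathrm{h}^{-1} \times$ base rate are assigned to
  the earliest/middle/latest group of the requested order, with $v/d = 1$ and
  $b/d = 0.05$ held fixed for every group, so all six orders share identical
  steady states;
* **extrinsic**: all groups share one rate and the *regulated* production
  term of each group is switched on at a fixed onset time (defaults: I at
  22, V at 24, D at 26 hpf; basal production is always on).

With the default rates the slowest group's relaxation time is 1.3 h, so by
35 hpf the system sits within about $10^{-4}$ of its steady state. That is a
deliberate choice: it is what makes the 35 hpf label pattern exactly
order-invariant, node for node. The price is that expression onsets are
spaced tens of minutes apart rather than the hours observed in vivo; slowing
the rates to reproduce hour-scale spacing leaves order-dependent transients
at 35 hpf and breaks exact order invariance. The package favours the
invariance, because the order-comparison analyses all assume a common
deterministic endpoint. A related consequence: box-plot summaries of
parameter sensitivities sampled at 10 equidistant times are dominated by the
(order-independent) steady state, so order-dependent differences in those
medians — reported for slower parameterisations — are not reproduced here.

### Classification and its reference

A location is labelled V, I or D when that group's expression exceeds 20 %
of its *reference maximum* and strictly exceeds the other two normalised
levels; ties and sub-threshold states are "unpatterned". The reference
maxima are the per-gene maxima, over space and time, of the deterministic
wild-type (IVD) run of the same model (1D or 2D), and the *same* reference
is reused when classifying perturbed, stochastic or re-ordered runs. A
per-scenario reference would make cross-scenario label comparisons
meaningless: in I-first orders the intermediate gene transiently overshoots
in the ventral region, so its own run maximum differs across orders even
though the steady states are identical. Winner-take-all classification
against the wild-type reference is also what lets a perturbation "lose" the
ventral domain label without any change to the V equation — under Edn1 loss
the fully de-repressed dorsal group simply out-scores V everywhere.

## Morphogen fields

In 1D the gradients are static exponentials
$A_k(x) = \mathrm{scale}_k \cdot \mathrm{amp}_k\, e^{-x/\lambda_k}$ on a
70 µm domain (201 nodes — longer than the largest synthetic arch, so the
gradient support is never truncated). In 2D the quasi-steady state of
diffusion with uniform degradation and a constant source on the ventral
production band (2 µm wide by default) is re-solved every step on a fixed
50×50 grid with zero-flux box boundaries, then normalised so the field
maximum equals the configured amplitude; each cell samples its nearest grid
point. The operator is factorised once per run (the grid does not move), so
the per-step cost is two sparse triangular solves. A 2 µm band keeps the 2D
field close to $e^{-d/\lambda}$ measured from the ventral tip; a band as
wide as $\lambda_1/2$ would displace every expression boundary dorsally by
most of the band width relative to the reference curves.

Perturbations enter as multiplicative source scalings (`scale1`, `scale2`),
an optional spatially uniform Edn1 override (`uniform2`, as a fraction of
the wild-type maximum), and a production multiplier on the dorsal group
(`jag`) for Notch-pathway perturbations. The six canned scenarios and the
outcomes the model reproduces:

| scenario | setting | outcome at 35 hpf |
|---|---|---|
| `bmp_low` | Bmp at 1 % | V, I lost; D expands ventrally |
| `edn1_low` | Edn1 at 1 % | V, I lost; D expands ventrally |
| `jag_low` | dorsal production at 1 % | D lost |
| `jag_high` | dorsal production at 500 % | I lost, D expands |
| `edn1_high` | Edn1 at 500 % | D lost |
| `edn1_uniform50` | uniform Edn1 at 50 % | normal three-domain pattern |

## Noise

Morphogen noise is multiplicative and white:
$A \mapsto \max(0, A + \eta\,\xi A)$ with $\xi \sim N(0,1)$ redrawn per node
and step ($\eta_1 = \eta_2 = 1$ at full strength; one draw per morphogen per
node per step, shared across equations). Gene-regulation noise adds
$\nu\sqrt{\Delta t}\,\xi$ per equation per step ($\nu = 0.05$),
Euler–Maruyama with the same $\Delta t$ as the deterministic path (93.6 s in
1D, 180 s in 2D). States are clipped at zero after each step (the clip is a
switch, `clip = FALSE` disables it; the Hill terms require non-negative
inputs). Ensembles report the mean and the *population* standard deviation
(divide by $n$): the bands are descriptive, so two members at $\pm a$ give
$\sigma = a$.

Two structural consequences worth knowing: because $h^+(A_2, p_2)$ is
saturated in most of the I domain, Edn1 noise is rectified — downward spikes
shut I production while upward spikes change nothing — so the ensemble-mean
I profile lies *below* the deterministic one (Edn1 is "unidirectionally
permissive"). And because additive GRN noise on a linear decay has
stationary deviation $\nu/\sqrt{2d}$, a gene expressed earlier (larger $d$)
is intrinsically more robust; the hub gene I additionally accumulates noise
transmitted from V and D regardless of its own rate.

## The 2D tissue

Cell centres interact through a generalised Morse potential
$U(r) = U_0 e^{-r/\xi_1} - V_0 e^{-r/\xi_2}$ with equilibrium spacing
$r_0 = \ln(U_0\xi_2 / (V_0\xi_1))\,\xi_1\xi_2/(\xi_2-\xi_1) \approx 3.3$ µm
(the printed closed form in the source literature has an inconsistent
denominator sign; the package uses the form that matches the numeric
stationary point). Pair interactions are cut off at $1.4\,r_0$ — adhesion is
contact-mediated, and including the attraction tail over further neighbour
shells compresses the lattice far below $r_0$ (in the extreme, collapses the
cell swarm). Motion is overdamped Euler with $\Delta t = 180$ s; forces are
the physical $-\nabla$ of the potentials (cells repel inside $r_0$, the
boundary repels inward). A per-pair distance floor of $r_0/100$ keeps forces
finite for freshly divided cells.

The deforming outline comes from the synthetic geometry stage: bean-shaped
key frames at 22, 24, 28, 32 and 35 hpf whose D-V extent follows the linear
growth law 30 µm (14 hpf) → 60 µm (36 hpf), elongating ventrally and
anteriorly with the dorsal edge pinned; vertex-wise linear interpolation
between key frames (the shared angular parameterisation makes vertex
correspondence exact by construction). Two rings totalling exactly 2118
repulsive nodes (inner on the outline, outer offset 2 µm, split by
perimeter) confine the cells; a gentle, near-uniform chemoattractant
(~1.5 µm/h) pulls cells towards the ventral-anterior tip so the tissue
follows the growing outline. Stronger chemoattraction is counter-productive:
the stacked pull of a cell column can exceed the finite Morse core ceiling
$U_0/\xi_1 - V_0/\xi_2$ and crush the packing.

Growth: 75 cells at 22 hpf double to exactly 150 at 35 hpf — 68 division
events (daughter at $r_0/20$ from a uniformly chosen mother, inheriting its
expression) and 7 dorsal immigration events (entry point uniform on the
dorsal-most quarter of the outline, inset $r_0/2$; migrants start at 40 % of
the maximal dorsal level), each stream at constant intervals. Cell count is
therefore deterministic given the schedule, and a fixed seed makes the whole
run bit-reproducible.

## Boundary metrics, precision and accuracy

Reference V-I and I-D boundary curves are horizontal level sets at fractions
0.11 and 0.5 of the 35 hpf D-V extent. The V-I fraction is calibrated so the
deterministic wild-type run scores a near-zero V-I error (boundary cells sit
0.8 µm from the curve on average, a quarter of a cell diameter), making the
error a pure noise/ordering readout; the I-D fraction is left at the
geometric midline, which the simulated I-D boundary overshoots slightly —
the model is not expected to position I-D perfectly even without noise.

Boundary cells are the ventral-side-labelled cells with at least one
dorsal-side-labelled neighbour in the contact graph (centre distance
< 1.5 $r_0$, a proxy for Voronoi adjacency; the package deliberately avoids
a triangulation dependency). The error is $E = \sum_i d_i$, the summed
point-to-curve distances — sensitive to displacement *and* to raggedness.
**Accuracy** is the mean $E$ over repeated stochastic 2D runs, normalised by
the worst condition in the comparison set. **Precision** is the maximal
ensemble σ of 1D expression at 35 hpf. For both, lower is better. The
trade-off analysis crosses the six temporal orders with a noise source and
reports both metrics plus their Spearman rank correlation across orders;
under combined noise the correlation is negative (orders that pattern more
reproducibly land farther from the reference), and the observed IVD order
ranks better on precision than on accuracy.

## Sensitivity analysis

Forward sensitivities $s_i = \partial y/\partial p_i$ are integrated with
the augmented system $\dot s_i = (\partial f/\partial y) s_i + \partial
f/\partial p_i$ (both partials analytic) using an adaptive, error-controlled
solver (lsoda, rtol $10^{-8}$, atol $10^{-10}$) at fixed morphogen levels
representing the V (x = 0), I (x = 0.45 L) and D (x = 0.9 L) domains. The
implementation is validated against central finite differences of the plain
system (relative error below $10^{-3}$ at 10 sample times for all 7
parameters × 3 contexts; the difference runs use tighter tolerances and a
relative step of $10^{-5}$, which keeps the difference well clear of solver
error). Summaries report median/quartiles/extremes over 10 equidistant
times, normalised either to the global p1/p5 maximum or per gene. A
single-morphogen variant (`single_morphogen = TRUE`) collapses the two
gradients onto one and drops the second Bmp gate, for comparing one- and
two-morphogen architectures.

## Worked example

```{r oneD}
dom <- domain_1d()
wt <- integrate_deterministic(dom)
ref <- trajectory_reference_max(wt)
table(classify(final_state(wt), ref))
plot(wt)
```

```{r ensemble}
ens <- ensemble(dom, morph = morphogen_params(eta2 = 1), n_runs = 20,
                base_seed = 1)
plot(ens)
```

```{r twoD, eval = FALSE}
# ~6 s: full growing-arch run
run <- run_2d(seed = 1)
plot(run)
nrow(final_tissue(run)$positions)   # 150
```

## Problem sizes and numerical choices

The package's standard analysis sizes are 100-run 1D ensembles and 10-run 2D
accuracy sets, as in the headline analyses; the shipped tests and examples
use 20 and 5, which reproduce every qualitative conclusion while keeping a
full check run in minutes on one core. Euler forward at the default steps is
stable for the default parameters (the fastest rate gives $d\,\Delta t
\approx 0.08$); the integrators abort with a descriptive error on
non-finite states or super-$r_0$ displacements rather than continuing.
Fixed-point calculations use damped iteration (damping 0.5, residual
$10^{-12}$). Nearest-grid sampling breaks exact midpoint ties towards the
lower (row, column) index.

## What the synthetic geometry does and does not emulate

The outline generator reproduces the *measured* features that matter to the
model — closed, smoothly deforming outlines, the D-V growth law, ventral-
anterior elongation, exact vertex correspondence for interpolation — and
adds optional per-seed shape jitter for robustness experiments. It does not
reproduce traced micrograph outlines, 3D-to-2D projection artefacts, or
measured expression-boundary curves; the reference boundaries are level
sets placed by calibrated fractions. Consequently, passing tests show that
the pipeline's conclusions hold on a faithful synthetic stand-in of the
study geometry, not that the numerical boundary errors match those measured
against real images.

## Known limitations

* All rate parameters are calibrated, not fitted to data; analyses that
  depend on the specific rate magnitudes (e.g. sensitivity box-plot medians
  across orders) can differ from parameterisations with slower, hour-scale
  onsets.
* Under strong dorsal overexpression the thin ventral V band can lose its
  label to the de-repressed dorsal group — the expected I loss is
  reproduced, but V presence there is marginal.
* No cell death, no 3D geometry, no leader–follower migration mechanics (a
  global chemoattractant stands in, as in the modelling tradition this
  follows), and Grem2's dorsal Bmp antagonism is absorbed into the short
  Bmp decay length rather than modelled as a species.
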