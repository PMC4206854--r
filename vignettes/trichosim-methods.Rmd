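---
title: "Methods: a cell-based model of gliding filamentous cyanobacteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a cell-based model of gliding filamentous cyanobacteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trichosim)
```

## The system being modelled

Dense cultures of the filamentous cyanobacterium *Pseudanabaena* organise,
within hours, into macroscopic reticulate patterns: networks of ridges and
streams of aligned filaments enclosing low-density polygons. Similar
structures in the fossil record are among the oldest traces of life, which
makes the minimal physical requirements for their formation a question of
real paleobiological interest. The working hypothesis implemented here is
that no signalling is needed: long, flexible, self-propelled filaments that
glide, reverse at random, and collide sterically are sufficient.

trichosim models each trichome (an unbranched chain of cells acting as one
filament) as an inextensible discrete elastic rod of length $\Lambda$ and
diameter $\Theta$, discretised into $N$ edges of rest length
$l = \Lambda / N$. The dynamics are overdamped (inertialess): each vertex
moves in response to the total force through an anisotropic slender-body
mobility,

$$\frac{d\mathbf{x}_i}{dt} = \frac{1}{\zeta}\left(\mathbf{F}_i^{\parallel} +
  \frac{1}{b}\,\mathbf{F}_i^{\perp}\right),$$

where the split is along the local unit tangent $\hat{\mathbf{t}}_i$ and
$b \approx 2$ for long thin filaments. The total force is the sum of
bending, gliding, contact and wall terms.

## Forces

**Bending.** The rod is naturally straight and torsion-free (torsion is
deliberately ignored: gliding trichomes are free to rotate about their
axis). Bending follows the discrete-elastic-rod framework: at each interior
vertex the curvature binormal

$$(\kappa \mathbf{b})_i = \frac{2\, \mathbf{e}_{i-1} \times \mathbf{e}_i}
  {\|\mathbf{e}_{i-1}\|\|\mathbf{e}_i\| + \mathbf{e}_{i-1}\cdot\mathbf{e}_i}$$

measures the turning angle ($\|\kappa\mathbf{b}\| = 2\tan(\phi/2)$), and the
bending energy is $E = (\alpha/l)\sum_i \|(\kappa\mathbf{b})_i\|^2$ with
bending modulus $\alpha$. The vertex forces are the *exact* analytic
negative gradient of this energy, including the terms from the variation of
the edge lengths in the denominator. Published forms of the gradient often
assume fixed (rest-length) denominators; we keep the full gradient so that
the force field is exactly conservative — the test suite verifies
$\mathbf{F} = -\nabla E$ against central finite differences to a relative
error below $10^{-4}$ on random chains, and checks that net force and net
torque vanish identically. Inextensibility is handled separately by the
constraint solver, which removes whatever extensional component the forces
produce.

**Gliding.** Propulsion acts tangentially along the whole filament (slime
extrusion at every cell junction): $\mathbf{F}^g_i = \zeta v_0 P
\hat{\mathbf{t}}_i$ with polarity $P \in \{-1, +1\}$. Combined with the
tangential mobility this produces an exact free-gliding speed $v_0$. The
polarity reverses stochastically: once per accepted integrator step, each
trichome draws one uniform number and flips if it is below
$\omega\,\Delta t$; the step-size cap $\omega\,\Delta t \le 0.05$ keeps
this Bernoulli approximation accurate (reversal intervals are then
exponential with mean $1/\omega$ to first order). Reversals are only drawn
on *accepted* steps; rejected trial steps consume no randomness. The draws
come from R's global RNG stream in fixed trichome order, so a single
`set.seed()` makes entire runs bit-reproducible.

**Contact.** Each segment is a capsule of diameter $\Theta$; trichome tips
carry semi-spherical caps, and at shared vertices the capsules are cut
perpendicular to the local tangent. Contact between two edges acts at
discrete points parameterised by $(a, b)$ along the edges. If the edges
cross when projected onto their common-parallel plane, the single crossing
interaction (perpendicular connector of the two lines) is used; otherwise
the four vertex-against-opposing-edge candidates are tested against the
segment domains. The domain conditions as printed in the source framework
are head/tail asymmetric (they admit tail-cap contacts but not head-cap
contacts, and reject lateral contacts on final segments); since reversing
trichomes cannot have orientation-dependent *geometry*, we restore the
intended symmetry: a slab condition at a shared vertex assigns each contact
to exactly one of the two adjacent segments, and at a trichome tip the slab
is relaxed (the spherical cap extends the domain). Duplicate candidates
that clamp to the same $(a,b)$ are merged and at most the two nearest
candidates are kept — a pair of capsules has at most two distinct contact
regions. The force magnitude is a truncated Lennard-Jones law,

$$f(h) = \tfrac{1}{2}\epsilon\left[(\Theta/h)^{13} - (\Theta/h)^{7}\right],$$

zero at $h = \Theta$, peak attraction $\approx 0.112\,\epsilon$ at
$h = (13/7)^{1/6}\Theta$, truncated at $h = 2\Theta$, with the repulsive
branch capped at $R$ to bound the stiffness. Positive $f$ is repulsive: the
force $-f\hat{\mathbf h}$ acts on edge 1 and its reaction on edge 2,
distributed to the four vertices by linear interpolation so that both
momentum and angular momentum balance exactly. (The untruncated magnitude
at the $2\Theta$ cutoff is about 3.4% of the peak attraction; we accept
this as the truncation error.) Cohesionless runs ($\beta = 0$) keep the
hard core with the repulsion strength corresponding to $\beta = 0.125$ and
suppress the attractive branch entirely.

**Walls and boundaries.** The box $W \times H \times D$ is periodic in $x$
and $y$ (minimum-image convention for all contact displacements; vertex
coordinates are stored unwrapped so rod geometry stays continuous) and
bounded in $z$ by stiff planes: a vertex closer than $\Theta/2$ to either
plane feels a linear restoring force with stiffness `wall_c`.

## Nondimensionalisation

Choosing the characteristic velocity $V = v_0$ and length
$L = \sqrt{\alpha / (\zeta v_0)}$ (so $T = L/v_0$) reduces the bending and
gliding coefficients to one, leaving a single dynamic control parameter,
the cohesion strength $\beta = \epsilon / (\zeta v_0)$, plus the reduced
groups $\omega T$, $\Lambda/L$, $\Theta/L$, the reduced domain size and the
volume fraction $\rho$. The acceptance suite exploits this directly: two
dimensionally different parameter sets related by a power-of-two length
scaling (lengths $\times 4$, $\alpha \times 4^3$, $\omega / 4$, accuracy
$\times 4$) produce bit-identical trajectories in units of $L$ and $T$,
because every internal default (initial step size, relaxation step cap,
list cutoffs, tolerances) is either relative or scales with $L$ and $T$.

## Parameters

Defaults describe the cultured *Pseudanabaena* system:

| symbol | meaning | default | unit |
|---|---|---|---|
| $\Theta$ | trichome diameter | 1.5 | µm |
| $\Lambda$ | trichome length | 750 | µm |
| $N$ | edges per trichome | 125 ($l = 6$ µm $= 4\Theta$) | — |
| $\alpha$ | bending modulus | $2\times10^{-21}$ | N m² |
| $\mu$ | medium viscosity | 1 | Pa s |
| $c$ | slender-body shape constant | 1/2 | — |
| $v_0$ | gliding speed | 1.3 | µm/s |
| $\omega$ | reversal frequency | 1/300 | s⁻¹ |
| $b$ | drag anisotropy | 2 | — |
| $\beta$ | cohesion ratio | 0 | — |
| $W \times H \times D$ | domain | 3500 × 7.5 × 3500 | µm |
| $\rho$ | volume fraction | 2.5 | % |
| — | integrator absolute accuracy | 0.1 | µm |

The per-vertex drag is the slender-body drag of the whole filament divided
over its $N+1$ vertices, $\zeta = \frac{1}{N+1} \frac{4\pi\mu\Lambda}
{\ln(2\Lambda/\Theta) + c}$. Hydrodynamic coupling between trichomes and
wall-proximity corrections are ignored. The repulsion cap defaults to
$R = 100\,\zeta v_0$ (bounding a contact's instantaneous speed to 100
gliding speeds) and the wall stiffness to $100\,\zeta v_0/\Theta$
(equilibrium wall penetration $0.01\Theta$ under a gliding-scale load);
the source model states only that a cap exists and that the walls are
stiff, so these are this package's own calibrations, exposed as
parameters.

Two stiffness conversions support the parameter choice. A thermally
flexing filament has $\alpha = k_B T \xi$ with persistence length $\xi$;
the measured $\xi = 480$ µm gives $\alpha \approx 1.94\times10^{-24}$ N m²
at 293 K (the conversion temperature is not stated in the source; any lab
temperature in 293–298 K reproduces the printed figures to two significant
figures, and 293.15 K — 20 °C — reproduces them to three, so that is the
default). Treating the cross-section as a hollow cylinder of wall
thickness $t$, the material stiffness is
$Y = 4\alpha / \pi(r^4 - (r - t)^4)$, giving a clearly unphysically soft
54 Pa for the thermal estimate — the justification for adopting the much
stiffer working value $\alpha = 2\times10^{-21}$ N m² ($\xi = 0.49$ m)
instead. Note one internal inconsistency of the source values: with
$d = 1.5$ µm and $t = 10$ nm, the lower-bound $Y = 3.1\times10^5$ Pa maps
through the formula to $\alpha \approx 4\times10^{-21}$ N m² (and
conversely $\alpha = 2\times10^{-21}$ implies $Y \approx 1.5\times10^5$
Pa), a factor ~2 from the stated pairing; we implement the formula as
printed — it does reproduce the 54 Pa example exactly — and keep
$2\times10^{-21}$ as the dynamical default.

## Numerics

**Integration.** First-order Euler with step-doubling error control: each
trial step is computed once with $\Delta t$ and once as two half-steps; the
maximum vertex discrepancy is the local error estimate, accepted when below
the absolute accuracy (0.1 µm by default), with safety factor 0.9, growth
capped at 1.5× per step, and $\Delta t \le 0.05/\omega$. The accepted state
is the more accurate two-half-step result. In practice the step size is
limited by the explicit-stability threshold of the stiffest bending mode
(amplified rounding noise shows up in the error estimate and the controller
settles just below the threshold), which also means an isolated "straight"
glider carries nanometre-scale transverse noise — far below the accuracy
target.

**Constraints.** After every unconstrained (sub)step, bond lengths are
restored by a LINCS-type projection: corrections act along the bond
directions of the pre-step chain, and the constraint coupling matrix
$S = B B^\top$ — tridiagonal for a chain, diagonal 2, off-diagonal
$-\mathbf{u}_k \cdot \mathbf{u}_{k+1}$ — is solved exactly with the Thomas
algorithm, iterating until every bond is within $10^{-8} l$. A truncated
series expansion of $S^{-1}$ (the textbook LINCS formulation) is not usable
here: for a long straight chain the coupling spectral radius approaches
$\cos(\pi/(N+1)) \to 1$ and the series barely contracts. Non-convergence of
the projection rejects the step and halves $\Delta t$.

**Neighbour lists.** Candidate contact pairs are edge pairs whose
minimum-image midpoint distance is below $2\Theta + l$ (a guaranteed
superset of all pairs with true separation below the $2\Theta$ force
cutoff), built by uniform spatial hashing in $x, y$ and reused until any
vertex has moved $\Theta$ from its build-time position. Same-trichome edge
pairs fewer than 3 positions apart are excluded (adjacent capsules overlap
by construction); distant self-contact remains possible. As in the source
model, forces may briefly be computed from a stale list; this is an
approximation knob, not a correctness property.

**Initialisation and relaxation.** Trichomes start straight, parallel to
the $xy$ plane, with uniform random centre, orientation, height and
polarity; the count is $\mathrm{round}(\rho W H D / (\pi (\Theta/2)^2
\Lambda))$ (end caps ignored; < 0.1% at these aspect ratios). The initial
state is then relaxed with gliding, reversals and cohesion off — hard-core
repulsion and walls only — until the deepest contact penetration is below
$0.01\Theta$ *or* the configuration reaches its steric equilibrium within
a simulated-time budget. The second clause is necessary, not cosmetic: a
7.5 µm channel fits exactly five $\Theta = 1.5$ µm layers, so a column of
six mutually crossing trichomes is geometrically unable to reach full
$\Theta$ spacing and instead equilibrates at $\approx 6/5 \cdot \Theta/1.5$
spacing with balanced forces. Only a *deep* residual overlap (separation
below $\Theta/2$) after the budget is treated as an infeasible packing.

## Pattern observables

All metrics consume trajectory frames through the documented schema only.

* **Global alignment**: length of the mean angle-doubled direction vector
  of the $xy$-projected edge angles,
  $\|\langle(\cos 2\theta_k, \sin 2\theta_k)\rangle\|$. The nematic
  (angle-doubled) form is a deliberate choice: trichomes are head/tail
  symmetric under reversals, so a polar mean would spuriously vanish for a
  perfectly aligned but bidirectional stream. For $M$ random orientations
  the expected value decays like $\sqrt{\pi}/(2\sqrt{M})$.
* **Local alignment**: per edge, the nematic resultant of the full 3-D
  relative angles to all edges passing within one diameter $\Theta$
  (minimum segment-segment separation, minimum-image in $x,y$), the edge
  itself included — an isolated edge scores 1, and values stay in [0, 1].
  Using true segment separation rather than midpoint distance matters: with
  $l = 4\Theta$, the midpoints of two touching edges are almost always
  farther apart than $\Theta$, which would empty every neighbourhood and
  pin the metric at 1.
* **Local cluster size**: per edge, the number of distinct trichomes with
  any edge within $2\Theta$, own trichome included.
* **Tangent correlation length**: the per-trichome tangent autocorrelation
  $\mathrm{acf}(k) = \frac{1}{N-k}\sum_i \mathbf{e}_i \cdot
  \mathbf{e}_{i+k}$, averaged over trichomes and fitted with
  $\exp(-k l / \xi)$ by nonlinear least squares on lags up to the first
  zero crossing ($\xi$ reported in length units; perfectly straight
  populations return an `Inf` sentinel). On synthetic worm-like chains with
  known persistence the estimator recovers the truth within 10%.
* **Sector alignment autocorrelation time**: the domain is divided into
  square sectors (100 µm by default), each occupied sector's nematic
  director is followed through the analysis window (the final 2 h at 288 s
  sampling by default), and $\langle\cos 2(\psi_{t+k} - \psi_t)\rangle$ is
  fitted with $\exp(-k\Delta t/T)$. A pattern that never decorrelates
  within the window reports the window length as a sentinel; one that
  decorrelates within a single frame reports 0.
* **Sector density distribution**: per-sector edge counts; the random
  initial state is approximately Gaussian (mean $\mu$, sd $\sigma$), and
  self-organisation into streams appears as positive skewness relative to
  that reference.

## What the synthetic generators do and do not show

The initial-condition generator and the worm-like-chain generator emulate,
respectively, a uniformly inoculated culture of straight filaments and a
thermally flexed filament population with a known persistence length. They
contain none of the things real cultures have: polydisperse lengths, growth
and fragmentation, substrate coupling of the gliding force,
light-modulated reversals, or vertical ridge growth beyond the 7.5 µm
ceiling. Passing tests therefore demonstrate that the *mechanical model*
is implemented correctly and that its collective behaviour (stream
formation at low $\beta$, density skew, the stability ordering between
cohesionless streams and strongly cohesive meshes) reproduces at reduced
scale — not that the model quantitatively matches any particular culture.

## Problem sizes used by the test and acceptance suites

The headline simulations of the original study (3.5 mm and 1 cm domains,
~1,700+ trichomes, 8–12 simulated hours) were GPU-scale; this package is a
CPU reference implementation and runs its collective-behaviour checks on
reduced systems chosen to keep the full suite in the minutes range: the
stream-formation check uses a 500 × 500 × 7.5 µm domain with 250 µm
trichomes at $\rho = 2.5\%$ (106 trichomes, ~4,500 vertices) for 2
simulated hours and three seeds, and the stability-ordering check a
300 × 300 × 7.5 µm domain with 150 µm trichomes for 1.5 simulated hours.
These are this package's own scaled-down study conditions; all mechanical
unit checks (gradients, geometry oracles, conservation, scale invariance)
are exact-scale and independent of system size. At the reduced scale the
local-alignment rise is a strong, seed-robust signal, whereas the sector
density skew is weaker and varies between seeds (a domain-spanning
uniformly aligned band raises alignment without concentrating mass); the
full-scale study domains leave far more room for distinct streams.

## Known limitations

* Explicit first-order stepping makes the bending term the step-size
  bottleneck; very stiff ($\alpha \gg 10^{-20}$ N m²) filaments would want
  an implicit or higher-order scheme.
* The admissibility rules resolve ties at exactly-perpendicular contacts
  asymmetrically (one side inclusive, one exclusive, as printed in the
  source framework); this is measure-zero in dynamics but visible in
  hand-built exactly-parallel fixtures.
* Relaxation accepts jammed multi-layer stacks at slightly sub-$\Theta$
  spacing (see above); with the default capped repulsion this is the
  correct steric equilibrium for a shallow channel, but it means "no
  overlaps" is approximate at the paper-scale density.
* Metrics load whole frames into memory; at the original 1 cm scale
  (~90,000 trichomes) the local-alignment scan would want a compiled
  neighbour search like the dynamics engine.
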