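---
title: "Fourier finite-element modeling of vestibular nerve stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fourier finite-element modeling of vestibular nerve stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the model it implements: the
physics, the numerical choices, the meaning and defaults of the tunable
parameters, what the synthetic phantom does and does not emulate, and the
known limitations. It states no empirical result beyond what the test
suite and `scripts/acceptance.R` themselves compute.

## 1. The field problem

A stimulation electrode drives a current waveform $I_0(t)$ through inner-ear
tissue. With purely resistive tissue (the quasi-static picture) the
potential obeys $-\nabla\cdot(\sigma\nabla\phi) = 0$ away from sources, and
the whole time course is one unit-current solve scaled by the waveform.
Biological tissue, however, is dispersive: its effective conductivity
$\sigma(f)$ and relative permittivity $\varepsilon_r(f)$ depend strongly on
frequency, and the displacement current matters whenever
$\omega\varepsilon_0\varepsilon_r/\sigma$ is not small. `qs_ratio()`
computes exactly this validity measure; for cerebrospinal fluid it stays
below $10^{-3}$ across the stimulation band, while for bone it reaches
$\sim 0.1$ and for nerve tissue $\sim 0.2$–$0.5$.

The package therefore solves, per frequency component $f_i$ of the
stimulus spectrum,

$$-\nabla\cdot\left[\boldsymbol\gamma(x, f_i)\,\nabla\phi(x, f_i)\right] = 0,
\qquad
\boldsymbol\gamma = \boldsymbol\sigma(x, f_i) +
j\,2\pi f_i\,\varepsilon_0\,\boldsymbol\varepsilon_r(x, f_i),$$

with complex potentials, and recombines time courses by inverse DFT at the
points where they are needed (electrode terminals, probe positions, nodes
of Ranvier). The stimulus is applied as a boundary condition, so the
source-free form is exact.

## 2. Dielectric model

Tissue properties come from multi-term Cole-Cole dispersions,
$$\hat\varepsilon(\omega) = \varepsilon_\infty + \sum_k
\frac{\Delta\varepsilon_k}{1 + (j\omega\tau_k)^{1-\alpha_k}} +
\frac{\sigma_i}{j\omega\varepsilon_0},$$
with $\varepsilon_r = \mathrm{Re}\,\hat\varepsilon$ (the ionic term is
purely imaginary) and $\sigma = \sigma_i - \omega\varepsilon_0\,
\mathrm{Im}\sum_k(\cdot)$. `tissue_library()` embeds the published
parameter sets for cerebrospinal fluid, cortical bone and nerve
(spinal-cord) tissue and tabulates them on a canonical logarithmic knot
grid (10 knots per decade, 100 Hz–500 kHz). Design choices:

* **Knot tables + splines rather than direct evaluation in the solver.**
  The solver interpolates `tissue_property` tables with a cubic spline on
  (log₁₀ f, log₁₀ value); properties span decades and a log-space spline
  cannot overshoot into negative values. A linear-space spline is kept for
  verification (it reproduces cubic polynomials exactly, which the tests
  exploit as an oracle).
* **Fluids.** Endolymph, perilymph and the outer saline shell all use the
  CSF parameterization — their measured conductivities differ by only
  ~15 % and no dispersion data distinguishes them at these frequencies.
* **Nerve anisotropy.** The literature table for nerve is not tied to a
  fiber orientation. `scale_nerve_conductivity()` rescales all
  conductivity knots so that $\sigma(100\,\mathrm{Hz})$ matches a
  longitudinal or transversal reference value; permittivity knots are left
  unchanged (whether $\varepsilon_r$ should co-scale is genuinely unknown;
  leaving it fixed keeps the displacement current identical across
  directions and is flagged here as a modeling choice). The default
  references are $\sigma_l = 0.3$, $\sigma_t = 0.03$ S/m — the roughly
  10:1 anisotropy reported for myelinated nerve trunks; both are plain
  arguments of `phantom_tissues()`.
* **Uncertainty bounds.** Nerve properties get fractional ±50 % bounds.
  Bone and CSF use the median-log-distance rule against an alternative
  literature table ($d$ = median over knots of
  $|\log_{10}\mathrm{lit} - \log_{10}\mathrm{default}|$, bounds
  $\mathrm{default}\cdot 10^{\pm d}$); when no literature table is
  supplied, a default half-width of 0.15 decades (a factor ≈ 1.4, the
  scale of spread between published bone conductivity datasets) is used
  and can be overridden.

## 3. Stimuli and their spectra

`build_biphasic()` constructs cathodic-phase-first, charge-balanced
biphasic pulses. Defaults follow the long stimulus used throughout the
package: 200 µs phases, 40 µs gap (one source in the underlying
literature says 50 µs; 40 µs is the Methods value and the gap is an
argument), 1 mA amplitude, onset 280 µs, in a 1 ms window sampled at
1 MHz. The DFT window of 1 ms fixes the canonical frequency resolution of
1 kHz; with a 500 kHz maximum frequency the spectrum has 501 bins
including DC. A charge-balanced pulse has essentially zero DC content, so
the DC bin always falls below the sweep's magnitude floor (default
$10^{-6}$ of the peak bin); if a user supplies a non-balanced stimulus,
the DC bin is solved with the interface reduced to its scar resistance and
a warning. The one-sided spectrum folds the synthesis weight (1 for
DC/Nyquist, 2 otherwise) into the stored magnitude, so synthesis is a
plain cosine sum and is exactly real.

Band-limiting a step-edged pulse produces Gibbs ripple near the edges.
All waveform comparisons in the tests therefore either use the full
500 kHz band or compare two series synthesized from the *same* retained
spectrum, so that truncation ripple cancels and the comparison isolates
the physics (this matters for the QS-equivalence oracle and the slope
comparisons below).

## 4. The phantom

The anatomy this simulator is meant for — ampullae, otolith organs, five
nerve branches inside a temporal bone — requires segmented µCT imaging.
The package instead generates a parametric phantom containing the minimum
structure on which recruitment selectivity is meaningful:

* a spherical fluid cavity (radius 2 mm, CSF properties) centered on the
  "sensory epithelium center" at the origin;
* spherical electrodes (radius 150 µm) on the transversal axis inside the
  cavity: monopolar at 750 µm from the center, bipolar source/sink at
  250 µm and 1250 µm;
* one target nerve bundle leaving the cavity along the electrode axis and
  two non-target bundles along orthogonal directions (radius 0.6 mm,
  length 6 mm, anisotropic with the fiber axis along the bundle);
* a bone sphere of radius 25 mm and a saline shell to 35 mm whose outer
  surface is the 0 V reference.

The non-target bundles are deliberately farther from the electrodes than
the target, so selectivity questions (which branch activates first, how
monopolar and bipolar configurations differ) have non-trivial answers.
What the phantom does **not** emulate: real branch geometry and curvature,
the facial and cochlear nerves, the membranous labyrinth, tissue
heterogeneity inside bone. Passing tests on the phantom therefore
validate the *method* (solver correctness, directional effects,
selectivity machinery), not anatomical predictions; absolute AUCs and
thresholds are phantom-specific by construction.

### Meshing

No tetrahedral meshing library is available to R here, so the package
carries its own mesher, built from three pieces with well-understood
behavior: (i) a base mesh of icosphere shells (geometrically graded radii,
ratio 1.22, angular level 3) around a coned core, giving an outer boundary
whose vertices lie exactly on the 35 mm sphere; (ii) parallel longest-edge
bisection with Rivara-style closure driven by a spatial size field — edge
length ≈ 60 µm at the electrodes growing at 0.72·distance, 0.8 mm in the
cavity, 0.55 mm in the bundles; (iii) a conforming spherical cut for each
electrode: every mesh edge crossing the sphere is split at its
(radially projected) intersection point, with near-endpoint crossings
resolved by projecting the endpoint (rolled back if an element would
collapse), so the electrode contact surface is an inscribed triangulation
with all vertices on the sphere. Default resolution yields ~1.2×10⁵
tetrahedra; the mesh volume matches the 35 mm ball to <1 % and electrode
patch areas match $4\pi r^2$ to <1 %. Conformity (each interior face
shared by exactly two elements) and positive orientation are asserted in
the tests. The bone/saline interface is labeled by element centroid
without surface snapping — a sub-resolution stairstep acceptable for a
smooth, low-contrast interface far from the sources.

## 5. Field solver

First-order (P1) Galerkin elements on tetrahedra. Per region the assembly
uses unit stiffness matrices (identity tensor, plus the rank-one
$aa^T$ part for nerve regions), so a frequency sweep only recombines
precomputed sparse matrices with complex coefficients
$\gamma_t$ and $\gamma_l-\gamma_t$.

* **Electrodes** are equipotential floating terminals: all patch nodes are
  collapsed into one unknown that receives the prescribed total current
  (inverted for the bipolar sink). This matches a metal contact and makes
  the terminal voltages well defined; the alternative (uniform current
  density over the patch) would leave the "electrode voltage" ambiguous.
  The lumped contact impedance $Z_{ET} = R_{scar} + 1/(j\omega C_{dl})$
  sits between the metal terminal and the tissue surface, so it never
  enters the field system: $V_E = V_M + Z_{ET} I$ is applied afterwards.
  Consequence (asserted in tests): the tissue-side voltage $V_M$ is
  exactly invariant under the interface model in a current-controlled
  drive.
* **Reference**: outer-boundary nodes clamped to 0 V (Dirichlet).
* **Linear algebra.** `Matrix`/CHOLMOD Cholesky of the (SPD) conductive
  part; the capacitive part is folded in by a preconditioned fixed-point
  iteration whose contraction rate is bounded by the largest local
  $\omega\varepsilon_0\varepsilon_r/\sigma$ — below ~0.5 for every tissue
  in the band, giving convergence to $10^{-10}$ in a few dozen triangular
  solves. A 2N×2N real block LU stands by as a fallback for hypothetical
  strongly capacitive inputs. Residuals are checked per solve
  (tolerance $10^{-8}$).
* **Bins** with magnitude below $10^{-6}$ of the peak are skipped and
  contribute zero — a documented speed/accuracy trade-off (the skipped
  energy is orders of magnitude below the solver tolerance).
* **Flux accounting** uses the variationally consistent discrete flux
  (the stiffness residual summed over patch nodes), the FEM analogue of
  $\oint \gamma\nabla\phi\cdot n\,dA$; it reproduces the injected current
  to machine precision and is the quantity conserved by the
  discretization.

Verification oracles in the suite: exact reproduction of linear fields on
a structured cube; the closed-form potential
$\phi(r) = I/(4\pi\sigma)\,(1/r - 1/R)$ of a central spherical source in a
grounded homogeneous sphere (mid-radius agreement within 2 % at default
resolution); reciprocity of the bipolar transfer impedance; and exact
equivalence of the permittivity-free sweep with the QS unit solve.

## 6. Electrode interface and power limitation

$C_{dl}$ = areal density × sphere area, default 15 µF/cm² (mid-range for
metal in aqueous solution) on a 150 µm sphere → 42.4 nF. Scar tissue is a
0.1 S/m spherical shell; its lumped resistance
$R = (1/4\pi\sigma)(1/r_1 - 1/r_2)$ (≈ 4.1 kΩ at 500 µm thickness) is the
default representation, with a meshed-shell mode available (thicker shells
demonstrably raise the electrode voltage at fixed current).

The stimulation power drawn at the electrode is $P(t) = I(t)V_E(t)$ with a
cap of $P_{max}$ = 5 mW. Because the volume conductor is linear in the
drive, capping is implemented as one global rescale
$s = \sqrt{P_{max}/\max_t P}$ applied to the current (and hence all
voltages), which makes the limited peak power exactly $P_{max}$ and
coincides with recomputing $I_{new} = \sqrt{P_{max}/Z_{tot}}$ at the
binding time step — the two published forms of the rule agree at the
worst-case instant, which is the one that binds. A per-step rescale would
distort the waveform shape and destroy charge balance, so it is not used.
The 5–7 V compliance ceiling of implant electronics is noted but not
enforced by default.

## 7. Neural model

Each fiber is a SENN chain: nodes of Ranvier with a nonlinear Na⁺
channel, a nonlinear K⁺ channel, a nonspecific delayed current, a leak and
a membrane capacitance (the classical amphibian-node kinetics with GHK
flux equations — the structural requirements are two voltage-gated
channels plus leak and capacitance, and this is the standard published
parameter set for threshold studies in that arrangement), coupled by the
axoplasmic conductance $g_a = \pi d^2/(4\rho\Delta x)$ and driven by the
extracellular potential differences at the nodes. Numeric choices:

* nodal gap 2.5 µm, axon diameter 0.7 × fiber diameter, internode
  100 × fiber diameter, axoplasmic resistivity 1.1 Ωm, rates Q10-corrected
  from 20 °C to body temperature;
* integration: backward-Euler on the linear cable system (its small dense
  inverse is precomputed once per fiber), exponential-Euler gating,
  explicit ionic currents, step 1 µs (thresholds change <0.5 % under step
  halving, asserted); gating variables remain in [0,1] by construction of
  the exponential update;
* activation when the Na⁺ activation gate $m$ exceeds 0.7 at any node;
* thresholds by bisection on the field scale factor (the extracellular
  field is linear in stimulus amplitude), bracket auto-expanded by
  doubling, terminating when the *relative* bracket width falls below
  0.1 % (the published stopping rule does not say relative-to-what; the
  upper bound is the natural normalizer since it is the value returned);
  never-activating fibers are flagged unconverged and excluded from
  recruitment denominators.

The afferent population mixes calyx, dimorphic and bouton fiber types.
Their diameters (3, 2, 1 µm) and occurrence fractions (0.25/0.5/0.25) are
implementation defaults: the study this follows defers those numbers to
its own prior work, so here they are plain arguments of
`generate_fibers()` with the defaults documented at this single place.
An independent integration of the identical ODE system with a stiff
adaptive solver (`deSolve::lsoda`) serves as the cross-check oracle for
the integrator in the tests.

## 8. Selectivity

Recruitment = empirical CDF of converged thresholds over an amplitude
grid (default: 100 logarithmic steps spanning the observed threshold range
±20 %). ROC: TPR = target fraction, FPR = max over non-target branches at
each amplitude (worst-case convention); the worst-case branch is the
argmax at the final amplitude, with saturation ties broken by grid-wide
dominance. AUC integrates TPR over FPR by trapezoid after prepending
(0, 0) and extending the last point horizontally to FPR = 1 — the
endpoint convention is not fixed by the published description, and this
choice makes the canonical constructions exact: a perfectly selective
target scores 1, a silent target 0, identical curves 0.5. Waveform
comparisons use the RMSE over a window from 40 µs before stimulus onset to
40 µs after its end.

## 9. Problem sizes used in the tests

The published study ran a 12-million-element anatomical mesh with 400
fibers per branch and 500 frequency bins on a parallel direct solver.
This package's test suite exercises the identical code paths at desk
scale, chosen as the smallest sizes at which the directional claims are
resolved: phantom meshes of ~2×10⁴ ("tiny") and ~3.5×10⁴ ("small")
elements plus the ~1.2×10⁵-element default mesh for the analytic-sphere
oracle; sweeps truncated at 50 kHz (≤ 50 bins of the canonical 1 kHz
resolution); 6 fibers per branch (calyx/dimorphic mix) for the
QS-vs-Fourier and monopolar-vs-bipolar comparisons. The full-scale
settings (500 kHz, 400 fibers, finer meshes) remain the documented
defaults of `scenario()` and `phantom_config()`.

## 10. Known limitations

* The phantom's geometric simplicity means absolute amplitudes, AUC values
  and recruitment percentages are not comparable to anatomical models;
  only directions and mechanisms transfer.
* The electrode surface is equipotential with a *lumped* interface; a
  distributed (per-area) contact impedance would allow current-density
  redistribution over the contact at high frequencies.
* Scar growth over time, Faradaic electrochemistry, stochastic channel
  gating and synaptic transduction are out of scope.
* P1 elements with a graded bisection mesh give ~1 % far-field accuracy at
  default resolution; near-field quantities at the electrode surface
  (e.g. $V_M$ at the contact) carry a few-percent geometric discretization
  error from the inscribed spherical cut.
* The fixed-point complex solver assumes the local QS ratio stays below 1;
  materials far more capacitive than the embedded tissues would trigger
  the (slower) block-LU fallback.
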