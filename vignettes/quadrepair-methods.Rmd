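---
title: "Methods: hydrodynamics, stoichiometry, kinetics and melting of AGT on telomeric G-quadruplexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hydrodynamics, stoichiometry, kinetics and melting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadrepair)
```

## The system and the questions

Human telomeric DNA, (TTAGGG)$_x$, folds into G-quadruplexes: three
stacked quartets of Hoogsteen-bonded guanines around a central K$^+$.
O6-methylguanine (6mG) adducts in this sequence are repaired by
O6-alkylguanine-DNA alkyltransferase (AGT), a small (21 519 g/mol)
single-turnover protein. The analysis chain in this package addresses
three quantitative questions:

1. **Does the telomere sequence fold, and how compactly?** Answered
   hydrodynamically (sedimentation coefficients, frictional ratios,
   Perrin axial ratios) and spectroscopically (CD topology bands,
   thermal melting).
2. **How many AGT monomers bind a folded versus unfolded substrate?**
   Answered by global multi-speed sedimentation-equilibrium fitting.
3. **Are 6mG adducts inside the quadruplex stack repaired, and how does
   position matter?** Answered by biphasic repair-kinetics fitting with
   statistical phase-count selection, bookkept by tetrad position.

No instrument data ship with the package: a seeded generator module
produces every input with the statistical structure the fitters assume,
and each fitting stage is validated by recovering the generator's truth
parameters.

## Hydrodynamic standardization

`correct_s20w()` applies the standard buffer correction

$$s_{20,w} = s_{T,B}\,
  \frac{1-\bar v\rho_{20,w}}{1-\bar v\rho_{T,B}}\,
  \frac{\eta_{T,B}}{\eta_{20,w}},$$

with $\bar v = 0.54$ ml/g for quadruplex-forming DNA and 0.55 ml/g for
unstructured single strands. Water properties are embedded as published
correlations — Kell's 1975 density polynomial (0–100 °C) and the
Hardy–Cottington/CRC viscosity forms (one branch below 20 °C, one
above, meeting at 1.002 cP) — and unit-tested at 4, 20 and 25 °C.
Dilute TE buffer (10 mM Tris, 1 mM EDTA) is treated as water; salt
buffers take user-supplied densities/viscosities, because published
increment tables for the KCl/MgCl$_2$ mixtures used here are not
reliable enough to impose silently (the hydrodynamic chain is therefore
validated only for the water-like rows).

`frictional_ratio()` computes $f/f_0$ from the Svedberg friction
$f = M(1-\bar v\rho_0)/(N_A s)$ against the anhydrous-sphere Stokes
friction; `axial_ratio_from_ff0()` splits $f/f_0$ into shape and
hydration factors,

$$f/f_0 = P(p)\,\Big(\frac{\bar v + \delta/\rho_0}{\bar v}\Big)^{1/3},$$

and inverts the prolate Perrin factor $P$ by bracketed root finding to
$|P(p)-\text{target}| < 10^{-8}$. The hydration default
$\delta = 0.59$ g/g is a declared configuration value, chosen once so
that the inversion reproduces the reference axial ratios from the
corresponding frictional ratios; it is an effective, not a measured,
hydration. Only the prolate branch is implemented (the elongated,
unfolded chains in question are prolate); a target shape factor below 1
is reported as a flagged sphere rather than an error, since noise in
$f/f_0$ can land there legitimately.

## Sedimentation-equilibrium stoichiometry

With protein in large molar excess over DNA and binding saturated, the
radial absorbance profile is a two-species sum

$$A(r) = \alpha_P e^{\sigma_P (r^2-r_0^2)}
       + \alpha_{P_nD} e^{\sigma_{P_nD}(r^2-r_0^2)} + \zeta,
\qquad \sigma = \frac{M(1-\bar v\rho)\,\omega^2}{2RT},$$

evaluated in CGS units so $\sigma$ is in cm$^{-2}$ (at 25 000 rpm, 4 °C,
AGT has $\sigma \approx 0.82$ cm$^{-2}$). The complex's $\bar v$ is the
mass-weighted average of its components, so a single parameter — the
stoichiometry $n$ — controls both the mass $nM_P + M_D$ and the buoyancy
of the second exponential in every scan.

`fit_global_stoichiometry()` exploits the model's structure: at fixed
$n$ the model is linear in each scan's $(\alpha_P, \alpha_{P_nD},
\zeta)$, which are solved exactly by least squares (amplitudes clamped
non-negative through reduced solves). The profiled RSS$(n)$ is then
scanned on a 0.25-spaced grid over $(0, 12]$ and the best bracket
refined by Brent's method. This variable-projection design was chosen
over a joint trust-region fit of all parameters because the $n$-surface
can be multimodal and a one-dimensional exhaustive profile is immune to
starting-point luck while costing only a linear solve per grid point.
$r_0$ is fixed at each scan's radial midpoint (it is absorbed by the
amplitudes, so the choice is a parameterization, not an assumption);
0.005 cm is trimmed from each scan end to mimic meniscus/base exclusion.
The standard error of $n$ comes from the curvature of the profiled RSS;
`runs_test()` implements the published fit-quality criterion (small,
randomly distributed residuals) and `equilibrium_attained()` the
scan-superposition equilibrium check (RMS < 0.01 AU).

AGT's $\bar v_P$ defaults to 0.744 ml/g, a typical globular-protein
value, as a configuration input; extinction coefficients are never used
in fitting (amplitudes are free), so no extinction coefficient for AGT
enters the chain at all.

The generator's two designs reproduce the study conditions: the folded
(K$^+$) design at 25 000/35 000 rpm with truth $n = 2$, and the
K$^+$-free design at 12 000/16 000/20 000 rpm with truth $n = 4$, each
at two loading dilutions, 4 °C, with amplitudes set by conservation of
the loading signal over a 6.95–7.15 cm column and Gaussian noise of
0.005 AU (a typical absorbance-optics scale). Under these conditions the
global fit recovers $n$ to about $\pm 0.03$ (1 SD), comfortably inside
the published confidence intervals.

## Lamm-equation simulation and c(S) inversion

`lamm_solve()` integrates the sector-cell transport equation

$$\frac{\partial c}{\partial t} = -\frac{1}{r}\frac{\partial}{\partial r}
  \Big[r\Big(s\omega^2 r c - D\frac{\partial c}{\partial r}\Big)\Big]$$

with no-flux boundaries, on a node-centred finite-volume grid (default
400 points; end cells of half width so the trapezoidal sector integral
$\int c\,r\,dr$ is an exact invariant of the discretization).
Advection is discretized centrally where the cell Péclet number
$u\,\Delta r/D \le 2$ (second-order, non-oscillatory in that regime) and
by first-order upwinding otherwise; diffusion is centred; time stepping
is Crank–Nicolson with the step capped at half the advective CFL limit
and sub-stepped automatically. Mass is conserved to machine precision;
halving the radial step from the default changes profiles by about
0.1 % RMS, and the simulated boundary midpoint follows
$r_b(t) = r_m e^{s\omega^2 t}$ to within 1 % until back-diffusion
dominates.

`cs_invert()` expresses observed scans as a non-negative superposition of
unit-loading forward solutions on an s-grid, each with the diffusion
coefficient implied by a common frictional ratio:
eliminating the Stokes radius between the Svedberg relation and
$f = (f/f_0)\,6\pi\eta R_0$ gives a unique $M(s)$ (strictly increasing)
and $D(s) = k_BT/f$, which reduces to Stokes–Einstein at $f/f_0 = 1$
(unit-tested). The coefficients are found by non-negative least squares
with a second-difference Tikhonov penalty; the weight is fixed by the
caller or chosen by a discrete L-curve corner heuristic over a
log-spaced candidate set. Maximum-entropy regularization is deliberately
not implemented — the smoothness penalty is transparent and sufficient
for the single- and two-species questions asked here. All quantities
(s, D, M) are handled consistently in the experimental-buffer frame; the
default velocity scenario is a quadruplex-like species, $s = 2.0$ S with
$f/f_0 = 1.36$, at 40 000 rpm and 4 °C, scanned hourly for 10 h.

## Repair kinetics and phase selection

Product formation is modelled as
$F(t) = \sum_i A_i\,(1 - e^{-k_i t})$ with $F(0)=0$ and plateau
$\sum_i A_i$. `fit_repair()` performs unweighted Levenberg–Marquardt
least squares (rates fitted on a log scale; amplitudes bounded in
$[0, 1.1]$ with a soft penalty on the total exceeding 1.1, since the
substrate cannot exceed its active fraction by much), reports phases
sorted fast-to-slow, merges rate ties within 1 % into a single phase,
and derives standard errors from the Jacobian at the optimum.
Unweighted residuals are a deliberate choice: the quantitation noise is
approximately homoscedastic on the mole-fraction scale.

`select_phase_count()` fits 1–3 phases and adopts a larger model only if
an F-test on the RSS improves at $\alpha = 0.05$ **and** every amplitude
in the larger model exceeds its own standard error. This mirrors the
experimental logic: single-phase fits of folded-quadruplex courses leave
systematic residuals, while third phases come back with amplitudes
within error of zero.

`scale_rate()` converts a mole-fraction rate constant to an absolute
rate $k\,[\mathrm{DNA}]\,V$ in mol/s. The reaction volume is not a
measured quantity here; the default $V = 4\times10^{-4}$ L reproduces
the $10^{-13}$ mol/s scale of the reported rates and is echoed in every
output so the assumption is never silent.

The generator's kinetic scenarios encode the study's amplitude
structure: in K$^+$ buffer, G1 (outer tetrad) repairs to 63 %
($A_1 = 0.45$, $A_2 = 0.18$) and G5 (inner tetrad) to 39 %
($A_1 = 0.24$, $A_2 = 0.15$); in the non-folding TEA buffer both repair
almost completely (95 %/94 %) in a single phase. Fast rates are set so
$k_1[\mathrm{DNA}]V$ lies in the 0.7–1.7 $\times 10^{-13}$ mol/s band;
slow rates sit in the upper part of their 0.015–0.11 $\times 10^{-13}$
band, where the slow phase is actually resolvable within the sampling
window — a requirement the original two-phase fits themselves imply.
The sampling grid is the gel-lane schedule (30 s – 3 h) plus the 8.8-h
extent measurement that anchors the plateau, and each fitted course
pools two parallel trials (offset by 1 s), following the duplex-assay
practice of fitting combined trials. Noise is 0.02 mole fraction
(gel/fluorimetry quantitation).

Two honest limits of this design, established by the package's own
simulation studies: at 0.02 noise the plateau $A_1+A_2$ carries an
asymptotic SE near 0.03, so single-replicate plateau recovery within
0.05 happens in roughly 93–94 % of seeds, not more; and individual
$k_1/k_2$ ratios have ~50 % relative error, so the ratio is a
population-level (median) quantity, not a per-replicate one. The duplex
(NarI) scenario is harsher still: on its 15–360 s window the
four-parameter biphasic model is nearly degenerate with a single
blended exponential, so only the fast rate is treated as recoverable.

`classify_tetrad()` encodes the geometric bookkeeping: in a
three-quartet fold each G-tract contributes its first and last guanine
to the outer (top/bottom) tetrads and its middle guanine to the inner
tetrad; the sequence fixtures map the labelled variants (G1, G3, G4, G6
outer; G2, G5, G11 inner) accordingly.

## CD spectra and thermal melting

`difference_spectrum()` subtracts a free-protein spectrum from a
protein/DNA mixture spectrum (linear interpolation onto the mixture
grid, non-overlapping wavelengths dropped), isolating the nucleic-acid
contribution. `classify_topology()` applies the standard diagnostic
windows: a global maximum at 285–305 nm with a negative band at
230–245 nm calls an antiparallel quadruplex; a maximum at 255–270 nm
calls a parallel fold; anything else is indeterminate. The windows are
arguments, not constants.

`fit_melting()` fits 295-nm melting curves to a two-state van 't Hoff
transition with linear baselines,

$$y(T) = b_f(T)\,\theta(T) + b_u(T)\,(1-\theta(T)),\qquad
\theta(T) = \frac{1}{1 + \exp[(\Delta H/R)(1/T_m - 1/T)]},$$

so $\theta(T_m) = \tfrac12$ exactly and the fitted $T_m$ is invariant to
affine rescaling of the signal axis. $\Delta H$ is a nuisance parameter
(reported, not validated). The transition is located by the steepest
descent of a lightly smoothed signal away from the grid edges; after
fitting, a curve whose two-state fit does not beat a straight line by at
least a factor of two in RSS is rejected as having no transition — this
guards against a sloping baseline masquerading as melting. No smoothing
is applied to the data that are fit. Temperatures are kelvin throughout;
file readers accept Celsius columns explicitly.

The synthetic melting panel spans 337 K (22wt) down to 313 K (G5) in the
stability order 22wt > G1 > G6 > G4 > G3 > G11 > G2 > G5, with
$\Delta H = 200$ kJ/mol and noise at 1 % of the transition amplitude
(0.5 K sampling). At these settings $T_m$ is recovered with an SE near
0.1 K, and `rank_stability()` reproduces the generated order exactly;
outer-tetrad variants always rank above inner-tetrad variants.

## What the generator does and does not emulate

The generators reproduce the *statistical structure the fitters assume*:
exact model mean curves, independent Gaussian noise at plausible
instrument scales (0.005 AU absorbance, 0.02 mole fraction gel
quantitation, 1 % CD amplitude), seeded and bit-reproducible, with truth
records attached to every dataset. They deliberately do not emulate:
detector saturation or nonlinearity, radial-dependent or correlated
noise, baseline drifts, meniscus artefacts, partial-activity substrates,
slow approach to sedimentation equilibrium, oligomerization of
inner-tetrad variants (the broadened c(S) tails seen experimentally), or
KCl-buffer viscosity effects. Passing recovery tests therefore
demonstrates the correctness and statistical calibration of the fitting
chain under its own assumptions — not robustness to every artefact real
instruments produce.

## Numerical and reproducibility choices

- Constants: $N_A = 6.02214076\times10^{23}$ /mol,
  $R = 8.314462618$ J/mol/K ($\times 10^7$ in CGS), 1 S = $10^{-13}$ s.
- Optimizers: Levenberg–Marquardt (minpack.lm) with tight tolerances
  (ftol = ptol = $10^{-14}$) and multi-start over decades where surfaces
  are ridged (melting $\Delta H$; kinetics via the data-driven start);
  iteration-limit returns on over-specified candidate models are
  expected and used as the best point found.
- Non-negative least squares: Lawson–Hanson via pracma; singular
  covariance blocks fall back to a pseudo-inverse and are reported as
  large-but-finite errors rather than dropped.
- Problem sizes in the shipped studies were chosen to give stable
  statistics at interactive cost: 20–25 replicates per recovery study in
  the analysis drivers and acceptance script, 100 replicates in the
  acceptance tests, 300–400 radial points in the velocity stage.
- Every stochastic path flows from one explicit integer seed; reruns are
  byte-identical (`run_pipeline()` and the acceptance script are tested
  for this).

## Known limitations

- The KCl-buffer hydrodynamic rows are not reproducible from standard
  water tables; buffer properties must be supplied to treat them, and
  the chain is validated on the water-like rows only.
- Stoichiometry fitting assumes exactly two species (saturating excess
  protein); partial saturation or protein self-association would bias
  $n$ and is out of scope.
- The c(S) inversion is validated on synthetic fixtures, not against an
  external reference implementation, and uses a single common $f/f_0$.
- Biphasic-fit uncertainties are asymptotic; bootstrap uncertainty is
  not implemented.
- The melting model is strictly two-state; intermediate-state melting
  would bias $\Delta H$ (though $T_m$ is robust in practice).
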