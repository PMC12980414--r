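---
title: "Methods: structure-based dynamics with SAXS-driven ensemble selection"
author: "sbmsaxs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-based dynamics with SAXS-driven ensemble selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbmsaxs)
```

## Scope and model

`sbmsaxs` determines which conformations of a multidomain protein are
compatible with a solution scattering measurement. The workflow couples
four ingredients:

1. an all-atom **structure-based (Go-like) model** whose global minimum is a
   chosen native structure, sampled with Langevin dynamics;
2. a **Debye-sum SAXS calculator** that turns every sampled conformation
   into a theoretical intensity curve;
3. a scale-optimized **chi-square** score against the experimental curve,
   with a band + projection-density rule that extracts a representative
   ensemble; and
4. the accompanying solution-biophysics fits: P(r)/Dmax and Guinier shape
   analysis, ^19^F relaxation exponentials, amide-I Voigt deconvolution,
   and DLS cumulant analysis.

Everything is exercised end-to-end on synthetic data with planted ground
truth, because the package is a re-usable analysis pipeline, not a data
deposit.

### The potential

For a conformation $\Gamma$ and native reference $\Gamma_0$:

$$
V(\Gamma-\Gamma_0)=\sum_{\mathrm{bonds}}\epsilon_r (r-r_0)^2
+\sum_{\mathrm{angles}}\epsilon_\theta (\theta-\theta_0)^2
+\sum_{\mathrm{planar}}\epsilon_\xi (\xi-\xi_0)^2
+\sum_{\mathrm{bb}}\epsilon_{\phi,bb}F_d(\phi)
+\sum_{\mathrm{sc}}\epsilon_{\phi,sc}F_d(\phi)
+\sum_{\mathrm{contacts}}\epsilon_C\left[\left(\tfrac{\sigma_{ij}}{r_{ij}}\right)^{12}-2\left(\tfrac{\sigma_{ij}}{r_{ij}}\right)^{6}\right]
+\sum_{\mathrm{noncontacts}}\epsilon_{NC}\left(\tfrac{\sigma_{NC}}{r_{ij}}\right)^{12}
$$

with $F_d(\phi)=[1-\cos(\phi-\phi_0)]+\tfrac12[1-\cos(3(\phi-\phi_0))]$.
Native values $r_0,\theta_0,\xi_0,\phi_0,\sigma_{ij}$ are measured on the
reference structure; every contact contributes exactly $-\epsilon_C$ at the
native geometry. Defaults: $\epsilon_r=100\,\mathrm{\AA^{-2}}$,
$\epsilon_\theta=20\,\mathrm{rad^{-2}}$, $\epsilon_\xi=10\,\mathrm{rad^{-2}}$,
$\epsilon_{NC}=0.01$, $\sigma_{NC}=2.5$ Å. Contact and dihedral weights are
resolved by `defaultWeights()` with the usual all-atom SBM convention: total
stabilizing energy equal to the atom count, contact/dihedral ratio 2,
backbone/sidechain dihedral ratio 2. These ratios are exposed because the
underlying convention is a modeling choice, not a law.

Native contacts come from a **shadow map**: pairs within 6.0 Å, at least 3
residues apart, not bonded/1-3/1-4, and with an unoccluded line of sight
(occluding atoms modeled as 1.0 Å spheres intersecting the segment). These
three numbers are conventional shadow-map settings and are arguments, not
constants. Pairs spanning different user-declared domains are excluded so
inter-domain arrangements are decided by the data rather than by the native
crystal packing, and proper dihedrals whose central bond lies in a declared
linker are released ($\epsilon_\phi = 0$) to let the linker explore.

### Dynamics

Langevin dynamics uses BAOAB splitting in reduced units (kB = 1, unit
masses; one reduced time unit maps to roughly 1 ps), time step 0.0005 rtu,
friction 1 rtu^-1, frames recorded every 1,000 steps. The paper-scale runs
this emulates use $2\times10^9$ steps; the package's tests run $10^5$-$10^6$
steps on toy systems, preserving cadence and thermostat while scaling length
down — so the tests validate integrator physics (equipartition, NVE
conservation with the thermostat off, thermal contact breaking), not
convergence of any particular protein's ensemble. Friction, masses and the
production temperature are not printed quantities; they are configuration
with documented defaults, and the temperature default (0.5) sits below the
toy systems' contact-melting range located by a short temperature scan.

### SAXS scoring

`debyeProfile()` evaluates
$I(q)=\sum_{ij} f_i(q) f_j(q)\,\mathrm{sinc}(q r_{ij})$ with per-element
$f(0)$ electron counts by default (a 4-Gaussian analytic form factor set is
available). There is no hydration-layer or excluded-volume fitting: that is
the main fidelity gap versus FoXS/CRYSOL-style calculators, accepted here
because it keeps the calculator verifiable against closed forms and a
brute-force double loop to $10^{-10}$ relative.

`chiSquare()` finds the scale $c$ minimizing
$\sum_k [(I_{\mathrm{exp}}(q_k)-cI_{\mathrm{th}}(q_k))/\sigma_k]^2$ in
closed form and divides the minimum by the number of points, so a fit
within noise sits near 1. Normalization by $n$ (not $n-1$) is deliberate
and switchable; an additive background term and a q-window restriction
(fit above 0.1 Å^-1^ first, extrapolate below) are optional flags.
`annotateChi2()` applies this per frame; for large frame-by-seed sweeps it
can bin the pair distances into a histogram (default exact; bin widths of
0.02-0.1 Å give relative profile errors of $10^{-6}$-$10^{-4}$, far below
counting noise).

### Ensemble selection

Frames are embedded in the plane from internal-distance dissimilarities
(Euclidean distance between vectors of intramolecular atom-pair distances,
normalized per pair; the pair subsample is seeded). The embedding is SMACOF
stress majorization initialized from classical scaling, which makes the
stress sequence provably non-increasing; normalized stress is reported.
Selection then follows the band + density rule: keep frames with
$\chi^2 \in [0.9, 1.1]$ (inclusive), estimate a Gaussian kernel density
(Scott's rule) over their projected points, take the connected region above
50% of the peak density, and return the k = 5 members nearest the peak
(ties by lower chi-square, then frame index). The 50% contour makes the
visual "densest cluster" rule explicit and configurable; all local density
maxima are reported so secondary clusters are visible rather than silently
discarded.

### Shape analysis

`guinierFit()` fits $\ln I$ vs $q^2$ on the largest low-q window with
$q_{max}R_g \le 1.3$ **and** no statistically significant curvature (a
quadratic term in $q^2$ with $|t|>4$ ends the window). The second condition
matters for exact non-Gaussian scatterers: a full 1.3-window on a perfect
sphere biases $R_g$ by about +1.8%, while the curvature stop keeps the fit
where the Guinier approximation actually holds (sphere error ~0.1%); for
noisy data the curvature test is insensitive and the window grows to the
1.3 cap as usual.

`prFromStructure()` histograms pairwise distances (form-factor weighted,
with the self-term correction that makes the second-moment $R_g$ agree with
the coordinate $R_g$ for unit weights). `prFromCurve()` is a regularized
indirect transform: linear-interpolation basis on $[0, D_{max}]$ with
$P(0)=P(D_{max})=0$, non-negativity by box-constrained L-BFGS-B, curvature
penalty weight chosen by a deterministic L-curve corner on a fixed log-spaced
scan, solved by continuation from large to small penalties (warm starts from
the ridge solution; without them the box-constrained solver can stall far
from the optimum). The refined Dmax is the end of the recovered support
(0.5% of peak), which deliberately errs long — regularization smears the
support outward and a conservative Dmax is the standard behavior of indirect
transforms.

### Spectroscopy fits

* **Relaxation**: $I(t)=I_0(1-2e^{-R_1t})$ and $I(t)=I_0e^{-R_2t}$, fitted
  by Levenberg-Marquardt with deterministic log-linear starts. Errors use
  the SNR convention $\sigma_I = I_0/\mathrm{SNR}$ with the known-sigma
  covariance $\sigma^2(J^TJ)^{-1}$ — the residual-variance scaling a default
  `nls` would apply is wrong when $\sigma$ is known, and with ~10 points it
  also miscalibrates. The calibration tests (empirical SD over reported SE
  within [0.7, 1.3] across 200 replicates) pin this down.
* **Amide-I deconvolution**: sums of area-normalized Voigt profiles (real
  Faddeeva function, Humlicek w4 rational approximation, validated against
  numerical Gauss-Lorentz convolution), centers bounded to the assignment
  windows (1,682 β-turn; 1,670 α-helix; 1,649 disordered; 1,637 and 1,622
  β-sheet, all ±8 cm^-1^). Amplitudes *are* areas because the profile is
  area-normalized, so secondary-structure fractions need no numerical
  integration; the two β-sheet bands are pooled. Initial amplitudes come
  from a linear least-squares solve at the initial centers/widths — with
  five strongly overlapped bands a naive equal-amplitude start converges to
  the wrong basin. Fourier self-deconvolution preprocessing is implemented
  (`fsdFilter()`) but off by default because no narrowing parameters are
  standard.
* **DLS cumulants**: $g_2(\tau)=B+\beta e^{-2\Gamma\tau}(1+\tfrac{\mu_2}{2}\tau^2)^2$
  weighted by the Poisson photon-count variance model; the fit is
  parameterized in $(B, \beta, \log\Gamma, \mu_2/\Gamma^2)$ so the
  polydispersity index is a parameter with a directly reported standard
  error. `hydrodynamicDiameter()` applies $\Gamma = Dq^2$ with
  $q = 4\pi n \sin(\theta/2)/\lambda$ and Stokes-Einstein, defaulting to a
  90-degree, 633 nm instrument at 293 K in water.

## Synthetic study conditions

The generators define the conditions every test runs under; they emulate
the data-generating processes of the corresponding experiments, not any
real protein.

* `makeTwoDomain()` builds a rigid-core-plus-flexible-domain monomer: two
  self-avoiding compact globules (CA walk, 2.93 Å steps, 4.5 Å clearance
  between non-consecutive residues) joined by an extended linker, decorated
  with 3 pseudo-atoms per residue (N, CA backbone; CB sidechain) so bonds,
  angles, planar/proper dihedrals of both classes all appear. Substituents
  are placed by a deterministic candidate search with coordinate-descent
  repair that keeps every bond angle in [0.6, 2.6] rad and the structure
  free of spurious distance-rule bonds: the harmonic angle gradient is
  singular at 0 and π, and early templates with near-linear native angles
  produced rare integration blow-ups. The 4.5 Å CA clearance (rather than a
  bare 2.5 Å excluded-volume threshold) exists for the same reason — with
  1.5 Å substituent arms, 2.5 Å between backbone traces leaves no
  clash-free direction to place them.
* `makeDimer()` applies a rigid 180-degree rotation and translates along
  the interface axis (bisection) until the minimum inter-chain distance
  equals the requested gap; chain A is the input monomer verbatim.
* `synthSAXS()` scales the Debye curve so the peak corresponds to a mean
  detector count (default $10^4$), draws Poisson counts per point, and
  reports $\sqrt{\mathrm{counts}}$ uncertainties — so chi-square against
  the generating model is calibrated near 1 by construction.
* `plantedEnsemble()` draws frames from labeled modes, each with a mean
  expansion factor about the centroid, a per-frame expansion spread
  (default 3%), and Gaussian jitter. The spread is essential: it gives the
  ensemble a continuum of compactness and therefore of chi-square, the
  situation the band + density rule is designed for (sampled ensembles in
  practice span a wide chi-square range, and a delta-distributed ensemble
  would make band membership an all-or-nothing accident of the noise draw).
  The selection studies score it against curves with 1,024 radial bins
  across q = 0.013-0.26 Å^-1^, a typical fine radial binning, under which
  the per-seed chi-square baseline concentrates to ±0.04 around 1.
* `synthRelaxation()`, `synthIR()`, `synthDLS()` are the exact forward
  models of the fitters above plus Gaussian (relaxation, IR) or
  count-model (DLS) noise, with the planted truth returned alongside.

What passing these tests shows: the estimators are consistent, their
uncertainties calibrated, and the selection logic recovers planted truth
under realistic noise. What they cannot show: fidelity to effects absent
from the generators — hydration-shell scattering, inter-particle structure
factor, baseline drifts, non-Voigt lineshapes, or real conformational
kinetics.

## Numerical choices and degenerate inputs

* Chain breaks (no linking bond within 2.0 Å between consecutive residues)
  and non-overlapping q ranges are errors, not warnings; extrapolating a
  theoretical curve outside its q support is refused.
* Duplicate frames project to coincident points; an empty chi-square band
  raises an error advising a wider band; `k` larger than the density
  cluster returns the whole cluster with a warning.
* All stochastic stages take explicit seeds and are bitwise reproducible;
  topology construction is deterministic (byte-identical JSON).
* Problem sizes in the test-suite: 20-50-residue toys, $10^5$-$4\times10^5$
  simulation steps, 100-seed recovery studies with 1,000-frame ensembles,
  200-replicate Monte-Carlo calibrations. These are the package's desk-scale
  standard conditions; the vignette-level claims above are exactly what the
  suite computes.

## Known limitations

* The Debye calculator omits solvent effects; absolute chi-square values
  against real, buffer-subtracted data will differ from hydration-aware
  calculators.
* The indirect P(r) transform reports a conservative (long) Dmax; treat it
  as an upper edge of support, as with any regularized transform.
* The command-line layer (`sbmsaxsCLI()`, `inst/scripts/sbmsaxs`) is a thin
  veneer over the exported functions for scripted pipelines; it does not
  attempt workflow management.
* Humlicek's w4 approximation is accurate to ~$10^{-4}$ relative; fitted
  Voigt parameters inherit that floor, far below the noise of any measured
  spectrum.
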