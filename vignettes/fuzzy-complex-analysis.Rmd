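---
title: "Mapping fuzzy protein complexes from NMR observables and ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping fuzzy protein complexes from NMR observables and ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzynmr)
```

When an intrinsically disordered protein (IDP) binds a folded partner but
large segments of it remain conformationally heterogeneous in the bound
state — a *fuzzy complex* — neither crystallography nor classical NOE-based
solution structure calculation is viable. What remains informative is a set
of per-residue NMR observables (chemical-shift perturbations, secondary
chemical shifts, amide temperature coefficients, ^15^N relaxation) combined
with statistics over conformational ensembles from molecular dynamics.
`fuzzynmr` implements that joint analysis as independent, composable stages
plus a synthetic-data module that generates every input type from known
ground truth, so each stage is validated by parameter recovery rather than
by eye.

The running example throughout the package is a 60-residue p53
transactivation domain (TAD1 + TAD2) binding the EF-hand homodimer S100A4:
a ~7 kDa disordered chain that associates with a ~24 kDa dimer into a
~31 kDa complex while keeping mobile termini, three transiently formed
helices, and three hydrophobic anchor residues (L26, M40, W53).

## Chemical-shift perturbation mapping

For each residue with amide shifts in both states the combined change is

$$\Delta\delta_{cum} = \sqrt{\Delta\delta_H^2 + (\alpha\,\Delta\delta_N)^2},$$

with $\alpha = 0.14$ by default, the common weight that compresses the
^15^N scale to the ^1^H one. Residues with $\Delta\delta_{cum} \ge 0.15$
ppm (the conventional limit below which residues count as non-perturbed)
are classified perturbed. A residue observed free but absent from the bound
spectrum within the matching gate is *broadened* — lost to
intermediate-exchange line broadening — and classified perturbed regardless,
because signal loss is itself binding information. `contiguous_regions()`
reports maximal runs of perturbed residues; a one-residue gap is bridged
only when that residue has no data at all (prolines, unassigned positions),
never when it was observed and found unperturbed. Both $\alpha$ and the
threshold are arguments, since the weighting convention varies between
groups.

Line widths are estimated by a Lorentzian fit rather than half-height
interpolation so the estimate does not depend on the sampling grid;
titration peak tracking uses nearest-neighbour matching in the scaled ppm
metric with a maximum-jump gate (default 0.05 scaled ppm) and refuses to
merge colliding trajectories — both are flagged ambiguous instead.
Titration fractions may exceed 1 (series are commonly run to ~115% molar
ratio); no normalisation is applied. For a labelled homodimeric partner,
`detect_peak_doubling()` counts resolved peaks around one-chain reference
positions: two matches mark binding-induced chain asymmetry, zero an
intermediate-exchange candidate.

## Secondary structure propensities

Secondary shifts are observed minus sequence-corrected random-coil
reference values. The propensity of residue $i$ sums the secondary shifts
of CA, CB and HA over a centred window (default 5 residues) with CB and HA
sign-inverted — helix formation moves CA downfield but CB and HA upfield —
and normalises by the corresponding full-structure magnitudes:

$$\mathrm{SSP}_i = \frac{\sum_{j,\,n} s_n\, \Delta\delta_{j,n}}
{\sum_{j,\,n} |\Delta\delta^{full}_{n}(ss)|},\qquad
s_{CA} = +1,\; s_{CB} = s_{HA} = -1,$$

where $ss$ is helix when the numerator is positive and strand otherwise.
This makes the statistic exactly testable: input built at a fraction $f$ of
the full-helix secondary shifts returns $\mathrm{SSP} = f$ identically,
ideal helix maps to $+1$, pure coil to $0$, fully extended to $-1$. The
sign inversion is applied to HA as well as CB because without it the
full-helix normalisation could not reach unity when HA is included. Both
the window and the full-shift reference table are arguments; the shipped
table uses per-nucleus consensus magnitudes (CA $+2.8$, CB $-0.38$, HA
$-0.39$ ppm for helix; $-1.5$, $+2.25$, $+0.37$ for strand) applied
uniformly across residue types. The random-coil table covers all 20
residue types for CA, CB (except glycine), HA and the amides, with a
neighbour-correction hook of which only the following-proline effect on
CA/HA is populated by default; users with residue-specific correction sets
can supply their own table.

## Amide temperature coefficients

The slope of the amide ^1^H shift against temperature (ppb/K, least
squares over at least three temperatures spanning at least 10 K)
distinguishes hydrogen-bonded amides (slope above $-4.5$ ppb/K) from
amides in fast exchange with solvent (below $-9$ ppb/K). The boundaries
are half-open: a slope of exactly $-4.5$ or $-9$ falls in the intermediate
class. Only the ^1^H dimension is fitted, as is standard practice.

## Relaxation and reduced spectral density mapping

$R_1$ and $R_2$ are fitted per residue as single-exponential decays
$I(t) = I_0 e^{-Rt}$ (Levenberg–Marquardt with a log-linear start) on the
experimental schedules: 10 delays between 0.01 and 2 s for $R_1$, 11
between 0.03 and 1.36 s for $R_2$, with one delay recorded twice as a
reproducibility check — a duplicate pair discrepant beyond 3 times the fit
residual noise flags the residue. Increasing intensity series are flagged
unfittable and excluded downstream rather than returning a negative rate.
The steady-state heteronuclear NOE is the saturated/unsaturated intensity
ratio; values above ~1.1 are physically implausible for ^15^N at high
field and only warn, values measured with a near-zero unsaturated
intensity are undefined.

The three rates invert into the spectral density at three frequencies
(reduced mapping, single high-frequency point at $0.87\omega_H$):

$$\sigma_{NH} = R_1(\mathrm{NOE}-1)\frac{\gamma_N}{\gamma_H},\quad
J(0.87\omega_H) = \frac{4\sigma_{NH}}{5d^2},$$
$$J(\omega_N) = \frac{R_1 - \tfrac{7d^2}{4}J(0.87\omega_H)}
{\tfrac{3d^2}{4} + c^2},\quad
J(0) = \frac{R_2 - (\tfrac{3d^2}{8}+\tfrac{c^2}{2})J(\omega_N)
- \tfrac{13d^2}{8}J(0.87\omega_H)}{\tfrac{d^2}{2}+\tfrac{2c^2}{3}}.$$

Constants: $r_{NH} = 1.02$ Å, $\Delta\sigma_N = -160$ ppm,
$\gamma_N/\gamma_H = -0.10136$ — standard ^15^N backbone values, all
exposed in `spectrometer_context()`. Because $\gamma_N < 0$, the
combination frequency $|\omega_H + \omega_N|$ lies *below* $\omega_H$;
getting this sign right is what makes the $0.87\omega_H$ reduction
accurate (the package's forward model and inversion agree within 0.6%
over $S^2 \in [0.2, 0.95]$, $\tau_c \in [2, 10]$ ns). No exchange term is
separated: $R_{ex}$ inflates the apparent $J(0)$ on purpose, which is how
elevated $J(0)$ is read as conformational-exchange evidence. Uncertainties
propagate by Monte-Carlo resampling (200 draws) from the fit standard
errors, which behaves better near $\mathrm{NOE} \approx 1$ than analytic
propagation.

`single_motion_curve()` draws the locus
$(J(0), J(\omega_N)) = (0.4\tau,\, 0.4\tau/(1+(\omega_N\tau)^2))$ of
single-correlation-time motion; `group_residues()` partitions residues
into four ordered groups of increasing $J(0)$ (mobile termini → rigid,
possibly exchange-affected sites) either at user-set boundaries or by
deterministic 1-D k-means with quantile initialisation — the grouping in
such studies is qualitative, so reproducibility matters more than the
particular cut points. Residues whose $J(0)$ exceeds the curve value
consistent with their $J(\omega_N)$ (slow-motion branch) by a factor of 2
or more are flagged exchange-suspect.

## Ensemble statistics

Ensembles are multi-MODEL PDB files with an invariant atom roster.
Superposition is least-squares (Kabsch, via SVD), by default onto the
iterated mean structure of the main-chain selection. Clustering is the
cutoff-based iterative neighbour-counting scheme (the snapshot with most
neighbours within the RMSD cutoff, default 1.0 Å, seeds a cluster; its
members are removed; repeat), with deterministic lowest-index tie breaking;
the max-neighbour member is the cluster mid-structure. B-factors are
$\frac{8\pi^2}{3}\langle|\mathbf{r}-\langle\mathbf{r}\rangle|^2\rangle$
after superposition, averaged over main-chain atoms per residue.

Helix assignment uses backbone dihedral windows ($\phi \in [-100,-30]$,
$\psi \in [-80,0]$ degrees, runs of ≥ 4) rather than hydrogen-bond
patterns, so it needs no hydrogen placement; the windows are arguments.
Terminal residues lack $\phi$ or $\psi$, so an ideal helix over residues
5–14 reports the segment 6–13. Hydrogen bonds use a donor–acceptor
distance cut (3.5 Å) plus a near-linearity gate (donor–H···acceptor within
30° of 180°); amide hydrogens absent from the roster are rebuilt 1.02 Å
from N along the backbone bisector and flagged inferred. Inter-chain
contacts are heavy-atom minimum-distance events (4.5 Å) counted across
snapshots; a pocket report lists partner residues contacting a query
residue in at least half the snapshots, the criterion used to call anchor
residues. NOE distance constraints are verified against
$\langle r^{-6}\rangle^{-1/6}$ ensemble averages — NOE intensities average
as $r^{-6}$, so transient close approaches dominate, and a pair
alternating between 3 and 8 Å correctly satisfies a 5 Å bound (effective
3.37 Å). Per-snapshot violation fractions are available as an option.

## What the synthetic data emulate — and what they do not

`ground_truth_model()` ships one preset, `p53tad_like`: 60 residues with
mobile termini (1–13, 56–60), bound-state helices 18–29 / 36–47 / 50–55,
order parameters 0.85 in helices vs 0.25–0.5 elsewhere under a global
$\tau_c = 8$ ns with $\tau_e = 50$ ps, exchange contributions of 3 s⁻¹ at
residues 23, 24, 32 and 51, endpoint shift perturbations covering regions
20–29 / 39–44 / 48–55 with the largest changes at the anchors 26/40/53,
intermediate-exchange broadening in the third binding region, and
temperature-coefficient classes that are hydrogen-bonded in the helices
and fast-exchanging in the disordered segments. Noise defaults are typical
of well-resolved HSQC data: 0.004 ppm (^1^H), 0.04–0.05 ppm (^15^N/^13^C),
1% intensity noise.

The generators are deliberately idealised: titration peaks move linearly
with bound fraction (fast exchange) and broadened peaks simply fade — no
lineshape or relaxation-dispersion physics; shift tables are coil plus
helical-fraction-weighted full secondary shifts — no residual dipolar or
ring-current effects; ensembles are ideal-geometry backbones (N–CA 1.46 Å,
CA–C 1.52 Å, C–N 1.33 Å) with CB side-chain proxies sampled independently
per snapshot — no excluded volume, no force field, and the "partner" is a
set of pseudo-atoms placed at contact distance from the anchor CBs to
emulate persistent pocket burial. Passing the recovery suite therefore
demonstrates that the *analysis* stages are correct and calibrated, not
that real spectra of comparable noise would behave as cleanly; in
particular peak overlap, heteroscedastic noise and assignment errors are
outside the generators' scope.

Two ensemble sampling modes exist because they test different things: the
default (tight helices, broad linkers) produces the B-factor and
helix-fraction contrast of a fuzzy complex, while `two_family` mode
samples *all* residues tightly around two distinct linker conformations —
cutoff clustering at 1.0 Å can only resolve families whose internal spread
is below the cutoff, which a genuinely disordered linker never is for a
60-residue chain.

## Numerical choices and degenerate inputs

Frequency referencing uses the DSS-referenced unified-scale ratios
(0.251449530 for ^13^C, 0.101329118 for ^15^N), matching internal-DSS
referencing; `spectrometer_context()` asserts the ^15^N/^1^H consistency
to 10⁻⁴ relative. Prolines are structurally absent from amide-based
tables, never NaN-filled. Exponential and Lorentzian fits report failure
(flags, errors) instead of silent NA; flat or monotone line profiles are
rejected before fitting. k-means grouping falls back to a single group
with a warning below four distinct $J(0)$ values. Numbering across
pipeline inputs is reconciled only through explicit per-input offset
declarations — residue-type clashes against the declared sequence are hard
errors listing the offending residues, never guessed around.

Problem sizes in the shipped tests and the acceptance script were chosen
to make every recovery check sharp at desk scale: 100-repeat fit
calibrations, 200 random ensembles of up to 50 snapshots against the
exhaustive clustering oracle, 2000-snapshot B-factor ensembles, and
12–30-snapshot structural ensembles of the 60-residue preset.

## Known limitations

No Kd estimation from titrations, no Lipari–Szabo $S^2/\tau_e$ fitting
(the analysis stops at spectral densities by design), no anisotropic
diffusion, no DSSP-style H-bond secondary structure, no trajectory formats
beyond multi-MODEL PDB, and the NMR-STAR reader handles only the
assigned-chemical-shift loop. The mobility grouping reproduces the
*method* of four-group clustering; reproducing a specific study's exact
memberships would require that study's per-residue data.
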