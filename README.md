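# fuzzynmr

Per-residue NMR and ensemble analysis of *fuzzy* protein complexes — bound
states in which an intrinsically disordered protein (IDP) partner remains
too conformationally heterogeneous for crystallography or classical
NOE-based structure calculation. The package is written for NMR
spectroscopists and computational structural biologists who need to turn
chemical-shift tables, titration peak lists, relaxation decay series and
multi-model conformational ensembles into per-residue binding and dynamics
maps, as in the characterisation of the p53 transactivation domain
(p53TAD^1–60^) bound to the metastasis-associated S100A4 dimer.

## What it computes

- **Chemical-shift perturbation (CSP) mapping** — cumulative amide shift
  changes Δδ_cum = √(Δδ_H² + (α·Δδ_N)²) with α = 0.14, classification at
  the 0.15 ppm limit, detection of residues broadened below the detection
  limit, contiguous binding regions, Lorentzian line widths, titration peak
  tracking, and peak-doubling (chain-asymmetry) analysis for a labelled
  homodimeric partner.
- **Secondary structure propensities (SSP)** — secondary shifts from
  sequence-corrected random-coil references; windowed CA/CB/HA propensity
  score normalised so full helix = +1, coil = 0, extended = −1.
- **Amide temperature coefficients** — ppb/K slopes with the −4.5 / −9
  ppb/K hydrogen-bond / fast-exchange classification.
- **¹⁵N relaxation** — single-exponential R1/R2 fits on the standard delay
  schedules (10 delays 0.01–2 s; 11 delays 0.03–1.36 s, one duplicated),
  heteronuclear NOE, reduced spectral density mapping to J(0), J(ωN),
  J(0.87ωH), the single-motion curve, and four-group mobility clustering
  with exchange-suspect flagging.
- **Ensemble statistics** — Kabsch superposition, cutoff-based (1.0 Å)
  iterative neighbour-count clustering with mid-structures, B-factors
  (8π²/3)·⟨|r−⟨r⟩|²⟩, φ/ψ helix assignment, hydrogen bonds, inter-chain
  contact frequencies and anchor pockets, and r⁻⁶-averaged NOE
  distance-constraint checks (5 Å bound).
- **Synthetic ground truth** — generators for every input type
  (`ground_truth_model("p53tad_like")`), so each stage is validated by
  parameter recovery.
- **Pipeline** — `run_pipeline()` joins all stages into one per-residue
  summary table from a single YAML/list config.

## Worked example

Simulate a study-like titration (free vs bound shift tables), map the
binding regions, then run relaxation analysis:

```r
library(fuzzynmr)

m  <- ground_truth_model()                       # 60-residue IDP preset
st <- simulate_shift_tables(m, seed = 42)        # free + bound states

prof <- classify_perturbed(cumulative_delta(st$free, st$bound),
                           threshold = 0.15)
contiguous_regions(prof, min_len = 3)
#>   start end length
#> 1    20  29     10
#> 2    39  44      6
#> 3    48  55      8
```

The three runs are the binding regions: the broadened third region (48–55)
is reported although its Δδ_cum is undefined, because signal loss marks
binding. Individual perturbed residues sit just above the 0.15 ppm limit:

```r
head(prof[prof$perturbed & !prof$broadened,
          c("residue_index", "residue_type", "delta_cum")], 4)
#>    residue_index residue_type delta_cum
#> 16            20            S 0.1732391
#> 17            21            D 0.1732071
#> 18            22            L 0.1688391
#> 19            23            W 0.1640290
```

Relaxation rates fitted from the simulated decay series invert into
spectral densities; residues cluster into mobility groups I (mobile
termini) to IV (most rigid / exchange-affected):

```r
sim <- simulate_relaxation(m, seed = 42)
rec <- relaxation_record(fit_exponential_decay(sim$t1),
                         fit_exponential_decay(sim$t2),
                         het_noe(sim$noe_sat, sim$noe_unsat,
                                 noise = sim$noise))
jm  <- group_residues(reduced_spectral_density(rec))
subset(as.data.frame(jm), residue_index %in% c(2, 23, 40),
       select = c(residue_index, J0, JwN, group))
#>    residue_index           J0          JwN group
#> 2              2 8.447622e-10 7.511025e-11     I
#> 19            23 3.694087e-09 2.077189e-10    IV
#> 33            40 2.893579e-09 2.073841e-10   III
```

J(0) is in s/rad: residue 2 (mobile N-terminus) shows a small J(0) near
the single-motion curve; the helical anchor region is an order of
magnitude slower; residue 23 carries an exchange contribution on top and
lands in group IV. Ensemble statistics work the same way from a
multi-MODEL PDB via `read_ensemble_pdb()`, or from
`simulate_ensemble(m, ...)`.

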