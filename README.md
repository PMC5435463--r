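# t4connectome

Quantitative connectome analysis of the synaptic inputs to *Drosophila*
T4 cells — the medulla neurons that compute the direction of ON-edge
motion — and of whether that wiring qualifies as a Hassenstein–Reichardt
(HR) or Barlow–Levick (BL) elementary motion detector.

Dense EM reconstruction of a seven-column medulla volume (Home plus
neighbours A–F) shows eight cell types supplying essentially all T4 input:
Mi1 and Tm3 (strongest, putatively excitatory, along the dendrite shaft),
GABAergic Mi4/C3/CT1 at the dendrite base, glutamatergic Mi9 at the tips,
TmY15, and other T4s — the latter strictly subtype-selective and displaced
opposite the preferred direction (PD). This package implements the
analyses that quantify that picture, for connectomicists and modellers who
want to rerun them on their own neuron/synapse/skeleton tables or on
synthetic data:

- **Connectivity**: PSD-level counts, input fractions, per-column input
  maps on the hexagonal column lattice, strength binning (<10 / 10–20 /
  >20 synapses), connectivity matrices, reconstruction-comparison
  arithmetic.
- **Anatomical subfields**: synapse-count-weighted field centres on an
  ideal hexagonal array (in ommatidial units, 1.0 = adjacent-column
  spacing), offsets referenced to Mi1, L1-based centres for multicolumnar
  Tm3, and raw vs completeness-adjusted Tm3–Mi1 displacements
  (each partial Tm3 reweighted by PSD count / completeness).
- **Dendritic maps**: synapse-to-skeleton attachment, path distance from
  the trunk, base/shaft/tip regions, permutation tests of segregation
  between input types, subtype classification from arbor orientation, and
  a T4–T4 selectivity audit.
- **Motion detectors**: minimal HR (opponent correlator) and BL (delayed
  inhibitory veto) simulators, configured directly from measured subfield
  centres and synaptic signs, scored with the direction selectivity index
  DSI = (PD − ND)/(PD + ND).
- **Synthetic connectomes**: a seeded generator with polyadic T-bars,
  planted field offsets, tip/shaft/base spatial profiles, volume
  truncation and a known-ground-truth completeness ladder, so every
  estimator is testable without EM data.

Inputs are plain formats: TSV neuron and synapse tables, SWC skeletons,
YAML run configs. See the vignette in `vignettes/` for the methods in
detail.

## Worked example

```r
library(t4connectome)

ds <- make_circuit(seed = 1)         # 7-column synthetic connectome
ds
#> <connectome> 112 neurons (14 types), 2889 postsynaptic sites, 434 T-bars,
#>   7 columns, 4 skeletons [synthetic, with ground truth]

round(input_fractions(ds, "T4a:0,0"), 3)
#>     Mi1     Tm3     Mi9     CT1 unknown   TmY15     Mi4      T4      C3    Mi10
#>   0.378   0.175   0.130   0.078   0.052   0.050   0.048   0.040   0.035   0.015

subfield_centre(ds, "T4a:0,0", "Mi9", min_synapses = 2)
#> <subfield> T4a:0,0 <- Mi9: centre (0.630, -0.017) om. units, n = 50 over 4 columns

offset_from_mi1(ds, "T4a:0,0", "Mi4", min_synapses = 2)
#> <offset> T4a:0,0: Mi4 - Mi1 = (-0.544, +0.188) om. units [raw]

segregation(ds, "T4a:0,0", "Mi4", "Mi9", seed = 2)
#> <segregation> Mi4 vs Mi9: index +0.522 (means 0.267 / 0.789; n = 19 / 52), p = 0.000999

t4_selectivity_report(ds)
#> <selectivity> 4 T4-T4 connections, 0 cross-subtype violation(s); 4/4 offsets opposite the PD

cfg <- anatomy_detector(ds, "T4a:0,0")   # BL detector from the measured anatomy
direction_tuning(cfg)
#>   speed  r_pd     r_nd   dsi
#> 1   0.5 0.127 3.25e-05 0.999
#> 2   1.0 0.125 1.31e-03 0.979
#> 3   2.0 0.122 9.91e-03 0.850
#> 4   5.0 0.117 3.84e-02 0.506
```

Reading the output: Mi1 and Tm3 dominate the input budget; the Mi9
subfield sits ~0.6 ommatidia towards the dendrite tips while Mi4 is
displaced the opposite way from the Mi1 centre; Mi4 synapses sit near the
dendrite base (mean normalized position 0.27) and Mi9 near the tips
(0.79), a segregation index of 0.52 with permutation p ≈ 0.001; every
T4–T4 contact joins same-subtype cells displaced opposite the PD; and the
BL detector built from those centres responds far more strongly to
preferred- than null-direction edges (DSI 0.51–1.0) across a decade of
speeds.

The full pipeline — generate, validate, connectivity, subfields,
dendrites, selectivity, detectors, summary report with provenance-stamped
outputs — is

```r
run_pipeline(run_config(seed = 1, out_dir = "t4_run"))
```

or, from a shell, `inst/exec/t4pipeline report --seed 1 --out t4_run`.

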