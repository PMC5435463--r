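---
title: "Methods: quantifying the synaptic input circuits of T4 motion-detector cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the synaptic input circuits of T4 motion-detector cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t4connectome)
```

## The scientific problem

Direction-selective T4 cells of the *Drosophila* medulla compute the local
direction of ON-edge motion on their dendrites in stratum M10. Dense EM
reconstruction of a seven-column medulla volume (a central "Home" column and
its six neighbours A--F) shows that eight cell types provide essentially all
synaptic input to T4: Mi1 and Tm3 (the strongest, putatively cholinergic and
excitatory, spread along the dendrite shaft), Mi4, C3 and CT1 (GABAergic,
clustered at the dendrite base), Mi9 (glutamatergic, sign uncertain, at the
dendrite tips), TmY15, and other T4s (at the tips, from the neighbouring
column displaced opposite the cell's preferred direction, and strictly
subtype-selective).

This package turns the quantitative analyses behind that picture into a
tested, reusable pipeline:

1. **Connectivity accounting** -- PSD-level connection counts, input
   fractions, per-column input maps, connection-strength binning, and the
   arithmetic for comparing reconstructions.
2. **Anatomical subfields** -- synapse-count-weighted field centres on an
   ideal hexagonal array, offsets referenced to Mi1, and the raw versus
   completeness-adjusted Tm3--Mi1 displacement.
3. **Dendritic synapse maps** -- attachment of synapses to skeletons, path
   distance from the trunk, base/shaft/tip localization, and permutation
   tests of segregation between input types.
4. **Subtype selectivity** -- an audit of every T4--T4 contact.
5. **Motion-detector candidacy** -- minimal Hassenstein--Reichardt (HR) and
   Barlow--Levick (BL) simulations parameterized directly by the measured
   anatomy and synaptic signs.
6. **A synthetic connectome generator** that stands in for the EM volume, so
   every stage is testable with known ground truth.

## Counting conventions

Fly synapses are polyadic: one presynaptic T-bar contacts several
postsynaptic densities (PSDs). One **synaptic input = one PSD = one row** of
the synapse table; T-bar-level counts are a derived quantity
(`tbar_id` recurs across rows). All coordinates are micrometres; lattice
positions are integer axial coordinates `(q, r)` converted to Cartesian
**ommatidial units** where 1.0 is the centre-to-centre spacing of adjacent
columns (`axial_to_cart()`, basis vectors at 60 degrees, `(1,0)` mapped to
+x by convention -- the eye's true orientation relative to body axes is a
labelling choice, not a result).

Cells of unicolumnar types (Mi1, Mi4, Mi9, C3, L1) carry a home column.
CT1, a single wide-field cell, is represented as one parent neuron plus one
column-assignable terminal unit per column, because each columnar arbour
acts as a local unit. Tm3 and TmY15 are multicolumnar and have no home
column; asking for their per-column counts is an error by design.

## Anatomical subfield centres

For a column-assignable input type, the subfield centre of a T4 is the
centre of mass of the presynaptic cells' home columns on an ideal hexagonal
array, weighted by per-cell PSD counts (`subfield_centre()`), and offsets
are reported relative to the Mi1 centre of the same T4
(`offset_from_mi1()`). Connections with a single synapse are excluded by
default (`min_synapses = 2`) before weighting, matching the convention used
for per-column input maps.

Because Tm3 has no home column, its retinotopic position is estimated
indirectly: each Mi1 and Tm3 is assigned the weighted centroid of the home
columns of its **L1 inputs** (`l1_field_centre()`), and the Tm3--Mi1 offset
of a T4 is the difference between the PSD-count-weighted means of those
per-cell centres (`tm3_mi1_offset()`).

### Completeness adjustment

Most Tm3 cells leave the imaged volume; a cell reconstructed with
completeness $c \in (0, 1]$ has only a fraction $c$ of its synapses
annotated, so its PSD count under-weights it. In `"adjusted"` mode each
Tm3's weight is $n_{\mathrm{PSD}} / c$. If a partial cell's synapses are
missed uniformly at random, this inverse-completeness reweighting makes the
population centre unbiased, while the raw estimate is pulled towards the
well-reconstructed (central) cells. The exact correction used in the
original analysis is not fully specified, so this simple, testable choice
is made here and recorded in the output metadata. Completeness for
synthetic cells comes from generator ground truth; for real data it is a
user-supplied column in the neuron table.

## Dendritic synapse maps

Synapses are attached to the nearest skeleton node (Euclidean), within a
**snap radius** of 2 um (unmatched synapses are flagged, never dropped).
Position along the dendrite is the **path distance** from the root -- the
axon's main trunk, where synthetic skeletons are rooted by construction and
where real SWC inputs must be pre-rooted -- normalized by the arbor's
maximum path distance. The base/shaft/tip vocabulary is qualitative in the
underlying data, so regions are configurable tertiles of `[0, 1]`
(half-open, so they tile the interval exactly). A path-distance criterion
was chosen over Euclidean proximity to the trunk; the two differ on curved
branches, and the choice is flagged here.

Segregation between two input types is tested with the difference of mean
normalized positions (index in `[-1, 1]`, positive when the second type is
more distal) against a seeded label-permutation null (default 1,000
permutations, two-sided, with the add-one correction
$p = (1 + \#\{|\Delta^\ast| \ge |\Delta|\}) / (n_{\mathrm{perm}} + 1)$).
The test suite verifies the null is calibrated (type-I error at nominal
0.05 stays below 0.07 across 500 null draws).

## T4 subtypes, arbor orientation and preferred direction

Subtype classification uses the angle of the mean displacement vector from
the trunk to the arbor nodes, assigned to 90-degree sectors by the lattice
convention a = +x, b = -x, c = +y, d = -y; ties on a 45-degree boundary
resolve to the earlier letter. The **preferred direction of each subtype is
the axis opposite its arbor growth**: PD runs from the excitatory shaft
inputs towards the inhibitory base inputs (i.e. from dendrite tips towards
the trunk), which is both the BL prediction and the direction convention
used for the selectivity audit. Consequently presynaptic same-subtype T4s,
which sit one column towards the tips, lie opposite the postsynaptic cell's
PD, and the audit checks `dot(offset, PD) <= 0` for every T4--T4 contact.

## Motion-detector simulations

Both models take two channels with offset fields of view, one carrying a
first-order low-pass delay with time constant $\tau$ (zero-order-hold
discretization, DC gain 1):

* **HR**: $\langle \mathrm{LP}(s_1)\, s_2 - s_1\, \mathrm{LP}(s_2)\rangle$ --
  fully opponent, exactly antisymmetric under channel swap.
* **BL**: $\langle \max(0,\; s_2 - g\,\mathrm{LP}(s_1)) \rangle$ -- delayed
  inhibition (gain $g$, default 1) vetoes excitation in the null direction.

`circuit_from_anatomy()` places the non-delayed excitatory channel at the
measured Mi1/Tm3 (shaft) centre and the delayed inhibitory channel at the
synapse-weighted Mi4/C3/CT1 (base) centre; the predicted PD is the
excitatory-to-inhibitory direction. $\tau$ defaults to 150 ms and is
config-exposed: the measured Mi1/Tm3 latency difference (~15 ms) is too
small to pin down the physiological delay, so $\tau$ is a free parameter,
not a fit. Stimuli are ON step edges (crossing the origin at half the
duration) or drifting sinusoids; responses are time-averaged after
discarding one filter time constant of transient, and selectivity is
summarized by $\mathrm{DSI} = (r_{PD} - r_{ND}) / (r_{PD} + r_{ND})$.
Detector evaluations use edge speeds of 0.5--5 ommatidia/s, a decade
bracketing the speed that yields the ~1 Hz temporal-frequency optimum at
the default 4-unit grating period. Mi9's synaptic sign is tentative in the
data; the template carries `NA` for it, both signs are runnable through the
configuration, and the BL construction uses only the Mi4/C3/CT1 channel.

## What the synthetic generator emulates

`make_circuit()` builds, on a hex disc lattice (`make_lattice(1)` gives the
seven-column geometry), one Mi1/Mi4/Mi9/C3/L1 cell and one CT1 terminal per
column, four T4 subtypes per column, three TmY15s, and a dedicated
eight-cell Tm3 population per analysed Home-column T4 (matching the eight
Tm3 inputs reported for the fully reconstructed front-to-back cell). The
four Home T4s receive full input sets; default parameters:

* **400 inputs per T4** (the reconstruction reports >200 per cell and
  several hundred for the fully contained cells), split by the per-type
  fractions Mi1 0.35, Tm3 0.16, Mi9 0.13, Mi4 0.06, C3 0.04, TmY15 0.08,
  CT1 0.07, T4 0.06, Mi10 0.006, unknown 0.044 -- generator defaults
  mirroring the reported input-fraction ranking, never assertions about
  data.
* **Spatial profiles** over normalized dendritic position: Beta(5, 1.5) for
  the tip types (Mi9, T4), Beta(1.5, 5) for the base types (Mi4, C3, CT1),
  Beta(2, 2) for the shaft/diffuse types (Mi1, Tm3, TmY15). The source data
  give the qualitative pattern only; the Beta family is the simplest
  `[0, 1]`-supported shape matching it, and all parameters are
  config-exposed.
* **Planted field offsets** along each subtype's arbor axis: Mi1 +0.25,
  Mi9 +1.0, Mi4/C3/CT1 -0.5 ommatidia, realized as Gaussian column-weight
  kernels (sd 0.75) on the lattice. The magnitudes emulate the measured
  subfield displacement regime, in which tip- and base-located types are
  displaced from Mi1 by up to and beyond one inter-ommatidial distance.
  Ground truth records the **exact discrete centroid** of each realized
  weight map, so estimator error is scored against what was actually
  planted on the finite lattice, not the nominal kernel centre.
* **Polyadic grouping**: 1 + Poisson(5) PSDs per T-bar, chosen to match the
  global PSD:T-bar ratio of roughly 315,500:53,500 in the annotated volume.
* **L1 scaffolding**: each Mi1 draws 40 L1 inputs (85% from its home
  column), each Tm3 30 L1 inputs from a Gaussian kernel (sd 0.7) around its
  true field centre -- the substrate for the L1-based centre estimates.
* **Determinism**: one global seed; per-cell streams are derived by a
  stable FNV-1a hash of `(seed, cell id)`, so datasets are bit-identical
  across runs and cells are independent of generation order.

Two truncation models emulate the finite imaged volume.
`truncate_connectome()` removes synapses and skeleton subtrees outside a
box and records each cell's retained-PSD fraction as its completeness --
the geometric picture. `thin_cell_synapses()` /
`emulate_partial_tm3()` implement the **uniform-truncation model**: each
targeted cell's rows are dropped independently with its target
completeness; the default ladder (100, 100, 94, 85, 72, 61, 49, 42%)
reproduces the completeness regime reported for the eight Tm3s of the
fully reconstructed front-to-back T4, assigned so that cells reaching
furthest past the dendrite tips are least complete. The inverse-completeness
correction is exactly matched to the uniform model -- the accompanying
tests verify that the adjusted estimator beats the raw one there -- whereas
under purely geometric box truncation the Tm3-to-T4 weights are barely
affected (those PSDs sit on central dendrites) and the correction has
little to work with.

**What the generator does not emulate**: EM imaging noise, segmentation or
proofreading errors, reciprocal-contact statistics, lens optics or
spherical eye geometry, dendrite-position/column-identity correlations
within a type, and any physiological dynamics beyond the two-channel
detector abstractions. Passing tests therefore certify the estimators and
their calibration under the stated statistical model -- not the biological
conclusions drawn from the real volume.

## Numerical and degenerate-input choices

* All-zero centroid weights, empty input sets, unknown ids, multicolumnar
  per-column requests, missing completeness in adjusted mode, and zero DSI
  denominators raise explicit errors; validation of a dataset
  (`validate_connectome()`) reports findings instead of raising.
* Boundary synapse counts 10 and 20 fall in the "medium" strength bin, as
  the printed ranges "<10" and ">20" force.
* `percent_increase()` rounds to integer percent, the precision at which
  reconstruction comparisons are quoted.
* Region boundaries are half-open so base/shaft/tip tile `[0, 1]` exactly;
  a normalized position of 1 is a tip.
* Subtype sector ties and the zero-offset detector are resolved
  deterministically (earlier letter; warned, direction-unselective config).

## Problem sizes used by the checks

The packaged checks run at deliberately desk-sized scales: centroid-oracle
equivalence on 100 random instances; planted-offset recovery at 500
synapses over 50 seeds per offset; the completeness ladder over 100
replicates; segregation power at 50 + 50 synapses over 100 seeds with a
500-draw null calibration; and detector tuning over four speeds per
subtype. The headline fractions and totals of the full EM dataset
(~53,500 T-bars, ~315,500 PSDs) are inputs to the generator's defaults,
not quantities these scales can reproduce.

## Known limitations

* The completeness correction reweights counts only; it cannot undo a
  *spatial* bias in a partial cell's own measured L1 centre.
* With one fully reconstructed T4 per direction in the source volume, no
  cross-cell statistics of subfield offsets are defined; the package
  reports per-cell offsets and leaves population claims alone.
* The BL/HR simulators are two-channel abstractions for candidacy checks,
  not biophysical models; they make no quantitative claim about the ~1 Hz
  temporal-frequency optimum.
* Real SWC inputs must be rooted at the trunk; the package does not infer
  trunk location from morphology.

## A short worked example

```{r example, eval = FALSE}
ds <- make_circuit(seed = 1)
input_fractions(ds, "T4a:0,0")
subfield_centre(ds, "T4a:0,0", "Mi9")
tm3_mi1_offset(ds, "T4a:0,0", mode = "raw")
segregation(ds, "T4a:0,0", "Mi4", "Mi9", seed = 2)
t4_selectivity_report(ds)
cfg <- anatomy_detector(ds, "T4a:0,0")
direction_tuning(cfg)
```

The full pipeline is `run_pipeline(run_config(seed = 1))`, or the
`t4pipeline` script under `inst/exec/` from a shell.
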