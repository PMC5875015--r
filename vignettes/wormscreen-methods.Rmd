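---
title: "wormscreen: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{wormscreen: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormscreen)
```

# The problem

Essential genes in *C. elegans* are commonly maintained as lethal or sterile
deletions balanced over a rearranged chromosome that carries a pharyngeal-GFP
marker. Homozygous mutants lack the marker; heterozygous carriers show a
bright green pharynx ("green head"). Screening such strains at scale requires
three automated capabilities, which this package implements and exercises on
synthetic data:

1. **Sorting** homozygotes out of a mixed population on a large-particle flow
   cytometer using the axial fluorescence profile of each animal;
2. **Whole-well image analysis** that segments worms from 2x-objective
   brightfield images, identifies residual green-headed heterozygotes, and
   measures reporter fluorescence with local background subtraction;
3. **Screen statistics** that turn per-worm measurements into per-clone hit
   calls, plus a luciferase-based molt-timing readout for developmental
   phenotypes.

# The sorter model

Each object passing the flow cell yields two aligned series of point
measurements along the body axis: extinction (optical density) and green
fluorescence. Four features summarize a profile: peak height (PH, the maximum
value) and peak width (PW) per channel, where PW *integrates the widths of
all regions exceeding the floor* — it is the total count of super-threshold
samples over all runs, not the width of the tallest peak. A first rectangular
gate on (ExtPH, ExtPW) removes debris; the green rule then accepts an object
iff

$$ 700 \le \mathrm{greenPH} \le 10{,}000
   \quad\wedge\quad \mathrm{greenPW} > 120 \text{ samples.} $$

The body-wide stress-reporter signal of homozygotes is moderate and long;
the pharyngeal signal of heterozygotes is brighter than 10,000 a.u. but far
narrower than 120 samples, so either bound rejects it. Design choices the
instrument description leaves open, fixed here: gate boundaries are closed
(a point on the edge is inside); PW is counted in samples, with the sample
spacing (default 3 µm) carried on the profile for µm conversion; the
two-lobed-pharynx peak count is computed as a diagnostic but is not part of
the accept rule; rejection reasons report the first violated criterion in
the order `ph_below`, `ph_above`, `pw_below`.

# The segmentation protocol

For each well: (i) the well interior is masked using the bright green
autofluorescence of the well edge — the largest thresholded component is
taken as the ring, and its filled interior (minus the ring) is the usable
area, falling back to the full frame with a warning if no ring is found;
(ii) the brightfield image is contrast-normalized by dividing by a heavily
blurred copy of itself, dark objects are thresholded inside the well mask,
and specks are removed; (iii) morphological acceptance criteria remove long
fibres, air bubbles and overlapping worms (area 500–6,000 px², skeleton
length 300–1,400 µm, form factor $4\pi A/P^2 \le 0.5$, border-touching
objects dropped); (iv) compact green objects at ≥ 4× the median worm-pixel
intensity and 20–600 px² are segmented as green heads and linked to the worm
they overlap by at least one pixel (per-worm Green Head ID = number of
linked heads; ID > 0 flags a heterozygote); (v) each worm is dilated to
define its immediate-background ring; (vi) worm, dilated-worm and
worm-minus-green-head targets are linked into one record per worm.

Worm length is the geodesic length of a Zhang–Suen morphological skeleton
(orthogonal steps count 1 px, unbridged diagonal steps $\sqrt2$), converted
to µm through the pixel size; the moment-based major-axis length is reported
separately. The numeric acceptance bounds are calibrated once on the
package's phantoms — the original screen's exact values are not published in
the main text — and all of them are exposed in `seg_config()`.

Two background-measurement choices matter. First, the ring statistic is the
*mean* of ring pixels (a median variant is a config flag away via the
records themselves). Second, the ring starts `dilation_gap` (default 2) px
beyond the worm boundary: brightfield segmentation is conservative at the
body edge, and without the guard gap the first ring pixels lie on the bright
body rim and inflate the background, which showed up on phantoms as a ~10%
negative bias in background-subtracted intensity. Worms whose ring is empty
(tight packing) inherit the plate-median ring intensity and carry a flag
rather than being dropped. Intensities are means over pixels so that records
compare across worm sizes; summed totals are also reported.

# The statistics pipeline

The order is fixed: worm filters → well filter → plate QC → normalization →
testing → hit calling, with an audit trail at each stage.

* Reporter readout filters: drop `green_head_id > 0`, then length < 550 µm,
  then per-well values strictly outside the well's 5th/95th percentiles
  (type-7 interpolated quantiles; applied per well — the alternative
  per-plate reading is noted as an open choice, switchable by pre-grouping).
  The size readout filters only on green head, keeping all sizes.
* Wells with fewer than five surviving worms are dropped (a five-worm well
  is kept: "fewer than five" is read strictly).
* Negative-control wells pass QC iff mean GFP ∈ [200, 500] a.u. (inclusive)
  and CV < 0.5 (strict); a plate needs ≥ 2 passing control wells. When only
  2–3 of the 4 controls pass, normalization uses the passing wells only —
  QC wins over the nominal "four wells".
* Normalization divides every worm's value by the grand mean over worms in
  the accepted negative-control wells, so the pooled control normalized mean
  is exactly 1.
* Testing: per plate, one-way ANOVA across wells with worms as replicates
  (the unit of replication is the individual worm, matching how the data
  are normalized and plotted), followed by Dunnett many-to-one comparisons
  of each well against the pooled control, two-sided single-step adjusted
  p-values from the multivariate-t distribution. The quasi-random
  integration is seeded so runs are reproducible; the test suite
  cross-checks the adjusted p against an independent 10⁶-draw Monte-Carlo
  max-|t| oracle to within 0.005. Wells left with fewer than two worms are
  excluded from testing and audited.
* Hit calling, strict inequalities throughout: reporter `down` iff
  p < 0.001 ∧ FC < 0.66, `up` iff p < 0.001 ∧ FC > 1.5; size `down` iff
  FC < 0.85 with *no* p condition (that is the published rule; an optional
  p condition exists but is off by default). Boundary values (FC exactly
  0.66, exactly five worms, mean exactly 200) follow the documented
  strict/inclusive readings above.

Library arithmetic: clones fill 96-well plates column-major over 88 usable
wells (the last column is reserved for controls), so 6,315 clones need 72
plates and 1,207 need 14; sequencing reliability is reported as the exact
fraction and the rounded percentage (131/144 → 91%).

# The molt-timing readout

Luciferase traces (5-min sampling) are trend-corrected by dividing by a
12-h centered running mean, then each sample is *feeding* iff its corrected
value is ≥ 75% of a centered moving average, else *molt*. The moving-average
window must exceed the longest molt: with a window equal to the molt
duration, the window at a molt's centre lies wholly inside the molt, the
ratio saturates at 1 and the centre is misclassified as feeding, splitting
the molt in two. The default is therefore 4 h against molts of ~2–2.5 h.
Molt runs shorter than a 30-min debounce are ignored; the first four
surviving runs become M1–M4, and larval stages are the gaps (L1 from trace
start). Because the threshold is a ratio, the schedule is invariant to
rescaling the whole trace; durations conserve the span from trace start to
the M4 offset to within one sample.

# The phantom generators and what they do (not) show

Every stage is tested against seeded generators that emit ground truth
alongside the data. The defaults are the package's study conditions, chosen
once:

* **Flow profiles**: 3 µm/sample so an L2 body (400–480 µm) spans ~130–160
  samples; homozygote green plateaus 2,000–4,000 a.u.; heterozygote
  pharyngeal lobes 15,000–30,000 a.u., two lobes ~12 samples apart; debris
  20–80 µm. Noise is multiplicative lognormal per sample.
* **Well images**: 512×512 px at 6.5 µm/px (a plausible 2x-objective scale;
  the true instrument scale is not published, so all µm thresholds convert
  through this configurable value); well ring at 92–99% of the half-width;
  young-adult worms 850–1,050 µm long with ~32 µm half-width, rendered as
  smooth random-walk tubes, dark with a faint halo in brightfield and
  painted with a hard constant-intensity mask in green so truth read-back
  is exact at zero noise; control body GFP ~300 a.u. over background 100,
  placing control wells inside the 200–500 a.u. QC window (the window is
  instrument-specific, so the generator is calibrated to it); heterozygote
  bodies at 40 a.u. with 3,000 a.u. pharynx lobes.
* **Screen tables**: per-worm GFP lognormal around control mean × clone fold
  change (CV 0.3, 30 worms/well by default), heterozygote contaminants with
  larval lengths, small larvae at a configurable rate.
* **Luciferase traces**: wild-type-like stage durations L1–L4 =
  12, 8, 8, 10 h and molts 2, 2, 2, 2.5 h at 20 °C, molt level 50% of the
  feeding plateau, optional exponential decay and noise.

The phantoms deliberately omit optics (PSF, vignetting), 3-D body shape,
worm-untangling cases, plate-edge effects and temporal drift. Passing tests
therefore demonstrate the correctness of the *algorithms* — gating logic,
mask algebra, background subtraction, filter order, test calibration — not
the performance of the segmentation on real micrographs, which depends on
contrast and artifact statistics the phantoms only sketch.

# Problem sizes used in the test suite

The suite exercises: 1,000-profile sorting runs; 20 phantom wells of 6 worms
for segmentation recall/precision/genotype accuracy; a 10⁶-draw Monte-Carlo
Dunnett oracle on one fixed 3-group fixture; 1,000 simulated null plates
(6 sample wells × 8 worms) for type-I calibration; 200 planted-effect plates
(FC 0.4, 30 worms/well) for power; and an image-mode end-to-end plate of
9 wells × 8 worms. These sizes give stable statistics at desk scale; all of
them are plain function arguments that scale up directly.

# Known limitations

* Unbalanced Dunnett designs rely on the multivariate-t implementation's
  handling of the correlation structure; extremely unbalanced wells (n = 2
  vs n = 100) have not been characterized against the oracle.
* The brightfield enhancement is a single divisive local-contrast operator;
  real acquisitions with strong meniscus shading may need the configurable
  threshold retuned.
* Skeleton length slightly overestimates true midline length on noisy masks
  (spur branches are not pruned); the acceptance bounds leave headroom for
  this.
* The molt detector assumes at most four molts and a trace that starts
  during feeding (L1), as in synchronized-hatch assays.
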