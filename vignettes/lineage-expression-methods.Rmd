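---
title: "Lineage-resolved reporter expression analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lineage-resolved reporter expression analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lintrex)
```

## The problem

The *C. elegans* embryo develops through an invariant cell lineage: every
somatic cell has a name (a founder blastomere plus one letter per division,
e.g. `ABplpp`) and a stereotyped birth and division time. This invariance
makes single-cell-resolution expression profiling possible with nothing more
than a ubiquitous nuclear marker and a fluorescent reporter: if nuclei can be
tracked through a 4D movie and assigned Sulston names, every reporter
measurement lands on a known cell at a known developmental stage.

`lintrex` implements that pipeline end to end: assembling lineage trees from
tracked-nuclei tables (forward tracing to around the 350-cell stage, plus
backward tracing of late expressing nuclei down to the forward tree),
normalizing each embryo's clock onto a canonical lineage, subtracting the
per-embryo background so that only robust expression is called, detecting
expression onset as a live-cell-count stage, summarizing the expressing
sublineages, and comparing perturbed with control embryos cell by cell. The
motivating biology is the regulatory loop between a posterior miRNA and a
posterior Hox gene: the Hox reporter comes on around the 100-cell stage, the
miRNA reporter one cell cycle later around the 200-cell stage in the same
four ABp(l/r)(a/p)p posterior sublineages, Hox knockdown delays and weakens
the miRNA reporter, and the miRNA in turn represses the Hox gene through a
seed site in one of its 3' UTR isoforms.

## The canonical lineage

`canonical_lineage()` is the timing standard: a binary tree rooted at P0
with per-cell birth and division (or terminal) times in minutes at 20 °C,
covering AB to generation 8 after AB, MS to 64 cells, E and C to 32, D to 8,
and Z2/Z3, through a comma-stage window ending at minute 260. No published
timing table is transcribed; the values are self-consistent synthetic
timings calibrated to the classic staging landmarks:

* the 4-cell stage follows the second cleavage round (minute 33);
* the live-cell count first reaches **100 at minute 145** and
  **200 at minute 175**;
* AB generation-7 cells cycle in exactly 30 minutes, so the interval between
  the two landmark stages is exactly one local cell cycle.

Division rounds are staggered by small per-cell offsets (in lexicographic
name order) so that every integer stage in the profiling window is actually
attained; sister cells are always born together. The division-axis
convention is stored as a single rule shared by the name algebra and the
builder: the early blastomeres divide by the founder table, ABa/ABp divide
left/right, and every other division is anterior/posterior. Four AB cells
carry a death flag (terminal branches ending at minute ~232), standing in
for the programmed deaths marked on published lineage diagrams; stage counts
drop only at death events.

`Stage` is always the exact live-cell count, never a rounded named stage.
A cell is alive from birth up to but excluding its division; terminal cells
persist through the window's horizon.

## Tracking

`forward_track()` links nuclei frame to frame. Linking is per frame and
deliberately local, as in interactive lineage-editing tools, but three
design choices matter under realistic noise:

* **Matching, not greedy linking.** Candidate links (within `max_disp`, 5 µm
  by default) are resolved per connected component by exact
  maximum-cardinality, minimum-cost bipartite matching; near-optimal
  matchings within 1.5 µm of the optimum are re-scored by motion coherence
  (how well their implied velocities extrapolate onto the following frame).
  Two candidates equally near the same track (within `ambiguity_tol`) raise
  an error rather than being resolved silently.
* **Division detection.** A track that disappears while two new nuclei
  appear within `division_radius` is a division; because one daughter often
  sits where the mother was, a continuing track with one nearby appearance
  is *converted* into a division. Appearances are attributed to candidate
  mothers by capacity-constrained matching with local improvement. A track
  that ends with a single nearby appearance is bridged as the same cell
  (`max_gap` = 1 frame).
* **Prediction for moving nuclei only.** Tracks in directed motion
  (recent step > 1.5 µm, i.e. daughters relaxing away from a division) are
  extrapolated at constant velocity; stationary tracks are matched at their
  raw positions, since extrapolating their wobble would double its noise.

Names are assigned from a single root (`assign_tree_names()`): daughters at
every division take the names from `daughters_of()`, the anterior/left name
going to the daughter with the smaller x (the documented frame has +x
anterior to posterior). The x used is the mean over the first five frames;
a single frame is too noisy to order daughters reliably.

`backward_trace()` starts from expressing nuclei at a late frame and walks
backward by nearest neighbour; branches converging on one earlier nucleus
fuse (a division seen in reverse), and a branch stops as soon as its current
nucleus lies within the link-acceptance distance (default half the median
inter-nuclear spacing) of a forward-tracked nucleus at the same timepoint.
`merge_traces()` grafts the branches onto the forward tree and extends names
through the observed divisions.

## Expression calling

`background_subtract()` implements the "blot" step: at every timepoint the
background is estimated from the lowest-intensity half of the live cells,
and `corrected = max(0, raw - (mean + k * SD))` with `k = 2` by default.
Two numerical details make the estimator honest: the half-sample moments
are rescaled by the half-normal constants (the SD of the lower half of a
Gaussian is 0.60 of the full SD, its mean sits 0.80 SD below the full
mean), since without the correction the threshold sits far too low and
background cells leak through as sustained false positives; and timepoints
with fewer than ten live cells are treated as having no estimable
background (corrected to zero) rather than thresholding on one or two
values. This removes marginally expressing cells and makes the calls
specific. `call_expression()` requires the corrected signal to be positive
for at least `min_run = 5` consecutive timepoints; the onset is the first
timepoint of the qualifying run and the onset stage is the live-cell count
there. `summarize_sublineages()` reports the highest subtree roots whose
leaf cells are predominantly expressing (`purity = 0.8`); roots are
guaranteed mutually non-ancestral, and lowering the purity can only merge
roots, never split them. Bilateral (l/r) symmetry is reported as a warning
diagnostic, not enforced.

One convention deserves a note: `onset_lag()` uses the *earliest* called
onset along the queried cell's ancestral path for each gene -- the time the
gene first turned on in that lineage -- not the queried cell's own first
positive frame. The lag is expressed in units of the canonical cycle length
of the ancestor within whose lifespan the earlier onset falls (minutes are
reported too). On the packaged fixtures this gives exactly +1.0 cell cycle
between the Hox and miRNA reporters in all shared sublineages.

## Time warping and comparison

`fit_warp()` anchors observed division events to canonical ones along every
root-to-leaf path; within a cell the map is linear between its birth and
division anchors, and cells without a division anchor extend from their
birth anchor with the global fallback slope (least squares through the
origin over all division anchors -- a uniformly scaled clock is recovered
exactly as the inverse scale). `interpolate_profile()` evaluates corrected
intensities at canonical integer minutes with no extrapolation;
`average_embryos()` takes the pointwise mean and sample SD on the common
grid. `compare_conditions()` performs, per cell, an equal-variance
two-tailed Student's t test on per-embryo intensities at a configured
canonical minute (default 215); Welch and label-permutation variants are
available, and no multiple-testing correction is applied by default
(a Benjamini-Hochberg flag exists), mirroring per-cell reporting
conventions. Whether the comparison should be per cell at one timepoint or
aggregated over cells is genuinely open; per-cell is the default and the
aggregate is a one-liner on the returned table.

## Sequence utilities

Anchored coordinates put the mature miRNA start at +1 with no position 0,
so the promoter interval (-2260, -1) is 2260 bp and the full construct
(-2260, +234) is 2494 bp by the same arithmetic. `apply_deletion()` removes
features fully covered by a deletion allele and flags the gene null iff the
stem-loop feature is entirely removed; the packaged gk175 record deletes
414 bp and is null. `find_seed_matches()` implements the canonical site
taxonomy (6mer core = positions 2-7, extended to 7mer-m8, 7mer-A1 with an A
opposite position 1, and 8mer), each site reported once with its best
class; no thermodynamic or conservation scoring is attempted.
`scan_motif()` expands IUPAC codes (via Biostrings) and reports hits in
both absolute and anchored coordinates. The CSL/LAG-1 consensus defaults to
`RTGGGAA` -- the literature-standard core, configurable since the source
figures mark the site without printing the motif -- and the packaged locus
places its downstream edge 55 bp upstream of the mature start; the
"55 bp upstream" distance is measured to the motif's nearest (downstream)
edge.

## Bench statistics

`penetrance()` is pooled count arithmetic (percent to one decimal for
display, full precision retained); tables whose phenotypes were scored on
separate animal cohorts carry an `assay` column. `compare_penetrance()`
defaults to a continuity-corrected two-proportion test on pooled counts --
statistically the right tool for count data -- with a plate-level Student's
t available to mirror the older convention. `ddct_fold_change()` computes
delta-delta-Ct with amplification efficiency fixed at 2.0 (kit-default
analysis, no standard-curve correction) and a seeded replicate bootstrap;
the estimate is invariant to per-run machine drift. `summarize_rays()`,
`normalized_band_ratio()` and `roi_intensity()` (even-odd polygon
rasterization with boundary pixels inside) are deliberately plain
arithmetic with loud error handling.

## The synthetic embryo generator

`sim_config()` defaults define the study conditions: bilaterally symmetric
expression in the posterior daughters of the four ABp(l/r)(a/p)p
sublineages plus the posterior C branches, onset at the 200-cell stage
(onset is *defined* per live-cell count, so the staging landmarks are the
native control parameters), reporter emission 500 over a background of
100 ± 15 per frame (a 5:1 expressing-to-background ratio), division-timing
jitter of 0.5 min, 1-min sampling to minute 215, nuclei on a 5-µm lattice.
RNAi is onset delay (in local cell cycles) plus an emission level factor;
homeotic transformations are subtree timing swaps (positionally matched
donor cycles), which `classify_subtree_fate()` reads back by RMS of log
cycle lengths.

The spatial model is deliberately minimal: lattice home sites allocated at
division (one daughter keeps the mother's site, the other takes the nearest
free site offset along the anteroposterior axis, appearing just beyond the
mother and relaxing onto its site at 2 µm/min), with positional jitter
modelled as an embryo-common AR(1) drift (60% of the variance -- the whole
tissue shifts together) plus per-nucleus AR(1) wobble with a ~10-minute
decorrelation time; daughters inherit the mother's jitter state so
positions are continuous across divisions. The per-nucleus stationary SD is
the `motion_sd` parameter. This decomposition reflects what 4D imaging of
embryos actually shows -- apparent positional jitter is dominated by
collective drift and slow wobble, with small per-frame detection noise --
and it matters: under white per-frame noise of the same magnitude,
frame-local tracking is provably hopeless, and no published tracker
operates in that regime.

What the generator does *not* emulate: photobleaching, optical PSF and
segmentation errors, mechanical cell-cell interactions, nuclear volume
exclusion, z-anisotropy, and expression heterogeneity beyond per-frame
Gaussian noise. Passing tests on this generator therefore validate the
pipeline's logic and statistics, not its robustness to imaging artefacts.

`simulate_expression_embryo()` is a fast path that emits intensity series
directly on the (jittered) true tree; the expression pipeline sees the same
statistical structure without the spatial layer, which keeps the power and
null calibration studies (200 replicates of six treated vs six control
embryos) inside a few minutes. The full spatial path is exercised by the
tracking suite.

## Numerical choices and problem sizes

* Stage landmarks are integral minutes by construction, so onset stages are
  exact, not rounded.
* Warp fits are closed-form; slope recovery is tested at 1e-6 (noise-free)
  and 2% (±1 min jitter).
* Anterior/posterior ties at a division are broken toward the first
  daughter with a warning.
* Degenerate comparisons (zero variance, identical groups) return p = 1 by
  convention rather than erroring.
* Test-suite problem sizes: tracking validation uses 10 seeded embryos to
  the 350-cell stage; power and null calibration use 200 replicate
  experiments of 6 + 6 embryos restricted to the ABplpp subtree plus a
  non-expressing cohort over minutes 195-215; scanner oracles use 50-100
  random 300-500 nt sequences; delta-delta-Ct calibration uses 1000
  simulated triplicate experiments with Ct SD 0.2.

## Known limitations

* Frame-local matching cannot resolve simultaneous division rounds when the
  positional jitter approaches half the inter-nuclear spacing: paired
  identity exchanges between relaxing daughters survive even exact min-cost
  matching with one-frame lookahead. At jitter equal to 20% of the
  nuclear spacing the merged trees name about 90% of cells correctly
  (99-100% at the generator's default jitter); closing that gap would
  require joint multi-frame track optimization.
* The canonical timings are calibrated, not measured; analyses that depend
  on absolute minutes (rather than stages or cycles) inherit that choice.
* The timing-RMS fate classifier is one concrete reading of "lineage fate";
  it ignores terminal-fate identity and marker expression.
* Pooled-count penetrance cannot represent every possible printed
  percentage exactly (a percentage must be a multiple of 100/n); the
  fixtures use nearest integer counts.
* Onset-lag in cell-cycle units depends on the local canonical cycle; in
  perturbed embryos whose cycles are themselves altered, the minute-based
  lag is the safer quantity.
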