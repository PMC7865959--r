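---
title: "Methods: validating 2D stereology of dendritic spines against 3D ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating 2D stereology of dendritic spines against 3D ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinestereo)
```

## The question the package addresses

Measuring excitatory synapses in brain tissue can be done two ways: on
single thin-section transmission EM micrographs (cheap, high resolution,
but two-dimensional), or on serial block-face SEM volumes (complete 3D
shape, but costly to acquire and segment). Whether the 2D route is adequate
for spine-head size, apposition size and synapse density is an empirical
question: answering it on tissue requires comparing two datasets whose
ground truth is unknown. `spinestereo` builds the machinery to answer it on
*simulated* tissue, where truth is known by construction, and implements
every quantitative step the tissue comparison itself needs:

1. a **conversion algebra** between 2D and 3D size measures under the
   sphere/disc approximation;
2. a **synthetic neuropil generator** calibrated to measured CA1 spine
   statistics;
3. a **virtual sectioning engine** emulating thin-section TEM measurement;
4. the **size-frequency density estimator** and the **direct 3D count**;
5. the **comparison protocol** (summary tables, fixed-bin frequency curves,
   Spearman correlations, rank-sum/ANOVA tests).

## The conversion algebra

A reconstructed spine head of volume $V$ is approximated as a sphere,
$R = (3V/4\pi)^{1/3}$, and its comparable 2D quantity is the equatorial
section $A = \pi R^2$. A measured 2D head profile of area $A$ is treated as
the largest section of a sphere, giving $V = \tfrac{4}{3}\pi (A/\pi)^{3/2}$.
An apposition length $L$ measured in 2D (PSD length `PSD_L` or synaptic
apposition length `SAL`) maps to the disc of that diameter,
$S = \pi (L/2)^2$, yielding `PSD_S` and `SAL_S`, which are comparable with
the 3D synaptic apposition surface (SAS). Each length is mapped to its own
disc independently; this is the only reading consistent with the two
separate published ranges for `PSD_S` and `SAL_S`.

Numerical choices: inputs must be non-negative (zero is legal and maps to
zero; degenerate spines are filtered by the I/O layer, not here); internal
computation is full precision, and `report_round()` rounds half-to-even at
three decimals only for reporting, matching the precision at which the
reference values are printed. The area-volume pair (0.004, 0.031) um^3/um^2
quoted in the literature does *not* reproduce from the rounded 0.004: the
exact conversion gives 0.030, consistent with an unrounded minimum volume
near 0.0042. This is an input-rounding artifact of the printed value, and
the package documents rather than reproduces it.

## The synthetic neuropil generator

The generator's defaults are the study conditions, not tuning knobs.

* **Head volumes**: lognormal truncated to $[0.004, 0.300]$ um^3. The
  lognormal is the standard model for right-skewed spine-size
  distributions; a truncated gamma is available as an alternative family.
  The log-scale SD is fixed at $\sigma_{\log V} = 0.85$, chosen once so the
  distribution shows the reported strong right skew with roughly 80% of
  volumes below 0.1 um^3 (the reported quantile puts at least 75% of heads
  below that size). The
  location parameter is not free: it is solved numerically at configuration
  time so the truncated mean equals 0.066 um^3.
* **SAS**: surface scales as volume to the two-thirds,
  $\mathrm{SAS} = c\,V^{2/3} e^{\varepsilon}$,
  $\varepsilon \sim N(0, \sigma^2)$ with $\sigma = 0.48$, fixed once so the
  Spearman correlation between SAS and volume is about 0.73 at large $n$;
  $c$ is solved numerically so the mean SAS is 0.089 um^2. SAS is clipped
  at the spherical-cap bound $4\pi R^2$ (clipping is negligible at the
  defaults, ~4.6 SD out, and the count is recorded on the returned table).
* **Shaft synapses**: Bernoulli fraction 0.07. Tissue measurements report
  the shaft contribution only as small, without a number; 7% is a typical
  value for
  CA1 stratum radiatum and is configurable. Shaft synapses carry an SAS but
  no head, so they appear in 3D counts but are never sectioned into head
  profiles.
* **Placement**: uniform centres in the block; by default centres are inset
  by the head radius so whole heads lie inside (as reconstructed heads do
  in a segmented volume), with `contain = FALSE` available for
  unbounded-medium sampling experiments. The hard-core tolerance defaults
  to 0 (touching allowed) because no packing statistics are published.
* **Shape classes** (mushroom/thin/stubby) are metadata only, assigned by
  volume thresholds; the qualitative classification carries no geometry.

What the generator does *not* emulate: necks, shafts and axons as
geometry; non-spherical heads; perforated or horseshoe PSDs; spatial
clustering of synapses; section compression or staining artifacts. Passing
tests therefore validate the estimators under the sphere model and uniform
spatial statistics — they show the machinery is correct, not that real
tissue is spherical.

## Virtual sectioning

Slabs are half-open intervals $[z_0, z_0 + t)$ with $t = 0.065$ um (thin
sections are 60–70 nm), and a TEM image is treated as a projection through
the slab: the observed head profile is the *largest* circle of the
sphere–slab intersection ($\pi R^2$ if the slab contains the equatorial
plane, else the circle at the nearer slab face). This projection model
deliberately reproduces the Holmes overestimate of profile sizes through a
finite section.

The apposition cap (area = SAS) is sectioned through its rim circle: the
chord of that tilted circle within the slab is the measured SAL. The PSD is
a concentric sub-cap whose rim diameter is a Beta-distributed fraction of
the SAL rim diameter (mean 0.75 = 0.217/0.291, concentration 20, one draw
per synapse), and its own rim chord is the measured PSD length, so the
counted, measured object is the PSD itself — exactly the object the tissue
protocol counts. The rim-circle *chord* is a tractable stand-in for the
projected arc of the cap; only the chord model is implemented.

Two visibility criteria stand in for "PSD and synaptic cleft clearly
visible, with at least three presynaptic vesicles":

* a minimum PSD chord of 0.05 um (below the shortest PSD observed in
  tissue, 0.089 um), and
* an orientation criterion $\sqrt{1-u_z^2} \ge 0.5$ (apposition plane
  within 60 degrees of vertical): a PSD cut en face shows no cleft line in
  projection and cannot be measured or counted. The 0.5 default is a round
  geometric midpoint, set once.

Because the slab projection inflates rather than shrinks profiles, the 2D
size *under*-estimation seen in tissue is reproduced here with a smaller
margin (a few percent at the defaults): simulated 2D areas are random —
not maximal — sections, which is the direction the tissue study argues,
but real tissue adds non-sphericity and segmentation effects the simulator
does not model.

## Density estimation

**Size-frequency (2D)**: $N_a = (N_d/A)/d$, with $N_d$ the number of
synaptic profiles not touching the exclusion boundary of their counting
frame, $A$ the total examined area and $d$ the mean PSD length of the
counted profiles (a single global mean, since the method defines $d$ only
as the average PSD length). The default frame is the unbiased two-edge
frame (forbidden line = bottom edge plus the left edge extended upward);
under a tiling of the plane each profile is counted exactly once, which the
test suite verifies literally. An `all_edges` mode reproduces the literal
convention of discarding every edge-touching profile instead, which
undercounts large profiles; it is
provided for comparison and is not the default.

**Direct count (3D)**: the unbiased-brick rule — count a head if its sphere
intersects the subvolume and does not cross any of the three excluding
planes (the low-coordinate faces, extended); heads crossing the three
opposite faces are counted. The combination is translation-unbiased (a
Monte-Carlo test confirms it to within simulation error). Which three faces
are excluding is a convention; low-$x$, low-$y$, low-$z$ is fixed here.
Shaft synapses are points counted by centroid.

At the reference sampling scale — a 190 um^3 block at 2 synapses/um^3,
75 fields totalling ~1900 um^2 — the 2D estimator lands a few percent high
(residual Holmes counting excess) and the spines-only 3D count a few
percent low (it excludes the ~7% shaft fraction from its numerator while
truth counts all synapses). The package therefore takes the 3D count *of
all PSDs* as the like-for-like comparator for the 2D estimate, since both
target total asymmetric synapse density, exactly as a manual count of
every PSD in a reconstructed volume does. Directional,
population-level claims (2D sizes below 3D sizes) are assessed on means
pooled over ten replicate pipelines, because the per-replicate gap (~5–8%)
is of the same order as per-replicate Monte-Carlo error at this sampling
size.

## Comparison protocol

Summary tables report mean, SEM ($s/\sqrt{n}$ with the $n-1$ SD), range
and $n$. Frequency curves use fixed bins — 10 x 0.08 um for lengths,
9 x 0.06 um^2 for areas, 10 x 0.03 um^3 for volumes — starting at zero
(the published curves do not state bin origins; zero is declared once
here). Bins are half-open, the last closed; overflow folds into the last
bin with a warning so curves always sum to one, and curves are relative
frequencies so that sets of different $n$ are comparable. Spearman's
coefficient is computed from mid-ranks explicitly and is cross-checked in
the tests against the classical rank-difference formula (ties-free) and
against `stats::cor` (with ties) to 1e-12. Two groups are compared with
the Mann–Whitney test (exact for small untied samples, otherwise the
continuity-corrected normal approximation), three or more with one-way
ANOVA; no multiple-testing correction is applied, matching the reference
protocol.

## A worked run

```{r pipeline}
cmp <- run_comparison(seed = 1)
cmp
head(cmp$summary)
```

The default problem sizes (340-spine cohorts, a 190 um^3 block, 75 fields,
ten replicate seeds for directional claims, 40 seeds for the unbiasedness
check) were chosen to match the reference sampling design while keeping a
full validation run in the order of seconds.

## Known limitations

* All geometry is spherical; systematic shape effects (ellipsoidal heads,
  curved PSDs) are outside the model, so absolute biases measured here are
  lower bounds on what irregular geometry could produce.
* SAL is not modelled as an independent structure: it is the apposition
  cap itself, with the PSD nested inside at a fixed-ratio rim. Tissue
  reports SAL only in 2D, so the nesting ratio, not the cap, carries the
  SAL/PSD distinction.
* The en-face visibility cutoff is a hard threshold; real recognisability
  degrades gradually with tilt.
* The size-frequency method inherits its known approximations: it is
  accurate to within ~10% here, not unbiased, and its error depends on the
  PSD size distribution through $d$.
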