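---
title: "Tracking nuclei by minimum-cost circulation with iterative error correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking nuclei by minimum-cost circulation with iterative error correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(celltracer)
```

This vignette is the package's own account of its models and the choices
behind them: what each stage assumes, which parameters matter and why their
defaults are what they are, what the synthetic generator does and does not
emulate, and where the method is expected to fail.

## Detection model

A fluorescently labelled nucleus is, to good approximation, a bright,
compact, roughly convex blob. At the centre of such a blob all three
principal curvatures of the intensity — the eigenvalues $\lambda_1 \le
\lambda_2 \le \lambda_3$ of the Hessian of the Gaussian-smoothed image — are
negative. The blob score used here is

$$ S_\sigma(x) = \sigma^2 \cdot \prod_{i=1}^{3} \max(0, -\lambda_i(x; \sigma)), $$

computed on the physical (micrometre) grid so that anisotropic sampling is
handled by per-axis smoothing sigmas, and combined over scales by a
pointwise maximum of the $\sigma^2$-normalised responses. The product form is
deliberately conservative: a single non-negative curvature (an edge, a ridge,
a dark blob) zeroes the score. The score is invariant to additive intensity
offsets and scales with the cube of a multiplicative gain, so thresholds are
never placed on the score itself.

Candidate maxima are instead filtered by a contrast z-score: the mean
intensity of an interior ball around the maximum minus the mean of a
surrounding shell, in units of the standard error implied by a robust global
noise estimate (median absolute deviation of first spatial differences,
divided by $\sqrt 2$). Two details matter:

* the interior has a physical floor (2.5 µm radius) regardless of the
  detected scale. Candidate maxima are *selected* points, so the mean of a
  very small interior is biased upward by the selection; a floor keeps the
  false-positive rate on pure noise below about one seed per $10^5$ voxels at
  the default threshold $z \ge 4$.
* the noise sd is estimated once per frame rather than per region; this keeps
  the test robust to intensity heterogeneity without fitting per-region
  variance models.

Voxel-level instances come from a seeded min-cut: within a dilated bounding
box around each spatial cluster of seeds, a voxel graph with neighbour
capacities $\exp(-\Delta I^2 / 2\sigma_g^2)$ and terminal capacities from a
two-Gaussian foreground/background log-likelihood ratio is cut once per seed,
against the background plus the other seeds' cores as hard constraints.
Contested voxels go to the nearer seed centre. Detections outside the volume
gates (defaults: $\tfrac43\pi(0.5r)^3$ to $\tfrac43\pi(2.2r)^3$ for nominal
radius $r$) are discarded — the lower gate doubles as the last line of
defence against noise fragments.

The detector assumes blob-like nuclei. Elongated or highly lobed
morphologies violate the all-negative-curvature premise and will be
under-detected; this is a known limitation of the approach, not of the
implementation.

## Association as a minimum-cost circulation

Each detection $d$ contributes a unit-capacity *observation* arc with cost
$-\log(p_d/(1-p_d))$, where $p_d$ is a logistic function of the detection's
contrast z-score above the threshold (clamped to $[10^{-3}, 1-10^{-3}]$);
confident detections therefore pay negative cost, and the optimiser is
rewarded for explaining them with tracks. Appearance and disappearance arcs
cost $C_\text{border} = 4$, reduced at the first/last frame and near the
spatial border where entering and leaving are expected. Transitions cost

$$ c(a \to b) = \frac{d^2}{2\sigma_m^2} + w_v \log^2\!\frac{v_b}{v_a}
   + (\text{gap}-1) \, C_\text{skip}, $$

gated at radius $R \cdot \text{gap}$; the stringent first pass uses half the
gating radius. Frame-skipping arcs (gap $\le g_\max = 2$) let a track jump a
missed detection; one-to-two and two-to-one matchings are realised by
discounted entry/exit arcs priced against a specific geometric partner
(candidate pairs limited to the three nearest neighbours, child/parent volume
ratio in $[0.2, 0.8]$), which preserves unit flow conservation. Division and
merge displacements are physically larger than frame-to-frame motion — a
newborn child sits about one radius from the parent axis — so those arcs use
a doubled motion scale $2\sigma_m$ in their distance term.

The network is a DAG between a dummy source and sink, so the exact optimum is
found by successive shortest augmenting paths with node potentials
(compiled); augmentation stops when no negative-cost path remains, which is
what lets the number of tracks emerge from the optimisation. Determinism
comes from a canonical arc ordering (frame, then detection id). An exhaustive
oracle (`brute_force_association`) enumerates every feasible track
decomposition of the same network on small instances; the test suite holds
the solver to exact agreement with it on one hundred random instances.

Two defaults deviate from the most obvious choices and deserve a note:

* $C_\text{skip} = 2.0$ (not 1.0). With a cheaper surcharge the *exact*
  optimiser discovers degenerate "weaving" solutions around over-segmented
  detections — two paths threading one true track via skip arcs — which
  scrambles the flow evidence the corrector reads. At 2.0 a skip is dearer
  than the transition-plus-bundle it would displace, yet far below the
  appear-plus-disappear alternative (8.0), so genuine missing-cell skips are
  always still taken.
* $\sigma_\text{motion} = r$ and $R = 3r$ per unit gap tie all motion scales
  to the nominal nucleus radius, the one number a user must supply.

## The correction loop

Each iteration: link with the stringent gate, then (i) for every skip arc
carrying flow, re-detect in a window of three nominal diameters around the
linearly interpolated centroid with the significance threshold relaxed by
half, after flattening already-explained labels plus a dilation margin for
their PSF tails; accept only within the gating radius, inside the volume
gates, and about as bright as the cohort (at least 35% of the median
detection contrast — residual PSF shoulders of explained neighbours are not);
(ii) where the redetection *failed because an existing label already covers
the spot*, or where a two-to-one arc feeds a detection whose outflow is a
one-to-two arc, propose splitting that label if its volume exceeds
$\gamma = 1.6$ times the windowed median of its own track or matches the sum
of the two putative members' previous volumes within $\tau = 30\%$; (iii)
propose merging a close pair when one member is a one-frame orphan and the
combined volume matches the pair's own flow predecessor and successor within
$\tau$. Splits are executed as two-seed min-cuts with small ball anchors
(single-voxel anchors let the cut collapse around the seed instead of the
neck); merges are exact voxel unions. Rejected proposals are memoised by
location so the loop cannot oscillate; it stops when an iteration accepts
nothing, at most `max_iterations = 5`.

The windowed (±3 frames, self-excluded) track median is used as the volume
baseline rather than the whole-track median because a track that crosses a
division halves its volume mid-way; a global median would flag every parent
frame of such a track as over-sized.

## Lineage assembly

Tracklet ends and starts form a second, far smaller circulation with the
relaxed gate $R \cdot \text{gap} \cdot 2$ and gaps up to 3 frames; observation
arcs are strongly negative so every tracklet is used. Division detection then
examines every chain start: its up-to-three nearest previous-frame detections
are candidate parents, and a candidate is accepted if the parent chain
continues, parent and new child are mutually nearest, the parent track is at
least 5 frames old (tracks already present at the block's first frame are
exempt — their true start is simply unobserved, which also makes batched and
whole-scene processing agree), and the children's volumes are consistent with
a division. Volume consistency is the per-child window $[0.3, 0.7] \times$
parent, *or* volume conservation ($r_1 + r_2$ within 30% of 1 with both
children at least 0.2): newborn sibling labels are systematically biased
small because the two half-peak regions truncate each other at one-radius
separation, which clips genuine symmetric divisions at the window's lower
edge, while a false candidate — a bystander whose own track continues at full
volume — has $r_1 \approx 1$ and fails the conservation sum. Volumes entering
these ratios are 3-frame means along the chains, since instantaneous label
volumes fluctuate by tens of percent.

Gap frames inside merged tracks are filled with interpolated virtual nodes
(flagged `interpolated`), so exported lineages have one node per frame per
track. Batch processing splits the frame range into overlapping blocks,
tracks each independently, and splices at the middle overlap frame by mutual
nearest neighbour within the gating radius; nodes and edges before the splice
frame come from the earlier batch, after it from the later one.

## Evaluation metrics and analyses

Predicted and ground-truth nodes are matched per frame by an exact one-to-one
assignment (minimum total distance within the match radius). A ground-truth
edge is correct iff both endpoints are matched and the prediction links their
matches; the error count adds predicted edges between matched nodes that
correspond to no ground-truth edge, and divides by the number of ground-truth
edges. Error-free statistics follow root-to-leaf paths and count the prefix
of correct edges from the track start (the longest correct run is available
behind a flag, since either reading of "consecutive time points without
errors" is defensible).

The mixing index fits a separating hyperplane to two labelled point
populations and reports misclassified fractions, averaged (0 = separated,
0.5 = fully mixed) or summed. The implementation takes the max-margin
direction from a linear support-vector machine on centred, isotropically
scaled coordinates, then chooses the intercept by enumerating thresholds
along that direction to minimise the mean misclassified fraction (ties break
toward the widest margin). The intercept refit matters: the pure SVM solution
optimises hinge loss, not the misclassification count the index is defined
by — on the one-dimensional configuration A = {0, 1, 2}, B = {1.5, 2.5, 3.5}
it puts the boundary at the pooled mean (index 1/3) where the
misclassification-optimal threshold gives 1/6. Isotropic scaling (rather than
per-axis standardisation) is what makes the index invariant under rigid
transformations applied jointly to both populations. Exact
misclassification-minimising hyperplanes are NP-hard in general; this
construction is exact in the direction's one-dimensional projection.

The dispersion index is the mean pairwise Euclidean distance of a point set
(translation-invariant, positively homogeneous). Velocity fields are central
differences along tracks (one-sided at ends, µm/min), with local mean speed
and local velocity variance (trace of the velocity covariance) over the
k = 50 nearest same-frame neighbours, k clamped to the population.
Expression–velocity correlation is a per-gene Pearson correlation against
local speed, ranked; zero-variance genes are reported as missing. Global
point-cloud matching aligns by centroid, rms scale and principal axes (sign
ambiguity resolved by the cheaper fit) and then solves an exact linear
assignment on squared distances with a per-point unmatched penalty.

## The synthetic generator

`simulate_embryo()` emulates the data regime the pipeline is built for:
nuclei on a spherical shell drifting tangentially toward a pole (an
epiboly-like flow, purely phenomenological) with Brownian jitter and soft
repulsion; divisions replace a cell by two half-volume children displaced one
radius apart. Rendering is a Gaussian blob per nucleus composed with a
Gaussian PSF (the composition is again Gaussian, so it is rendered directly),
additive background, Poisson noise on the signal and Gaussian read noise;
SNR is defined as blob-peak contrast over read-noise sd, and the generator is
calibrated so the measured ratio is within 10% of the configured value.
Ground-truth labels assign every voxel above a nucleus' half-peak to the
nearest centre.

Default study conditions: 200 initial cells, 50 frames, SNR 10, division
probability 0.01 per cell per frame. Two defaults reflect deliberate
realism choices. First, divisions have a refractory period (8 frames):
real cell cycles cannot re-divide immediately, and lineages in embryonic
recordings contain a handful of divisions over hundreds of frames. (The
branching-process unit test sets the refractory period to zero because the
closed-form expectation $N_0 (1+p)^T$ assumes memoryless division.) Second,
the default shell geometry (radius 147 µm inside a 40×200×200 µm domain)
gives ~330 nuclei a typical internuclear distance near 9 µm. A gastrula-stage
embryo has thousands of surface cells spread over ~10⁶ µm², i.e. spacings
above 10 µm; cramming the same cells onto a small cap pins every nucleus at
the repulsion floor, which is both unrealistic and pathological for
ground-truth label volumes (mutual truncation makes them fluctuate wildly).

What the simulator does *not* emulate: realistic light-sheet optics (stripe
artefacts, depth-dependent blur), photobleaching, intensity variation between
nuclei, apoptosis, non-blob morphologies, and multi-view geometry. Passing
tests on synthetic scenes therefore demonstrate the correctness of the
algorithms under controlled violations (noise, missed/merged/split
detections, divisions, crowding), not performance on any particular
microscope's data.

## Numerical choices and degenerate inputs

* Gaussian smoothing is FFT-based with circular boundaries; sub-voxel
  detection scales are clamped to one voxel with a warning.
* The flow solver works in doubles with an epsilon guard on reduced costs;
  capacities are integers and the returned flow is integral.
* Empty networks, empty detection sets and noise-only frames are all valid
  inputs with empty results; a ground truth without edges is an error for the
  edge error rate (the metric is undefined).
* Block-matching motion flow windows each block (Hann) and iterates the
  correlation on a re-cropped target; without the window, crop boundaries
  anchor a spurious zero-shift peak, and without the re-crop large shifts are
  biased low.
* Registration of pure noise is reported with a low correlation score and
  `reliable = FALSE` rather than an error.
* Problem sizes in the test suite (a 20×200×200-voxel, 50-frame standard
  scene; 12–25-cell unit scenes) were chosen as the smallest configurations
  that still exercise crowding, divisions and all three corruption types.

## Known limitations

Cost terms for linking are a documented stand-in family (quadratic motion,
log-volume consistency, constant border/skip surcharges); they honour the
structural design — skips, one-to-two and two-to-one arcs, stringent-then-
relaxed gating — but other monotone costs would serve. Division detection
assumes roughly symmetric divisions; strongly asymmetric divisions fall
outside both volume gates by design. The corrector can only repair what the
flow localises: two adjacent simultaneous errors on the same track (e.g.
merges in consecutive frames) need one extra iteration each, and errors
within `g_max` frames of the sequence ends have weaker skip evidence. On
crowded data the residual error rate is dominated by identity swaps between
adjacent tracks, which no volume prior can detect.
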