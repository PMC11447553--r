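---
title: "Methods: domain mapping, neighbor statistics and thermotropic order in stratum corneum lipid multilayers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: domain mapping, neighbor statistics and thermotropic order}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models and
procedures it implements, the parameters that matter, what the synthetic
generator does and does not emulate, and the numerical and design choices
made where the methodology was genuinely open.

## The system and its data model

The package targets stacked multilayer membranes of ceramide NS (CER NS),
cholesterol (CHOL) and free fatty acid (FFA) — the three-component model of
the stratum corneum short periodicity phase (SPP). A configuration is a
topology table (particle → lipid, species, chain role, bead name, mass,
head flag) joined to per-frame coordinates in nm with the bilayer normal
along z. Head beads are the coarse-grained headgroup particles (MHEAD2,
AMIDE, OH1, OH2 for CER NS; HEAD for FFA; CHEAD for CHOL); every other
non-water bead is a tail bead. Coordinates are treated as periodically
wrapped in x–y and unwrapped in z — thickness and density-profile math
requires monotone z, so readers never re-wrap it.

A CER NS contributes two tails (C24 acyl and C18 sphingosine); its
*conformer* is **extended** when the two chain-terminal beads lie in
different leaflets (the molecule bridges two bilayers through the headgroup
region) and **hairpin** when they share one. Chain order in the topology is
head-proximal to terminal, so "terminal bead" is well defined.

## Leaflet detection

The leaflet structure is assumed by every analysis but no standard
detection procedure exists for multilayers, so the package uses a
deterministic histogram-watershed: per-lipid head-bead centroid z is
histogrammed (0.1 nm bins), smoothed with a 3-bin moving average, and the
`n_leaflets` highest local maxima become leaflet planes; any z is assigned
to the basin of its nearest plane, with basin boundaries at the smoothed
density minimum between adjacent peaks (the midpoint of a flat minimum).
Consecutive leaflet pairs form bilayers; the central bilayer is the middle
pair by mean z. This is robust and iteration-free, which is why it was
preferred over k-means-style clustering; it fails loudly when fewer than
`n_leaflets` distinct head-density bands exist.

CER tails are assigned the leaflet of their *terminal* bead rather than the
lipid's head centroid — an extended CER's head sits at the interface
between two bilayers and its two tails genuinely occupy adjacent leaflets,
so a head-based assignment could not classify conformers at all. With
coarse-grained chain lengths (acyl span ≈ 2.35 nm against a ≈ 2.7 nm
half-bilayer) terminal beads stay on their own side of the bilayer
midplane; strongly interdigitated atomistic C24 chains can cross it, so
conformer classification is intended for the CG representation (which is
also where the neighbor analysis operates).

## Local thickness and composition maps

At each point of a G × G grid (default 50 × 50) the lipids with whole-lipid
center of mass within 0.8 nm of the grid point (periodic x–y distance) are
isolated. The 0.8 nm neighborhood is a *circle*: the literal reading of a
radius, and a square window would overweight diagonals. A head-bead mass
histogram along z (0.1 nm bins) is scanned for local maxima (after 3-bin
smoothing, keeping peaks ≥ 5% of the maximum to suppress single-bead
spikes); the local thickness is the distance between the two peaks closest
to and flanking the central-bilayer midplane, each refined by a
mass-weighted centroid over the peak bin ± 1, which gives sub-bin accuracy.
Head beads only are histogrammed: the peaks being measured *are* headgroup
planes, and tail-bead mass between them would only blur the minimum. Cells
with fewer than `min_lipids = 3` contributors or without two flanking peaks
are masked — two peaks cannot be estimated from fewer lipids.

Composition uses tail centers of mass (counts are per *tail*, and the two
chains of an extended CER belong to different bilayers): per cell, the
fraction of CER acyl, CER sphingosine, CHOL and FFA tails among
central-bilayer tails within the radius; fractions sum to 1 at every valid
cell. Pooled histograms use 0.05 nm (thickness) and 0.01 (excess fraction)
bins. Cell values are quantized by the 0.1 nm density bin, so individual
cells carry ~±0.05–0.1 nm error while region means are accurate to half a
bin — tests assert at both scales accordingly.

## Domain statistics

Pearson r and Spearman ρ (average ranks for ties, the standard convention)
relate local thickness to each tail-type fraction over pooled valid cells;
positive r means the fraction rises with thickness. Domains are identified
with a two-component full-covariance Gaussian mixture on standardized
(thickness, composition) vectors; k = 2 is fixed — the question is the
larger/smaller-thickness dichotomy, not model selection. Two numerical
points:

* The four fractions sum to 1 exactly, so the naive joint 5-vector is rank
  deficient and every full covariance is singular; the mixture is fitted on
  thickness plus three fractions (the fourth is linearly determined), and
  summaries report all four.
* EM is initialized with model-based hierarchical agglomeration (mclust),
  which is deterministic — random restarts exist to de-sensitize random
  initialization and are unnecessary here. Duplicated grid cells can still
  produce a singular component; the fit then restarts once on coordinates
  jittered by 10^-6 standard deviations, far below any physical scale.

The component with the greater mean thickness is labelled "larger", and the
summary reports each domain's mean thickness and mean tail composition as
percentages next to the mixture-wide average. A mean-thickness gap below
0.1 nm raises a `no_separation` flag rather than an error: a homogeneous
system is a valid answer.

## Neighbor statistics and the mixing null

Six tail classes (extended/hairpin × acyl/sphingosine CER chains, CHOL,
FFA) form 21 unordered pair types. Each tail is linked to its k = 6 nearest
tails by full 3D center-of-mass distance — minimum image in x–y, z
unwrapped; z-separation naturally suppresses cross-leaflet pairs, so no
leaflet restriction is imposed. CHOL queries use k = 7 (its Voronoi
neighborhood is larger); ties break by particle order, making the
computation deterministic.

Raw counts are directed — each query→neighbor relation adds one to its
unordered pair bin, so raw counts total `6·n_nonCHOL + 7·n_CHOL`. The
*normalized* statistic divides relative occurrence by the perfectly-mixed
null probability, proportional to `N_i·N_j` for unlike and `N(N−1)/2` for
like pairs. One subtlety required care: with unequal k, plain directed
counts do **not** calibrate — in expectation a directed i–j count is
`N_i·N_j·(k_i + k_j)/(N−1)`, so the `(k_i+k_j)` factor cancels against the
null only when all k are equal, and a mixed system would show CHOL–CHOL
≈ 1.14. The occurrence entering the normalization therefore weights each
relation by 1/k(query): its expectation becomes `2·N_i·N_j/(N−1)` for
unlike and `N_i(N_i−1)/(N−1)` for like pairs, exactly proportional to the
null weights for any k mix, restoring the defining property that every
normalized count is 1 in a perfectly mixed system. Replicate tables are
aggregated as mean ± sd and presented sorted ascending.

Coordination numbers give the same information per reference class: the
mean count of class-j tails among a class-i tail's k_i neighbors divided by
`k_i·(N_j − δ_ij)/(N−1)`, which is exactly calibrated as defined.

At the calibration scale used in tests (600 tails, 20 seeds), the rarest
pair class (extended acyl–acyl at the study composition with 35% extended
CERs) has a seed-mean standard error of ~0.02–0.06, so per-pair means sit
within a few hundredths of 1 while the grand mean over pairs and seeds is
stable to ~0.005.

## Thermotropic metrics

* **S2** — per chain, the director is the dominant principal axis of a
  12-carbon section (carbons 4–15 from the head-proximal end, clamped for
  shorter chains with a warning); the principal axis is robust to mid-chain
  kinks where an end-to-end vector is not, and the window avoids both the
  headgroup-adjacent segment and the interdigitation zone. S2 is the
  largest eigenvalue of `Q = ⟨(3uuᵀ − I)/2⟩`, computed per inner leaflet
  (the outer two touch bulk water) and averaged. Classification bands are
  exposed as constants: ordered ≥ 0.8, fluid 0.3–0.8, isotropic < 0.3.
* **S_CH** — `(1/2)⟨3cos²θ − 1⟩` of C–H bond vectors against z, averaged
  over both hydrogens, chains and frames per carbon index; bounds −0.5
  (perpendicular) to 1 (parallel) hold exactly on noiseless constructions.
* **NLA** — weighted tails per lateral area, weights 1 (CER acyl,
  sphingosine, FFA) and 1.9 (CHOL cross-section), computed per leaflet and
  averaged. Both NLA and its reciprocal (area per weighted tail) are
  reported, since a melting transition is equally naturally described by
  either; the reciprocal is the one that *increases* on melting.
* **Membrane thickness** — the water mass-density profile along z; the bulk
  level is the mean over the outermost 0.5 nm of each slab, and each
  interface is found by scanning *outward from the dry interior* to the
  first half-bulk crossing, interpolated linearly. Scanning from the slab
  edge inward was rejected: Poisson noise in the bulk occasionally dips
  below half-bulk and would bias the interface outward.

Series tagged by temperature are block-averaged in half-open [T, T+5) degC
windows. Transitions are located by continuous piecewise-linear (hinge)
least squares with the breakpoint searched exhaustively over block
boundaries with ≥ 3 points per segment; an SSE improvement under 5% against
a single line flags "no transition" (with an absolute-zero-residual guard
so an exact line is never misread as a transition).

## Lamellar scattering

Spacings are `2π/q`; repeat distances `d = 2nπ/q_n`. Peaks are fitted with
Pearson VII profiles `A[1 + ((q−q₀)/w)²(2^{1/m}−1)]^{−m}` — parameterized
by half-width-at-half-maximum w and exponent m so that m = 1 is Lorentzian
and m → ∞ Gaussian — plus one flat background per window, by
Levenberg–Marquardt with bounds w > 0, m > 0.51 and tight (10⁻¹²)
convergence control; non-convergence is flagged, never silently accepted.

Phase assignment generates candidate repeat distances from every (peak,
order ≤ 4) pair, refines each d by least squares over its matching peaks
(|q − 2πn/d| ≤ 0.02 nm⁻¹), and accepts candidates with ≥ 2 matching orders
*whose first order is itself observed* — the rule that suppresses the
spurious doubled-repeat phase every lamellar series otherwise admits, while
still reporting genuine commensurate pairs (a 10.8 nm series sharing its
even orders with the 5.4 nm SPP is reported as two phases with shared
peaks). Near-duplicate candidates (Δd ≤ 0.1 nm) collapse to the
best-fitting one; unassigned peaks are reported as unknown-phase spacings
2π/q. Repeat distances print at 0.1 nm precision.

## The synthetic generator

`make_multilayer()` builds what the analyses need and no more: chains on a
jittered triangular lattice (0.20 nm² per chain), straight bead rods
(0.47 nm spacing, CG) or all-trans zigzag carbon chains (0.127 nm rise,
"atomistic") tilted by directions drawn from a von Mises–Fisher
distribution about z whose concentration maps to an expected S2 in closed
form (`kappa_to_s2()`); head beads at leaflet planes (5.4 nm head-to-head
bilayers, 0.8 nm inter-bilayer gaps); water slabs at bulk density outside
the outer leaflets (40 waters per lipid by default); defaults of 2000
lipids at 1:0.5:1 CER/CHOL/FFA and 35% extended CERs — the emulated study
conditions. Domains are *imposed*, not emergent: per-region central-bilayer
thickness shifts the two central head planes symmetrically about the
midplane, and per-region composition enrichment reweights site selection —
including per-chain-type keys for extended CERs, since only the chain that
sits in the central bilayer (acyl for centrally-anchored, sphingosine for
adjacent-anchored molecules) can carry a lateral composition signal there.
Extended conformers are sampled at an exact count per home leaflet, which
keeps the central bilayer's acyl/sphingosine census balanced and makes
generator labels exact ground truth. Everything is a deterministic function
of the seed, and the topology is identical across seeds of one spec, so
temperature sweeps can share a topology across frames.

What it does **not** emulate: self-assembly, energetics, realistic chain
packing or interdigitation statistics, headgroup chemistry, undulations, or
emergent domain boundaries. Passing tests therefore demonstrate that the
*analysis machinery* is correct and calibrated — they do not validate any
physical claim about real SC membranes.

Desk-scale problem sizes are deliberate choices: tests use 120–2000 lipids,
20-seed calibration ensembles, 30 × 30 grids and 14-point temperature
sweeps, which a single CPU core completes in well under a minute per suite
while keeping estimator noise within the asserted tolerances. The vignette
text and README examples use the same sizes the tests run.

## Known limitations

* Conformer classification by terminal-bead leaflet assumes chains do not
  cross the bilayer midplane (true for the CG geometry; not guaranteed for
  strongly interdigitated atomistic chains).
* The density-histogram thickness is quantized by its 0.1 nm bin at the
  single-cell level.
* The GMM feature-space and leaflet-detection procedures are package
  choices where the methodology is not standardized; both are documented
  above and deterministic.
* The normalized-pair-count statistic treats the k = 7 CHOL neighborhood
  through per-query weighting; raw directed counts (also reported) retain
  the k asymmetry by construction.
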