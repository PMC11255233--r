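---
title: "Methods: simulating and analysing peptide-array adhesion screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing peptide-array adhesion screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepscreen)
```

## The screen

A high-density peptide array presents thousands of candidate peptides as
square synthesis spots on a chip whose technical unit is a 30 µm × 30 µm
synthesis pixel (s-pixel). In the main configuration each spot is 4 × 4
s-pixels (120 µm on a side; abutting spots pack to
$(10^4/120)^2 \approx 6{,}944$ spots/cm²), and a large-spot configuration
uses 20 × 20 s-pixels (600 µm). Fluorescently labelled cells are seeded
on the chip, incubated, and scanned; the fluorescence over each spot
measures how many cells settled there, i.e. how adhesive or repellent the
synthesized peptide is.

`pepscreen` implements this screen in silico: the combinatorial library,
the randomized layout, a ground-truth scan simulator, the median-based
quantification, and the downstream analyses that turn per-spot
fluorescence into ranked peptides, critical substitutions and minimal
motifs.

## Library design

Three groups plus controls, mirroring the standard chip design:

1. **Tiling (scan) group.** Every k-mer window of each screened protein at
   offset 1 (`tile_protein()`, default k = 15). Adjacent windows share
   k − 1 residues, which is what later makes motif inference possible.
   Proteins of lengths 314, 266 and 233 yield 300 + 252 + 219 = 771
   windows.
2. **Substitution group.** For each parent peptide, every variant with one
   position replaced by one of the other 19 canonical residues
   (`substitution_scan()`). Two 5-mer and two 14-mer parents give
   19 × (5 + 5 + 14 + 14) = 722 variants; with the four parents
   themselves included as entries (the default) the group holds 726. We
   include parents by default because the parent's own intensity is
   needed to fill the diagonal of the substitution matrix.
3. **Random group.** `recombine_fragments()` draws two tiling peptides,
   splits at a uniform random point, joins the prefix of one to the
   suffix of the other and centre-crops to the target length, rejecting
   duplicates and pool members. The construction is one deliberate,
   documented reading of "random combinations of fragments"; it is a pure
   function of (pool, n, length, seed).

Controls are the HA epitope `YPYDVPDYA` (an array quality control and, in
adhesion screens, the strongest adhesive sequence) and explicit blank
entries. Only the canonical 20-letter alphabet is accepted; `X`, `U`,
`B` etc. are rejected at parse time.

**Deduplication is report-only.** Sequences can legitimately collide
across groups (a recombination can in principle re-create a substitution
variant, and repeated subsequences within or across proteins duplicate
windows). We keep every entry — each has distinct provenance and its own
replicate spots — and `library_duplicates()` reports collisions so a
unique-sequence count can be reconciled with per-group totals.

Residue coordinates are 1-based inclusive everywhere inside the package;
only the BED export converts to 0-based half-open.

## Layout

`build_layout()` expands each entry to its replicate spots (defaults
5/3/2 for the three groups) and assigns them to grid cells by a seeded
uniform permutation — a bijection between replicate-expanded entries and
occupied cells. Random placement prevents local effects (edge drift,
meniscus artefacts, clumps of cells) from biasing any single peptide.
Replicates are placed independently, with no minimum-spacing constraint:
randomness is the stated design requirement, and spacing constraints
would make the placement distribution non-uniform. All unused cells
become explicit `BLANK` spots so that quantification covers the whole
grid and the background floor is measured rather than assumed. Spots are
assumed to abut (pitch = spot edge); inter-spot gaps, if any, would only
rescale the packing density.

The GAL-dialect serialization is a deliberately minimal TSV — one
metadata line with the grid geometry and seed, a header, one row per
spot — chosen over full GenePix GAL blocks because it is lossless for
everything the pipeline uses, diffable, and trivially parseable.

## The scan simulator and what it does (not) emulate

The generator provides *known ground truth* so every downstream analysis
can be validated by recovery rather than by eyeballing.

**Latent adhesion.** Unplanted peptides draw
$a_p \sim \mathrm{LogNormal}(\mu, \sigma_{\text{base}})$ with defaults
$\mu = \log 2500$, $\sigma_{\text{base}} = 0.8$. A log-normal baseline is
the natural choice because real ranked intensity curves are plotted on a
log axis and span orders of magnitude; $\sigma_{\text{base}} = 0.8$
spreads 5,000 draws over a factor of roughly 200, i.e. >2 decades above
background. Planted repulsive peptides and blanks get exactly
$a_p = 0$; planted adhesive peptides get
$a_p = \max(\text{unplanted}) \times U(2.5, 2.75)$, guaranteeing they
dominate every unplanted draw while staying tightly enough clustered
that the body→planted jump remains the dominant gradient at the curve's
high edge.

**Spot readout.** $I_s = b + a_p\,\varepsilon_s$,
$\varepsilon_s \sim \mathrm{LogNormal}(0, \sigma_{\text{rep}})$,
independent across replicate spots; defaults $b = 200$ scanner units
(the blank floor) and $\sigma_{\text{rep}} = 0.1$ (a 10% multiplicative
replicate scatter, the scale of spot-to-spot variability replicate
medians are meant to absorb). Because the noise multiplies the adhesion
term only, zero-adhesion spots read exactly $b$ — matching how empty
spots define a sharp background reference level in real scans.

**Image rendering.** `render_scan_image()` draws a Poisson number of
cells per spot (rate $\propto a_p$, default 0.1 cells per adhesion
unit), stamps each as a solid disk of fixed 7 µm radius (a simulation
convenience, not a biological claim) at a uniform position in the spot
footprint, accumulates overlaps, and adds constant background, optional
off-spot lawn cells, and Gaussian read noise, clamped to 16 bit. At the
default 5 µm/pixel a 120 µm spot is 24 × 24 pixels.

**What it does not emulate.** Synthesis failures and truncated peptides;
cell morphology, spreading and migration; island-like partial spot
filling; optical point-spread and scanner registration error; spatial
gradients across the chip. Passing recovery tests on this generator
therefore shows that the *analysis* is correct under the stated noise
model, not that any particular biological screen will be as clean: in
particular, the median-based readout saturates at background for spots
whose cells cover less than half the footprint (see below), and spatial
artefacts in real scans would first have to be removed by registration
and normalization steps that are out of scope here.

## Quantification

`quantify_spots()` takes, for every spot, the median over all pixels of
its rectangular synthesis footprint; even pixel counts average the two
central order statistics. There is no segmentation inside the footprint
— the synthesis rectangle defines the spot, cells do not — and no
background subtraction: the blank-spot median is *reported* alongside
each measurement, preserving the background as a visible reference level
instead of silently removing it. Grid registration is assumed exact
(simulator and quantifier share the layout object); registering a real
scanner image to the grid is out of scope.

`aggregate_replicates()` then takes the median over each peptide's
replicate spots — the per-peptide intensity *Int.* used everywhere
downstream. Medians at both levels make the readout robust to single
aberrant pixels and single failed spots.

A consequence worth knowing: the pixel **median** of a sparsely covered
spot equals the background, so the image route compresses the lowest part
of the adhesion range. The pipeline's default simulation route is
therefore the intensity table (the GPR-like readout real screens
export), with image rendering + quantification available as the explicit
scan-emulation route; the rank-recovery property (Spearman ≥ 0.9 between
latent adhesion and recovered medians at n ≥ 500 peptides) is tested on
the image route, where it holds because fewer than ~5% of peptides fall
below half-coverage at the default cell density.

## Ranked curve and extreme detection

`rank_curve()` sorts *Int.* ascending (ties broken by peptide id, so
ranking is deterministic) and attaches the discrete gradient
$g_i = I_{(i+1)} - I_{(i)}$. Specifically repellent and adhesive
peptides appear as steep gradient spikes at the curve's edges, against a
gradually rising body.

`detect_extremes()` formalizes "the regions of the curve's maximum
gradients": within the low-edge window (default the bottom 5% of ranks)
and the high-edge window (top 5%), gradients exceeding
`gradient_factor` × median(g) (default factor 3) count as spikes, and
the boundary on each side is the rank of the **largest** spike in the
window. We use the maximum-gradient rank rather than the innermost or
outermost spike because heavy-tailed intensity distributions produce
incidental spikes throughout their tails; the largest gap is the robust
estimate of where the specific population detaches from the body. When a
window holds no spike the side falls back to a plain quantile cut
(recorded in the detection report, and invariant under monotone
intensity transforms since it depends only on ranks) or, with
`fallback = FALSE`, makes no calls — so a flat or featureless curve
yields zero extremes rather than forced ones. Blanks are excluded before
ranking: they define the floor, they are not a peptide phenotype.

## Peptide properties

`compute_property_profile()` computes whole-peptide sums of per-residue
tables, shipped as named, swappable TSV data files: total charge
(K, R = +1; D, E = −1; H = 0 by default, configurable), total molecular
weight (average residue masses plus one water per intact chain — stated
explicitly because "sum of molecular weights" is ambiguous between free
amino acids and residues), total hydrophobicity *SH* (Kyte–Doolittle)
and total helix propensity *HP* (Pace–Scholtz helix-propensity
ΔΔG values). The analysis depends only on having a fixed per-residue
table, so any alternative scale can be supplied as a file.
`correlate_properties()` reports Spearman's rho with a two-sided
permutation p per property, uncorrected — only four descriptive
properties are tested, and the screen draws no inferential conclusion
from them.

## Substitution matrices and critical mutations

`build_substitution_matrix()` re-indexes the variant measurements of one
parent into a |parent| × 20 matrix (long tibble plus `submatrix_wide()`);
cells at the parent's own residue carry the parent's *Int.*, and missing
variants are masked, never imputed. `find_critical_substitutions()`
returns cells below a repulsion threshold; the default threshold is the
global blank median + 2 × blank MAD (`repulsion_threshold()`), treating
the empty-spot signal as the floor. The `specific` flag is true when the
same destination residue leaves the intensity above threshold at every
other position — separating position-specific switches (a critical
residue in a motif context) from residues that are repulsive wherever
they appear.

## Minimal motifs

For a maximal run of $r$ consecutive flagged window starts
$[i, i+r-1]$ at window length $k$, the residues shared by all windows
are $[i+r-1,\; i+k-1]$: a minimal motif of length $k - r + 1$. A single
flagged window ($r = 1$) reports the whole k-mer; a run of 13 windows at
$k = 15$ localizes a 3-residue core. Runs with $r > k$ share no residue
at all; they are reported with `core_empty = TRUE` and the run's span
instead of pretending to a motif. Calls map back to 1-based protein
coordinates and export as BED (0-based half-open, scored 0–1000 by
scaled mean intensity) plus a per-residue table for structure coloring.
The implementation is validated against a brute-force oracle that
intersects the windows' residue-position sets directly, and by planted
motif recovery (100/100 exact at lengths 3–15 under noise-free flags).

## Numerical and design choices

- **Seeding.** Every stochastic operation takes an explicit seed and runs
  in an isolated RNG stream; the pipeline derives stage seeds from one
  master seed, all below 2³¹. Identical configurations give
  byte-identical outputs, and every output file carries the
  configuration hash that produced it.
- **Ties.** Ranking ties break by peptide id; the sample median uses the
  mean of central order statistics; duplicate grid positions are a parse
  error, not a warning.
- **Degenerate inputs.** Proteins shorter than k, planted ids absent from
  the library, layouts exceeding grid capacity, footprints outside the
  image, thresholds outside the observed range and empty runs all raise
  explicit errors naming the offender; an empty motif-call list and a
  no-spike curve are valid results, not errors.
- **Problem sizes.** The test suite exercises full-scale library design
  (771/726/9,818 entries), a 5,000-peptide simulated screen with 50
  planted repulsive and 10 planted adhesive peptides for
  ordering-recovery and detection checks, an n ≥ 500 image-route
  recovery check, and 100 planted motif cases — sizes chosen so each
  statistical property is measured where it is meaningful while the
  whole suite stays fast enough to run routinely.

## Known limitations

- The random-group construction and the inclusion of parents in the
  substitution group are documented conventions where the chip-design
  description admits more than one reading; both are parameters.
- Extreme detection assumes the planted/specific populations separate
  from the body by gradient; phenotypes that grade continuously into the
  body have no detectable boundary and will be under-called (the
  quantile fallback then reports a fixed fraction, flagged as such).
- The image route's median readout is insensitive below ~50% spot
  coverage; rate-based (mean or count) readouts would extend the dynamic
  range but are not what spot-quantification software reports.
- Real-scan registration, normalization across chips, and any biological
  interpretation of particular sequences are out of scope.
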