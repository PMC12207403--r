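---
title: "Methods: detecting and annotating stable 3' RNA ends from Term-seq coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and annotating stable 3' RNA ends from Term-seq coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Term-seq libraries capture the 3' termini of RNA molecules: after adapter
ligation to RNA 3' ends, the 5' end of each sequenced read marks where a
transcript ended. Genome-wide, the per-base coverage of read 5' ends is
therefore a map of RNA 3' ends — a mixture of genuine transcription
termination sites (intrinsic and Rho-dependent), RNA processing sites,
and stable degradation intermediates, sitting on a noisy background of
spurious single-replicate signal. `termseqr` answers three questions:

1. Which 3'-end positions are *reproducible* across biological
   replicates (stable 3' RNA ends, summarized as points of observed
   termini, POTs)?
2. How *efficiently* does transcription terminate at each one, given
   matched RNA-seq coverage?
3. Which POTs are plausibly products of *intrinsic (Rho-independent)
   termination* — a G/C-rich hairpin immediately followed by a U-rich
   tract?

The package consumes per-replicate, per-strand, depth-normalized
coverage (bigWig or bedGraph; one file per strand, since bigWig has no
strand field), a genome FASTA, and a GFF3/GTF annotation. Read
preprocessing, mapping, and 5'-end coverage extraction are upstream
concerns and out of scope.

## Peak calling and trimming

Peaks are called independently per replicate and strand with
deliberately relaxed settings (`min_height = 0`, `min_distance = 1`):
every local maximum of the coverage vector becomes a candidate, because
the decision about what is real is delegated entirely to the
reproducibility filter. The raw span of a peak is the maximal contiguous
run of non-zero signal containing the apex; prominence is the apex
height minus the higher of the two flanking minima (track ends count as
base level zero).

Each peak is then trimmed: with `S` the total coverage of the peak and
threshold `0.10 * S`, positions are removed from each end, moving
inward, while their coverage is strictly below the threshold. Trimming
stops at the first retained position, never removes the apex, and is
idempotent. We read the trimming rule as *iterative end-inward removal
with a strict comparison* because that narrows the span to the region
of the most probable 3' end while guaranteeing a non-empty result; the
interpretation is pinned by a brute-force equivalence test on random
profiles. The trimmed result is insensitive to the raw-span convention
for well-formed peaks, which is why the simple contiguous-non-zero
definition suffices.

## The reproducibility filter (IDR)

For every unordered pair of replicates, overlapping trimmed peaks are
matched one-to-one (maximum base overlap, ties by higher joint
prominence, then leftmost start), and the paired prominence scores are
modeled with an irreproducible-discovery-rate copula mixture (after Li,
Brown, Huang & Bickel 2011): ranks of each score vector are mapped
through the pseudo-inverse of the marginal of a two-component bivariate
Gaussian mixture — a reproducible component with weight $\pi_1$, mean
shift $\mu$, variance $\sigma^2$ and correlation $\rho$, and a noise
component fixed at the standard bivariate normal with zero correlation.
Parameters are fitted by EM; each iteration refreshes the pseudo-data
from the current parameters and takes one EM step, stopping when the
log pseudo-likelihood changes by less than 1e-6 or the parameters move
by less than 1e-4 (cap 500 iterations; initialization
$\pi_1 = 0.5, \mu = 1, \sigma^2 = 1, \rho = 0.5$). The single-step
refresh is used because running the inner EM to convergence between
refreshes lets the model drift toward fitting the marginal ranks
instead of the dependence structure; with single steps the planted
mixing weight in simulations is recovered within a few percent. The fit
is deterministic: ties in scores are broken by average rank, so the
`seed` argument exists only for interface stability.

The *local* IDR of a pair is its posterior probability of arising from
the noise component; the *global* IDR at rank $k$ (pairs sorted by
local IDR) is the mean of the $k$ smallest local values — the expected
irreproducibility rate among the top $k$. The threshold (default 0.05)
is applied to the global IDR, the convention of the IDR method this
filter follows; a switch (`threshold_on = "local"`) is exposed because
the choice is genuinely open. One model is fitted per replicate pair
and strand, pooling contigs, because the EM needs a reasonable number
of pairs (`min_pairs`, default 20) to be stable.

A peak region is reported as a stable 3' RNA end iff it attains an IDR
below the threshold in at least `min_no_comp` (default 1) pairwise
comparisons. Passing regions are unioned across replicates; each merged
region carries its minimum IDR, its support count, and a summit — the
argmax of the cross-replicate mean coverage, with ties resolved to the
most downstream position in transcription direction (largest coordinate
on `+`, smallest on `-`). "Highest point of the peak across replicates"
could also mean the max of per-replicate maxima; we use the mean
because it is robust to a single deep replicate and consistent with the
cross-sample merging rule.

## Termination efficiency

With matched RNA-seq coverage, the termination efficiency at a summit
is

$$T = \frac{u - d}{u} \cdot 100\%$$

where $u$ and $d$ are means of the replicate-averaged coverage over the
10 positions from 13 to 4 bases upstream and from 4 to 13 bases
downstream of the summit (transcription direction; the three positions
nearest the summit on each side are excluded to avoid the pileup edge
itself). Replicates are averaged before the windowed means, since the
quantity is defined on the pooled coverage of all replicates. The
estimate is reported only when $u \ge$ `min_upstream` (default 0.25
RPM); we resolved the strict-versus-inclusive ambiguity as inclusive
($\ge$). Negative values (coverage rising across the site) are reported
as-is and flagged `readthrough_gain` — clamping would hide processing
artifacts.

## Intrinsic-terminator calling

Two protocols examine the sequence upstream of each POT; hairpins are
simple contiguous stem-loops (Watson-Crick and G·U pairs, no bulges in
this version — a bulge-tolerant mode is deliberately deferred because
the loop/stem limits are stated for simple stem-loops).

**Genome scan (canonical criteria).** Stem of at least 4 pairs, loop
3-13 nt, stem-loop at most 59 nt, at least 3 U in the 6 nt after the
stem, and a free energy at or below 0 kcal/mol (a stem-loop not
predicted to form at all is not a candidate — without this, spurious
weak stems pairing into the U tract can shadow the real hairpin). The
nearest qualifying hairpin whose 3'-most paired base lies within
`distance_range` (default 0-10 nt) upstream of the POT is assigned;
ties go to the lower hairpin score. The scan is performed in a window
just wide enough to contain every hairpin that could satisfy the
distance rule, which is equivalent to a genome-wide scan restricted to
the assignment range. An adapter (`read_terminator_bed()`) lets users
substitute externally produced genome-wide predictions.

**Local scan (permissive criteria).** The window from 80 nt upstream to
30 nt downstream of the POT is scanned with permissive limits (min stem
4, loop 4-20, stem-loop at most 40 nt, at least 1 U in the 6 nt after
the stem) to catch real terminators with weak or absent U tracts.
Candidates within the distance range are ranked by confidence, then
hairpin score, then tail score — in that order — and the best candidate
is verified thermodynamically: its free energy must be at most
-3 kcal/mol.

Distance is measured from the hairpin's 3'-most *paired* base (not the
first U-tract base); the alternative convention would shift all
distances by one and is noted as an open choice.

Three scores describe each candidate:

* **Hairpin score** — additive per-pair heuristic (G-C -2.3, A-U -0.9,
  G·U +1.3, +0.1 per loop base; lower = stronger). These constants are
  package defaults exposed in the configuration; the score ranks
  candidates and approximates relative stability, it is not a free
  energy.
* **Tail score** — U-richness of the 15 nt after the stem, weighted
  toward the hairpin: $ts = -\sum_{n=1}^{15} x_n$ with $x_0 = 1$ and
  $x_n = 0.9\,x_{n-1}$ if base $n$ is U, $0.6\,x_{n-1}$ otherwise.
  Bounded between $-9(1-0.9^{15})$ (all U) and $-1.5(1-0.6^{15})$ (no
  U); every non-U→U substitution strictly decreases it. Tails truncated
  by a contig edge are padded as non-U and flagged.
* **Confidence** — a 0-100 logistic combination,
  $100\,\mathrm{logit}^{-1}(-(hs + ts + 8)/4)$. The original
  genome-wide scanner uses a confidence value whose exact formula lives
  in its own publication; ours is a documented, configurable
  approximation calibrated so that a strong hairpin with a proximal U
  tract scores above 90 and a weak hairpin with no tract below 35.
* **Free energy** — the default backend is an internal simplified
  nearest-neighbor model (published Turner-style stack energies for
  Watson-Crick stacks, representative values for G·U stacks,
  hairpin-loop initiation by size with Jacobson-Stockmayer
  extrapolation, +0.45 terminal A-U/G·U penalty). It is deterministic
  and needs no external process; a `"rnafold"` backend shells out to
  ViennaRNA for full Turner-model folding, and the test suite pins the
  internal model to within 2 kcal/mol or 30% of ViennaRNA on a fixture
  panel. U and T are treated identically throughout.

**Atlas selection.** For a high-confidence intrinsic-terminator set,
`atlas_filter()` keeps POTs at most 200 nt downstream of the nearest
same-strand CDS that carry a call from either protocol, requiring
calls confirmed *only* by the local scan to have free energy at most
-8 kcal/mol.

## Merging and annotation

Stable ends from multiple samples are merged by single-linkage interval
overlap per strand — full trimmed regions, not summit points, define
overlap, matching the merge of "overlapping positions of peaks" —
and each merged region is summarized by the position of highest
cross-sample mean coverage (downstream tie-break). Gene context reports
overlapping features of any type plus nearest same-strand and antisense
genes upstream/downstream with 0-based gap distances (the number of
bases strictly between POT and gene; 0 when overlapping or adjacent);
`gene` features are preferred, with `CDS` as fallback for
annotations without gene rows. Custom BED sets attach per-POT overlap
flags and record names under half-open BED semantics. Output formats:
narrowPeak (BED6+4) with `score = min(1000, round(-125 log2 IDR))`,
`qValue = -log10(IDR)` and the summit offset in the `peak` column —
encodings of our choosing, since only the format itself is standard —
and a versioned tab-separated annotation table with a constant column
set and explicit `NA`s, the POT base capitalized inside the reported
sequence context.

## The synthetic-data generator

`simulate_genome()` / `simulate_coverage()` define the desk-scale study
conditions used by the tests and the acceptance script:

* genome 60 kb, 55 CDS genes in equal slots with alternating strands,
  50 planted terminators (GC-rich stem 6-10 bp, loop 4-6 nt, U tract
  with 6-9 U; 10% get a weak dispersed 3-U tract that only the local
  scan should call);
* per-terminator expression factors, log2-uniform in [-1, 1.5], shared
  across replicates — without expression variation, replicate
  prominence ranks would be uncorrelated even at real sites and no
  rank-based reproducibility measure could work;
* planted termination efficiencies uniform in 20-95%;
* 3 replicates with depth factors 0.8-1.2x (to exercise
  normalization), Poisson 5'-end counts spread over the termination
  position ±2 nt (weights 0.05/0.15/0.60/0.15/0.05), 100 noise peaks
  per replicate at independent random positions with low, varying
  Poisson counts;
* RNA-seq as piecewise-constant transcript coverage dropping by the
  planted efficiency at each terminator (300 nt of readthrough),
  per-base Poisson noise, CPM-normalized.

The generator emulates replicate-consistent signal, irreproducible
noise, and efficiency steps; it does **not** emulate Rho-dependent
diffuse 3'-end signal, overlapping transcription units, sequencing
biases, or read-level artifacts — so passing tests demonstrate
correctness of the algorithms under the stated model, not performance
on any real library. Problem sizes (60 kb, 50 sites, 3 replicates,
2000 IDR pairs) were chosen as the smallest at which the statistical
components are well-conditioned: about 25 matched peak pairs per strand
per replicate pair is comfortably above the EM's `min_pairs` floor, and
Poisson depths of 30-120 reads per base give the efficiency estimator
a standard error near 2 percentage points, so recovery within ±5
points is a meaningful check rather than a coin flip (per-site
efficiency estimates at the 20-read floor have a standard error near
3.5 points, which is why the recovery criterion is stated as mean
absolute error and the fraction of sites within ±5 points rather than
a per-site guarantee).

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive internally (the R/Bioconductor
  convention used by every container this package builds on); BED,
  bedGraph and narrowPeak conversion happens at the I/O boundary.
* Reverse-strand tracks stay in genomic orientation; strand is resolved
  at use sites (summit tie-break, efficiency windows, scan windows).
* The copula marginal's pseudo-inverse is evaluated on a 4096-point
  monotone grid spanning both components to ±6 SD.
* Flat tracks produce zero peaks; an all-zero track writes a file with
  no data intervals; a peak of one position trims to itself.
* Efficiency windows extending past a contig edge are not evaluable
  (`window_out_of_bounds`); terminator-scan windows truncated at an
  edge are scanned as-is and flagged.
* With fewer than `min_pairs` matched pairs the IDR fit refuses to run
  rather than returning an unstable estimate; with fewer than two
  replicates the find command refuses to run.
* EM non-convergence within the iteration cap returns the last iterate
  with a warning — this occurs in near-degenerate regimes (almost all
  pairs reproducible, or pure noise) where the IDR ordering is still
  usable even though the likelihood surface is flat.

## Limitations

Rho-dependent terminators produce diffuse 3'-end signal and are outside
the model. Stems with bulges or internal loops are not enumerated.
The internal energy model is a deliberate simplification of the full
Turner model (no dangling ends, no tetraloop bonuses, representative
G·U stack values). Overlapping terminators are not deconvolved. The
confidence score and the hairpin-score constants approximate, but do
not reproduce, the original genome-wide scanner's internal scoring.
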