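---
title: "Simulating and analysing CRISPR-induced global chromosome rearrangement"
author: "gcrsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing CRISPR-induced global chromosome rearrangement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcrsim)
```

## The biological setting

Mammalian genomes carry enormous numbers of dispersed retroelement
copies: on the order of 5 x 10^5 LINE-1 (L1) elements and more than 10^6
Alu elements in human. A single CRISPR-Cas9 guide matching a conserved
region of such a family targets thousands to hundreds of thousands of
sites at once. Sustained expression of Cas9 with such a guide produces
many simultaneous double-strand breaks (DSBs); the cell's non-homologous
end joining (NHEJ) machinery rejoins the free ends, frequently in the
wrong order or orientation. Cells that survive carry *global chromosome
rearrangement* (GCR): hundreds of translocations and inversions,
segmental losses and gains, visible as copy-number variation (CNV)
against a matched control line.

`gcrsim` implements this process as a fully observable simulation, plus
the analyses used to characterise such genomes:

* binned read-depth CNV differencing between a rearranged sample and the
  control;
* permutation (shuffle) tests for enrichment of breakpoints in region
  sets such as high-CNV regions;
* a Monte-Carlo null for the intra- versus inter-chromosomal split of
  translocations;
* breakpoint-to-nearest-repeat distance profiles;
* long-read translocation calling anchored on repeat elements.

Because every stage consumes standard formats (FASTA, BED, BEDPE, PAF,
TSV), the same analysis functions apply unchanged to real data products
(aligner outputs, SV caller breakpoint lists, RepeatMasker annotations).

## The synthetic genome and what it does and does not emulate

`generate_genome()` draws i.i.d. bases at a configurable GC fraction
(default 0.41, the human genome-wide value). `embed_repeats()` writes
non-overlapping copies of an L1-like (6 kb) and an Alu-like (300 bp)
consensus at uniform positions on random strands. A 20-nt guide
protospacer, followed by a TGG PAM, sits at a fixed offset (default 100)
inside each consensus; declared fractions of the copies carry the exact
protospacer, 1- or 2-mismatch variants, or an ablated (non-targetable)
guide region, and all non-guide positions are diverged per copy at a
configurable substitution rate (default 5%).

The default scale is 4 chromosomes x 2.5 Mb (10 Mb total) with 50 kb CNV
bins — a 1/300 linear scale-down of a 3 Gb genome analysed in 500 kb
bins. Scale lives entirely in the configuration, not in the code.

Deliberate simplifications (hence limits on what passing tests show
about real data): repeat copies never overlap or nest, there is no
repeat phylogeny or truncation structure, base composition is i.i.d.
rather than isochore-structured, and the genome is haploid. Tests passing
on this generator demonstrate algorithmic correctness and statistical
calibration, not robustness to the full repeat complexity of a real
genome; for that, the PAF import path exists so that a production
long-read aligner can replace the builtin mapper.

## Guide target enumeration

`find_guide_matches()` reports every 20-bp window on either strand
within Hamming distance 0–2 of the guide — the all-alignments census a
short-read aligner run with "report all, up to k mismatches" settings
would produce. Overlapping sites are all reported; ambiguous bases never
match; a reverse-strand site is reported at the leftmost base of its
window. PAM filtering (`NGG`, strand-aware, `N` wildcard) is available
but off by default, because raw site censuses of this kind are sequence
matching only. The scan is vectorised per guide position (20 vector
comparisons per strand per chromosome), and its contract is set equality
with a naive per-window oracle, which the test suite enforces on small
genomes directly and on megabase genomes against an independent
`Biostrings::matchPattern()` oracle.

The package ships the three guides used throughout (`gcr_guides`): an
L1-targeting guide, an Alu-targeting guide, and a no-target negative
control.

## The cut-and-rejoin model

`select_cut_sites()` cleaves each matching site independently with
probability `cut_probability`. The blunt cut falls `cut_offset = 17`
bases into the protospacer on its own strand — the canonical Cas9 cut 3
bp 5' of the PAM, encoded as a documented default rather than hard-wired.

`rejoin()` splits chromosomes at the selected cuts and reassembles:

* Internal segments (both ends free) are lost with
  `segment_loss_probability` and duplicated with
  `segment_duplication_probability`. Telomeric segments are exempt, which
  guarantees that every derivative chromosome begins and ends with an
  original telomere. Free-end parity is checked as an internal invariant.
* Each free end may be resected by 0..`end_resection_max` bp (default 0,
  keeping base accounting exact).
* Free ends are then paired *sequentially*: an open derivative's end
  draws a partner with weight `intra_bias * exp(-d / distance_scale)`
  for ends on the same source chromosome at distance `d`, and uniform
  weight `1 - intra_bias` otherwise. Sequential random matching (rather
  than a global optimum) mirrors the stochastic biology and is O(n^2) at
  worst, ample at desk scale. Closing a derivative with a telomeric
  segment is forbidden while unplaced internal segments remain, so
  assembly always terminates with telomere-capped linear chromosomes and
  no circles.

Junctions are recorded with the read-pair strand convention (`+` = the
joined piece lies below the breakpoint) and classified from local
geometry: different chromosomes give `translocation_inter`, equal
strands give `inversion`, and opposite-strand same-chromosome joins are
`deletion`/`duplication` only when the skipped or re-covered interval
was genuinely lost or duplicated (the simulator knows), otherwise
`translocation_intra`. Perfect religations with no trimmed bases restore
the original sequence and are not recorded. There is no microhomology
model: junctions are clean or resected blunt joins, because no
junction-sequence model is available to parameterise one.

Copy-number ground truth is kept in source-genome coordinates (all CNV
analyses operate in reference coordinates): per bin, the mean per-base
copy count implied by the derivative segment map. An exact integer
accounting identity — derivative bases + lost bases = source bases +
duplicated bases — holds whenever resection is off and is enforced in
the tests.

Realised intra-chromosomal fractions depend on cut density as well as
`intra_bias`: with few ends, the exponential kernel dominates; with many
ends the uniform inter-chromosomal mass grows. The tested property is
monotonicity in `intra_bias`, not a specific fraction.

## Short-read counts and CNV statistics

Read counts are simulated per bin directly, `Poisson(depth x copy /
baseline_ploidy)`, with no alignment stage: the downstream statistic
consumes per-bin match counts, so an alignment step would add an
external tool without exercising any analysis code. Depth defaults to
100 reads per copy-neutral bin.

`cnv_difference()` subtracts binned counts (rearranged minus control) on
a shared grid. With `total_count` normalisation (default) the rearranged
sample is rescaled to the *control* library size before subtraction, so
the profile lives on the control's depth scale and is exactly invariant
to the rearranged sample's sequencing depth. A symmetric
"scale-both-to-the-mean" variant would leave the profile's overall scale
dependent on both libraries; anchoring to the control was chosen so the
control defines the reference frame. Whether real libraries should be
normalised at all is data-dependent, so `normalization = "none"` is
also provided.

"High-CNV" has no canonical definition; the default rule,
`abs_quantile(0.95)`, flags bins whose `|difference|` exceeds the 95th
percentile of the profile and merges adjacent flagged bins. It is
scale-free (robust to depth) and matches the visual treatment of
extremes in genome-wide CNV heatmaps; an `abs_z(t)` rule is available
when an absolute threshold is preferred. `common_regions()` intersects
two region sets base by base (via `IRanges`), and `cnv_correlation()`
fits ordinary least squares per bin or on per-chromosome sums,
reporting R², slope and intercept. `interval_coverage_ratio()` computes
mean-depth ratios between two intervals — e.g. an integrated nuclease
cassette relative to a selection marker that every surviving cell
retains, the signature used to detect loss of the nuclease gene itself.

## Breakpoint statistics

**Permutation enrichment.** `permutation_enrichment()` holds breakpoints
fixed and re-places the region set uniformly at random, lengths
preserved, without overlap, `n_perm = 1000` times by default. Placement
uses the exact gap-insertion construction (draw starts in the genome
shrunk by the total region length, re-expand), retrying draws that cross
a chromosome boundary; shuffling is genome-wide, matching the default
behaviour of the standard interval-shuffling tools, with the same-
chromosome variant intentionally out of the default path. The one-sided
upper-tail P uses the normal approximation to the permutation null
(enrichment is the hypothesis of interest), with an empirical P reported
alongside; a degenerate null (no breakpoints, zero variance) reports
P = 1 with a flag. Counting defaults to `per_breakpoint` — each junction
end counts separately, reflecting that each breakpoint is a distinct
site — with `per_junction` as an option.

**Monte-Carlo intra/inter null.** `mc_intra_inter()` draws `n_events`
random breakpoint pairs per run — each endpoint lands on a chromosome
with probability proportional to its length — and averages intra/inter
counts over `n_runs = 10` runs. The observed split is compared with the
expectation by a 1-df chi-square goodness of fit without continuity
correction (two categories, expected counts from the averaged runs). The
exact closed form for the null intra fraction, `sum((L_i/L)^2)`, is
computed alongside and the simulated fraction is validated against it;
endpoints are drawn independently with no distance kernel, because this
is the *null* — the simulator's `intra_bias` provides the alternative.
One run's coordinates are retained for 2D plotting.

**Nearest elements.** `nearest_element_distance()` scans, for each
junction end, the repeat elements of the requested class on the same
chromosome; distance is 0 inside an element and the gap to the closest
boundary otherwise, binned into the categories in-element, <1 kb,
1–10 kb, 10–100 kb, >100 kb. Overlapping or nested elements (as in real
RepeatMasker tables) are handled with a running-maximum scan, and
chromosomes lacking the class yield an explicit `no_element_on_chrom`
category rather than an arbitrary large distance.

**2D linearisation.** `linearize_breakpoints()` maps each junction to a
single (x, y) point on the concatenated genome, with end A canonically
the smaller (chromosome index, position); intra-chromosomal events
cluster around the diagonal in `plot_breakpoints_2d()`.

## Long-read translocation calling

The caller reproduces the classic repeat-anchored workflow: reads at
least 500 bp long (with the injected error rate standing in for a mean
base-quality filter on synthetic FASTA — real FASTQ qualities are used
when present) are screened for element content, and reads whose element
is flanked by sequence from *different chromosomal parts* yield calls.

* `find_element_reads()` seeds each read with 12-mers from each
  consensus (both orientations); the seed-count threshold adapts to the
  chance-match rate between the read and the seed table, so long random
  reads rarely trigger alignment against a long consensus. The dominant
  diagonal cluster of seeds is kept and refined with a banded
  Smith–Waterman local alignment
  (match +1, mismatch −1, gap −2; implemented in C++ with start
  coordinates and match counts propagated through the DP so no traceback
  is needed). A hit requires identity ≥ 0.8 over the aligned span and an
  aligned span ≥ 100 bp.
* `map_flanks()` maps the sequence on either side of the element with
  the builtin mapper: anchors are k-mers (k = 14) unique in the
  reference, chained by diagonal within a band; identity is estimated
  from anchor density as `(matched/possible)^(1/k)`. Chains below 0.5
  estimated identity are dropped at the mapper, and calling requires
  ≥ 0.8 — at 5% read error the true-chain estimate is ≈ 0.95 while
  chance anchor clusters sit near 0.6, so the bands are well separated.
  The mapper is intentionally minimal; correctness on repeat-rich flanks
  is explicitly delegated to PAF imported from a production long-read
  aligner (`paf_to_split_alignments()`), which slots into the same
  calling step.
* `call_translocations()` requires a mapped flank of ≥ 200 bp on both
  sides, reaching to within 150 bp of the element boundary (a gap means
  the element-adjacent locus is unresolved and the read is discarded
  rather than risk a misplaced breakpoint). "Different chromosomal
  parts" is quantified as: different chromosome, OR the same chromosome
  more than 100 kb apart (safely beyond any intact element locus), OR
  strand-inconsistent orientation. Breakpoints are the element-proximal
  ends of the two flank alignments — within an element length of the
  true junction, so a 300 bp anchor element localises breakpoints well
  inside the ±500 bp matching tolerance used throughout. Per-read calls
  are clustered within ±500 bp on both ends (resection/error jitter) and
  support accumulated; `min_support` defaults to 1.
* `evaluate_calls()` matches calls to simulated truth greedily, 1-1, by
  increasing distance, both ends within ±500 bp.

The validation scene for the caller is 10 Mb, ~30 junctions anchored in
Alu-like elements, 15x long-read coverage at 8 kb mean length. Alu-like
elements anchor the scene because a 300 bp element bounds the
breakpoint-localisation error well below the matching tolerance; a 6 kb
L1 anchor localises breakpoints only to within the element and needs
junction-aware split alignments (the PAF path) for the same resolution.
On that scene the caller attains precision = recall = 1.0 on
inter-chromosomal junctions with error-free reads and stays above
0.95/0.9 at 5% read error.

## The pipeline, seeds and degenerate inputs

`run_all()` wires the stages together per guide arm — including the
negative-control guide, whose arm must and does produce zero cuts, zero
junctions, a zero-mean CNV profile and a degenerate (P = 1) permutation
test. Every stochastic stage derives its own seed from the base seed, so
any stage can be re-run without disturbing the rest; the report is
byte-identical across runs with the same configuration. Wall times go to
a JSON-lines log only, never into the report. Numerical edge cases are
handled explicitly rather than by accident: zero-variance permutation
nulls report P = 1 with a `degenerate` flag, empty junction sets refuse
the Monte-Carlo test with a clear error, a zero-count library refuses
normalisation, and region shuffles that cannot fit error out rather than
loop.

Validation scales, chosen to exercise each method at the scale its
guarantees are stated for while keeping a full run on one CPU in
minutes: guide-search oracle equivalence on ten 1 Mb genomes; simulator
conservation at 10 Mb with 200 cuts; CNV recovery over 20 simulated
genomes at depth 100 per bin; permutation calibration over 500 null
datasets of 150 junctions (200 permutations each — the 1000-permutation
default applies to a single analysis, not to a 700-dataset calibration
study) with type-I error required inside [0.03, 0.07] and power ≥ 0.9 at
2x enrichment; Monte-Carlo closed-form agreement at 10^5 pairs; and the
long-read scene above.

## Known limitations

* The simulator models only guide-directed cuts; secondary DSBs arising
  from ongoing genome instability in real GCR cells are not modelled, so
  real breakpoint-to-element distance profiles will have a heavier far
  tail than simulated ones.
* End pairing is uninformed by nuclear organisation; contact-informed
  rejoining (e.g. Hi-C-weighted) is out of scope.
* The builtin flank mapper requires unique k-mer anchors and will not
  resolve flanks that are themselves repetitive; import PAF from a real
  aligner for such data.
* Junction classes for same-chromosome joins are assigned from local
  geometry plus simulator ground truth; on imported (real) breakpoint
  lists only the geometric classes are available.
* `deletion`/`duplication` classes, segment-level ploidy and haplotype
  phasing are simplified to a haploid frame.
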