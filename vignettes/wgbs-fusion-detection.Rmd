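---
title: "Targeted fusion detection from WGBS alignments: model and methods"
author: "wgbsfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted fusion detection from WGBS alignments: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Whole-genome bisulfite sequencing encodes methylation in the read
sequence itself: unmethylated cytosines are converted to uracil and read
as thymine. The price is reduced sequence complexity and heavier
fragmentation, which is why structural-variant analysis is usually done
on separate WGS or RNA-seq libraries. Yet when the question is narrow —
*is a known fusion between gene A and gene B present in this sample?* —
the alignments a bisulfite-aware, split-capable aligner produces already
contain the answer. `wgbsfuse` implements that targeted fusion call,
together with the supporting metrics a validation study needs and a
simulator that generates fully controlled WGBS fusion data with ground
truth.

This vignette explains the evidence model, every tunable parameter with
its default and rationale, the simulator's design and its limits, the
numerical choices made where the design was genuinely open, and the
problem sizes used by the validation suite.

## The evidence model

All coordinates are SAM-native: 1-based, inclusive. BED input (0-based,
half-open) is converted at the boundary by `read_targets_bed()`.

A *target pair* is two named, disjoint gene intervals. From a
coordinate-sorted SAM/BAM, `fetch_pairs()` extracts read pairs where at
least one mate's primary alignment overlaps either interval with at
least one aligned (non-clipped) reference base. Secondary and
supplementary records never enter pairing; the content of supplementary
alignments reaches the caller only through the `SA:Z` tag of primaries.
`pass_filters()` then requires both mates mapped, neither flagged
duplicate (duplicate marking is assumed upstream; the package does no
duplicate detection of its own), and both with MAPQ ≥ 20.

Each filtered pair receives exactly one class:

* **split** — one mate lies in one target gene and carries an SA entry
  whose alignment reaches the other target gene, while its mate maps to
  that other gene (`mode = "strict"`) or to either gene
  (`mode = "lenient"`);
* **discordant** — the mates' primary alignments lie in the two
  different target genes and neither carries a qualifying SA entry;
* **none** — everything else.

A pair satisfying the split condition is never also counted discordant,
so split + discordant = total always. If both mates carry qualifying SA
entries the pair is classified split once and flagged ambiguous.

For each split read, `locate_breakpoint()` reads the junction off the
clip boundaries: for an alignment whose leading clip is at least its
trailing clip, the boundary is the first aligned base (`pos`); otherwise
it is the last aligned base (`pos + reference span − 1`). The rule is
applied independently to the primary CIGAR and to the SA entry's CIGAR.
Both are expressed in their own reference orientation, which is how
strand is accounted for: a junction segment that aligns to the minus
strand simply presents its clip on the opposite side. Soft and hard
clips count alike for side determination, since aligners typically
soft-clip the primary record and hard-clip the supplementary. Unique
(posA, posB) pairs are tallied with their support; deduplication is at
exact coordinates (a window option was considered and rejected as the
oracle data shows zero coordinate jitter; windowed merging can be done
downstream on the breakpoint table).

A sample is *detected* when total fusion read pairs ≥ 1
(`detection_min`, configurable). Fusion-negative controls show zero
pairs in the target region, which is what makes a single supporting pair
meaningful in the targeted setting.

### Open choices and how they were settled

* **Strict vs lenient mate placement.** The narrow definition requires
  the split read's mate in the *other* gene. But a fragment whose
  junction falls near one end places the mate on the *near* side of the
  breakpoint — same gene as the split read's primary. Strict mode
  follows the narrow definition and is the default; lenient mode accepts
  either gene. On oracle data, strict discards roughly half of the
  junction-crossing read-2 events, so the validation suite and the
  pipeline use lenient mode; both are exposed and counts are comparable
  across a study as long as one mode is used throughout.
* **SA entry selection.** When several SA entries exist, the entry
  overlapping the partner gene with the highest SA MAPQ wins; ties break
  by lowest NM, then leftmost position. SA entries are also required to
  meet the same MAPQ threshold as primaries — symmetric filtering is the
  conservative reading.
* **Clip-side ties.** With equal leading and trailing clips the leading
  side is used. This cannot occur on oracle alignments (one side is
  always the clip) and is a documented tie-break, not a tuned value.
* **No minimum split-segment length in the caller.** The aligner (or
  oracle simulator) already refuses to report supplementary alignments
  shorter than its seed length; the caller trusts the SA tag it is
  given.

## Supporting metrics

* `depth_profile()` bins mean coverage from aligned reference-consuming
  bases of primary, non-duplicate records; clipped bases contribute
  nothing. This is deliberately the quantity in which a fusion junction
  appears as a local dip: reads crossing the junction align split, so
  half of each crossing read is clipped away. Depth conservation holds
  exactly: sum(bin depth × bin width) equals aligned bases in the
  region.
* `downsample_pairs()` keeps a qname when a seeded 32-bit hash of the
  name, mapped to [0, 1), falls below the target fraction. Hashing by
  qname rather than per record keeps mates and supplementaries together
  and makes subsets nested (a 20% subset is contained in the 50% subset
  under the same seed) and reproducible across runs and platforms.
* `background_scan()` operationalizes a "fusion-like pair anywhere in
  the genome" as: mates on different contigs, mates more than
  `min_distance` apart on the same contig (default 1 Mb), or an SA entry
  crossing such a distance. The target/background partition counts a
  chimeric pair *inside* when both ends lie within the target intervals;
  everything else is genome-wide background. Inside + outside = total,
  no pair double-counted.
* `conversion_rate()` computes per-context conversion from the reads
  themselves. The conversion strand of a record follows the
  directional-library rule (read 1 equals the converted strand in
  reference orientation when mapped forward; the complement otherwise):
  a record observing the top strand is informative at reference C
  positions (T = converted, C = retained), a bottom-strand record at
  reference G positions (A = converted, G = retained). Context is taken
  from the reference trinucleotide, strand-aware. On an unmethylated
  control the all-context rate estimates conversion efficiency; on a
  CpG-methylated control `cpg_retention()` reports 1 − CpG conversion.
* `replicate_concordance()` is plain Pearson correlation of per-target
  split, discordant and total counts between replicate call tables, with
  zero-variance inputs rejected rather than returning NA.

## The limit of detection

Detection is binary per sample. Over a dilution series with fractions
$x$ (percent fusion-positive DNA) the detection probability is modelled
as $\Pr(\text{detect}) = \Phi(a + b x)$, fitted by maximum-likelihood
binomial regression with a probit link (`glm`), and the LoD at
confidence $c$ (default 0.95) is $(\Phi^{-1}(c) - a)/b$.

Two specification choices are genuinely open and both are exposed:

* **Fraction scale.** Linear percent is the default; log10 is offered.
  On the log scale zero-fraction controls cannot enter and are dropped
  with a message.
* **Zero-fraction negative controls.** Included by default
  (`include_zero = TRUE`); a flag excludes them.

`lod_configurations()` fits all four combinations side by side. On the
reference dilution table (triplicates; 0%: 0/3, 2%: 1/3, 5%: 2/3,
10–100%: 3/3) they give 7.36, 8.08, 9.32 and 9.32%; the linear-scale fit
on the non-zero fractions is the configuration that reproduces the
published style of estimate and is the one the acceptance script
reports. High dilution points that are all detected produce
quasi-separation warnings from `glm`; the fit is still the MLE and is
flagged (`separation`) rather than silently accepted or rejected. A
non-positive fitted slope makes the LoD non-identifiable and is reported
as such, never clamped to a number.

`probit_lod()` returns a classed model object with the usual verbs —
`coef()`, `predict()`, `residuals()`, `plot()`, `summary()` (including a
delta-method standard error for the LoD) — and
`simulate_detection_curve()` draws detection outcomes from a known curve
for validation.

## The simulator

The simulator stands in for both the wet-lab dilution series and the
aligner, so that every downstream claim can be checked against known
truth.

* `make_toy_reference()` draws two uppercase A/C/G/T contigs (default
  50 kb each, GC 0.42 — human-like) and annotates one gene per contig
  spanning the central 60%. Distinct contigs make any read pair joining
  the genes unambiguously chimeric.
* `plant_fusion()` joins gene A's retained left side (contig start
  through `posA`) to gene B's retained side from `posB`, either forward
  (`orientation = "same"`) or as the reverse complement of the slice up
  to `posB` (`"opposite"`), recording the junction offset.
* `simulate_fragments()` draws each fragment from the fusion allele with
  probability `fraction`, otherwise from the wildtype gene loci.
  Fragment count is set so expected coverage over the two gene intervals
  approximates `depth`. Lengths are Normal(`fragment_mean`,
  `fragment_sd`) truncated below at `read_length`. A fusion fragment is
  marked junction-spanning when it covers the junction boundary.
* `bisulfite_convert()` models a directional (OT/OB) protocol: a strand
  is chosen uniformly per fragment; each cytosine on the converted
  strand is first assigned methylated with its context probability
  (CpG/CHG/CHH, context from the unconverted sequence plus two flanking
  reference bases so edge cytosines are classified correctly), then, if
  unmethylated, rendered as thymine with probability `conversion_rate`.
  Read 1 is the converted strand's 5' end, read 2 the reverse complement
  of its 3' end, so read 2 shows the complementary G→A pattern in
  sequencing orientation.
* `emit_oracle_sam()` places every read at its true wildtype locus.
  Junction-crossing reads get a soft-clipped primary for the longer
  segment and a hard-clipped supplementary for the shorter one with
  reciprocal SA tags; segments shorter than `min_clip` (default 20 bases
  — below typical aligner seed lengths a split would not be reported)
  are absorbed into the clip. Optional knobs emit exact-duplicate pairs
  flagged with the SAM duplicate flag (`dup_rate`), low-MAPQ fragments
  (`lowmapq_rate`, exercising the MAPQ filter), and artificial
  inter-contig pairs at random non-gene positions (`n_chimeric`,
  exercising the background scan).

Defaults are chosen once to match the emulated study conditions:
`read_length` 100, `fragment_mean` 300 with sd 30 (sonication to
~300 bp), `conversion_rate` 0.99 (typical enzymatic/bisulfite
efficiency), `meth_cpg` 0.8 with low CHG/CHH (human somatic
methylome), oracle MAPQ 60 for unique placements, base qualities
constant Q37, `seq_error` 0. Identical configuration and seed give
byte-identical FASTQ/SAM/truth outputs; all randomness flows through a
single seeded stream per simulation.

**What the simulator does not emulate** — and hence what passing tests
do and do not show about real data: indels and CNVs, non-directional
(PBAT) libraries, realistic quality/error profiles, mappability
artifacts, incomplete-conversion heterogeneity between molecules, and
breakpoint microhomology or jitter. Oracle alignments are exact, so
breakpoint recovery on simulation is a test of the caller's arithmetic,
not of aligner behavior on converted sequence. Conclusions about real
WGBS require the real aligner stack upstream; the package consumes its
output contract (flags, MAPQ, CIGAR, SA tags, duplicate flags).

## Problem sizes in the validation suite

The test suite builds everything it needs in code, sized to be
informative rather than large; these are the package's own choices:

* compact 1.5 kb toy contigs with mid-gene junctions, so that roughly a
  tenth of fragments cover the junction and a depth-63 simulation stays
  in the hundreds of fragments;
* breakpoint recovery on 1,000 fusion fragments (fraction 1), requiring
  ≥ 99% of junction-crossing, filter-passing reads with both segments ≥
  `min_clip` to be classified split and the planted coordinates to be
  the modal unique breakpoint with zero-base error;
* fusion-negative nulls at 5/10/20× with 30 injected chimeric pairs,
  requiring exactly zero target-region pairs while the injected
  background is counted genome-wide;
* downsampling linearity at ten fractions of a depth-200 simulation
  (r ≥ 0.99 against a line through the origin);
* replicate concordance over ten fusions at graded depths 4–356×,
  giving expected supports from roughly ten to several hundred pairs —
  a spread wide enough that Poisson counting noise predicts r > 0.99,
  mirroring how real multi-fusion panels span orders of magnitude of
  support;
* conversion calibration over ≥ 10⁴ cytosine observations (3 binomial
  s.d. band) plus exact endpoints (fully methylated CpG retains
  completely at conversion 1);
* probit recovery over 200 seeded dilution designs (7 fractions × 3
  replicates) from a known curve, requiring the interquartile range of
  the LoD estimates to bracket the truth and the median bias to be small
  against the spread. At n = 3 per fraction the estimator is visibly
  variable and slightly low-biased — the honest picture of what a
  triplicate design can support.

## Known limitations

* Gene-interval scope: both breakpoints must fall inside the configured
  intervals; junctions in flanking or intergenic sequence are invisible
  (padding is available at the fetch boundary).
* Exact-coordinate breakpoint deduplication may oversplit clusters on
  real data with alignment jitter.
* The background definition (inter-contig or > 1 Mb) is an
  operationalization; "genome-wide fusion-like noise" has no single
  canonical definition.
* Count-based (non-binary) LoD modelling is out of scope; detection is
  thresholded at `detection_min` before the probit fit.
* The CLI is a thin script over the package functions, not a workflow
  engine.
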