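---
title: "Methods: tag-based methylation profiling with mmsdk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tag-based methylation profiling with mmsdk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement model

MMSDK couples a methylation-sensitive restriction enzyme to tag
sequencing. MluI (ACGCGT) cuts only unmethylated sites; cut fragments
are trimmed to the nearest NlaIII (CATG) site on each side, and a 17-bp
tag is released immediately interior to the CATG. The number of
sequenced tags mapping back to an MluI site is therefore a count
observation of that site's *unmethylated* state. Two consequences shape
everything in this package:

* counts are modeled as Poisson draws whose rate is proportional to the
  site's unmethylation probability times sequencing depth, and
* all directional statements invert: a site with *fewer* tags in one
  group is *more methylated* there. `runDifferential()` reports raw tag
  directions (`higher_in_clone` / `higher_in_control`); interpretation
  is left explicit rather than silently flipped.

# The virtual library

Both recognition motifs are reverse-complement palindromes, so a
plus-strand scan is exhaustive; this is asserted at library-build time
rather than assumed. Coordinates are 0-based half-open everywhere
internally; conversion happens only in the readers/writers (BED is
native; GFF3 and RepeatMasker `.out` are shifted on input). `N` never
matches a motif base, and soft-masked (lowercase) sequence is uppercased
— repeat status comes only from the annotation file, never from case.

**Fragment boundary convention.** For an MluI site at `p` (motif
`[p, p+6)`) and nearest NlaIII starts `q` on either side, the left
fragment is `[q, p+6)` and the right fragment is `[p, q+4)`. Any
consistent convention would do — downstream analysis consumes counts and
tag interiors, not boundary bases — but this one is frozen so that
digestion output is reproducible bit for bit.

**Adjacent MluI sites with no NlaIII between them** yield a single
shared fragment (`side = "mlu_mlu"`). It carries no CATG end, hence no
tag, and is excluded from the mappable reference. This gives the library
accounting rule `mappableFragmentCount(n, k, e) = 2n − 2k − e`: each of
the `k` NlaIII-free intervals removes one left and one right fragment,
and `e` counts sites that lack any NlaIII before the chromosome start or
after its end. End losses are tracked separately because a genome-scale
build can legitimately have `e = 0` while toy sequences often do not.

**Tags.** The tag is the 17 bases immediately interior to the CATG, read
toward the MluI end: the plus-strand substring after a left fragment's
CATG, the reverse complement of the 17 bases before a right fragment's
CATG (stored in reading orientation, strand `-`). Fragments with
interiors under 17 bp, or whose 17-mer contains N, are dropped with a
logged count. A 17-mer occurring more than once among all virtual tags
is removed from the mappable set (all copies), but retained in a side
list so the low-confidence mapper can still place reads ambiguously.

**CpG islands** are predicted with a sliding 501-bp window (step 1) and
the three island criteria — GC fraction > 0.5, observed/expected CpG
`(#CpG × L)/(#C × #G)` > 0.6, length > 500 bp — with N-containing
windows skipped. Overlapping or book-ended passing windows are merged
and each merged region is re-tested on its full extent; regions failing
the re-test are dropped, so every emitted region satisfies all three
criteria by construction. The window length is the smallest integer
satisfying the length criterion; the dedicated promoter-prediction
heuristics of specialised tools are out of scope, only the three
criteria are implemented.

**Site annotation** uses the 6-bp motif interval: CGI membership is ≥ 1
base of overlap; repeat class ties are resolved by largest overlap, then
smallest interval start, then annotation order (logged); the nearest
gene minimizes the coordinate gap (0 when overlapping or adjacent), ties
going to the smaller gene start.

# Tag mapping: the two-tier model

Full quality-aware alignment is not reimplemented. The two mapping-
quality tiers used in this kind of analysis act purely as inclusion
criteria, and are modeled as such:

* **high** (MQ20 analog): exact match, in exactly one orientation, to a
  unique virtual tag;
* **low** (MQ0 analog, inclusive of high when counting): exact match to
  a duplicated tag, a double-orientation hit, or a best placement with
  one mismatch; when several targets are equally good, one is drawn
  uniformly with the caller's seed — mirroring how multi-mappers are
  conventionally placed at mapping quality 0;
* **unmapped**: any N in the read, or > `maxMismatch` mismatches
  everywhere.

One mismatch is the default ceiling (`maxMismatch = 1`): 17-mers admit
little more before ambiguity dominates; the threshold is a configuration
knob, not a constant. Reads are matched both as read and as reverse
complement because tag sequencing orientation is assay-dependent; a hit
in both orientations is ambiguous by construction. Identical inputs and
seed give bit-identical assignments.

# Filtering and normalization

The two-step filter keeps a site if its mean raw count across libraries
is ≥ `meanThresh` (default 5), or, failing that, if its sample standard
deviation is ≥ `sdThresh` (default 5) — the second branch rescues sites
that are silent in most libraries but strongly active in one. The SD
uses the n−1 denominator, the small-sample convention appropriate for
cohort sizes of a handful of libraries; this choice is frozen in the
filter report rather than left implicit.

Normalization divides by the library's *total* mapped tag count of the
matching tier — not the total over surviving sites — so filtering and
normalization commute. The default scale is 1e6 (tags per million) for
readability; `scale = 1` recovers raw fractions, and no test statistic
depends on the constant. Totals are per tier (the high-tier matrix is
normalized by high-tier totals); whether an overall total would be more
faithful is undecidable from the method description, so the per-tier
choice is logged in the run artifacts.

The unique/repeat partition routes the high-confidence matrix of
non-repeat sites into filtering and the site-level test, and the
low-confidence matrix of repeat sites into the per-class rank tests —
repeats are exactly where unique exact matching under-counts, so the
inclusive tier is the informative one there.

# Clustering and multiscale bootstrap

Libraries are compared with Pearson-correlation distance
`d(i, j) = 1 − r(i, j)` over sites, then clustered agglomeratively
(average linkage by default; complete and single are available — the
linkage is exposed because the method description does not pin it).
Equally close pairs are merged smallest-index-first, making the tree a
deterministic function of the input; the implementation is cross-checked
against `stats::hclust` on tie-free inputs in the test suite.

Support values resample **sites** (features), never libraries: with 4–8
libraries there is nothing to resample on the library axis, and feature
resampling is what the multiscale theory describes. For each scale `r`
in 0.5–1.4 (step 0.1), `B` resamples of `round(r·n)` sites are drawn
with replacement and reclustered; `BP_r` of a cluster is the fraction of
resample trees containing exactly its leaf set. The reported BP is
`BP_r` at the scale closest to 1. AU comes from weighted least squares
on `z_r = Φ⁻¹(1 − BP_r)` against `v√r + c/√r` with delta-method binomial
weights `B·φ(z_r)²/(BP_r(1−BP_r))`, and `au = 1 − Φ(v − c)`; an
unweighted fit is available as a fallback. Numerical edge cases are
handled explicitly rather than papered over:

* clusters whose `BP_r` is 0 at every scale (or 1 at every scale) cannot
  be fitted; AU is set to that constant and flagged `degenerate`;
* fewer than two informative scales: AU falls back to BP, flagged
  `insufficient`;
* resamples in which a library has zero variance (possible with sparse
  counts) are dropped from the denominator;
* the root always has AU = BP = 1 by convention and is flagged `root`.

Internally support values are fractions in [0, 1]; the Newick export
writes them in percent on node comments, which is how such values are
conventionally displayed on dendrogram edges.

# Differential methylation

The site-level test is the exact conditional comparison of two Poisson
totals: pooling counts within groups gives `x1` from pooled depth `N1`
and `x2` from `N2`; conditional on `T = x1 + x2`, under equal rates
`x1 ~ Binomial(T, N1/(N1+N2))`, and the two-sided p-value is
`min(1, 2·min(lower tail, upper tail))` with both tails inclusive of the
observed count (`T = 0` gives p = 1). This is the canonical exact test
for the stated Poisson model, is verifiable against exhaustive
enumeration (the suite checks every `x1` for all `T ≤ 60`), and — being
exact — runs slightly conservative: null calibration lands just below
the nominal level, which the acceptance band [0.03, 0.06] at α = 0.05
anticipates. Upper tails are computed with `lower.tail = FALSE` to avoid
the catastrophic cancellation of `1 − pbinom(...)` at extreme counts.

Replicates are pooled within group rather than modeled hierarchically:
the design this pipeline targets has two biological replicates per
group, too few to estimate per-site overdispersion, and the simulator's
Poisson sampling matches the analysis model (an overdispersed mode would
stress robustness but is deliberately not part of acceptance).

FDR families: site-level p-values are adjusted per tissue over all
tested sites; repeat-class p-values are adjusted across classes within a
tissue. The class-level family size is reported explicitly (`n_sites`,
one row per class) because family choices of this kind are frequently
ambiguous in published tables; the family is whatever the function was
given.

The repeat-class test pools per-site normalized values of all libraries
in each group into two samples and applies the two-sided Wilcoxon
rank-sum test: exact enumeration when both samples have under 20 values
and no ties, otherwise the normal approximation with tie and continuity
corrections. Pooling per-library values (rather than comparing per-site
group means) preserves library-to-library variation in the test; the
alternative is a one-line change at the call site.

# The synthetic-data generator

`simulationConfig()` defines the study conditions; its defaults describe
the cohort this pipeline was designed around: two tissues × (2 clone +
2 control) libraries, baseline unmethylation probability 0.5, a tissue
effect (multiplier 0.3 on 30% of sites in the second tissue), a clone
effect at 10% of sites per tissue with rate multiplier 3 in the
hypermethylation direction (clone unmethylation probability divided by
3 — the direction reported for cloned animals), sequencing depth 50
expected tags per fully unmethylated site, and a per-base read error
rate of 0.005.

The genome generator plants each MluI site as a cassette
`CATG … ACGCGT … CATG` with flank distances uniform in 20–2000 bp,
separated by 800–2000 bp of background at GC 0.42 (a mammalian-genome
value). CpG-island sites are embedded in ~800-bp blocks at GC 0.65 with
CpG thinning toward observed/expected 0.8 and tighter flanks (20–200 bp)
so the island remains one contiguous high-CpG block; the inter-cassette
spacing exceeds the 501-bp scan window so distinct islands resolve as
distinct predictions, as they do in real genomes where islands are rare
and well separated. Repeat and gene intervals are *annotation only* —
their base content is ordinary background, because downstream analysis
consumes the intervals, not the sequence. Background sequence creates
accidental motifs at the expected rate; rather than fighting this, the
truth is defined *post hoc* by scanning the emitted genome, so planted
and accidental sites are treated identically.

What the generator deliberately does not emulate: linker/ditag structure
and raw sequencer reads (tags are emitted directly), bisulfite
chemistry, overdispersed counts (optional stress mode aside), indels,
base-quality profiles, and genuinely repetitive sequence content.
Passing tests therefore demonstrate the pipeline's correctness under its
own model — Poisson counts from a known reference with substitution
noise — not robustness to alignment artifacts in low-complexity regions.

All randomness flows from the single master seed via fixed offsets, so a
configuration determines every byte of output; the determinism test
compares md5 sums of two full pipeline runs.

# Problem sizes in the test suite

The suite verifies properties at sizes chosen to make the checks sharp
but quick: digestion/tag oracles on 100 random 10-kb sequences; Poisson
enumeration for all totals ≤ 60; null calibration on 10,000 sites;
spike-in FDR/power on ~300 planted sites at depth 50 with 4 libraries
per group; bootstrap behavior at B = 1000 on 8-library matrices with 500
(planted) and 300 (noise) features over 20 noise replicates. These sizes
are the package's validation design; the same code paths scale to
genome-sized inputs linearly in sequence length and read count.

# Known limitations

* The mapper is a model of two-tier mapping semantics, not a
  re-implementation of a quality-aware aligner; base qualities are
  ignored.
* Pooling within groups forfeits per-site dispersion estimates; with
  more replicates a count-regression framework would be preferable.
* CpG-island prediction implements the three printed criteria only; no
  promoter-specific heuristics.
* AU values for very small trees (few leaves) rest on a fit across
  scales of a bounded proportion; flags (`degenerate`, `insufficient`)
  mark the nodes where the fit could not be performed and should be
  consulted before interpreting borderline support.
* Expression analysis is consumed, never computed: differential-
  expression gene lists enter as TSV input to the cross-comparison.
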