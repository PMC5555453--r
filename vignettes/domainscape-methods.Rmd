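---
title: "Methods: comparative analysis of repeat-dense chromosomal domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative analysis of repeat-dense chromosomal domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domainscape)
```

## The scientific setting

Heterochromatic chromosomal domains — such as the Muller F ("dot") element
of Drosophilidae — are repeat-rich, late-replicating, and marked by
H3K9me2/3, yet their resident genes are transcribed at levels comparable to
euchromatic genes. Contrasting such a domain with a euchromatic reference
region (conventionally the base of the Muller D element) requires a chain
of analyses: how much of each region is transposon-derived and of which
classes; whether apparent foreign-genome (endosymbiont) matches are real or
transposon contamination of the foreign assembly; how gene architecture
(coding spans, introns, exon counts) differs; whether codon bias reflects
mutational pressure or selection; and how physical (DNA melting
temperature) and epigenomic (ChIP enrichment) profiles are organized around
genes. `domainscape` implements each step as a tested function, and ships a
synthetic-genome generator with exact ground truth so the whole chain can
be validated end to end without any external data.

All internal coordinates are 0-based half-open; the converters live at the
file boundaries (RepeatMasker `.out` and GFF3 are 1-based inclusive,
BED/bedGraph 0-based half-open). A single internal convention removes the
usual off-by-one drift between interval operations.

## Repeat-density accounting

Repeat annotations arrive as scored fragments. `merge_by_class()` merges
overlapping fragments of the same canonical class (LINE, LTR, DNA,
RC/Helitron, Satellite, simple/low-complexity, other) into single segments
and reclassifies bases covered by two or more *different* classes as
`Overlapping`. Only the shared bases are reclassified — the non-overlapping
flanks of a partially overlapping fragment keep their own class — so
class-specific base counts are conserved outside the conflict region. For
three-way and deeper stacks the pairwise rule generalizes by base-level
voting: any base under two or more distinct classes is `Overlapping`. The
output partitions the covered bases exactly, a property the tests verify
against a per-base labeling oracle.

Densities are fractions of region length covered by merged segments, so
per-class densities sum to the total and can never exceed 1. Top-repeat
tables intentionally use different accounting: fragment counts are raw
annotation rows and the "% of all repeat bp" denominator is the unmerged
cumulative fragment size, matching how such tables are conventionally
tabulated from RepeatMasker output; both conventions are labeled in the
reports. Rows flagged as overridden by a higher-scoring match (`*`) are
kept by default for the same reason, with `keep_overridden = FALSE`
available.

Foreign-genome match filtering (`score_filter()`) takes a user-supplied
cutoff per comparison; the score cutoffs are inputs, not constants, because
appropriate values depend on the query/target pair. `overlap_attribution()`
then measures what fraction of the (unioned) match bases coincide with
annotated transposons and ranks the contributing repeat names — the
forensic that distinguishes genuine endosymbiont insertions from
transposon-contaminated foreign assemblies. `coverage_track()` collates
matches into a per-base alignment coverage track.

## Gene architecture

Only `CDS` features are consumed from GFF3 (the analysis concerns coding
spans; UTR/exon rows are ignored). Per gene, the *most comprehensive
isoform* — the one with the largest total coding-exon size — represents the
gene, avoiding double-counting under alternative splicing; ties break on
the lexicographically smallest isoform id so the choice is deterministic.
The coding span runs from the leftmost to the rightmost CDS base (start
codon to stop codon, introns included), introns are the gaps between
genomically adjacent CDS segments, and the identity
`coding_span = total_CDS + total_introns` is asserted both in tests and at
report time. Genes with a single CDS segment have an undefined median
intron size and are excluded from intron-size distributions but kept in all
other tables. Multi-contig or multi-strand (trans-spliced) isoforms are
rejected with a named error. Report tables carry `log10(x + 1)` companions
of each size column for log-scale plotting.

`partition_regions()` splits a region into coding, intronic and intergenic
space with a fixed precedence — coding beats intronic beats intergenic — so
bases inside one gene's intron but another gene's exon count as coding and
the three sets always partition the region exactly.

Ortholog difference records are signed as species A minus species B, so a
positive coding-span difference means the A ortholog is larger; the record
is antisymmetric under swapping the pair.

## Codon bias

Wright's effective number of codons treats each synonymous family through
its homozygosity `F`: in `proportions` mode `F = sum(p_i^2)` (the
infinite-length limit), in `finite_sample` mode
`F_hat = (n*sum(p_i^2) - 1)/(n - 1)`, the small-sample-corrected estimator.
Then `Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6` over the mean homozygosity of
each degeneracy class. Sixfold families (Leu, Ser, Arg) are kept whole —
under that convention the bounds are exactly `20 = 2+9+1+5+3` (one codon
per family) and `61 = 2+18+3+20+18` (equal usage). Families that are
absent, observed once, or whose finite-sample homozygosity is non-positive
are imputed by the mean of their degeneracy class, or by `1/k` when the
entire class is unobserved (Wright's recommendation). Note that on
*sampled* genes the proportions-mode estimator is biased low (its
expectation adds `(1 - sum p^2)/n` per family), so finite-length uniform
genes should be assessed in `finite_sample` mode; the exact value 61 holds
for exactly equal counts in proportions mode.

CAI follows the relative-adaptiveness construction: within each family
`w = count/max(count)` against a reference gene set, zero-count reference
codons floored at `w = 0.01`, Met/Trp and stops excluded; the gene score is
the geometric mean of `w` over codon occurrences. The *equal-usage
threshold* — the CAI of a hypothetical gene using every synonymous codon
equally — is computed with every included sense codon weighted equally (the
codon-weighted geometric mean `exp(mean(log w))`). An amino-acid-weighted
alternative exists; the codon-weighted convention was chosen because the
hypothetical gene is defined by equal codon usage, and the choice is
isolated in `equal_usage_cai()` if a different convention is needed.
Codons containing `N` are excluded from every statistic and counted
separately.

GC partitions report GC at each codon position and at fourfold-degenerate
sites (third positions of Ala, Gly, Pro, Thr, Val), where any base is
synonymous and GC content reads out mutation/selection pressure at silent
sites.

The Nc-vs-CAI diagnostic: genes whose codon bias is mutational sit on a
rising limb of the trend (low CAI, Nc falling with GC3 drift), genes under
translational selection on a falling limb (high CAI, low Nc), producing an
inverted-V LOESS curve. `loess_trend()` fits degree-1 local regression with
tricube weights; the span is selected by generalized cross-validation
(`n*RSS/(n - tr(L))^2`, trace of the smoother matrix) on a non-robust pass
over the grid 0.20–0.95 (step 0.05), then the final fit reruns at the
chosen span with four bisquare robustness iterations
(`family = "symmetric"`). Selecting the span before the robustness
iterations keeps the GCV denominator well-defined; the alternative
(re-selecting under the robust weights) is ambiguous because the robust fit
has no single smoother matrix.

## Profiles and metagenes

**Melting temperature.** `window_tm()` computes nearest-neighbor
thermodynamic Tm over a sliding window (default 9 bp, step 1 — the length
of the RNA–DNA hybrid in the transcription elongation complex):
`Tm(°C) = 1000*ΔH / (ΔS + R*ln(Ct/4)) − 273.15 + 16.6*log10([Na+])`, with
ΔH/ΔS summed over the window's stacked pairs from the Breslauer 1986 table
plus duplex-initiation entropy (−16.8 cal/mol/K with at least one G/C pair,
−20.1 all-A/T), total strand concentration 50 nM and 50 mM monovalent salt
by default. The thermodynamic table is pluggable (`tm_params(table = ...)`)
and the validation is property-based (GC monotonicity, hand-summed window
oracles) rather than matched to any particular program's absolute °C.
Windows containing `N` are missing, never guessed.

**Enrichment.** `loglik_enrichment()` computes, per base, the signed
Poisson log10 likelihood ratio between a treatment and a control track
with a symmetric pseudocount (default 1e-5):
`LLR = sign(x−y) * (x*ln(x/y) − x + y)/ln(10)` with `x = t + p`,
`y = c + p`. This equals `log10[PMF(x; x)/PMF(x; y)]` in magnitude — the
comparison a peak caller's logLR track makes between ChIP and input.
Because the Poisson deviance is not symmetric in its arguments, swapping
the tracks flips the sign of every call but not, in general, the exact
magnitude; the tests therefore assert exact agreement with the log-PMF
oracle plus sign antisymmetry.

**Metagenes.** Each gene contributes its coding span rescaled to a common
3-kb length plus 2-kb flanks, oriented so upstream is always 5′. Rescaling
is linear interpolation (endpoints preserved exactly; missing values
propagate rather than being interpolated across) — bin-averaging was
rejected because it distorts endpoints. Aggregation is the position-wise
median, ignoring missing values, with the number of contributing genes
recorded per position. Smoothing uses `stats::smooth.spline` with ordinary
leave-one-out cross-validation (`cv = TRUE`); profiles with fewer than 10
defined positions pass through unsmoothed with a warning.

## Statistics

Group comparisons use the Kruskal–Wallis rank-sum test (tie-corrected,
chi-square reference) with Dunn's post hoc pairwise z tests from the pooled
ranks and Holm step-down correction at `alpha = 0.05`; the post hoc runs
only after KW rejects (`gatekeep = FALSE` overrides). Holm rejections are
stepped down in order of unadjusted p and stop at the first non-rejection,
so the rejected set is always a prefix of the p-ordered list. Enrichment
questions use the one-tailed upper hypergeometric probability, computed by
the exact combinatorial sum for populations up to 1000 and via log-gamma
beyond; all other tests are two-sided. Spearman correlation uses midranks
and the t approximation, returning an explicit undefined status for
constant input.

## The synthetic-data generator

`simulation_config()` defaults describe the study conditions the package
emulates: a 1-Mb repeat-dense region with per-class transposon densities
LTR 0.421, LINE 0.218, RC/Helitron 0.073, DNA 0.056 (total 0.768); 60
coding genes; a two-component log-normal intron mixture with ~70-bp and
~4.3-kb components mixed 1:1 (matching a bimodal median-intron
distribution whose quartiles sit near 70 bp and 4.3 kb); an AT-shifted
codon model with GC3 target 0.30 against a GC-shifted (0.65) alternative;
Gaussian promoter peaks (height 3, sd 200 bp) and uniform body enrichment
(1.0) over a 0.1 baseline with 0.1-sd noise, emitted at 25-bp bins; and an
8.6-fold intron inflation factor for ortholog pairs. Tests and the
analysis scripts run the same generator at 30–800 kb and 3–40 genes — the
smallest sizes at which each property is statistically unambiguous.

Generation order matters: gene structures are placed first (genes never
overlap each other and keep a 2.1-kb margin from region edges), then
transposon fragments are planted anywhere *except CDS exons* — introns and
intergenic space fill with repeats, as in real repeat-dense domains —
until each class's density target is met exactly (the final fragment is
trimmed). With nesting disabled (the default) fragments never overlap and
the planted truth is exact; with nesting enabled the truth counts visible
(last-written) bases, which is what an annotator of the final sequence
could see. Fragment scores are drawn as length × quality so that planted
low-score decoys (`n_spurious`) give the cutoff filter a controllable
spurious class. CDS codons are drawn per amino acid uniformly over the
synonymous families whose third-base split makes the per-codon GC3
probability exactly the target (all multi-codon families except Ile, whose
2:1 AT-ending split distorts it; Met/Trp are non-degenerate), so the
realized GC3 is unbiased for the target. The background sequence is i.i.d.
at the configured GC — no higher-order structure, which none of the
consumers here require.

What the generator deliberately does *not* emulate: transposon phylogenies
and divergence decay, real codon-usage tables, isochore structure,
alternative isoforms, UTRs, or an actual endosymbiont genome (foreign-match
attribution is tested with planted feature sets). Passing tests therefore
demonstrate the correctness of the accounting and statistics on data with
the assumed structure, not robustness to annotation errors or assembly
artifacts in real genomes.

## Numerical and design choices

- Degenerate inputs: empty repeat files parse to empty lists; an empty
  query in overlap attribution reports an explicit "no matches" status
  rather than 0; zero-length regions are errors; constant input to
  Spearman is an explicit undefined status.
- A reference family with no counts at all yields uninformative weights
  (`w = 1`) with a warning rather than an error, keeping CAI computable
  on partial references.
- Ties: top-repeat tables break size ties lexicographically; isoform
  selection breaks CDS-size ties on isoform id. Both make reports
  deterministic.
- `run_compare()` writes into a fresh directory only (or `force = TRUE`)
  and records a config hash, seed and row counts in a manifest, so a rerun
  is verifiably identical.
- Problem sizes: the default pipeline scale (1 Mb, 60 genes) runs the full
  comparison in minutes on one CPU; the shipped analysis scripts use two
  500-kb regions with 25 genes each.

## Known limitations

- The Tm thermodynamic parameter set matches the Breslauer-1986 convention
  of the classic EMBOSS-style calculators; absolute °C values for 9-mers
  are not physically meaningful melting points and should be read as a
  relative stability profile.
- Nc imputation for rare families follows Wright; other tools differ in
  unspecified ways, so per-gene Nc can differ from theirs by a fraction of
  a unit for short genes.
- The equal-usage CAI threshold depends on the reference set; thresholds
  from different references are not comparable.
- LOESS span selection on very small inputs can reject most of the grid;
  at least 10 points are required and a minimum span of 0.2 is enforced.
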