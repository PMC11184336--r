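---
title: "Methods: directed-evolution screen analysis for hAT-family transposases"
author: "hatscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: directed-evolution screen analysis for hAT-family transposases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hatscreen)
```

# The problem

Hyperactive variants of DNA transposases such as TcBuster are engineered
by (i) nominating candidate substitutions from family-level sequence
conservation, (ii) shuffling those substitutions into a combinatorial
mutant library, (iii) selecting cells whose transposase variant performs
many transposition events, and (iv) scoring each designed mutation by how
strongly it is enriched in the sorted population relative to the naive
library. The engineered enzyme's genomic safety is then characterised by
mapping transposon integration sites and summarising their distance to
transcription start sites (TSS) and genomic context against a random
baseline.

`hatscreen` implements the computational side of this programme as
testable units, and ships generators that produce every input with known
ground truth, so each analysis can be validated closed-loop: simulate
with known parameters, analyse, and check that the parameters are
recovered.

# Candidate finding from conservation

`candidate_substitutions()` scans a protein multiple alignment for
columns where the homolog family holds a conserved residue that the
target sequence lacks (the "V356L" pattern: the target carries V where
the family consensus is L). Two decisions matter:

* The consensus is computed **excluding the target row** — the question
  is what the family agrees on, not what the average including the
  target looks like.
* Gaps and ambiguity codes (X, B, Z) are excluded from frequency
  denominators, and a per-column coverage gate (`min_coverage`, default
  0.5) suppresses sparsely aligned columns.

The conservation threshold (`min_conservation`, default 0.6) is a free
parameter: published screens describe this step as partly manual, so no
canonical value exists. Raising it can only remove candidates
(monotonicity, asserted in the tests).

# Library genotyping

Long, high-accuracy (CCS-like) reads each span a full variant cDNA, so a
read is genotyped directly:

1. **Full-length filter.** Reads equal in length to the reference are
   compared by Hamming identity (no indels possible); length-discrepant
   reads are aligned semi-globally with free end gaps and projected onto
   reference coordinates. Reverse-complement orientation is
   auto-detected. Defaults `min_coverage = 0.95`, `min_identity = 0.85`
   are deliberately permissive: the designed mutations themselves
   perturb identity by well under 1%.
2. **Codon scan.** Every designed position is classified WT (wild-type
   codon), MUT (the designed mutant codon), or OTHER (anything else,
   including deletion-disrupted codons). Matching is codon-exact: a
   codon equal to neither allele is never force-assigned, which keeps
   sequencing errors from inflating either count.
3. **Genotype identity** is exact set equality of designed-mutation ids.
   OTHER positions do not distinguish variants, since only designed
   mutations are tracked.

Library statistics follow: unique variant count, per-variant read
support, and the mean mutation load averaged **over unique variants**
(not reads). Note one consequence of codon-exact calling worth knowing:
at a per-base error rate of 0.5%, a small fraction of wild-type codons
is misread as the designed mutant codon (when the two differ by a single
base), so the load estimated from noisy reads sits a few percent above
the generator's configured mean, and spurious low-support "variants"
appear. Error-free reads recover genotypes with 100% accuracy (asserted
in the acceptance tests); on real data, support thresholds on the
variant table play this role.

`combinatorial_space()` reports the design-space size in exact integer
arithmetic (a small built-in big-integer routine, since
$2^{108} - 1 \approx 3.2\times10^{32}$ overflows doubles): 108
substitutions give 5,569,137 variants at loads 1–4. A note on published
figures: the count of distinct double mutants from 108 substitutions is
$\binom{108}{2} = 5{,}778$; a figure of 7,558 circulates for this
quantity and does not match any sum of binomial coefficients of 108 —
the package reports the combinatorics and leaves the discrepancy to the
reader.

# Enrichment scoring

For each designed mutation, with `Reads_mut` / `Reads_wt` the reads
carrying the mutant / wild-type codon at that position (OTHER reads
excluded from the denominator):

$$F = \frac{\mathrm{Reads_{mut}}}{\mathrm{Reads_{mut}} +
\mathrm{Reads_{wt}}},\qquad
E = \frac{F_\mathrm{sort}}{F_\mathrm{naive}},\qquad
\mathrm{WES} = \ln(E)\,\sqrt{\mathrm{Reads_{mut,sort}} +
\mathrm{Reads_{mut,naive}}}$$

The square-root weight upweights well-sampled mutations relative to
rarely observed ones. Zero counts make the literal formulas undefined;
`enrichment_table()` therefore defaults to a pseudocount of 0.5 **inside
F only** — the weight term keeps raw counts so WES retains the literal
formula's scale — and `pseudocount = 0` reproduces the literal formulas,
flagging undefined records rather than dropping them. Ranking is by WES
descending, ties broken by mutation id.

# The synthetic screen

The generator chain emulates the study conditions of the screen being
modelled:

* **Design**: 108 codon substitutions at distinct positions of a 686-aa
  reference, each changing the amino acid.
* **Load distribution**: zero-truncated Poisson with configurable mean,
  default 4.4 (only means are reported for the real library — "two to
  three" designed, 4.4 realized — so the distribution family is a
  stand-in, chosen as the simplest support-on-$\{1,2,\dots\}$ count
  model).
* **Selection**: each mutation may carry an activity effect on a log
  scale; variant $v$ is sampled into the sorted population with weight
  $\exp(\sigma \sum_{m \in v} \beta_m)$, where $\sigma$ is
  `selection_stringency`. Additivity is a modelling choice, not a claim
  about the enzyme: the screen selects on multi-copy transposition
  events, and an additive log-scale model is the minimal structure that
  produces graded, recoverable enrichment.
* **Reads**: full-length copies of a variant with i.i.d. substitution
  errors (default 0.5% per base; CCS-style indel errors are off by
  default). Error counts per read are Binomial(L, rate) with uniform
  positions — at these rates indistinguishable from per-base Bernoulli.
* **MOI helper**: `moi_copy_distribution()` evaluates the Poisson pmf
  motivating low-MOI transduction (at MOI 0.3, 96.3% of cells carry 0–1
  copies).

Seeding: every generator derives an independent stream from the master
seed via a fixed affine map per stage name (`derive_seed()`), so equal
seeds give byte-identical outputs and adding reads to one stage never
perturbs another.

What the generator does **not** model: PCR/shuffling chemistry and its
position biases, lentiviral integration sequence preference,
hybridization-capture efficiency, chimeric reads, or quality-value
structure. Passing closed-loop tests therefore demonstrates correctness
of the analysis under the stated statistical model, not robustness to
every artefact of real libraries.

## What recovery looks like — and a ceiling worth knowing

With 10 planted mutations at effect +1 among 108 (10,000 variants,
200,000 reads per population), all 10 positives land in the WES top 20
essentially always. The Spearman correlation between the **binary**
truth vector and WES, however, is capped near 0.50 regardless of how
perfect the ranking is: a 10-vs-98 two-valued vector cannot correlate
more strongly with any full ranking (the point-biserial ceiling,
$\sqrt{pq}\,(\bar r_1 - \bar r_0)/\sigma_r \approx 0.502$ here). With
graded true effects the same pipeline reaches $\rho > 0.9$ (shown in the
test suite); when judging a screen by rank correlation, use graded
truth or report top-$k$ recovery.

A related design point: very strong selection (large effects or high
stringency) concentrates the sorted sample onto a handful of variants,
which *reduces* rank agreement for the remaining mutations — diversity
of the sorted population, not only read depth, limits recovery.

# Integration-site profiling

Junction reads start with a (possibly far-end truncated) suffix of the
transposon's terminal sequence (ITR probe) followed by genomic DNA.
`extract_junctions()` requires at least `min_itr_match = 12` probe bases
at the read start (either orientation), trims them, and discards
transposon-only reads and fragments shorter than 20 nt.

`map_fragments()` is a desk-scale exact mapper: the first W bases of
every fragment (W = shortest fragment) are indexed with a
`Biostrings::PDict` and searched on both strands, and candidate hits are
verified over the full fragment. Fragments with more than one verified
hit are flagged `multimap`, with none `unmapped`; both are excluded from
site calling. Externally produced mappings can be imported instead
(`read_mapped_loci()`); bit-exact replication of any particular
short-read aligner is out of scope.

Coordinates are 0-based between-base internally. A forward hit is a
junction with genome continuing to the **right** of the boundary; a
reverse-complement hit, to the **left**. `cluster_sites()` merges
same-side boundaries within `merge_window = 5` bases (support summed,
modal boundary as representative; published site lists do not state a
dedup rule, so this one is ours) and collapses a right-side boundary at
$p$ with a left-side boundary at exactly $p + t$ — the signature of a
target-site duplication of length $t$ (8 bp for hAT elements) — into one
insertion at $p$, with the TSD read out of the genome.

The safety profile reports, per site, the unsigned distance to the
nearest strand-aware TSS of any transcript, and a context class with
precedence `coding_exon` > `transcript_noncoding` >
`outside_transcript`. `profile_summary()` adds a matched uniform-random
baseline (`n_random` positions over the same contigs) and
observed/baseline fraction ratios; the median TSS distance carries a
bootstrap SE over sites — reported explicitly as a bootstrap SE, since
published "±" values on such medians rarely state their definition.
Signed upstream/downstream distances are deliberately excluded from the
headline summary (the comparison metric across integration systems is
unsigned).

# Numerical and degenerate-input choices

* Zero reads: generators emit valid empty FASTQ files; `library_stats()`
  on nothing returns zeros rather than erroring.
* Zero counts: frequency/enrichment functions error with a pointer to
  pseudocount mode instead of returning NaN silently.
* Consensus ties resolve to the alphabetically first residue;
  enrichment ties to the lexicographically first mutation id — both
  deterministic.
* All numeric table output is serialized at 6 significant digits so
  reruns under one seed are byte-identical and diffable.
* Big-integer combinatorics use base-1e9 limbs with exact division at
  every step of the binomial recurrence.

# Problem sizes used in the shipped analyses

The `analysis/` drivers and the acceptance checks run at: 686-aa
reference, 108 designed mutations, 10,000 variants, 100,000–200,000
reads per population; a 2-Mb annotated genome with 60 gene models
(~30% transcript bp) and 500 insertions with 2,000 junction reads; null
calibration uses 50 replicates at 1,000 variants and 10,000 reads per
population. These sizes give the closed-loop statistics comfortable
precision (e.g. binomial SE below 2.5 percentage points on context
fractions at 500 sites) while a full workflow run stays in the minutes
range on one core.

# Known limitations

* The designed-mutation catalogue is the unit of analysis: no de novo
  variant discovery, no phasing of non-designed changes, and no
  epistasis model (mutation-level scores are marginal effects).
* The exact mapper assumes fragments long enough to be unique in a toy
  genome; real genomes need a real aligner, via the import path.
* The TSD reconciliation requires the exact `tsd_length` offset;
  elements with variable TSDs would need a tolerance window.
* The bootstrap SE on the median TSS distance resamples sites only; it
  does not model donor-to-donor variability.
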