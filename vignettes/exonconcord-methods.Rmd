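---
title: "Exon-level concordance between RNA-Seq and exon arrays: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exon-level concordance between RNA-Seq and exon arrays: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exonconcord)
```

# The problem

Short-read RNA sequencing estimates the expression of a locus by counting
the reads that align to it, while exon microarrays report a hybridization
signal per probe selection region together with a detection p-value (a
DABG-style score: the probability that the signal resembles background).
Comparing the two platforms at the granularity of individual exons asks a
series of linked questions: how low is the sequencing background; at what
read-count threshold should an exon be called Present; how well do
detection calls and fold changes agree across platforms; how should
differential expression be called from a single count per condition; and
can reads falling outside annotation reveal novel exons and novel splice
junctions? `exonconcord` implements that full cascade as reusable,
tested functions, and ships a synthetic-data generator with known truth
so every stage can be validated end to end.

# Models and statistics

## Expected-error read filtering

A base with Phred quality value $QV$ has error probability
$p = 10^{-QV/10}$. The expected number of erroneous calls in a read is
$\sum_n p_n$ over its positions, and reads with expected error above 6
are discarded (`filter_reads()`, strict "greater than": a read exactly
at 6 is kept). For a 50-base read, a uniform $QV$ of 10 gives expected
error 5 (kept) and $QV$ of 7 gives about 10 (discarded), which is why
the threshold of 6 is a meaningful scale for 50-base reads.

## Mappability and effective length

A genomic start position is *non-unique* if the 50-mer beginning there
occurs at two or more start positions anywhere in the genome
(exact-match, same strand; reverse-complement matching is available
behind a flag because the all-against-all formulation of the search
compares reference regions directly). `build_mappability_profile()`
hashes all k-mers at once; the contract is identical to the literal
all-against-all search, which the test suite runs as an oracle on small
genomes. For an interval of length $L$ containing $U$ non-unique start
positions, the *effective length* is $L - U$: the denominator a read
counter can actually hit.

## Normalized expression

Expression is an RPKM-style measure corrected for mappability:

$$E = \frac{C \cdot S}{(L - U)\, T}$$

with $S$ the reads on the region, $T$ the sample's total uniquely
mappable reads, and $C = 10^9$. With $U = 0$ this is exactly RPKM.
Exons with $L - U \le 0$ are excluded rather than given an arbitrary
value.

## Correspondence score

Cross-platform agreement of binary calls is scored with a modified
Matthews correlation on the $2\times2$ table — $A$ agreements in the
Present (or differentially-expressed, or exon-like) state, $B$
agreements in the Absent state, $C$ and $D$ the two disagreement kinds:

$$CS = \frac{AB - CD}{\sqrt{(A+C)(A+D)(B+C)(B+D)}}$$

$CS = 1$ is perfect correspondence, $0$ no better than random, $-1$
perfect disagreement. A zero marginal makes the score undefined; the
package raises an error in scalar use and reports `NaN` inside grids,
never a silent 0. The same statistic drives three threshold searches:
the Present/Absent detection grid (read-count threshold $t$ versus
detection p-value cutoff $\alpha$), the differential-expression grid
(one threshold axis per platform), and the read-cluster threshold
separating exon-like from intron-like clusters.

## Detection calls and threshold grids

An exon is Present in RNA-Seq when its read count exceeds $t$ (strict),
or its normalized expression exceeds $\tau$ in expression mode; a
probeset is Present when its detection p-value is strictly below
$\alpha$, by default in at least 2 of 3 replicates (a single chosen
replicate reproduces single-replicate behaviour). The exon universe is
restricted to exons targeted by exactly one probeset. Grid ties break
toward the smallest $t$, then the smallest $\alpha$.

## Fold changes

Log2 fold changes add a pseudocount of $10^{-4}$ to both normalized
expression values, so exons undetected in both samples have a fold
change of exactly 0 and no logs of zero occur. The headline
cross-platform correlation is computed on the class of exons Present in
both samples on both platforms; among exons flagged Absent-to-Present
on at least one platform, the fraction with sign-matching fold changes
is reported separately (a zero fold change agrees only with zero).

## Audic-Claverie differential expression

With a single count per condition, the probability of observing $y$
reads in sample 2 given $x$ reads in sample 1 and library sizes
$N_1, N_2$ is

$$p(y \mid x) = \left(\frac{N_2}{N_1}\right)^{\!y}
\frac{(x+y)!}{x!\,y!\left(1 + \frac{N_2}{N_1}\right)^{x+y+1}}$$

computed in log space via `lgamma`. For fixed $x$ this is a proper
distribution over $y$ (it is the negative binomial with size $x+1$ and
probability $N_1/(N_1+N_2)$, which the tests use as an independent
cross-check). P-values are tail sums; the two-sided default doubles the
smaller tail and caps at 1 — the conservative convention, since the
source material does not state sidedness. No multiple-testing
correction is applied anywhere: the analyses compare raw thresholds
across platforms.

Because the test operates on raw counts, its power at a fixed per-base
sampling rate grows with exon length; `length_bias()` quantifies this
by stratifying the DE call rate by exon-length quartile (strict
boundaries: below the lower quartile, above the upper).
Fold-change-based calls carry no such bias, and the acceptance suite
demonstrates both behaviours on simulation. The array-side DE stand-in
for synthetic triplicates is a plain Welch t-test on log2 signals;
moderated array statistics are deliberately out of scope.

## Junction databases and the toy junction aligner

A junction sequence is the last $\min(49, L)$ bases of the donor exon
followed by the first $\min(49, L)$ bases of the acceptor, both in
transcript orientation, so no sequence exceeds 98 nt and a 50-base read
can only match if it spans the boundary. Known junctions join adjacent
exon pairs across transcripts (duplicates collapsed); putative
junctions are **all** ordered pairs $(i, j), i \ne j$ within a gene
minus the known pairs — the permissive reading of "permuting", which
captures both exon skipping and scrambled order (a transcript-order-only
mode is available). Reads are aligned to junction sequences by exact
full-read substring match; reads hitting more than one junction record,
or also present in the genome, are discarded, and a counted read must
cover the boundary by at least one base on each side. A production-scale
6-mismatch genome aligner is out of scope; exact matching is the
deliberate desk-scale choice. High-confidence novel junctions need at
least 5 sense reads, 2 distinct start sites and a 12-base boundary
overlap. When junction evidence is folded back into exon detection,
each sense read credits both flanking exons — the only symmetric choice.

## Read clusters and novel loci

Overlapping reads union into clusters and clusters separated by at most
50 bases merge ("separated by 50 bases" read inclusively: a gap of
exactly 50 merges, 51 does not; both boundaries are tested). Labels
follow the precedence exonic > predicted-exonic > intronic >
predicted-intronic > intergenic, with predicted-exonic placed above
intronic because overlap with any exon model is stronger evidence of
transcription than residence in an intron. The exon-calling read-count
threshold $t^*$ is the smallest integer maximizing $CS$ with
$A$ = exonic clusters at or above $t$, $B$ = intronic below,
$C$ = exonic below, $D$ = intronic at or above. Intergenic candidates
must reach $t^*$ and the lower quartile of the known-exon length
distribution. The open-reading-frame filter translates the candidate on
its consensus strand in three frames (six, with a warning, for
mixed-strand clusters) and removes a candidate only when **all** frames
contain a stop — the reading under which real protein-coding sequence
survives; requiring every frame to be open would discard nearly
everything. Probe-selection-region proximity uses a 300-base pad,
implemented as "separating gap at most 300".

# The synthetic-data generator

`sim_config()` defines the study conditions; `simulate_dataset()`
produces a genome (FASTA), annotation (GFF3), probesets (BED),
strand-aware alignments (BED6), reads with qualities (FASTQ),
triplicate array data (TSV) and a truth table, all reproducible
bit-for-bit from the seed. The generator emulates:

* **Poisson counts given truth.** Per-exon read counts are Poisson with
  mean proportional to expression times length (matching the count
  model the AC test assumes); negative-binomial over-dispersion is a
  config option, off by default.
* **Strandedness.** Reads carry their transcript's strand except for an
  `antisense_fraction` of $10^{-4}$.
* **Near-zero background**: a fraction $5\times10^{-4}$ of reads placed
  uniformly over the genome.
* **A silent chromosome** (`chrY`): annotated but generating no signal
  reads, so any unique read mapping there is a technical artifact.
* **Duplicated segments** creating non-unique 50-mers at two loci
  (the two-genes-with-high-identity situation).
* **Junction reads** spanning adjacent junctions of expressed
  transcripts and planted non-adjacent (novel) junctions, at roughly
  3–4% of signal reads, as seen in stranded short-read libraries.
* **Intronic (pre-mRNA) reads** at 5% of the exonic per-base rate.
  This channel is what gives introns the low but non-zero coverage that
  the cluster-threshold calibration needs; without it the exonic
  versus intronic comparison is degenerate. Setting
  `intronic_rate_factor = 0` restores mature-transcript-only reads.
* **Planted intergenic loci** carrying probe selection regions and an
  open reading frame (stop-free codons on the locus strand). These
  emulate transcribed proto-exons of protein-coding character; uniform
  random sequence would essentially never survive an ORF filter
  ($\left(61/64\right)^{n_\text{codons}}$), so without planted frames
  the ORF stage would have no true positives to find. Any read cluster
  inside such a locus retains a stop-free frame because one of its
  three frames realigns to the locus codon grid.
* **Array signals** per replicate:
  $a + b\,\log_2(\text{expr}+1) + \mathcal N(0, \sigma)$ with
  homoscedastic noise on the log scale — the simplest model with the
  triplicate structure; detection p-values are Uniform(0,1) for
  unexpressed probesets and Beta(0.01, 1) for expressed ones, giving a
  Present rate of $0.01^{0.01} \approx 0.955$ at the 0.01 cutoff.

Sizes default to 3 chromosomes of 150 kb, 42 genes of 2–8 exons
(log-normal exon lengths, median ~150 b, clamped to 60–1500 b; introns
300–1500 b), and 30,000 expected signal reads per sample. These are
desk-scale choices: large enough that every stage has signal to work
with, small enough that a full simulate-and-analyze cycle runs in
seconds. Intron lengths are far shorter than genomic reality but long
enough that intron-derived read clusters separate from exon clusters
under the 50-base merge rule. Reads never span exon boundaries in their
genomic alignments; boundary-spanning transcription lives entirely in
the junction-read channel, mirroring the separate junction search
downstream. Colour-space encoding, base-composition bias, PCR
duplicates and paired ends are not modelled.

What passing tests on this generator do and do not show: they verify
the machinery — formulas, filters, threshold searches, conservation
invariants, and qualitative parameter recovery (background ≈ 0 recovers
a zero detection threshold; planted fold-change compression recovers a
higher RNA-Seq than array threshold; count-based DE shows length bias
while fold-change DE does not). They do not certify behaviour on real
data, where alignment error, coverage non-uniformity, cross
hybridization and annotation error all violate the generator's clean
assumptions.

# Numerical and boundary conventions

* Internal coordinates are 0-based half-open everywhere; GFF3
  (1-based inclusive) and `IRanges` conversions happen only at the
  boundaries.
* Strict inequalities: Present iff count $> t$; array Present iff
  p $< \alpha$; discard iff expected error $> 6$.
* Ties in threshold grids break toward the smallest threshold
  (RNA-Seq axis first).
* A cluster's strand consensus is the majority strand of its reads,
  `"mixed"` on ties.
* The background simulation with `background_rate = 0` is the regime
  in which the detection optimum provably sits at $t = 0$; at the
  package's small exon universe (~70 truly absent exons) even the
  default $5\times10^{-4}$ background can move the optimum to 1 on the
  strength of a single stray read — a discreteness artifact of desk
  scale, checked explicitly in the tests together with the
  heavy-background case where the optimum must exceed 0.
* Undefined correspondence scores (zero marginal) are errors or `NaN`,
  never 0.

# A worked example

```{r example, eval = FALSE}
library(exonconcord)

report <- run_pipeline(sim_config(seed = 7), verbose = TRUE)
report
#> exonconcord pipeline report (seed 7)
#>   library sizes:  34697 / 35350
#>   detection optimum: t = 1, alpha = 0.05, CS = 1
#>   fold-change r (all-Present class): 0.966
#>   clusters: 77 (t* = 16)
```

The numbered scripts under `analysis/` run the same cascade stage by
stage against files on disk and narrate what they find; see the README
for the sequence and the outputs each writes.

# Known limitations

* Exact-match junction alignment finds no junction read carrying a
  sequencing error; at the default error rate about 10% of planted
  junction reads go unmapped, which the hit counts reflect honestly.
* The array detection model ties the Beta shape to expression only
  through the expressed/unexpressed dichotomy; detection power does not
  grade smoothly with signal strength.
* Single-transcript genes: alternative isoforms exist in the data only
  through the permuted junction database, not in the expression truth.
* The cluster-threshold calibration needs both exonic and intronic
  clusters; on configurations without intronic coverage
  (`intronic_rate_factor = 0`) it errors by design rather than
  guessing.
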