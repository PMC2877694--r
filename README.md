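# exonconcord

Fine-grained, exon-level comparison of RNA-Seq read counts with exon
microarray detection calls, built for methodologists who want to study
how the two platforms agree — on detection, on fold change, and on the
discovery of transcription outside annotated loci — with every stage
exercised on synthetic data with known truth.

The package implements the complete analysis cascade:

1. **Read quality filtering** — discard reads whose expected error
   `sum(10^(-QV/10))` exceeds 6.
2. **Mappability** — exact-match 50-mer uniqueness profile of the
   genome; the per-interval count of non-unique start positions `U`
   defines the effective length `L - U`.
3. **Expression** — per-exon counts (strand-aware, unique or all-loci
   mode) and mappability-corrected normalized expression
   `E = C*S / ((L - U)*T)` with `C = 1e9`, plus a silent-chromosome
   background estimate.
4. **Concordance** — Present/Absent calls on both platforms (count
   `> t` vs detection p-value `< alpha`), scored over threshold grids
   with the correspondence score

   `CS = (A*B - C*D) / sqrt((A+C)(A+D)(B+C)(B+D))`

   (a modified Matthews correlation: 1 = perfect agreement, 0 = random,
   -1 = perfect disagreement), and fold-change comparison with a 1e-4
   pseudocount.
5. **Differential expression** — the Audic-Claverie Poisson test
   `p(y|x) = (N2/N1)^y (x+y)! / (x! y! (1+N2/N1)^(x+y+1))` for
   single-replicate count data, CS-aligned threshold grids against the
   array, and exon-length bias diagnostics.
6. **Junctions** — known (adjacent) and putative (permuted within-gene)
   exon-exon junction databases with 49/49-base contributions (max
   98 nt), an exact-match junction read aligner, and a high-confidence
   filter (>= 5 reads, >= 2 start sites, >= 12-base overlap).
7. **Clusters** — read clusters (gaps <= 50 merged), annotation labels,
   a CS-optimal exon-calling read-count threshold, and intergenic
   novel-exon candidates filtered by length, open reading frame and
   probeset proximity (± 300 bases).

A seeded synthetic-data generator (`sim_config()`,
`simulate_dataset()`) produces the genome, annotation, probesets,
strand-aware reads with qualities, junction reads and triplicate array
data that drive all of the above; the methods vignette
(`vignettes/exonconcord-methods.Rmd`) documents the models, parameter
choices and limitations.

## Worked example

The numbered scripts under `analysis/` run the cascade stage by stage,
writing tables under `results/`:

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

On the default configuration (seed 7; 3 chromosomes x 150 kb, 42 genes,
~30k signal reads per sample, triplicate arrays) the run prints, among
other things:

```
sample 1: 36472 reads, 685 removed (1.88%) at expected error > 6
non-unique 50-mer start positions: 0.20% of the genome
silent chromosome: 1/50 eligible exons with >= 1 read (2.00%)
detection optimum: t = 1, alpha = 0.05, CS = 1.000
fold-change correlation (Present everywhere): r = 0.966
direction agreement among 25 Absent-to-Present exons: 100.0%
AC DE rate: 34.4% overall; 46.3% upper length quartile (> 208 b) vs 22.2% lower (< 100 b)
FC DE rate: 30.2% overall; 31.5% upper quartile vs 25.9% lower
junction databases: 174 known, 896 putative
  high-confidence novel junctions: 5
exon-calling read-count threshold t* = 16 (CS = 0.886)
3 candidate(s) with a stop-free reading frame
100% of candidates lie within 300 bases of a probeset; 100% of those probesets are Present
```

Reading these: the sequencing background is essentially zero (a lone
background read accounts for the one silent-chromosome exon), so
Present/Absent correspondence peaks at a minimal read-count threshold;
fold changes correlate strongly across platforms where both have
signal, and every Absent-to-Present exon changes in the same direction
on both; the count-based Audic-Claverie test calls differential
expression twice as often in the longest exon quartile as in the
shortest (the expected length bias) while fold-change thresholding is
flat; all 5 planted novel junctions are recovered at high confidence;
and the read-cluster threshold separates exon-like from intron-like
clusters, leaving exactly the 3 planted intergenic loci as novel-exon
candidates, all ORF-positive and all next to Present probesets.

The same cascade is available in one call:

```r
library(exonconcord)
report <- run_pipeline(sim_config(seed = 7))
report
#> exonconcord pipeline report (seed 7)
#>   library sizes:  34697 / 35350
#>   detection optimum: t = 1, alpha = 0.05, CS = 1
#>   fold-change r (all-Present class): 0.966
#>   clusters: 77 (t* = 16)
```

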