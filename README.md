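# homeoquant

Homeolog expression quantification for allopolyploid RNA-seq.

## The problem

Allopolyploids (many crops, *Arabidopsis kamchatica*, bread wheat) carry two
or three parental subgenomes whose duplicated gene copies — homeologs — are
typically 97–98% identical. Standard RNA-seq quantification against a
concatenated reference misassigns a substantial fraction of reads to the
wrong subgenome, which distorts homeolog expression ratios, especially for
low-expression genes. homeoquant implements the subgenome-classification
alternative: map reads to each subgenome separately, then decide per
fragment which subgenome it came from, using the sequence differences that
discriminate the homeologs.

The package provides, as composable functions and a thin CLI:

* **Homeolog catalog** — reciprocal-best-hit pairing of subgenome transcript
  sets (affine-gap overlap alignment; hits kept at E < 1e-10 with ≥ 200
  aligned bases in both transcripts), triple assembly for hexaploids, and
  enumeration of the discriminating variants inside the aligned regions.
* **Read classification** — two decision rules per fragment:
  * *likelihood*: with per-base Phred error probability `e_i`, the
    log-likelihood of a read under subgenome hypothesis `G` sums
    `log(1 − e_i)` over matching discriminating sites and `log(e_i/3)` over
    mismatching ones. The posterior
    `P[r ∈ G_ref] = P[r|G_ref] / Σ_G P[r|G]` decides the label, accepted
    only when the winner reaches probability ≥ 0.95 with marginal
    probability ≥ 0.51; otherwise the read is unknown. Reads covering no
    discriminating site are subgenome-common.
  * *mismatch*: fewest mismatches wins, up to a cap of 10 mismatches per
    alignment, the read must be mappable to both subgenomes, ties are
    common.
  * hexaploids are handled bottom-up from the three pairwise comparisons
    (consensus voting, or the three-hypothesis posterior with a shared
    denominator).
* **Quantification** — transcript-level exon-overlap counting of classified
  fragments, optional proportional distribution of subgenome-common reads,
  and the homeolog expression proportion `p̂ = focal / Σ subgenomes`.
* **Differential homeolog expression** — a per-subgenome DE filter
  (FDR ≤ 0.05 in at least one subgenome; built-in exact binomial test or
  externally supplied q-values) combined with Fisher's exact tests on the
  replicate-combined counts (P < 0.05 and fold change ≥ 2; for hexaploids
  the contrasts A vs BD, B vs AD, D vs AB at P < 0.05/3).
* **Evaluation harness** — classification error by direction under
  explicit denominators (mapped / classified / quantified reads), RMSD and
  r² concordance, expression-stratified comparisons.
* **Synthetic data generator** — diverged subgenomes from a shared
  ancestor, expression-weighted paired reads with recorded origin truth,
  alignment projection by coordinate lift-over, and a k-mer uniqueness
  simulation for duplicated gene copies.

## Worked example

A 50-gene synthetic allotetraploid at ~2.5% homeolog divergence, 20,000
paired fragments with a 70/30 subgenome bias:

```r
library(homeoquant)

cfg <- sim_config(n_genes = 50, gene_length_range = c(1200, 1800),
                  snp_divergence = 0.0125, fragments_per_sample = 20000,
                  expression = list(sdlog = 1, pi = 0.7), seed = 42)
genomes <- simulate_subgenomes(cfg)
sim     <- simulate_reads(genomes, sample_id = "leaf1")
aln     <- project_alignments(sim, genomes)

catalog <- build_catalog(genomes$seqs)
catalog
#> homeolog_catalog: 50 group(s) over subgenomes H/L; 1876 variant site(s)

cls <- classify_sample(aln, catalog, method = "likelihood")
cls
#> read_classification: 20000 fragment(s) mapped (100.0%)
#>   classified: 19876  common: 124  unknown: 0  non-homeolog: 0
#>     H: 13861
#>     L: 6015

classification_error(cls, sim$truth, denominator = "classified")
#> classification error (% of classified reads, n = 19876): 0.000% overall
#>   H to L: 0.000%
#>   L to H: 0.000%

cnt    <- count_reads(cls, aln, catalog, sample_id = "leaf1")
counts <- distribute_common(cnt$counts, cnt$common)
ratios <- phat(counts, focal = "H")
mean(ratios$phat, na.rm = TRUE)
#> [1] 0.701
```

The classifier recovers every fragment that crosses a discriminating site
(124 fragments fell between variants and are subgenome-common), no read is
assigned to the wrong subgenome, and the mean homeolog expression
proportion recovers the planted 0.7.

The same stages are available from a shell via the bundled script
(`inst/cli/homeoquant`): `simulate`, `catalog`, `classify`, `quantify`,
`deh`, `evaluate`, each writing TSV/JSON artifacts so externally produced
alignments can be injected between stages.

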