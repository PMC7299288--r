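---
title: "Subgenome read classification and homeolog expression quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subgenome read classification and homeolog expression quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homeoquant)
```

## Motivation and model

An allopolyploid genome contains two (tetraploid) or three (hexaploid)
parental subgenomes. Homeologs — the duplicated gene copies across
subgenomes — are highly similar (a recent allotetraploid such as
*Arabidopsis kamchatica* shows roughly 2–3% divergence between homeologs),
so a short read frequently aligns almost equally well to both copies.
homeoquant quantifies homeolog expression by *subgenome classification*:
reads are aligned to each subgenome reference separately and each fragment
is assigned to the subgenome it most plausibly came from, to a
subgenome-common class, or discarded as unknown.

### The homeolog catalog

Homeologs are paired by reciprocal best hit (RBH) between the subgenome
transcript sets. Transcript pairs are aligned with a global
free-end-gap (overlap) affine-gap aligner (`Biostrings::pairwiseAlignment`
under the hood; defaults match +2, mismatch −3, gap open 5, gap extend 2).
A pair is kept when each transcript is the other's best hit, the E-value is
below `1e-10`, and at least 200 bases are aligned in *both* transcripts.
E-values use the Karlin–Altschul form `E = K·m·n·exp(−λS)` with fixed
constants `K = 0.41`, `λ = 0.625`: only the ordering of hits and the
`1e-10` cut matter, so the constants are documented defaults rather than
per-search estimates. Ties on score are broken by lexicographic target id
so runs are deterministic. For hexaploids, a pair (a, b) from the AB list
becomes a triple with d exactly when (a, d) and (b, d) appear in the AD and
BD lists for the same d.

All-vs-all alignment is avoided by a shared-k-mer prefilter (15-mers,
top 3 candidate partners per query) before alignment — a seeding heuristic
in the spirit of the aligners used for this task. On realistic transcript
sets at a few percent divergence the true partner dominates the k-mer
counts by a wide margin.

Within each group, every mismatch or gap column of the pairwise
alignment(s) becomes a *discriminating variant* with per-subgenome
transcript coordinates and alleles; adjacent gap columns are merged into
single indel events (one biological event, one variant). For triples the
sites of the anchor–B and anchor–D alignments are merged by anchor
position; sites in regions not aligned to the anchor (first subgenome) are
not enumerated, and classification only uses sites where every member has
a defined allele, so all hypotheses are always evaluated on a common site
set. Regions outside the aligned blocks are recorded: fragments falling
entirely in such regions cannot be classified and are reported unknown,
mirroring the exclusion of exons that were never pairwise aligned.

### Read classification

**Likelihood rule.** For a fragment aligned to subgenome frame *f*, let
`e_i = 10^(−q_i/10)` be the Phred-implied error probability at
discriminating site *i* covered by the read. Under subgenome hypothesis
*G* the site contributes `log(1 − e_i)` if the read base equals *G*'s
allele and `log(e_i/3)` otherwise (a deletion allele mismatches every
base). Mates of a fragment are summed. The posterior of the reference
hypothesis is its likelihood over the sum across all reference hypotheses
— two terms for ploidy 2, three for ploidy 3 with one shared denominator.
The winning hypothesis is accepted only if its posterior is at least
`p_min = 0.95` and its marginal probability (winner over the sum of all
reference-hypothesis posteriors) is at least `marginal_min = 0.51`;
otherwise the fragment is unknown. Exactly tied likelihoods, or fragments
covering no discriminating site, are subgenome-common: they carry no
information about the origin but are usable for proportional
distribution. Since the hypotheses share one denominator the marginal
equals the posterior; it is still computed as written, for fidelity to the
published decision rule.

**Mismatch rule.** The fragment's mismatch counts (SAM `NM`, or derived
from `MD`) against each subgenome are compared; alignments with more than
`max_mismatches = 10` are treated as unmappable; the fragment must be
mappable to all subgenomes under comparison (otherwise unknown); strictly
fewest mismatches wins and ties are common. This requires no variant
catalog but is blind to *where* the mismatches fall.

**Hexaploid bottom-up.** Classification runs on the three pairwise
comparisons AB, AD, BD. In consensus mode a read is labeled A exactly when
both comparisons involving A voted A (likewise B and D); a read common in
all three comparisons is common; every other pattern is unknown. In
max-posterior mode the three per-subgenome likelihoods enter one
three-term posterior and the thresholds above apply. Pairwise comparisons
in consensus mode use only the sites that discriminate that particular
pair.

**Mate handling.** The published procedure classifies "reads" without
specifying paired-end handling; homeoquant classifies per fragment,
summing mate log-likelihoods and mismatch counts. If only one mate maps,
it alone decides. This is the natural fragment-level analogue and makes
the counting unambiguous.

### Quantification and ratios

Classified fragments increment the homeolog member on their assigned
subgenome when the alignment overlaps that transcript's exons by at least
one base; fragments overlapping more than one feature on the assigned
subgenome are dropped (transcript-level counting without multi-mapper
rescue, the behavior of the standard counting tools this mirrors).
Subgenome-common fragments are held aside and can be distributed across
subgenomes proportionally to the classified base counts
(`distribute_common`, equal split when all base counts are zero). The
distribution step is opt-in: classification-error evaluation uses raw
classified counts, expression reporting typically adds the distributed
common mass. The homeolog expression proportion is
`p̂ = focal count / total across subgenomes` (NA when the total is zero).

### Differential homeolog expression

A homeolog group is differentially expressed (DEH) when two independent
conditions hold: (i) its expression changes between conditions with
FDR ≤ 0.05 (Benjamini–Hochberg) in at least one subgenome — by default a
built-in exact conditional binomial test of the replicate-summed counts
against the library-size-ratio null, or externally supplied q-values from
a dedicated DE package, which is the route to reproduce published filters
exactly; and (ii) Fisher's exact test on the replicate-combined 2×2 table
(focal vs rest, condition 1 vs condition 2) gives P < 0.05 with fold
change ≥ 2. For hexaploids the three contrasts A vs BD, B vs AD, D vs AB
are tested at the Bonferroni level 0.05/3. No further FDR correction is
applied to the Fisher tests, reproducing the published procedure. The
"fold change" of a ratio shift is not defined in the original procedure;
homeoquant uses the symmetrized odds ratio `max(OR, 1/OR)` of the 2×2
table — the effect size native to Fisher's test — with a Haldane 0.5
correction when the table contains a zero. Replicate-level inference is
carried by the DE filter; the Fisher test intentionally runs on combined
counts.

### Evaluation

Because published error rates switch denominators between analyses, the
error report makes the denominator explicit: `mapped` (all mapped
fragments), `classified` (fragments assigned to a subgenome), or
`quantified` (fragments that entered the count table). Errors are reported
per direction (H→L, L→H; AB→D, D→AB). Concordance between quantification
routes uses RMSD `sqrt(Σ(x_i − y_i)²/n)` and the squared sample
correlation r²; groups with undefined p̂ (zero totals) are dropped
pairwise, a choice the original analyses leave unstated. The
expression-stratified comparison partitions groups at total count ≤ 100
(low) and > 200 (high) and compares the stratum RMSDs with a paired
t-test.

## The synthetic data generator

The generator emulates the ground-truth designs that make error
measurable: parental or extracted lines whose reads have a known subgenome
of origin (diploid parents for the tetraploid case; an AB-only extracted
line and a D-only diploid relative for the hexaploid case).

* An ancestral transcript is drawn per gene (lengths uniform in
  1.2–1.8 kb by default); each subgenome copy receives independent
  substitutions at rate `snp_divergence` per base, so pairwise divergence
  is ≈ `2d(1−d)` plus a small coincident-mutation term. The default
  `d = 0.0125` gives ~2.5% pairwise divergence, the middle of the 2–3%
  estimate for the recent-allotetraploid study system.
* `annotation_asymmetry` gives a gene, with that probability, an extra
  unalignable 3′ exon on the first subgenome — the asymmetric-annotation
  situation in which one homeolog is much longer and partly unalignable.
* Reads are 2×100 bp fragments of 200 bp, allocated to genes by fixed
  log-normal weights, to subgenomes by the focal proportion π, uniformly
  within transcripts, with base errors injected at the Phred-30 rate by
  default. The truth table records every fragment's origin and injected
  errors.
* Alignments are *projected*: each fragment is emitted at its exact source
  coordinates and lifted to the other subgenome(s) through the (identity,
  when indels are off) homeolog coordinate map, with the
  divergence-induced mismatches materialized in the `NM` counts. A
  fragment whose window extends past the shared core gets no
  cross-subgenome record. Projection requires `indel_rate = 0`; externally
  produced SAM can be injected instead via the CLI stages.
* The k-mer simulation duplicates sampled genes, assigns SNPs at each
  divergence level and counts the k-mer windows unique to one copy — the
  quantity that controls how much of a pseudo-alignment index remains
  informative when a second gene copy appears. The design default is 1000
  trials of 100 genes at k = 31; the test suite runs smaller replicates
  (10–20 trials of 20–25 genes), which is ample for the exact single-SNP
  oracle and the monotonicity property.

What the generator deliberately does not emulate: positional or GC bias,
empirical quality profiles, intron-containing genomic alignment,
transposon activation or rearrangements after polyploidization, and
within-species divergence between the sequenced accession and its
reference (the last is exercised separately in the evaluation tests by
mutating a source accession away from its reference). Passing tests on
generated data therefore demonstrate correctness of the classification
and counting logic under a clean error model, not robustness to every
artifact of real libraries.

## Numerical and design choices

* Internal coordinates are 0-based half-open everywhere; GFF3 and SAM
  conventions are converted at I/O only.
* Mismatch counts prefer `NM` and fall back to `MD`; soft-clipped bases
  never count. Records with neither tag are an error rather than a guess.
* The multi-transcript-gene policy for RBH is longest-transcript-per-gene
  (gene-level homeolog notion); the simulator emits one transcript per
  gene so the policy only matters for imported annotations.
* Posterior computation subtracts the max log-likelihood before
  exponentiating; exact ties are detected on log-likelihoods, not
  posteriors.
* `classify_posteriors` demands at least two hypotheses; a single
  hypothesis is a caller error, not a trivial classification.
* The built-in DE filter requires ≥ 2 replicates per condition and refuses
  to run otherwise, pointing to the external-q-value route.
* Degenerate inputs: empty FASTA yields an empty record set with a
  warning; an all-zero Fisher table returns p = 1, fold change 1; zero
  variance makes r² NA with a warning; zero-total groups give NA p̂.
* Seeds: every stochastic function takes an explicit seed (or inherits the
  config seed); a fixed seed makes FASTA/FASTQ/SAM/TSV outputs
  byte-identical, which the test suite asserts.

## Problem sizes used in the bundled checks

The acceptance benchmark simulates 3 × 100,000 fragments over 200
transcripts and classifies them with both rules (about a minute on one
core). The test suite's statistical checks use 10–50 gene sets with
400–30,000 fragments, three seeds where a property is asserted
statistically, and exhaustive enumeration where the domain is small (all
2×2 tables with total ≤ 30 for the Fisher oracle, all 27 vote triples for
the hexaploid consensus rule).

## Known limitations

* Likelihood classification evaluates alternative hypotheses by allele
  substitution in the frame of the read's own alignment; it does not
  re-align the read to the other subgenome. Very indel-rich homeologs are
  therefore better served by the mismatch rule or by supplying real
  cross-alignments.
* B–D variants in triple groups falling in regions unaligned to the anchor
  subgenome are not enumerated (anchor-frame merge).
* The built-in DE filter is a deliberately simple exact test on summed
  counts; it does not model biological dispersion and is not a substitute
  for a dedicated DE package when replicate variability matters — the
  external q-value route exists precisely for that.
* Counting is fragment-level with no multi-mapper rescue or EM
  redistribution; the proportional distribution of common reads is the
  only sharing mechanism.
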