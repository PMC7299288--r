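## Shared fixtures and independent oracles for the test suite.

## deterministic random sequence
rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## substitute specific 1-based positions of a sequence with given bases
subst_at <- function(s, pos, base) {
  ch <- strsplit(s, "")[[1]]
  ch[pos] <- base
  paste(ch, collapse = "")
}

## a minimal two-subgenome catalog: one group, one transcript pair of length
## `len`, SNP variants at the given 0-based positions (H allele = ref base,
## L allele = a different base)
toy_catalog <- function(len = 100L, snp_pos = c(20L, 60L), seed = 42L) {
  set.seed(seed)
  h <- rand_seq(len)
  ch <- strsplit(h, "")[[1]]
  l <- ch
  for (p in snp_pos) {
    l[p + 1L] <- setdiff(c("A", "C", "G", "T"), ch[p + 1L])[1]
  }
  l <- paste(l, collapse = "")
  variants <- data.table::rbindlist(lapply(seq_along(snp_pos), function(i) {
    data.table::data.table(group_id = "g1", variant_id = i, kind = "SNP",
                           subgenome = c("H", "L"), pos = snp_pos[i],
                           allele = c(substr(h, snp_pos[i] + 1L, snp_pos[i] + 1L),
                                      substr(l, snp_pos[i] + 1L, snp_pos[i] + 1L)))
  }))
  catalog <- structure(list(
    subgenomes = c("H", "L"),
    groups = data.table::data.table(group_id = "g1", ploidy = 2L),
    members = data.table::data.table(group_id = "g1", subgenome = c("H", "L"),
                                     transcript_id = c("tH", "tL"),
                                     aligned_fraction = 1),
    variants = variants,
    blocks = data.table::data.table(group_id = "g1", sub_q = "H", sub_t = "L",
                                    q_start = 0L, q_end = len,
                                    t_start = 0L, t_end = len)),
    class = "homeolog_catalog")
  list(catalog = catalog, seq_h = h, seq_l = l)
}

## one alignment-table row
aln_row <- function(read_id, subgenome, contig, pos, seq,
                    qual = strrep("I", nchar(seq)), mate = 0L,
                    cigar = paste0(nchar(seq), "M"), mismatches = 0L,
                    mapq = 60L, is_secondary = FALSE) {
  data.table::data.table(read_id = read_id, mate = mate,
                         subgenome = subgenome, contig = contig, pos = pos,
                         cigar = cigar, mismatches = mismatches, mapq = mapq,
                         seq = seq, qual = qual, is_secondary = is_secondary)
}

## ---- independent oracles -------------------------------------------------

## Needleman-Wunsch with affine gaps and free end gaps, returning the score
## (oracle for the overlap aligner on short sequences)
nw_overlap_score <- function(a, b, match = 2, mismatch = -3, gap_open = 5,
                             gap_extend = 2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  X[, 1] <- 0; X[1, ] <- NEG; X[1, 1] <- 0   # free end gaps
  Y[1, ] <- 0; Y[, 1] <- NEG; Y[1, 1] <- 0
  for (i in 1:n) X[i + 1, 1] <- 0
  for (j in 1:m) Y[1, j + 1] <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      s <- if (av[i] == bv[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                             X[i, j + 1] - gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                             Y[i + 1, j] - gap_extend)
    }
  }
  ## free end gaps: best score over last row/column; the empty alignment
  ## (everything in end gaps) scores 0
  max(0, M[n + 1, ], M[, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

## two-sided Fisher p by exhaustive enumeration over the hypergeometric
## support with fixed margins
fisher_p_oracle <- function(a, b, c_, d) {
  m <- a + b; n2 <- c_ + d; k <- a + c_
  if (m + n2 == 0) return(1)
  lo <- max(0, k - n2); hi <- min(k, m)
  xs <- lo:hi
  probs <- stats::dhyper(xs, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## per-base product oracle for the read likelihood model
loglik_oracle <- function(read_bases, quals, alleles) {
  stopifnot(nchar(read_bases) == length(alleles))
  rb <- strsplit(read_bases, "")[[1]]
  e <- 10^(-(utf8ToInt(quals) - 33) / 10)
  sum(ifelse(rb == alleles & alleles != "-", log(1 - e), log(e / 3)))
}

## textbook formulas for rmsd and squared correlation
rmsd_oracle <- function(x, y) sqrt(sum((x - y)^2) / length(x))
r2_oracle <- function(x, y) {
  (sum((x - mean(x)) * (y - mean(y))))^2 /
    (sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
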