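## Synthetic allopolyploid data: subgenomes diverged from a shared ancestral
## transcript set, expression-weighted paired-end reads with Phred errors and
## recorded origin truth, alignments projected to every subgenome by
## coordinate lift-over, and the k-mer uniqueness simulation.

BASES <- c("A", "C", "G", "T")

#' Simulation configuration
#'
#' Defaults describe the study conditions the generator emulates: ~1.5 kb
#' transcripts, per-copy substitution rate 0.0125 from the shared ancestor
#' (~2.5% pairwise divergence between homeologs, matching the 2-3% estimate
#' for a recent allotetraploid), 100 bp paired-end reads at Phred 30.
#'
#' @param n_genes number of ancestral genes.
#' @param gene_length_range transcript length range (bases).
#' @param ploidy 2 or 3.
#' @param subgenomes labels; default H/L (ploidy 2) or A/B/D (ploidy 3).
#' @param snp_divergence per-base substitution rate applied independently to
#'   each subgenome copy (pairwise divergence is ~ 2d(1-d) plus a small
#'   coincident-mutation correction).
#' @param indel_rate per-base indel rate per copy (alignment projection
#'   requires 0).
#' @param annotation_asymmetry probability that a gene's annotation differs
#'   between subgenomes (the first subgenome's copy gains an extra,
#'   unalignable 3' exon).
#' @param expression list: `sdlog` of the log-normal gene expression
#'   weights and `pi`, the focal-subgenome (first label) read proportion.
#' @param read_length,fragment_length read and fragment lengths (bases).
#' @param fragments_per_sample fragments simulated per sample.
#' @param base_quality uniform Phred base quality of simulated reads.
#' @param paired paired-end if TRUE.
#' @param seed integer seed; a fixed seed makes all outputs byte-identical.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200L, gene_length_range = c(1200L, 1800L),
                       ploidy = 2L, subgenomes = NULL,
                       snp_divergence = 0.0125, indel_rate = 0,
                       annotation_asymmetry = 0,
                       expression = list(sdlog = 1, pi = 0.5),
                       read_length = 100L, fragment_length = 200L,
                       fragments_per_sample = 100000L, base_quality = 30L,
                       paired = TRUE, seed = 1L) {
  if (is.null(subgenomes)) {
    subgenomes <- if (ploidy == 2L) c("H", "L") else c("A", "B", "D")
  }
  stopifnot(length(subgenomes) == ploidy,
            snp_divergence >= 0, snp_divergence <= 1,
            indel_rate >= 0, indel_rate <= 1,
            annotation_asymmetry >= 0, annotation_asymmetry <= 1,
            n_genes >= 0)
  structure(list(n_genes = as.integer(n_genes),
                 gene_length_range = as.integer(gene_length_range),
                 ploidy = as.integer(ploidy), subgenomes = subgenomes,
                 snp_divergence = snp_divergence, indel_rate = indel_rate,
                 annotation_asymmetry = annotation_asymmetry,
                 expression = utils::modifyList(list(sdlog = 1, pi = 0.5),
                                                expression),
                 read_length = as.integer(read_length),
                 fragment_length = as.integer(fragment_length),
                 fragments_per_sample = as.integer(fragments_per_sample),
                 base_quality = as.integer(base_quality), paired = paired,
                 seed = as.integer(seed)),
            class = "sim_config")
}

random_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

## substitute each base independently with probability rate (to a different
## base); returns list(seq, pos (0-based), alleles)
mutate_seq <- function(s, rate) {
  n <- nchar(s)
  hit <- which(stats::runif(n) < rate)
  if (length(hit) == 0L) return(list(seq = s, pos = integer(0),
                                     allele = character(0)))
  ch <- strsplit(s, "")[[1]]
  old <- ch[hit]
  new <- vapply(old, function(b) sample(setdiff(BASES, b), 1L), character(1))
  ch[hit] <- new
  list(seq = paste(ch, collapse = ""), pos = hit - 1L, allele = unname(new))
}

apply_indels <- function(s, rate) {
  n <- nchar(s)
  k <- stats::rbinom(1L, n, rate)
  if (k == 0L) return(s)
  ch <- strsplit(s, "")[[1]]
  pos <- sort(sample(seq_len(n - 1L), k))
  for (p in rev(pos)) {
    if (stats::runif(1) < 0.5 && length(ch) > p + 3L) {
      ch <- ch[-(p:(p + sample(1:3, 1L) - 1L))]          # deletion
    } else {
      ch <- append(ch, sample(BASES, sample(1:3, 1L), replace = TRUE), p)
    }
  }
  paste(ch, collapse = "")
}

#' Simulate diverged subgenomes from a shared ancestor
#'
#' Generates an ancestral transcript per gene, derives each subgenome copy
#' by independent substitutions (and optional indels), optionally makes a
#' gene's annotation asymmetric (extra unalignable 3' exon on the first
#' subgenome's copy), and records the planted variant table by comparing
#' the final copies (exact when `indel_rate = 0`).
#'
#' @param config a [sim_config()].
#' @return list of class `sim_genomes`: config, seqs (named list per
#'   subgenome of transcript sequences), transcripts and exons tables,
#'   `gene_weights` (log-normal expression weights shared by all samples),
#'   and `planted` (data.table gene_id, variant_id, kind, subgenome, pos,
#'   allele; NULL when indels were simulated).
#' @export
simulate_subgenomes <- function(config) {
  if (config$n_genes == 0L) stop("n_genes must be positive")
  set.seed(config$seed)
  subs <- config$subgenomes
  lens <- sample(config$gene_length_range[1]:config$gene_length_range[2],
                 config$n_genes, replace = TRUE)
  gene_ids <- sprintf("g%04d", seq_len(config$n_genes))
  asym <- stats::runif(config$n_genes) < config$annotation_asymmetry
  seqs <- setNames(vector("list", length(subs)), subs)
  for (s in subs) seqs[[s]] <- character(config$n_genes)
  planted <- list()
  transcripts <- list(); exons <- list()
  for (i in seq_len(config$n_genes)) {
    anc <- random_seq(lens[i])
    core <- setNames(character(length(subs)), subs)
    site_map <- list()
    for (s in subs) {
      m <- mutate_seq(anc, config$snp_divergence)
      core[s] <- m$seq
    }
    if (config$indel_rate > 0) {
      for (s in subs) core[s] <- apply_indels(core[s], config$indel_rate)
    } else {
      ## planted variant table from the final copies: positions where any
      ## pair of copies differs
      mats <- vapply(core, function(x) strsplit(x, "")[[1]],
                     character(lens[i]))
      diff_pos <- which(apply(mats, 1, function(r) length(unique(r)) > 1L))
      if (length(diff_pos) > 0L) {
        planted[[length(planted) + 1L]] <- data.table::data.table(
          gene_id = gene_ids[i],
          variant_id = seq_along(diff_pos),
          kind = "SNP",
          subgenome = rep(subs, each = length(diff_pos)),
          pos = rep(diff_pos - 1L, length(subs)),
          allele = as.vector(mats[diff_pos, ]))
      }
    }
    for (si in seq_along(subs)) {
      s <- subs[si]
      tid <- paste0(gene_ids[i], "_", s)
      full <- core[s]
      n_ex <- 1L
      if (asym[i] && si == 1L) {
        extra <- random_seq(max(200L, round(0.25 * lens[i])))
        full <- paste0(full, extra)
        n_ex <- 2L
      }
      seqs[[s]][i] <- full
      transcripts[[length(transcripts) + 1L]] <- data.table::data.table(
        gene_id = gene_ids[i], transcript_id = tid, subgenome = s,
        contig = tid, strand = "+", spliced_length = nchar(full))
      if (n_ex == 1L) {
        exons[[length(exons) + 1L]] <- data.table::data.table(
          transcript_id = tid, start = 0L, end = nchar(full))
      } else {
        exons[[length(exons) + 1L]] <- data.table::data.table(
          transcript_id = tid, start = c(0L, nchar(core[s])),
          end = c(nchar(core[s]), nchar(full)))
      }
    }
  }
  for (s in subs) names(seqs[[s]]) <- paste0(gene_ids, "_", s)
  weights <- stats::rlnorm(config$n_genes, meanlog = 0,
                           sdlog = config$expression$sdlog)
  structure(list(config = config, subgenomes = subs, seqs = seqs,
                 transcripts = data.table::rbindlist(transcripts),
                 exons = data.table::rbindlist(exons),
                 gene_weights = setNames(weights, gene_ids),
                 asymmetric = setNames(asym, gene_ids),
                 core_lengths = setNames(lens, gene_ids),
                 planted = if (config$indel_rate == 0)
                   data.table::rbindlist(planted) else NULL),
            class = "sim_genomes")
}

#' Simulate expression-weighted paired reads with recorded truth
#'
#' Fragments are allocated to genes by the genome set's log-normal weights,
#' to subgenomes by the focal proportion `pi` (first subgenome; the
#' remainder is split equally among the others), and uniformly within the
#' transcript. Base errors are injected at the Phred-implied rate. Both
#' mates are stored in reference orientation.
#'
#' @param genomes a `sim_genomes`.
#' @param sample_id sample name (part of read ids).
#' @param n_fragments number of fragments (default from the config).
#' @param pi focal-subgenome proportion (default from the config).
#' @param seed seed for this sample (default: config seed).
#' @return list of class `sim_reads`: `reads` (read_id, mate, seq, qual),
#'   `truth` (read_id, subgenome, gene_id, transcript_id, frag_start,
#'   n_err1, n_err2) and `sample_id`.
#' @export
simulate_reads <- function(genomes, sample_id = "s1", n_fragments = NULL,
                           pi = NULL, seed = NULL) {
  cfg <- genomes$config
  n_fragments <- n_fragments %||% cfg$fragments_per_sample
  pi <- pi %||% cfg$expression$pi
  set.seed(seed %||% cfg$seed)
  subs <- genomes$subgenomes
  rl <- cfg$read_length
  fl <- if (cfg$paired) cfg$fragment_length else cfg$read_length
  e <- 10^(-cfg$base_quality / 10)
  qual <- paste(rep(rawToChar(as.raw(cfg$base_quality + 33L)), rl),
                collapse = "")

  ## skip transcripts shorter than the fragment (warn once)
  min_len <- min(nchar(unlist(genomes$seqs)))
  if (min_len < fl) {
    warning("transcripts shorter than the fragment length are skipped")
  }
  w <- genomes$gene_weights
  ## per-gene minimum copy length across subgenomes
  gene_min <- vapply(names(w), function(g) {
    min(vapply(subs, function(s) {
      nchar(genomes$seqs[[s]][[paste0(g, "_", s)]])
    }, numeric(1)))
  }, numeric(1))
  usable <- gene_min >= fl
  w <- w[usable]
  gene <- sample(names(w), n_fragments, replace = TRUE, prob = w)
  p_sub <- c(pi, rep((1 - pi) / (length(subs) - 1L), length(subs) - 1L))
  sub <- sample(subs, n_fragments, replace = TRUE, prob = p_sub)
  tid <- paste0(gene, "_", sub)
  tlen <- vapply(seq_len(n_fragments), function(i) {
    nchar(genomes$seqs[[sub[i]]][[tid[i]]])
  }, numeric(1))
  start <- floor(stats::runif(n_fragments) * (tlen - fl + 1L))
  read_id <- sprintf("%s_f%06d", sample_id, seq_len(n_fragments))

  txseq <- unlist(genomes$seqs, use.names = FALSE)
  names(txseq) <- unlist(lapply(genomes$seqs, names), use.names = FALSE)
  s1 <- substring(txseq[tid], start + 1L, start + rl)
  inject_errors <- function(sv) {
    k <- stats::rbinom(length(sv), rl, e)
    idx <- which(k > 0L)
    for (i in idx) {
      ch <- strsplit(sv[i], "")[[1]]
      p <- sample.int(rl, k[i])
      ch[p] <- vapply(ch[p], function(b) sample(setdiff(BASES, b), 1L),
                      character(1))
      sv[i] <- paste(ch, collapse = "")
    }
    list(seq = unname(sv), n_err = k)
  }
  r1 <- inject_errors(s1)
  if (cfg$paired) {
    s2 <- substring(txseq[tid], start + fl - rl + 1L, start + fl)
    r2 <- inject_errors(s2)
    reads <- data.table::data.table(
      read_id = rep(read_id, 2L),
      mate = rep(c(1L, 2L), each = n_fragments),
      seq = c(r1$seq, r2$seq),
      qual = qual)
  } else {
    r2 <- list(n_err = rep(NA_integer_, n_fragments))
    reads <- data.table::data.table(read_id = read_id, mate = 0L,
                                    seq = r1$seq, qual = qual)
  }
  truth <- data.table::data.table(read_id = read_id, subgenome = sub,
                                  gene_id = gene, transcript_id = tid,
                                  frag_start = as.integer(start),
                                  n_err1 = r1$n_err, n_err2 = r2$n_err)
  structure(list(reads = reads, truth = truth, sample_id = sample_id,
                 config = cfg),
            class = "sim_reads")
}

#' Project simulated reads to alignments on every subgenome
#'
#' Emits each fragment as an exact-coordinate alignment to its source
#' transcript and, where the homeolog correspondence covers the window, a
#' lifted alignment to every other subgenome with the divergence-induced
#' mismatches materialized in the mismatch count. Reads extending into
#' regions without a homeolog counterpart (the asymmetric extra exon) get
#' no cross-subgenome record. Requires `indel_rate = 0` (identity
#' coordinate map on the shared core).
#'
#' @param sim a `sim_reads`.
#' @param genomes the `sim_genomes` the reads came from.
#' @param mapq mapping quality stamped on every record.
#' @return alignment table in the [read_sam()] layout.
#' @export
project_alignments <- function(sim, genomes, mapq = 60L) {
  cfg <- genomes$config
  if (cfg$indel_rate > 0) {
    stop("alignment projection requires indel_rate = 0")
  }
  subs <- genomes$subgenomes
  rl <- cfg$read_length
  fl <- if (cfg$paired) cfg$fragment_length else rl
  truth <- sim$truth
  reads <- sim$reads
  core_len <- genomes$core_lengths
  txseq <- unlist(genomes$seqs, use.names = FALSE)
  names(txseq) <- unlist(lapply(genomes$seqs, names), use.names = FALSE)

  mates <- if (cfg$paired) 1:2 else 0L
  ## fragment-level liftability: a fragment whose window extends past the
  ## shared core gets no cross-subgenome records at all (its mate pair
  ## cannot be placed on the other subgenome)
  frag_in_core <- truth$frag_start + fl <= core_len[truth$gene_id]
  out <- list()
  for (m in mates) {
    rm_ <- reads[mate == m]
    rm_ <- rm_[match(truth$read_id, read_id)]
    mstart <- if (m == 2L) truth$frag_start + fl - rl else truth$frag_start
    for (s in subs) {
      tgt_tid <- paste0(truth$gene_id, "_", s)
      is_source <- truth$subgenome == s
      keep <- is_source | frag_in_core
      if (!any(keep)) next
      tseq <- substring(txseq[tgt_tid[keep]], mstart[keep] + 1L,
                        mstart[keep] + rl)
      nm <- str_mismatch_counts(rm_$seq[keep], tseq)
      out[[paste(m, s)]] <- data.table::data.table(
        read_id = truth$read_id[keep],
        mate = m,
        subgenome = s,
        contig = tgt_tid[keep],
        pos = mstart[keep],
        cigar = paste0(rl, "M"),
        mismatches = as.integer(nm),
        mapq = as.integer(mapq),
        seq = rm_$seq[keep],
        qual = rm_$qual[keep],
        is_secondary = FALSE)
    }
  }
  aln <- data.table::rbindlist(out)
  data.table::setorder(aln, read_id, mate, subgenome)
  aln[]
}

#' Build a homeolog catalog directly from the planted truth
#'
#' Bypasses alignment: uses the simulator's gene pairing and planted
#' variant table. Intended for fast pipeline tests; [build_catalog()] is
#' the inference route.
#'
#' @param genomes a `sim_genomes` (indel_rate must be 0).
#' @return a `homeolog_catalog` whose groups are the simulated genes.
#' @export
catalog_from_truth <- function(genomes) {
  if (is.null(genomes$planted)) {
    stop("planted catalog requires indel_rate = 0")
  }
  subs <- genomes$subgenomes
  genes <- names(genomes$gene_weights)
  members <- data.table::rbindlist(lapply(genes, function(g) {
    data.table::data.table(group_id = g, subgenome = subs,
                           transcript_id = paste0(g, "_", s = subs),
                           aligned_fraction = vapply(subs, function(s) {
                             genomes$core_lengths[g] /
                               nchar(genomes$seqs[[s]][[paste0(g, "_", s)]])
                           }, numeric(1)))
  }))
  if (nrow(genomes$planted) > 0L) {
    variants <- data.table::copy(genomes$planted)
    data.table::setnames(variants, "gene_id", "group_id")
  } else {
    variants <- data.table::data.table(group_id = character(),
                                       variant_id = integer(),
                                       kind = character(),
                                       subgenome = character(),
                                       pos = integer(), allele = character())
  }
  blocks <- data.table::rbindlist(lapply(genes, function(g) {
    data.table::data.table(group_id = g, sub_q = subs[1], sub_t = subs[-1],
                           q_start = 0L, q_end = genomes$core_lengths[[g]],
                           t_start = 0L, t_end = genomes$core_lengths[[g]])
  }))
  structure(list(subgenomes = subs,
                 groups = data.table::data.table(group_id = genes,
                                                 ploidy = length(subs)),
                 members = members, variants = variants, blocks = blocks),
            class = "homeolog_catalog")
}

#' Count k-mers that discriminate two gene copies
#'
#' @param seq_a,seq_b the two copies.
#' @param k k-mer length.
#' @return named vector: windows of each copy absent from the other copy
#'   (`unique_a`, `unique_b`) and total windows per copy (`windows`).
#' @export
count_discriminating_kmers <- function(seq_a, seq_b, k = 31L) {
  if (k > nchar(seq_a) || k > nchar(seq_b)) {
    stop("k exceeds the gene length")
  }
  wa <- substring(seq_a, 1:(nchar(seq_a) - k + 1L), k:nchar(seq_a))
  wb <- substring(seq_b, 1:(nchar(seq_b) - k + 1L), k:nchar(seq_b))
  c(unique_a = sum(!wa %in% wb), unique_b = sum(!wb %in% wa),
    windows = length(wa))
}

#' Unique-k-mer reduction under duplicated gene copies
#'
#' For each trial, a random gene set is duplicated and one copy receives
#' SNPs at each divergence level; the fraction of k-mer windows unique to
#' one copy (i.e. still informative about which copy a read came from) is
#' reported per divergence as mean and sd over trials.
#'
#' @param gene_seqs optional character vector of gene sequences to sample
#'   from; when NULL a random pool is generated.
#' @param gene_set_size genes per trial (design default 100).
#' @param trials number of trials (design default 1000).
#' @param k k-mer length (default 31, the pseudo-alignment regime).
#' @param divergence_grid per-base SNP rates to scan.
#' @param gene_length length of generated pool genes.
#' @param pool_size size of the generated pool.
#' @param seed integer seed.
#' @return data.table divergence, mean_unique_fraction, sd_unique_fraction,
#'   n_trials; the mean is monotone non-decreasing in divergence.
#' @export
kmer_uniqueness_sim <- function(gene_seqs = NULL, gene_set_size = 100L,
                                trials = 1000L, k = 31L,
                                divergence_grid = c(0.005, 0.01, 0.02, 0.03),
                                gene_length = 1000L, pool_size = 500L,
                                seed = 1L) {
  set.seed(seed)
  if (is.null(gene_seqs)) {
    gene_seqs <- vapply(seq_len(pool_size), function(i) {
      random_seq(gene_length)
    }, character(1))
  }
  if (k > min(nchar(gene_seqs))) stop("k exceeds the shortest gene")
  res <- matrix(NA_real_, trials, length(divergence_grid))
  for (tr in seq_len(trials)) {
    genes <- sample(gene_seqs, min(gene_set_size, length(gene_seqs)))
    for (di in seq_along(divergence_grid)) {
      d <- divergence_grid[di]
      uniq <- 0; tot <- 0
      for (g in genes) {
        copy <- mutate_seq(g, d)$seq
        cnt <- count_discriminating_kmers(g, copy, k)
        uniq <- uniq + cnt[["unique_a"]] + cnt[["unique_b"]]
        tot <- tot + 2L * cnt[["windows"]]
      }
      res[tr, di] <- uniq / tot
    }
  }
  data.table::data.table(divergence = divergence_grid,
                         mean_unique_fraction = colMeans(res),
                         sd_unique_fraction = apply(res, 2, stats::sd),
                         n_trials = trials)
}

#' Simulate replicate homeolog count tables for two conditions
#'
#' Direct count-level generator for differential-homeolog-expression
#' studies: per group, replicate totals are negative binomial around a mean
#' (optionally fold-changed in condition 2 for shifted groups) and the
#' focal-subgenome count is binomial with the condition's proportion.
#'
#' @param n_groups homeolog groups.
#' @param subgenomes subgenome labels (focal first).
#' @param reps replicates per condition (length-2 integer).
#' @param mean_total mean fragment total per group and replicate.
#' @param dispersion negative-binomial dispersion (1/size).
#' @param pi1,pi2 focal proportion in condition 1 and (for shifted groups)
#'   condition 2.
#' @param total_fc2 expression fold change of shifted groups in condition 2.
#' @param prop_shifted fraction of groups with a planted shift.
#' @param seed integer seed.
#' @return list: `counts` (long count table), `conditions` (sample to
#'   condition map) and `shifted` (logical truth per group).
#' @export
simulate_homeolog_counts <- function(n_groups = 200L,
                                     subgenomes = c("H", "L"),
                                     reps = c(3L, 3L), mean_total = 200,
                                     dispersion = 0.05, pi1 = 0.5,
                                     pi2 = 0.5, total_fc2 = 1,
                                     prop_shifted = 0, seed = 1L) {
  set.seed(seed)
  gid <- sprintf("g%04d", seq_len(n_groups))
  shifted <- stats::runif(n_groups) < prop_shifted
  samples <- c(paste0("c1r", seq_len(reps[1])), paste0("c2r", seq_len(reps[2])))
  conditions <- setNames(rep(c("c1", "c2"), reps), samples)
  size <- 1 / dispersion
  rows <- list()
  for (s in samples) {
    c2 <- conditions[[s]] == "c2"
    mu <- ifelse(shifted & c2, mean_total * total_fc2, mean_total)
    tot <- stats::rnbinom(n_groups, mu = mu, size = size)
    p <- ifelse(shifted & c2, pi2, pi1)
    focal <- stats::rbinom(n_groups, tot, p)
    rest <- tot - focal
    if (length(subgenomes) == 2L) {
      rows[[s]] <- data.table::data.table(
        group_id = rep(gid, 2L), sample_id = s,
        subgenome = rep(subgenomes, each = n_groups),
        count = c(focal, rest))
    } else {
      split2 <- stats::rbinom(n_groups, rest, 0.5)
      rows[[s]] <- data.table::data.table(
        group_id = rep(gid, 3L), sample_id = s,
        subgenome = rep(subgenomes, each = n_groups),
        count = c(focal, split2, rest - split2))
    }
  }
  list(counts = data.table::rbindlist(rows), conditions = conditions,
       shifted = setNames(shifted, gid))
}
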