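test_that("overlap aligner recovers identity, substitutions and indels", {
  s <- rand_seq(300, seed = 1)
  hit <- align_transcript_pair(s, s)
  expect_equal(nrow(hit$blocks), 1L)
  expect_equal(hit$aligned_query_bases, 300L)
  expect_equal(hit$aligned_target_bases, 300L)
  expect_lt(hit$evalue, 1e-10)

  s2 <- subst_at(s, 150, setdiff(c("A", "C", "G", "T"),
                                 substr(s, 150, 150))[1])
  hit2 <- align_transcript_pair(s, s2)
  expect_equal(hit2$aligned_query_bases, 300L)
  expect_equal(hit2$aligned_target_bases, 300L)
  v <- pair_alignment_variants(strsplit(hit2$q_aln, "")[[1]],
                               strsplit(hit2$t_aln, "")[[1]],
                               hit2$q_offset, hit2$t_offset)
  expect_equal(nrow(v), 1L)
  expect_equal(v$q_pos, 149L)

  expect_error(align_transcript_pair("", "ACGT"), "zero-length")
})

test_that("single-deletion alignment matches the dynamic-programming oracle", {
  a <- "ACGTACGTAC"
  b <- "ACGTCGTAC"   # a with the base at offset 4 deleted
  hit <- align_transcript_pair(a, b)
  expect_equal(hit$score, nw_overlap_score(a, b))
  expect_equal(hit$blocks,
               data.table::data.table(q_start = c(0L, 5L), q_end = c(4L, 10L),
                                      t_start = c(0L, 4L), t_end = c(4L, 9L)))
  v <- pair_alignment_variants(strsplit(hit$q_aln, "")[[1]],
                               strsplit(hit$t_aln, "")[[1]],
                               hit$q_offset, hit$t_offset)
  expect_equal(v$kind, "deletion")
  expect_equal(v$q_pos, 4L)
})

test_that("alignment scores agree with the DP oracle on random short pairs", {
  set.seed(99)
  for (i in 1:20) {
    a <- rand_seq(sample(10:30, 1))
    b <- rand_seq(sample(10:30, 1))
    hit <- align_transcript_pair(a, b)
    expect_equal(hit$score, nw_overlap_score(a, b),
                 info = paste(a, b))
  }
})

test_that("reciprocal best hits apply the E-value and aligned-base filters", {
  mk <- function(q, t, ev, ab, tb, sc) {
    data.table::data.table(query_id = q, target_id = t, evalue = ev,
                           score = sc, aligned_query_bases = ab,
                           aligned_target_bases = tb)
  }
  ## mutual best, strong hit -> kept
  ab <- mk("a1", "b1", 1e-20, 500L, 500L, 900)
  ba <- mk("b1", "a1", 1e-20, 500L, 500L, 900)
  expect_equal(reciprocal_best_hits(ab, ba)$a, "a1")
  ## weak E-value -> rejected
  expect_equal(nrow(reciprocal_best_hits(
    mk("a1", "b1", 1e-5, 500L, 500L, 30),
    mk("b1", "a1", 1e-5, 500L, 500L, 30))), 0L)
  ## aligned bases below threshold on one side -> rejected
  expect_equal(nrow(reciprocal_best_hits(
    mk("a1", "b1", 1e-20, 150L, 500L, 900),
    mk("b1", "a1", 1e-20, 500L, 150L, 900))), 0L)
  ## not mutual -> rejected
  ab2 <- rbind(mk("a1", "b1", 1e-20, 500L, 500L, 900),
               mk("a1", "b2", 1e-18, 500L, 500L, 800))
  ba2 <- mk("b1", "a2", 1e-20, 500L, 500L, 900)
  expect_equal(nrow(reciprocal_best_hits(ab2, ba2)), 0L)
})

test_that("reciprocal best hits are symmetric in the two directions", {
  set.seed(7)
  hits1 <- data.table::data.table(
    query_id = rep(paste0("a", 1:5), each = 2),
    target_id = paste0("b", c(1, 2, 2, 3, 3, 1, 4, 5, 5, 4)),
    evalue = 10^-sample(15:40, 10), score = sample(300:900, 10),
    aligned_query_bases = 400L, aligned_target_bases = 400L)
  hits2 <- data.table::copy(hits1)
  data.table::setnames(hits2, c("query_id", "target_id",
                                "aligned_query_bases", "aligned_target_bases"),
                       c("target_id", "query_id",
                         "aligned_target_bases", "aligned_query_bases"))
  fwd <- reciprocal_best_hits(hits1, hits2)
  rev <- reciprocal_best_hits(hits2, hits1)
  expect_setequal(paste(fwd$a, fwd$b), paste(rev$b, rev$a))
})

test_that("triple homeolog assembly requires a consistent triangle", {
  pab <- data.table::data.table(a = "a1", b = "b1")
  pad <- data.table::data.table(a = "a1", d = "d1")
  pbd <- data.table::data.table(b = "b1", d = "d1")
  tri <- triple_homeologs(pab, pad, pbd)
  expect_equal(as.data.frame(tri$triples),
               data.frame(a = "a1", b = "b1", d = "d1"))

  ## inconsistent D partners -> pair stays a two-copy homeolog
  tri2 <- triple_homeologs(pab,
                           data.table::data.table(a = "a1", d = "d1"),
                           data.table::data.table(b = "b1", d = "d2"))
  expect_equal(nrow(tri2$triples), 0L)
  expect_true("a1" %in% tri2$pairs$id1)
})

test_that("triple assembly on a 4-pair toy catalog matches exhaustive checking", {
  ## 3 consistent triangles + 1 inconsistent
  pab <- data.table::data.table(a = paste0("a", 1:4), b = paste0("b", 1:4))
  pad <- data.table::data.table(a = paste0("a", 1:4),
                                d = c("d1", "d2", "d3", "d4"))
  pbd <- data.table::data.table(b = paste0("b", 1:4),
                                d = c("d1", "d2", "d3", "dX"))
  tri <- triple_homeologs(pab, pad, pbd)
  ## oracle: exhaustively test every (a,b) against every d
  expected <- list()
  for (i in 1:4) {
    for (dd in unique(c(pad$d, pbd$d))) {
      if (any(pad$a == pab$a[i] & pad$d == dd) &&
          any(pbd$b == pab$b[i] & pbd$d == dd)) {
        expected[[length(expected) + 1]] <- c(pab$a[i], pab$b[i], dd)
      }
    }
  }
  expect_equal(nrow(tri$triples), 3L)
  expect_setequal(paste(tri$triples$a, tri$triples$b, tri$triples$d),
                  vapply(expected, paste, character(1), collapse = " "))
  expect_equal(tri$pairs[subgenomes == "12", id1], "a4")
})

test_that("variant enumeration finds substitutions and aligned fractions", {
  s <- rand_seq(400, seed = 5)
  ## identical members: no variants, full aligned fraction
  ev <- enumerate_variants(c(H = s, L = s))
  expect_equal(nrow(ev$variants), 0L)
  expect_equal(unname(ev$aligned_fraction), c(1, 1))

  ## one substitution at offset 10
  l <- subst_at(s, 11, setdiff(c("A", "C", "G", "T"), substr(s, 11, 11))[1])
  ev2 <- enumerate_variants(c(H = s, L = l))
  expect_equal(nrow(ev2$variants), 2L)  # one site, a row per subgenome
  expect_equal(ev2$variants$pos, c(10L, 10L))
  expect_equal(ev2$variants$kind, c("SNP", "SNP"))
  expect_true(ev2$variants[subgenome == "H", allele] !=
                ev2$variants[subgenome == "L", allele])
})

test_that("partially alignable members report reduced aligned fraction", {
  core <- rand_seq(300, seed = 8)
  extra <- rand_seq(200, seed = 9)
  long_h <- paste0(core, extra)     # 500 bases, only 300 alignable
  ev <- enumerate_variants(c(H = long_h, L = core))
  expect_equal(unname(ev$aligned_fraction["H"]), 300 / 500, tolerance = 0.02)
  expect_equal(unname(ev$aligned_fraction["L"]), 1, tolerance = 0.02)
  ## oracle: column scan of the core region finds no variants there
  expect_true(all(ev$variants[subgenome == "H", pos] < 310))
})

test_that("recovered variant count tracks the planted divergence", {
  ## binomial check: per-gene variant count ~ Binomial(L, pairwise rate)
  cfg <- sim_config(n_genes = 30, gene_length_range = c(900, 1100),
                    snp_divergence = 0.0125, seed = 21)
  g <- simulate_subgenomes(cfg)
  n_sites <- nrow(g$planted) / 2
  L <- sum(g$core_lengths)
  d <- cfg$snp_divergence
  ## two independently mutated copies differ at ~ 2d(1-d) + (coincident
  ## different-base mutations) of positions
  p_diff <- 2 * d * (1 - d) + d^2 * 2 / 3
  expect_lt(abs(n_sites - L * p_diff), 3 * sqrt(L * p_diff * (1 - p_diff)))
})

test_that("catalog inference recovers the planted variant table exactly", {
  cfg <- sim_config(n_genes = 8, gene_length_range = c(700, 900),
                    snp_divergence = 0.0125, indel_rate = 0, seed = 13)
  g <- simulate_subgenomes(cfg)
  cat_b <- build_catalog(g$seqs)
  expect_equal(nrow(cat_b$groups), cfg$n_genes)
  map <- merge(cat_b$members[subgenome == "H"],
               data.table::data.table(
                 transcript_id = paste0(names(g$gene_weights), "_H"),
                 gene_id = names(g$gene_weights)),
               by = "transcript_id")
  v <- merge(cat_b$variants, map[, .(group_id, gene_id)], by = "group_id")
  got <- data.table::setorder(v[, .(gene_id, subgenome, pos, allele)],
                              gene_id, subgenome, pos)
  want <- data.table::setorder(
    g$planted[, .(gene_id, subgenome, pos, allele)],
    gene_id, subgenome, pos)
  expect_equal(as.data.frame(got), as.data.frame(want))
})

test_that("catalog TSV round trip preserves members and variants", {
  cfg <- sim_config(n_genes = 4, gene_length_range = c(500, 600), seed = 3)
  g <- simulate_subgenomes(cfg)
  ct <- catalog_from_truth(g)
  pre <- withr::local_tempfile()
  write_catalog(ct, pre)
  back <- read_catalog(pre)
  expect_equal(as.data.frame(back$members), as.data.frame(ct$members))
  expect_equal(as.data.frame(back$variants), as.data.frame(ct$variants))
})
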