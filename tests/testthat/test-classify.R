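test_that("read likelihood equals the direct per-base product", {
  ## two informative sites, both matching at q30
  q30 <- "?"  # phred 30
  ll <- read_likelihood("AACCA", strrep(q30, 5),
                        alleles = c("A", "C"), positions = c(1L, 3L))
  expect_equal(attr(ll, "n_sites"), 2L)
  expect_equal(as.numeric(ll), log(0.999^2), tolerance = 1e-12)
  expect_equal(as.numeric(ll), -0.002001, tolerance = 1e-6)

  ## one match, one mismatch at q30
  ll2 <- read_likelihood("AACCA", strrep(q30, 5),
                         alleles = c("A", "G"), positions = c(1L, 3L))
  expect_equal(as.numeric(ll2), log(0.999 * 0.001 / 3), tolerance = 1e-12)
  expect_equal(as.numeric(ll2), -8.007, tolerance = 1e-3)

  ## oracle on random cases with mixed qualities
  set.seed(31)
  for (i in 1:25) {
    n <- sample(5:20, 1)
    rb <- rand_seq(n)
    quals <- rawToChar(as.raw(sample(35:70, n, replace = TRUE)))
    alleles <- strsplit(rand_seq(n), "")[[1]]
    got <- read_likelihood(rb, quals, alleles, positions = 0:(n - 1))
    expect_equal(as.numeric(got), loglik_oracle(rb, quals, alleles),
                 tolerance = 1e-12)
  }
})

test_that("read likelihood handles uncovered positions and no information", {
  ## positions outside the read contribute nothing
  ll <- read_likelihood("AAAA", "IIII", alleles = c("A", "C"),
                        positions = c(2L, 50L))
  expect_equal(attr(ll, "n_sites"), 1L)
  ## no informative site -> sentinel, not zero log-likelihood
  ll0 <- read_likelihood("AAAA", "IIII", alleles = "C", positions = 50L)
  expect_true(is.na(ll0))
  expect_equal(attr(ll0, "n_sites"), 0L)
  ## a deletion allele mismatches any read base
  lld <- read_likelihood("AAAA", "IIII", alleles = "-", positions = 1L)
  e <- 10^(-(utf8ToInt("I") - 33) / 10)
  expect_equal(as.numeric(lld), log(e / 3), tolerance = 1e-12)
})

test_that("posterior decision rule applies the 0.95 and 0.51 thresholds", {
  ## equal likelihoods -> posterior 0.5 each -> COMMON
  r <- classify_posteriors(c(H = -1, L = -1))
  expect_equal(r$label, "COMMON")
  expect_equal(unname(r$posteriors), c(0.5, 0.5))

  ## likelihood ratio 99:1 -> posterior 0.99 >= 0.95 -> labeled
  r2 <- classify_posteriors(c(H = log(99), L = log(1)))
  expect_equal(r2$label, "H")
  expect_equal(unname(r2$posteriors["H"]), 0.99, tolerance = 1e-12)

  ## three hypotheses at (0.90, 0.05, 0.05): max posterior 0.90 < 0.95
  r3 <- classify_posteriors(c(A = log(0.90), B = log(0.05), D = log(0.05)))
  expect_equal(r3$label, "UNKNOWN")
  expect_equal(unname(r3$posteriors["A"]), 0.90, tolerance = 1e-12)

  ## posteriors sum to 1
  set.seed(4)
  for (i in 1:20) {
    ll <- stats::setNames(stats::rnorm(3, sd = 5), c("A", "B", "D"))
    expect_equal(sum(classify_posteriors(ll)$posteriors), 1,
                 tolerance = 1e-12)
  }

  ## all no-information -> COMMON; single hypothesis -> error
  expect_equal(classify_posteriors(c(H = NA_real_, L = NA_real_))$label,
               "COMMON")
  expect_error(classify_posteriors(c(H = -1)), "two")
})

test_that("adding a matching site never decreases that posterior", {
  set.seed(12)
  for (i in 1:20) {
    ll <- stats::setNames(stats::rnorm(2, sd = 3), c("H", "L"))
    p0 <- classify_posteriors(ll)$posteriors["H"]
    ## a matching site multiplies H's likelihood by (1-e) and L's by e/3
    e <- 0.001
    ll2 <- ll + c(log(1 - e), log(e / 3))
    p1 <- classify_posteriors(ll2)$posteriors["H"]
    expect_gte(p1, p0)
  }
})

test_that("mismatch rule: fewest wins, ties common, cap and both-mappable", {
  expect_equal(classify_mismatch(c(H = 0, L = 1))$label, "H")
  expect_equal(classify_mismatch(c(H = 3, L = 3))$label, "COMMON")
  ## cap 10: H unmappable, both-mappable requirement fails
  r <- classify_mismatch(c(H = 12, L = 2))
  expect_equal(r$label, "UNKNOWN")
  expect_equal(unname(r$mappable), c(FALSE, TRUE))
  ## unmapped on one subgenome -> UNKNOWN
  expect_equal(classify_mismatch(c(H = NA, L = 0))$label, "UNKNOWN")
  ## exactly at the cap is still mappable
  expect_equal(classify_mismatch(c(H = 10, L = 9))$label, "L")
})

test_that("bottom-up consensus reproduces the pairwise voting rule", {
  ## worked rule: A iff AB voted A and AD voted A
  expect_equal(hexaploid_bottom_up(list(AB = "A", AD = "A", BD = "COMMON")),
               "A")
  expect_equal(hexaploid_bottom_up(list(AB = "A", AD = "D", BD = "COMMON")),
               "UNKNOWN")
  expect_equal(hexaploid_bottom_up(list(AB = "B", AD = "COMMON", BD = "B")),
               "B")

  ## exhaustive: all 3^3 vote combinations against a truth table written
  ## independently from the rule
  vote_sets <- list(AB = c("A", "B", "COMMON"),
                    AD = c("A", "D", "COMMON"),
                    BD = c("B", "D", "COMMON"))
  grid <- expand.grid(vote_sets, stringsAsFactors = FALSE)
  oracle <- function(ab, ad, bd) {
    if (ab == "A" && ad == "A") return("A")
    if (ab == "B" && bd == "B") return("B")
    if (ad == "D" && bd == "D") return("D")
    if (ab == "COMMON" && ad == "COMMON" && bd == "COMMON") return("COMMON")
    "UNKNOWN"
  }
  for (i in seq_len(nrow(grid))) {
    got <- hexaploid_bottom_up(list(AB = grid$AB[i], AD = grid$AD[i],
                                    BD = grid$BD[i]),
                               subgenomes = c("A", "B", "D"))
    expect_equal(got, oracle(grid$AB[i], grid$AD[i], grid$BD[i]),
                 info = paste(grid[i, ], collapse = "/"))
  }

  ## missing votes -> UNKNOWN; max_posterior delegates to the posterior rule
  expect_equal(hexaploid_bottom_up(list(AB = "A", AD = NA, BD = "B")),
               "UNKNOWN")
  mp <- hexaploid_bottom_up(loglik = c(A = log(0.98), B = log(0.01),
                                       D = log(0.01)),
                            mode = "max_posterior")
  expect_equal(mp$label, "A")
})

test_that("sample classifier recovers noiseless single-origin reads fully", {
  ct <- toy_catalog(len = 100L, snp_pos = c(20L, 60L))
  reads <- lapply(1:10, function(i) {
    p <- (i - 1) * 4L
    aln_h <- aln_row(paste0("r", i), "H", "tH", p,
                     substr(ct$seq_h, p + 1, p + 40))
    aln_l <- aln_row(paste0("r", i), "L", "tL", p,
                     substr(ct$seq_h, p + 1, p + 40))  # read is H-origin
    rbind(aln_h, aln_l)
  })
  aln <- data.table::rbindlist(reads)
  cls <- classify_sample(aln, ct$catalog, method = "likelihood")
  covered <- cls[cls$n_informative_sites > 0, ]
  expect_gt(nrow(covered), 0)
  expect_true(all(covered$label == "H"))
  ## reads covering no discriminating site are COMMON, none UNKNOWN
  expect_true(all(cls$label %in% c("H", "COMMON")))
})

test_that("reads in unaligned exon regions are unknown", {
  ## catalog whose blocks cover only the first 60 bases
  ct <- toy_catalog(len = 100L, snp_pos = c(20L))
  ct$catalog$blocks <- data.table::data.table(
    group_id = "g1", sub_q = "H", sub_t = "L",
    q_start = 0L, q_end = 60L, t_start = 0L, t_end = 60L)
  aln <- rbind(
    aln_row("rin", "H", "tH", 10L, substr(ct$seq_h, 11, 50)),
    aln_row("rout", "H", "tH", 65L, substr(ct$seq_h, 66, 100)))
  cls <- classify_sample(aln, ct$catalog, method = "likelihood")
  expect_equal(cls[cls$read_id == "rout", ]$label, "UNKNOWN")
  expect_equal(cls[cls$read_id == "rin", ]$label, "H")
})

test_that("zero divergence: every homeolog-mapped read is common", {
  cfg <- sim_config(n_genes = 10, gene_length_range = c(500, 700),
                    snp_divergence = 0, fragments_per_sample = 500,
                    seed = 17)
  g <- simulate_subgenomes(cfg)
  expect_equal(nrow(g$planted), 0L)
  sim <- simulate_reads(g, "s1")
  aln <- project_alignments(sim, g)
  cls <- classify_sample(aln, catalog_from_truth(g), method = "likelihood")
  expect_true(all(cls$label == "COMMON"))
  expect_equal(attr(cls, "summary")$n_classified, 0L)
})

test_that("relabeling subgenomes permutes classifications consistently", {
  cfg <- sim_config(n_genes = 10, gene_length_range = c(500, 700),
                    fragments_per_sample = 400, seed = 23)
  g <- simulate_subgenomes(cfg)
  sim <- simulate_reads(g, "s1")
  aln <- project_alignments(sim, g)
  ct <- catalog_from_truth(g)
  cls <- classify_sample(aln, ct, method = "likelihood")

  ## swap the labels everywhere (order flips too)
  swap <- c(H = "L", L = "H")
  aln2 <- data.table::copy(aln)[, subgenome := swap[subgenome]]
  ct2 <- ct
  ct2$subgenomes <- c("L", "H")
  ct2$members <- data.table::copy(ct$members)[, subgenome := swap[subgenome]]
  ct2$variants <- data.table::copy(ct$variants)[, subgenome := swap[subgenome]]
  ## blocks are in anchor coordinates; with symmetric planted blocks the
  ## relabeled anchor has identical intervals
  ct2$blocks <- data.table::copy(ct$blocks)[, `:=`(sub_q = "L", sub_t = "H")]
  cls2 <- classify_sample(aln2, ct2, method = "likelihood")
  m <- merge(as.data.frame(cls)[, c("read_id", "label")],
             as.data.frame(cls2)[, c("read_id", "label")], by = "read_id")
  relabeled <- ifelse(m$label.x %in% c("H", "L"), unname(swap[m$label.x]),
                      m$label.x)
  expect_equal(m$label.y, relabeled)
})

test_that("likelihood classifier is at least as accurate as mismatch rule", {
  ## statistical assertion over 3 seeds at moderate divergence
  for (seed in c(101, 202, 303)) {
    cfg <- sim_config(n_genes = 15, gene_length_range = c(600, 900),
                      snp_divergence = 0.0125, fragments_per_sample = 2000,
                      base_quality = 20, seed = seed)
    g <- simulate_subgenomes(cfg)
    sim <- simulate_reads(g, "s1")
    aln <- project_alignments(sim, g)
    ct <- catalog_from_truth(g)
    e_lik <- classification_error(
      classify_sample(aln, ct, method = "likelihood"), sim$truth)
    e_mm <- classification_error(
      classify_sample(aln, ct, method = "mismatch"), sim$truth)
    expect_lte(e_lik$overall_error_pct, e_mm$overall_error_pct + 1e-9)
  }
})

test_that("paired mates combine into one fragment decision", {
  ct <- toy_catalog(len = 200L, snp_pos = c(50L, 150L))
  ## mate 1 covers the site at 50, mate 2 the site at 150; both match H
  aln <- rbind(
    aln_row("f1", "H", "tH", 30L, substr(ct$seq_h, 31, 70), mate = 1L),
    aln_row("f1", "H", "tH", 140L, substr(ct$seq_h, 141, 180), mate = 2L),
    aln_row("f1", "L", "tL", 30L, substr(ct$seq_h, 31, 70), mate = 1L),
    aln_row("f1", "L", "tL", 140L, substr(ct$seq_h, 141, 180), mate = 2L))
  cls <- classify_sample(aln, ct$catalog, method = "likelihood")
  expect_equal(nrow(cls), 1L)  # one fragment, not two mates
  expect_equal(cls$label, "H")
  expect_equal(cls$n_informative_sites, 2L)
})
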