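## Homeolog catalog: pairwise transcript alignment, reciprocal best hits,
## triple assembly for hexaploids, and enumeration of the discriminating
## variants inside aligned regions.

## Karlin-Altschul constants for the default +2/-3 scoring; only the relative
## ordering of hits and the E-value cutoff matter downstream, so these are
## fixed documented defaults rather than estimated per search.
KA_LAMBDA <- 0.625
KA_K <- 0.41

#' Align two transcript sequences
#'
#' Global alignment with free end gaps (overlap alignment) under an affine
#' gap model, as used to pair homeolog transcripts. Returns the aligned
#' segment pairs (blocks), aligned base counts on both sides, the alignment
#' score and an approximate E-value (Karlin-Altschul form with fixed
#' constants).
#'
#' @param seq_a,seq_b sequences (character scalars).
#' @param gap_open,gap_extend affine gap penalties (positive).
#' @param match,mismatch match score and mismatch penalty.
#' @param query_id,target_id identifiers recorded on the hit.
#' @return object of class `pairwise_hit`: list with query_id, target_id,
#'   score, evalue, aligned_query_bases, aligned_target_bases, blocks
#'   (data.table q_start, q_end, t_start, t_end; 0-based half-open), and the
#'   gapped alignment strings `q_aln`, `t_aln` with their 0-based offsets
#'   `q_offset`, `t_offset`.
#' @export
align_transcript_pair <- function(seq_a, seq_b, gap_open = 5, gap_extend = 2,
                                  match = 2, mismatch = -3,
                                  query_id = "query", target_id = "target") {
  if (nchar(seq_a) == 0L || nchar(seq_b) == 0L) {
    stop("cannot align zero-length sequences")
  }
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(seq_a, seq_b, type = "overlap",
                                      substitutionMatrix = sm,
                                      gapOpening = gap_open,
                                      gapExtension = gap_extend)
  q_aln <- as.character(Biostrings::alignedPattern(pa))
  t_aln <- as.character(Biostrings::alignedSubject(pa))
  q_off <- Biostrings::start(Biostrings::pattern(pa)) - 1L
  t_off <- Biostrings::start(Biostrings::subject(pa)) - 1L
  qc <- strsplit(q_aln, "")[[1]]
  tc <- strsplit(t_aln, "")[[1]]
  both <- qc != "-" & tc != "-"
  ## blocks = maximal runs of gap-free columns
  r <- rle(both)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  qpos <- cumsum(qc != "-")   # 1-based query coordinate at each column
  tpos <- cumsum(tc != "-")
  blocks <- data.table::data.table(q_start = integer(), q_end = integer(),
                                   t_start = integer(), t_end = integer())
  for (i in which(r$values)) {
    a <- starts[i]; b <- ends[i]
    blocks <- rbind(blocks, data.table::data.table(
      q_start = q_off + qpos[a] - 1L, q_end = q_off + qpos[b],
      t_start = t_off + tpos[a] - 1L, t_end = t_off + tpos[b]))
  }
  aligned_q <- sum(blocks$q_end - blocks$q_start)
  aligned_t <- sum(blocks$t_end - blocks$t_start)
  s <- Biostrings::score(pa)
  ev <- KA_K * nchar(seq_a) * nchar(seq_b) * exp(-KA_LAMBDA * s)
  structure(list(query_id = query_id, target_id = target_id,
                 score = s, evalue = ev,
                 aligned_query_bases = aligned_q,
                 aligned_target_bases = aligned_t,
                 blocks = blocks, q_aln = q_aln, t_aln = t_aln,
                 q_offset = q_off, t_offset = t_off),
            class = "pairwise_hit")
}

#' @export
print.pairwise_hit <- function(x, ...) {
  cat(sprintf("pairwise_hit %s ~ %s: score %.1f, E = %.3g, %d/%d aligned bases, %d block(s)\n",
              x$query_id, x$target_id, x$score, x$evalue,
              x$aligned_query_bases, x$aligned_target_bases,
              nrow(x$blocks)))
  invisible(x)
}

## coerce a list of pairwise_hit objects to a hit table
hits_to_table <- function(hits) {
  data.table::rbindlist(lapply(hits, function(h) {
    data.table::data.table(query_id = h$query_id, target_id = h$target_id,
                           evalue = h$evalue, score = h$score,
                           aligned_query_bases = h$aligned_query_bases,
                           aligned_target_bases = h$aligned_target_bases)
  }))
}

#' Reciprocal best hits between two transcript sets
#'
#' A pair (x, y) is kept iff y is x's best hit in the forward search, x is
#' y's best hit in the reverse search, the E-value is below `evalue_max`,
#' and at least `min_aligned_bases` bases are aligned in *both* transcripts.
#' Score ties are broken by lexicographic target id, deterministically.
#'
#' @param hits_ab,hits_ba hit tables (columns query_id, target_id, evalue,
#'   score, aligned_query_bases, aligned_target_bases) for the two search
#'   directions, or lists of `pairwise_hit` objects.
#' @param evalue_max E-value cutoff (default 1e-10).
#' @param min_aligned_bases minimum aligned bases required in both
#'   transcripts (default 200).
#' @return data.table of homeolog pairs: columns a (query side of hits_ab),
#'   b, evalue, score, aligned bases on each side.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba, evalue_max = 1e-10,
                                 min_aligned_bases = 200L) {
  as_tab <- function(h) {
    if (is.list(h) && !is.data.frame(h) &&
        (length(h) == 0L || inherits(h[[1]], "pairwise_hit"))) {
      hits_to_table(h)
    } else data.table::as.data.table(h)
  }
  ab <- as_tab(hits_ab)
  ba <- as_tab(hits_ba)
  if (nrow(ab) == 0L || nrow(ba) == 0L) {
    return(data.table::data.table(a = character(), b = character(),
                                  evalue = numeric(), score = numeric(),
                                  aligned_a = integer(), aligned_b = integer()))
  }
  best <- function(h) {
    data.table::setorder(h, query_id, -score, target_id)
    h[, .SD[1], by = query_id]
  }
  best_ab <- best(data.table::copy(ab))
  best_ba <- best(data.table::copy(ba))
  m <- merge(best_ab, best_ba,
             by.x = c("query_id", "target_id"),
             by.y = c("target_id", "query_id"),
             suffixes = c("", ".rev"))
  m <- m[evalue < evalue_max &
           aligned_query_bases >= min_aligned_bases &
           aligned_target_bases >= min_aligned_bases]
  out <- m[, .(a = query_id, b = target_id, evalue, score,
               aligned_a = aligned_query_bases,
               aligned_b = aligned_target_bases)]
  data.table::setorder(out, a)
  out[]
}

#' Assemble triple homeologs from three pairwise RBH lists
#'
#' A pair (a, b) from the AB list becomes a triple with d iff (a, d) is in
#' the AD list and (b, d) is in the BD list for the same d. Leftover pairs
#' are reported as two-copy homeologs; transcripts in no pair are singletons.
#'
#' @param pairs_ab,pairs_ad,pairs_bd RBH pair tables with columns a/b, a/d,
#'   b/d respectively (extra columns ignored).
#' @param all_ids optional named list of full transcript id vectors per
#'   subgenome (names A, B, D positionally) used to report singletons.
#' @return list with `triples` (data.table a, b, d), `pairs` (data.table
#'   subgenomes, id1, id2 of unresolved two-copy homeologs), and
#'   `singletons` (data.table subgenome_index, id; empty unless `all_ids`).
#' @export
triple_homeologs <- function(pairs_ab, pairs_ad, pairs_bd, all_ids = NULL) {
  ab <- data.table::as.data.table(pairs_ab)
  ad <- data.table::as.data.table(pairs_ad)
  bd <- data.table::as.data.table(pairs_bd)
  if (!"d" %in% names(ad)) data.table::setnames(ad, "b", "d")
  if (!"d" %in% names(bd)) data.table::setnames(bd, "b", "d")
  if ("a" %in% names(bd) && !"b" %in% names(bd)) {
    data.table::setnames(bd, "a", "b")
  }
  x <- merge(ab[, .(a, b)], ad[, .(a, d_from_a = d)], by = "a")
  x <- merge(x, bd[, .(b, d_from_b = d)], by = "b")
  triples <- x[d_from_a == d_from_b, .(a, b, d = d_from_a)]
  data.table::setorder(triples, a)
  used_ab <- paste(triples$a, triples$b)
  rest_ab <- ab[!paste(a, b) %in% used_ab]
  rest_ad <- ad[!a %in% triples$a & !d %in% triples$d]
  rest_bd <- bd[!b %in% triples$b & !d %in% triples$d]
  pairs <- rbind(
    data.table::data.table(subgenomes = "12", id1 = rest_ab$a, id2 = rest_ab$b),
    data.table::data.table(subgenomes = "13", id1 = rest_ad$a, id2 = rest_ad$d),
    data.table::data.table(subgenomes = "23", id1 = rest_bd$b, id2 = rest_bd$d))
  singletons <- data.table::data.table(subgenome_index = integer(),
                                       id = character())
  if (!is.null(all_ids)) {
    in_any <- list(c(triples$a, rest_ab$a, rest_ad$a),
                   c(triples$b, rest_ab$b, rest_bd$b),
                   c(triples$d, rest_ad$d, rest_bd$d))
    for (i in 1:3) {
      s <- setdiff(all_ids[[i]], in_any[[i]])
      if (length(s)) {
        singletons <- rbind(singletons,
          data.table::data.table(subgenome_index = i, id = s))
      }
    }
  }
  list(triples = triples[], pairs = pairs[], singletons = singletons[])
}

#' Variant columns of one gapped pairwise alignment
#'
#' Scans the aligned strings column by column: mismatch columns become SNP
#' rows and runs of adjacent gap columns are merged into single indel
#' events (one biological event, one variant).
#'
#' @param qc,tc aligned query/target strings as character vectors (gaps as
#'   `"-"`).
#' @param q_off,t_off 0-based offsets of the alignment start on each
#'   sequence.
#' @return data.table with kind, q_pos, t_pos (0-based), q_allele, t_allele.
#' @export
pair_alignment_variants <- function(qc, tc, q_off, t_off) {
  qpos <- cumsum(qc != "-") + q_off   # 1-based coordinate of current base
  tpos <- cumsum(tc != "-") + t_off
  n <- length(qc)
  state <- ifelse(qc == "-", "ins_t",              # target has extra bases
                  ifelse(tc == "-", "ins_q",
                         ifelse(qc != tc, "snp", "match")))
  out <- list()
  i <- 1L
  while (i <= n) {
    if (state[i] == "snp") {
      out[[length(out) + 1L]] <- data.table::data.table(
        kind = "SNP", q_pos = qpos[i] - 1L, t_pos = tpos[i] - 1L,
        q_allele = qc[i], t_allele = tc[i])
      i <- i + 1L
    } else if (state[i] %in% c("ins_q", "ins_t")) {
      j <- i
      while (j < n && state[j + 1L] == state[i]) j <- j + 1L
      if (state[i] == "ins_q") {
        ## query has bases the target lacks: deletion in target
        out[[length(out) + 1L]] <- data.table::data.table(
          kind = "deletion", q_pos = qpos[i] - 1L, t_pos = tpos[i],
          q_allele = paste(qc[i:j], collapse = ""), t_allele = "-")
      } else {
        out[[length(out) + 1L]] <- data.table::data.table(
          kind = "insertion", q_pos = qpos[i], t_pos = tpos[i] - 1L,
          q_allele = "-", t_allele = paste(tc[i:j], collapse = ""))
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  data.table::rbindlist(out)
}

#' Enumerate discriminating variants for one homeolog group
#'
#' Aligns the anchor member (first subgenome) against every other member and
#' converts each mismatch or gap column inside the aligned blocks into a
#' discriminating variant with transcript-coordinate positions per
#' subgenome. Adjacent gap columns are merged into single indel variants.
#' For ploidy 3 the sites from the two anchor pairings are merged by anchor
#' position; a member aligned but identical to the anchor at a site carries
#' the anchor allele, and a member whose alignment does not cover the site
#' carries NA.
#'
#' @param member_seqs named character vector of member sequences, names are
#'   subgenome labels in fixed order (anchor first).
#' @param member_ids named character vector of transcript ids per subgenome.
#' @param group_id group identifier stamped on the output.
#' @param ... passed to [align_transcript_pair()].
#' @return list with `variants` (data.table group_id, variant_id, kind,
#'   subgenome, pos, allele), `aligned_fraction` (named numeric per
#'   subgenome), and `blocks` (data.table group_id, sub_q, sub_t, q_start,
#'   q_end, t_start, t_end; anchor coordinates on the q side).
#' @export
enumerate_variants <- function(member_seqs, member_ids = NULL,
                               group_id = "g", ...) {
  subs <- names(member_seqs)
  if (is.null(subs) || length(subs) < 2L) {
    stop("member_seqs must be a named vector with >= 2 subgenomes")
  }
  anchor <- subs[1]
  others <- subs[-1]
  lens <- nchar(member_seqs)
  per_pair <- list()
  blocks_all <- list()
  covered_anchor <- rep(FALSE, lens[anchor])
  frac <- setNames(numeric(length(subs)), subs)
  for (s in others) {
    hit <- align_transcript_pair(member_seqs[[anchor]], member_seqs[[s]],
                                 query_id = anchor, target_id = s, ...)
    if (nrow(hit$blocks) == 0L) {
      warning("no aligned blocks between ", anchor, " and ", s,
              " in group ", group_id)
      next
    }
    qc <- strsplit(hit$q_aln, "")[[1]]
    tc <- strsplit(hit$t_aln, "")[[1]]
    v <- pair_alignment_variants(qc, tc, hit$q_offset, hit$t_offset)
    per_pair[[s]] <- v
    blocks_all[[s]] <- data.table::data.table(
      group_id = group_id, sub_q = anchor, sub_t = s, hit$blocks)
    frac[s] <- hit$aligned_target_bases / lens[s]
    for (k in seq_len(nrow(hit$blocks))) {
      covered_anchor[(hit$blocks$q_start[k] + 1L):hit$blocks$q_end[k]] <- TRUE
    }
  }
  frac[anchor] <- sum(covered_anchor) / lens[anchor]
  if (length(per_pair) == 0L) {
    return(list(variants = data.table::data.table(
                  group_id = character(), variant_id = integer(),
                  kind = character(), subgenome = character(),
                  pos = integer(), allele = character()),
                aligned_fraction = frac,
                blocks = data.table::data.table()))
  }
  ## merge sites across pairs by anchor position
  site_key <- sort(unique(unlist(lapply(per_pair, function(v) v$q_pos))))
  rows <- list()
  vid <- 0L
  for (p in site_key) {
    vid <- vid + 1L
    kinds <- character(0)
    alleles <- setNames(rep(NA_character_, length(subs)), subs)
    positions <- setNames(rep(NA_integer_, length(subs)), subs)
    positions[anchor] <- p
    for (s in others) {
      v <- per_pair[[s]]
      hit_row <- v[v$q_pos == p, ]
      if (nrow(hit_row) == 1L) {
        kinds <- c(kinds, hit_row$kind)
        alleles[anchor] <- hit_row$q_allele
        alleles[s] <- hit_row$t_allele
        positions[s] <- hit_row$t_pos
      } else {
        ## site not discriminating for this member: allele equals anchor's if
        ## the site is inside an aligned block, else unknown
        blk <- blocks_all[[s]]
        inside <- !is.null(blk) && nrow(blk) > 0 &&
          any(p >= blk$q_start & p < blk$q_end)
        if (inside) {
          alleles[s] <- substr(member_seqs[[s]],
                               lift_pos(blk, p) + 1L, lift_pos(blk, p) + 1L)
          positions[s] <- lift_pos(blk, p)
        }
      }
    }
    if (is.na(alleles[anchor])) {
      alleles[anchor] <- substr(member_seqs[[anchor]], p + 1L, p + 1L)
    }
    kind <- if (all(kinds == "SNP")) "SNP" else kinds[kinds != "SNP"][1]
    rows[[vid]] <- data.table::data.table(
      group_id = group_id, variant_id = vid, kind = kind,
      subgenome = subs, pos = unname(positions[subs]),
      allele = unname(alleles[subs]))
  }
  variants <- data.table::rbindlist(rows)
  if (nrow(variants) == 0L) {
    variants <- data.table::data.table(group_id = character(),
                                       variant_id = integer(),
                                       kind = character(),
                                       subgenome = character(),
                                       pos = integer(), allele = character())
  } else {
    ## assert: every variant discriminates (>= 2 distinct alleles)
    chk <- variants[!is.na(allele),
                    .(ok = data.table::uniqueN(allele) >= 2L),
                    by = variant_id]
    if (any(!chk$ok)) {
      stop("internal error: non-discriminating variant emitted")
    }
  }
  list(variants = variants[],
       aligned_fraction = frac,
       blocks = data.table::rbindlist(blocks_all))
}

## lift an anchor (q-side) position through block coordinates to the t side
lift_pos <- function(blocks, p) {
  i <- which(p >= blocks$q_start & p < blocks$q_end)[1]
  blocks$t_start[i] + (p - blocks$q_start[i])
}

## k-mer shared-count prefilter: for each query, the candidate targets that
## share the most k-mers (a seeding heuristic so RBH need not align all pairs)
kmer_candidates <- function(qseqs, tseqs, k = 15L, max_candidates = 3L) {
  kmers <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1L), k:n))
  }
  tk <- data.table::rbindlist(lapply(seq_along(tseqs), function(i) {
    data.table::data.table(kmer = kmers(tseqs[[i]]), target = names(tseqs)[i])
  }))
  qk <- data.table::rbindlist(lapply(seq_along(qseqs), function(i) {
    data.table::data.table(kmer = kmers(qseqs[[i]]), query = names(qseqs)[i])
  }))
  sh <- merge(qk, tk, by = "kmer", allow.cartesian = TRUE)
  if (nrow(sh) == 0L) {
    return(data.table::data.table(query = character(), target = character()))
  }
  cnt <- sh[, .N, by = .(query, target)]
  data.table::setorder(cnt, query, -N, target)
  cnt[, head(.SD, max_candidates), by = query][, .(query, target)]
}

#' Build a homeolog catalog from subgenome transcript sequences
#'
#' Runs reciprocal-best-hit homeolog identification between all subgenome
#' transcript sets (candidate pairs are pre-selected by shared k-mer counts,
#' then aligned with [align_transcript_pair()]), assembles pairs (ploidy 2)
#' or triples (ploidy 3), and enumerates discriminating variants per group.
#'
#' @param seqs_by_subgenome named list (one element per subgenome, in fixed
#'   order) of named character vectors of transcript sequences.
#' @param evalue_max,min_aligned_bases RBH filters (defaults 1e-10 and 200).
#' @param k_prefilter,max_candidates k-mer seeding parameters.
#' @param ... alignment parameters passed to [align_transcript_pair()].
#' @return object of class `homeolog_catalog`: list with `subgenomes`,
#'   `groups` (group_id, ploidy), `members` (group_id, subgenome,
#'   transcript_id, aligned_fraction), `variants` (long table, see
#'   [enumerate_variants()]) and `blocks`.
#' @export
build_catalog <- function(seqs_by_subgenome, evalue_max = 1e-10,
                          min_aligned_bases = 200L, k_prefilter = 15L,
                          max_candidates = 3L, ...) {
  subs <- names(seqs_by_subgenome)
  if (length(subs) < 2L || length(subs) > 3L) {
    stop("2 or 3 subgenomes required")
  }
  align_dir <- function(qs, ts) {
    cand <- kmer_candidates(qs, ts, k = k_prefilter,
                            max_candidates = max_candidates)
    hits <- vector("list", nrow(cand))
    for (i in seq_len(nrow(cand))) {
      hits[[i]] <- align_transcript_pair(qs[[cand$query[i]]],
                                         ts[[cand$target[i]]],
                                         query_id = cand$query[i],
                                         target_id = cand$target[i], ...)
    }
    hits_to_table(hits)
  }
  rbh_pair <- function(i, j) {
    reciprocal_best_hits(
      align_dir(seqs_by_subgenome[[i]], seqs_by_subgenome[[j]]),
      align_dir(seqs_by_subgenome[[j]], seqs_by_subgenome[[i]]),
      evalue_max = evalue_max, min_aligned_bases = min_aligned_bases)
  }
  if (length(subs) == 2L) {
    pairs <- rbh_pair(1L, 2L)
    member_sets <- lapply(seq_len(nrow(pairs)), function(i) {
      setNames(c(pairs$a[i], pairs$b[i]), subs)
    })
  } else {
    ab <- rbh_pair(1L, 2L)
    ad <- rbh_pair(1L, 3L); data.table::setnames(ad, "b", "d")
    bd <- rbh_pair(2L, 3L)
    data.table::setnames(bd, c("a", "b"), c("b", "d"))
    tri <- triple_homeologs(ab, ad, bd)
    member_sets <- lapply(seq_len(nrow(tri$triples)), function(i) {
      setNames(c(tri$triples$a[i], tri$triples$b[i], tri$triples$d[i]), subs)
    })
  }
  groups <- list(); members <- list(); variants <- list(); blocks <- list()
  for (i in seq_along(member_sets)) {
    ids <- member_sets[[i]]
    gid <- sprintf("hg%05d", i)
    seqs <- setNames(
      vapply(subs, function(s) seqs_by_subgenome[[s]][[ids[[s]]]],
             character(1)), subs)
    ev <- enumerate_variants(seqs, member_ids = ids, group_id = gid, ...)
    groups[[i]] <- data.table::data.table(group_id = gid,
                                          ploidy = length(subs))
    members[[i]] <- data.table::data.table(
      group_id = gid, subgenome = subs, transcript_id = unname(ids),
      aligned_fraction = unname(ev$aligned_fraction[subs]))
    variants[[i]] <- ev$variants
    blocks[[i]] <- ev$blocks
  }
  structure(list(subgenomes = subs,
                 groups = data.table::rbindlist(groups),
                 members = data.table::rbindlist(members),
                 variants = data.table::rbindlist(variants),
                 blocks = data.table::rbindlist(blocks)),
            class = "homeolog_catalog")
}

#' @export
print.homeolog_catalog <- function(x, ...) {
  n_sites <- if (nrow(x$variants)) {
    data.table::uniqueN(paste(x$variants$group_id, x$variants$variant_id))
  } else 0L
  cat(sprintf("homeolog_catalog: %d group(s) over subgenomes %s; %d variant site(s)\n",
              nrow(x$groups), paste(x$subgenomes, collapse = "/"), n_sites))
  invisible(x)
}

#' Write / read a homeolog catalog as TSV files
#'
#' Writes `<prefix>.members.tsv`, `<prefix>.variants.tsv` and
#' `<prefix>.blocks.tsv`.
#'
#' @param catalog a `homeolog_catalog`.
#' @param prefix path prefix.
#' @export
write_catalog <- function(catalog, prefix) {
  data.table::fwrite(catalog$members, paste0(prefix, ".members.tsv"), sep = "\t")
  data.table::fwrite(catalog$variants, paste0(prefix, ".variants.tsv"), sep = "\t")
  data.table::fwrite(catalog$blocks, paste0(prefix, ".blocks.tsv"), sep = "\t")
  invisible(prefix)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(prefix) {
  members <- data.table::fread(paste0(prefix, ".members.tsv"), sep = "\t")
  variants <- data.table::fread(paste0(prefix, ".variants.tsv"), sep = "\t",
                                na.strings = c("NA", ""))
  blocks <- data.table::fread(paste0(prefix, ".blocks.tsv"), sep = "\t")
  subs <- unique(members$subgenome)
  groups <- unique(members[, .(group_id)])
  groups[, ploidy := length(subs)]
  structure(list(subgenomes = subs, groups = groups, members = members,
                 variants = variants, blocks = blocks),
            class = "homeolog_catalog")
}
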