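## Read (fragment) classification to subgenome of origin.
##
## Likelihood route: per-base Phred error model evaluated at the
## discriminating variant positions a read covers. For each subgenome
## hypothesis G, log P[r|G] = sum over informative sites of log(1 - e_i)
## when the read base equals the hypothesis allele and log(e_i / 3)
## otherwise, with e_i the Phred-implied error probability. The posterior
## P[r in G_ref] = P[r|G_ref] / sum over all reference hypotheses; the
## winning hypothesis is accepted when its posterior is at least `p_min`
## (0.95) and its marginal probability at least `marginal_min` (0.51),
## otherwise the read is unknown. Reads covering no discriminating site are
## subgenome-common.
##
## Mismatch route: fewest mismatches wins, alignments with more than
## `max_mismatches` (10) are treated as unmappable, the read must be
## mappable to all subgenomes under comparison, and ties are common.

NO_INFORMATION <- NA_real_   # sentinel log-likelihood: no informative site

#' Log-likelihood of a read under a genotype hypothesis
#'
#' @param read_bases character scalar: the read sequence (aligned
#'   orientation).
#' @param base_quals character scalar: Phred+33 quality string.
#' @param alleles expected hypothesis alleles at the informative positions.
#' @param positions 0-based positions of those alleles in the frame of the
#'   alignment's reference.
#' @param aln_pos 0-based alignment start on that reference.
#' @return log-likelihood with attribute `n_sites`; positions the read does
#'   not cover contribute nothing, and when no informative position is
#'   covered the no-information sentinel (NA) is returned. A gap allele
#'   (`"-"`, a deletion in the hypothesis) counts as a mismatch against any
#'   read base.
#' @export
read_likelihood <- function(read_bases, base_quals, alleles, positions,
                            aln_pos = 0L) {
  stopifnot(length(alleles) == length(positions))
  off <- positions - aln_pos
  keep <- off >= 0L & off < nchar(read_bases)
  off <- off[keep]
  alleles <- alleles[keep]
  if (length(off) == 0L) {
    return(structure(NO_INFORMATION, n_sites = 0L))
  }
  rb <- substring(read_bases, off + 1L, off + 1L)
  e <- qual_to_err(substring(base_quals, off + 1L, off + 1L))
  ll <- ifelse(rb == alleles & alleles != "-", log1p(-e), log(e / 3))
  structure(sum(ll), n_sites = length(off))
}

#' Classify one read from per-subgenome log-likelihoods
#'
#' Applies the posterior decision rule: posteriors are the normalized
#' likelihoods over all evaluable reference hypotheses (two terms for
#' ploidy 2, three for ploidy 3, sharing one denominator); the winning
#' hypothesis is accepted iff its posterior is at least `p_min` and its
#' marginal probability (winning posterior over the sum of all
#' reference-hypothesis posteriors) at least `marginal_min`; a read whose
#' hypotheses are all uninformative, or exactly tied, is COMMON; anything
#' else is UNKNOWN.
#'
#' @param loglik named numeric vector of log-likelihoods per subgenome; the
#'   no-information sentinel is NA.
#' @param p_min,marginal_min acceptance thresholds (defaults 0.95, 0.51).
#' @return list with `label`, `posteriors` (named, summing to 1 when
#'   evaluable) and `n_hypotheses`.
#' @export
classify_posteriors <- function(loglik, p_min = 0.95, marginal_min = 0.51) {
  if (length(loglik) < 2L) {
    stop("classification requires at least two genotype hypotheses")
  }
  subs <- names(loglik)
  if (all(is.na(loglik))) {
    return(list(label = LABEL_COMMON,
                posteriors = setNames(rep(NA_real_, length(loglik)), subs),
                n_hypotheses = 0L))
  }
  ## with a common informative-site set, hypotheses are all-or-none evaluable
  ll <- ifelse(is.na(loglik), -Inf, loglik)
  m <- max(ll)
  post <- exp(ll - m) / sum(exp(ll - m))
  names(post) <- subs
  winners <- which(ll == m)
  if (length(winners) > 1L) {
    return(list(label = LABEL_COMMON, posteriors = post,
                n_hypotheses = sum(!is.na(loglik))))
  }
  marginal <- post[winners] / sum(post)
  label <- if (post[winners] >= p_min && marginal >= marginal_min) {
    subs[winners]
  } else LABEL_UNKNOWN
  list(label = label, posteriors = post,
       n_hypotheses = sum(!is.na(loglik)))
}

#' Classify one read from per-subgenome mismatch counts
#'
#' Alignments with more than `max_mismatches` mismatches are treated as
#' unmappable; the read must be mappable to all subgenomes under comparison
#' (otherwise it is UNKNOWN); strictly fewest mismatches wins and ties are
#' COMMON.
#'
#' @param mismatches named numeric vector of mismatch counts per subgenome
#'   (NA where the read did not map).
#' @param max_mismatches mappability cap (default 10).
#' @return list with `label` and `mappable` (named logical).
#' @export
classify_mismatch <- function(mismatches, max_mismatches = 10L) {
  mappable <- !is.na(mismatches) & mismatches <= max_mismatches
  if (!all(mappable)) {
    return(list(label = LABEL_UNKNOWN, mappable = mappable))
  }
  best <- which(mismatches == min(mismatches))
  label <- if (length(best) > 1L) LABEL_COMMON else names(mismatches)[best]
  list(label = label, mappable = mappable)
}

#' Combine pairwise classifications bottom-up for a hexaploid
#'
#' `consensus` mode: a read is labeled X iff both pairwise comparisons
#' involving X voted X (e.g. A requires an A vote in both the AB and the AD
#' comparison); a read voted COMMON in all three comparisons is COMMON; any
#' other pattern is UNKNOWN. `max_posterior` mode: the three per-subgenome
#' log-likelihoods share one denominator and the posterior decision rule of
#' [classify_posteriors()] is applied.
#'
#' @param pairwise named list of pairwise labels, names like "AB", "AD",
#'   "BD" (each value one of the two subgenome labels, COMMON or UNKNOWN);
#'   used in consensus mode.
#' @param loglik named per-subgenome log-likelihood vector (max_posterior
#'   mode).
#' @param mode `"consensus"` or `"max_posterior"`.
#' @param subgenomes the three subgenome labels in fixed order.
#' @param ... thresholds passed to [classify_posteriors()].
#' @return the final label (consensus mode) or the [classify_posteriors()]
#'   result (max_posterior mode).
#' @export
hexaploid_bottom_up <- function(pairwise = NULL, loglik = NULL,
                                mode = c("consensus", "max_posterior"),
                                subgenomes = NULL, ...) {
  mode <- match.arg(mode)
  if (mode == "max_posterior") {
    if (is.null(loglik)) stop("max_posterior mode requires log-likelihoods")
    return(classify_posteriors(loglik, ...))
  }
  if (is.null(pairwise)) stop("consensus mode requires pairwise labels")
  if (is.null(subgenomes)) {
    subgenomes <- unique(unlist(strsplit(names(pairwise), "")))
  }
  if (length(pairwise) < 3L || any(is.na(unlist(pairwise)))) {
    return(LABEL_UNKNOWN)
  }
  votes <- unlist(pairwise)
  for (s in subgenomes) {
    involving <- names(votes)[vapply(names(votes), function(nm) {
      s %in% strsplit(nm, "")[[1]]
    }, logical(1))]
    if (length(involving) >= 2L && all(votes[involving] == s)) {
      return(s)
    }
  }
  if (all(votes == LABEL_COMMON)) return(LABEL_COMMON)
  LABEL_UNKNOWN
}

## ---------------------------------------------------------------------------
## vectorized per-sample driver

## per-fragment informative-site table: one row per (read_id, mate, variant,
## subgenome hypothesis) with the site log-likelihood contribution
build_site_table <- function(aln, catalog) {
  subs <- catalog$subgenomes
  tx2g <- catalog$members[, .(contig = transcript_id, group_id, subgenome)]
  a <- merge(aln, tx2g, by = c("contig", "subgenome"))
  if (nrow(a) == 0L) return(NULL)
  a[, ref_span := cigar_ref_span(cigar)]
  ## choose one frame per (read, mate): the first subgenome (in fixed order)
  ## the mate aligns to
  a[, frame_rank := match(subgenome, subs)]
  data.table::setorder(a, read_id, mate, frame_rank)
  a <- a[, .SD[1], by = .(read_id, mate)]
  ## variants in wide allele layout + position in each frame
  site_rows <- list()
  vw <- if (nrow(catalog$variants) > 0L) {
    data.table::dcast(catalog$variants,
                      group_id + variant_id + kind ~ subgenome,
                      value.var = c("pos", "allele"))
  } else NULL
  for (f in if (is.null(vw)) character(0) else unique(a$subgenome)) {
    af <- a[subgenome == f]
    poscol <- paste0("pos_", f)
    vv <- vw[!is.na(vw[[poscol]])]
    if (nrow(vv) == 0L || nrow(af) == 0L) next
    ## complete-allele sites only: every hypothesis evaluated on the same set
    allele_cols <- paste0("allele_", subs)
    ok <- stats::complete.cases(vv[, ..allele_cols])
    vv <- vv[ok]
    if (nrow(vv) == 0L) next
    j <- merge(af[, .(read_id, mate, group_id, pos, cigar, ref_span, seq, qual)],
               vv, by = "group_id", allow.cartesian = TRUE)
    j <- j[j[[poscol]] >= pos & j[[poscol]] < pos + ref_span]
    if (nrow(j) == 0L) next
    j[, offset := .SD[[1]] - pos, .SDcols = poscol]
    nonM <- !grepl("^[0-9]+M$", j$cigar)
    if (any(nonM)) {
      ## general cigars: map reference offsets through the cigar per read
      j_non <- j[nonM]
      j_non[, offset := {
        cigar_ref2query(cigar[1], offset)
      }, by = .(read_id, mate, cigar)]
      j <- rbind(j[!nonM], j_non)
      j <- j[!is.na(offset)]
    }
    j[, readbase := substring(seq, offset + 1L, offset + 1L)]
    j[, err := qual_to_err(substring(qual, offset + 1L, offset + 1L))]
    keep_cols <- c("read_id", "mate", "group_id", "variant_id", "readbase",
                   "err", allele_cols)
    site_rows[[f]] <- j[, ..keep_cols]
  }
  frag_frames <- a[, .(read_id, mate, group_id, subgenome, pos, ref_span)]
  list(sites = data.table::rbindlist(site_rows),
       fragments = frag_frames)
}

## does an alignment overlap any pairwise-aligned block in its frame?
## (vectorized: join frames to blocks by group, then interval test)
frame_block_overlap <- function(frames, catalog) {
  b <- catalog$blocks
  anchor <- catalog$subgenomes[1]
  hit <- rep(FALSE, nrow(frames))
  if (is.null(b) || nrow(b) == 0L) return(hit)
  f <- data.table::copy(frames)[, idx := .I]
  fa <- f[subgenome == anchor]
  if (nrow(fa) > 0L) {
    j <- merge(fa, b, by = "group_id", allow.cartesian = TRUE)
    j <- j[q_start < pos + ref_span & q_end > pos]
    hit[unique(j$idx)] <- TRUE
  }
  fo <- f[subgenome != anchor]
  if (nrow(fo) > 0L) {
    j <- merge(fo, b, by = "group_id", allow.cartesian = TRUE)
    j <- j[sub_t == subgenome & t_start < pos + ref_span & t_end > pos]
    hit[unique(j$idx)] <- TRUE
  }
  hit
}

#' Classify all fragments of a sample
#'
#' Vectorized driver over an alignment table: fragments are classified to a
#' subgenome, COMMON, or UNKNOWN with either the likelihood posterior rule
#' or the mismatch-count rule. Mates of a fragment are combined before
#' classification (summed log-likelihoods; summed mismatch counts). For
#' ploidy 3 the mismatch method uses the bottom-up consensus of the three
#' pairwise comparisons; the likelihood method uses `mode` (`max_posterior`
#' computes the three-hypothesis posterior with a shared denominator,
#' `consensus` combines the three pairwise posterior decisions).
#'
#' @param aln alignment table ([read_sam()] layout) covering all subgenomes;
#'   the `subgenome` column must be filled.
#' @param catalog a `homeolog_catalog`.
#' @param method `"likelihood"` or `"mismatch"`.
#' @param p_min,marginal_min,max_mismatches decision thresholds.
#' @param mode bottom-up mode for ploidy-3 likelihood classification.
#' @param n_total_fragments optional total fragments sequenced (for the
#'   mapped percentage in the summary).
#' @return object of class `read_classification`: data.table with read_id,
#'   label, n_informative_sites and one posterior column per subgenome;
#'   attributes `summary` (list) and `subgenomes`.
#' @export
classify_sample <- function(aln, catalog,
                            method = c("likelihood", "mismatch"),
                            p_min = 0.95, marginal_min = 0.51,
                            max_mismatches = 10L,
                            mode = c("max_posterior", "consensus"),
                            n_total_fragments = NULL) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  aln <- data.table::as.data.table(aln)
  subs <- catalog$subgenomes
  prim <- aln[is_secondary == FALSE]
  all_ids <- unique(prim$read_id)
  tx2g <- catalog$members[, .(contig = transcript_id, group_id, subgenome)]
  on_catalog <- merge(prim, tx2g, by = c("contig", "subgenome"))
  noncat_ids <- setdiff(all_ids, unique(on_catalog$read_id))

  if (method == "mismatch") {
    res <- classify_mismatch_table(on_catalog, subs, max_mismatches)
  } else {
    res <- classify_likelihood_table(prim, catalog, subs, p_min,
                                     marginal_min, mode)
  }
  if (length(noncat_ids) > 0L) {
    extra <- data.table::data.table(read_id = noncat_ids,
                                    label = LABEL_UNKNOWN,
                                    n_informative_sites = 0L)
    for (s in subs) extra[, (paste0("post_", s)) := NA_real_]
    res <- rbind(res, extra, fill = TRUE)
  }
  n_mapped <- length(all_ids)
  lab <- res$label
  summary <- list(
    n_fragments = n_total_fragments %||% n_mapped,
    n_mapped = n_mapped,
    mapped_pct = 100 * n_mapped / (n_total_fragments %||% n_mapped),
    n_classified = sum(lab %in% subs),
    n_common = sum(lab == LABEL_COMMON),
    n_unknown = sum(lab == LABEL_UNKNOWN),
    n_non_homeolog = length(noncat_ids),
    classified_by_subgenome = setNames(
      vapply(subs, function(s) sum(lab == s), numeric(1)), subs))
  data.table::setattr(res, "summary", summary)
  data.table::setattr(res, "subgenomes", subs)
  data.table::setattr(res, "class",
                      c("read_classification", class(res)))
  res
}

## mismatch-rule classification over the joined alignment table
classify_mismatch_table <- function(on_catalog, subs, max_mismatches) {
  if (nrow(on_catalog) == 0L) {
    out <- data.table::data.table(read_id = character(),
                                  label = character(),
                                  n_informative_sites = integer())
    for (s in subs) out[, (paste0("post_", s)) := numeric(0)]
    return(out)
  }
  ## per (fragment, subgenome): mates mapped there and summed mismatches,
  ## honoring the per-alignment mappability cap
  per <- on_catalog[, .(mm = sum(mismatches),
                        n_mates = data.table::uniqueN(mate),
                        capped = any(mismatches > max_mismatches)),
                    by = .(read_id, subgenome)]
  frag_mates <- on_catalog[, .(total_mates = data.table::uniqueN(mate)),
                           by = read_id]
  per <- merge(per, frag_mates, by = "read_id")
  per[, mappable := !capped & n_mates == total_mates]
  wide <- data.table::dcast(per, read_id ~ subgenome, value.var = c("mm", "mappable"))
  for (s in subs) {
    mc <- paste0("mm_", s); pc <- paste0("mappable_", s)
    if (!mc %in% names(wide)) wide[, (mc) := NA_real_]
    if (!pc %in% names(wide)) wide[, (pc) := FALSE]
    wide[is.na(wide[[pc]]), (pc) := FALSE]
  }
  mmv <- as.matrix(wide[, paste0("mm_", subs), with = FALSE])
  mapv <- as.matrix(wide[, paste0("mappable_", subs), with = FALSE])
  mmv[!mapv] <- NA_real_
  if (length(subs) == 2L) {
    lab <- apply_mismatch_rule(mmv, subs)
  } else {
    ## bottom-up: three pairwise comparisons, then consensus
    pair_idx <- utils::combn(seq_along(subs), 2, simplify = FALSE)
    votes <- matrix(NA_character_, nrow(mmv), length(pair_idx))
    pnames <- character(length(pair_idx))
    for (k in seq_along(pair_idx)) {
      ij <- pair_idx[[k]]
      votes[, k] <- apply_mismatch_rule(mmv[, ij, drop = FALSE], subs[ij])
      pnames[k] <- paste0(subs[ij], collapse = "")
    }
    colnames(votes) <- pnames
    lab <- consensus_votes(votes, subs)
  }
  out <- data.table::data.table(read_id = wide$read_id, label = lab,
                                n_informative_sites = NA_integer_)
  for (s in subs) out[, (paste0("post_", s)) := NA_real_]
  out
}

## vectorized pairwise mismatch rule over a matrix (rows = fragments)
apply_mismatch_rule <- function(mm, subs) {
  n_map <- rowSums(!is.na(mm))
  lab <- rep(LABEL_UNKNOWN, nrow(mm))
  full <- n_map == ncol(mm)
  if (any(full)) {
    m <- mm[full, , drop = FALSE]
    mins <- do.call(pmin, as.data.frame(m))
    is_min <- m == mins
    nmin <- rowSums(is_min)
    sub_lab <- subs[max.col(is_min, ties.method = "first")]
    sub_lab[nmin > 1L] <- LABEL_COMMON
    lab[full] <- sub_lab
  }
  lab
}

## vectorized consensus over pairwise vote columns named e.g. AB, AD, BD
consensus_votes <- function(votes, subs) {
  lab <- rep(LABEL_UNKNOWN, nrow(votes))
  for (s in subs) {
    involving <- grepl(s, colnames(votes), fixed = TRUE)
    ok <- rowSums(votes[, involving, drop = FALSE] == s, na.rm = TRUE) ==
      sum(involving) &
      !apply(is.na(votes[, involving, drop = FALSE]), 1, any)
    lab[ok] <- s
  }
  all_common <- rowSums(votes == LABEL_COMMON, na.rm = TRUE) == ncol(votes)
  lab[all_common & lab == LABEL_UNKNOWN] <- LABEL_COMMON
  lab
}

## likelihood-rule classification over the alignment table
classify_likelihood_table <- function(prim, catalog, subs, p_min,
                                      marginal_min, mode) {
  st <- build_site_table(prim, catalog)
  empty <- function() {
    out <- data.table::data.table(read_id = character(), label = character(),
                                  n_informative_sites = integer())
    for (s in subs) out[, (paste0("post_", s)) := numeric(0)]
    out
  }
  if (is.null(st)) return(empty())
  frames <- st$fragments
  sites <- st$sites
  ## fragments overlapping no aligned block are unclassifiable (unknown)
  frames[, in_blocks := frame_block_overlap(frames, catalog)]
  frag_ok <- frames[, .(in_blocks = any(in_blocks)), by = read_id]

  if (nrow(sites) > 0L) {
    ## per-site contribution per hypothesis, then sum per fragment
    ll_long <- data.table::rbindlist(lapply(subs, function(s) {
      al <- sites[[paste0("allele_", s)]]
      match_ <- sites$readbase == al & al != "-"
      data.table::data.table(read_id = sites$read_id,
                             variant_id = sites$variant_id,
                             group_id = sites$group_id,
                             hyp = s,
                             ll = ifelse(match_, log1p(-sites$err),
                                         log(sites$err / 3)),
                             al = al)
    }))
    ## pairwise-discriminating masks are needed for consensus mode
    frag_ll <- ll_long[, .(loglik = sum(ll)), by = .(read_id, hyp)]
    wide_ll <- data.table::dcast(frag_ll, read_id ~ hyp, value.var = "loglik")
    nsites <- sites[, .(n_informative_sites =
                          data.table::uniqueN(paste(mate, group_id, variant_id))),
                    by = read_id]
  } else {
    wide_ll <- data.table::data.table(read_id = character())
    nsites <- data.table::data.table(read_id = character(),
                                     n_informative_sites = integer())
  }
  res <- merge(frag_ok, nsites, by = "read_id", all.x = TRUE)
  res[is.na(n_informative_sites), n_informative_sites := 0L]
  res <- merge(res, wide_ll, by = "read_id", all.x = TRUE)
  for (s in subs) if (!s %in% names(res)) res[, (s) := NA_real_]

  llm <- as.matrix(res[, subs, with = FALSE])
  if (length(subs) == 2L || mode == "max_posterior") {
    cls <- apply_posterior_rule(llm, subs, p_min, marginal_min)
    lab <- cls$label
    post <- cls$post
  } else {
    ## consensus over pairwise posterior decisions; each pairwise comparison
    ## uses only the sites that discriminate that pair
    pair_idx <- utils::combn(seq_along(subs), 2, simplify = FALSE)
    votes <- matrix(NA_character_, nrow(res), length(pair_idx))
    pnames <- character(length(pair_idx))
    for (k in seq_along(pair_idx)) {
      ij <- pair_idx[[k]]
      s1 <- subs[ij[1]]; s2 <- subs[ij[2]]
      disc <- sites[sites[[paste0("allele_", s1)]] !=
                      sites[[paste0("allele_", s2)]]]
      if (nrow(disc) > 0L) {
        pll <- data.table::rbindlist(lapply(c(s1, s2), function(s) {
          al <- disc[[paste0("allele_", s)]]
          match_ <- disc$readbase == al & al != "-"
          data.table::data.table(read_id = disc$read_id, hyp = s,
                                 ll = ifelse(match_, log1p(-disc$err),
                                             log(disc$err / 3)))
        }))[, .(loglik = sum(ll)), by = .(read_id, hyp)]
        pw <- data.table::dcast(pll, read_id ~ hyp, value.var = "loglik")
        for (s in c(s1, s2)) if (!s %in% names(pw)) pw[, (s) := NA_real_]
        pw <- pw[match(res$read_id, read_id)]
        pm <- as.matrix(pw[, c(s1, s2), with = FALSE])
      } else {
        pm <- matrix(NA_real_, nrow(res), 2)
      }
      votes[, k] <- apply_posterior_rule(pm, c(s1, s2), p_min,
                                         marginal_min)$label
      pnames[k] <- paste0(s1, s2)
    }
    colnames(votes) <- pnames
    lab <- consensus_votes(votes, subs)
    post <- apply_posterior_rule(llm, subs, p_min, marginal_min)$post
  }
  ## no-information fragments: COMMON inside aligned blocks, else UNKNOWN
  lab[res$n_informative_sites == 0L] <- LABEL_COMMON
  lab[!res$in_blocks] <- LABEL_UNKNOWN
  out <- data.table::data.table(read_id = res$read_id, label = lab,
                                n_informative_sites = res$n_informative_sites)
  for (i in seq_along(subs)) {
    out[, (paste0("post_", subs[i])) := post[, i]]
  }
  out
}

## vectorized posterior decision rule over a log-likelihood matrix
apply_posterior_rule <- function(llm, subs, p_min, marginal_min) {
  n <- nrow(llm)
  lab <- rep(LABEL_COMMON, n)
  post <- matrix(NA_real_, n, length(subs))
  have <- rowSums(!is.na(llm)) > 0L
  if (any(have)) {
    ll <- llm[have, , drop = FALSE]
    ll[is.na(ll)] <- -Inf
    m <- apply(ll, 1, max)
    p <- exp(ll - m)
    p <- p / rowSums(p)
    post[have, ] <- p
    pm <- apply(p, 1, max)
    win <- max.col(p, ties.method = "first")
    tied <- rowSums(ll == m) > 1L
    hl <- ifelse(tied, LABEL_COMMON,
                 ifelse(pm >= p_min & pm / rowSums(p) >= marginal_min,
                        subs[win], LABEL_UNKNOWN))
    lab[have] <- hl
  }
  list(label = lab, post = post)
}

#' @export
print.read_classification <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("read_classification: %d fragment(s) mapped (%.1f%%)\n",
              s$n_mapped, s$mapped_pct))
  cat(sprintf("  classified: %d  common: %d  unknown: %d  non-homeolog: %d\n",
              s$n_classified, s$n_common, s$n_unknown, s$n_non_homeolog))
  for (s2 in names(s$classified_by_subgenome)) {
    cat(sprintf("    %s: %d\n", s2, s$classified_by_subgenome[[s2]]))
  }
  invisible(x)
}

#' Write a classification table as TSV
#'
#' @param x a `read_classification`.
#' @param path output path.
#' @export
write_classification <- function(x, path) {
  data.table::fwrite(data.table::as.data.table(x), path, sep = "\t")
  invisible(path)
}
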