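## Differentially expressed homeologs: a per-subgenome differential
## expression filter (FDR <= alpha_de in at least one subgenome) combined
## with Fisher's exact tests on the shift in the homeolog expression ratio
## between conditions (P < alpha_ratio, fold change >= fc_min; for ploidy 3
## the three contrasts A vs BD, B vs AD, D vs AB at alpha_ratio / 3,
## Bonferroni). No further FDR correction is applied to the ratio tests.

#' Per-subgenome differential-expression filter
#'
#' `builtin` mode tests, per homeolog group and subgenome, the summed counts
#' of the two conditions against the null given by the conditions'
#' library-size ratio (exact conditional binomial test), then adjusts
#' p-values by Benjamini-Hochberg within subgenome. `external` mode passes a
#' user-supplied q-value table through unchanged, so q-values from a
#' dedicated DE package can drive the filter.
#'
#' @param counts count table (group_id, sample_id, subgenome, count).
#' @param conditions named character vector mapping sample_id to condition
#'   (exactly two levels).
#' @param method `"builtin"` or `"external"`.
#' @param external_q for external mode, a data.table (group_id, subgenome,
#'   qvalue).
#' @return data.table group_id, subgenome, pvalue, qvalue.
#' @export
de_filter <- function(counts, conditions, method = c("builtin", "external"),
                      external_q = NULL) {
  method <- match.arg(method)
  if (method == "external") {
    if (is.null(external_q)) stop("external mode requires a q-value table")
    return(data.table::as.data.table(external_q))
  }
  counts <- data.table::as.data.table(counts)
  cond_levels <- unique(conditions)
  if (length(cond_levels) != 2L) stop("exactly two conditions required")
  reps <- table(conditions)
  if (any(reps < 2L)) {
    stop("builtin DE filter requires >= 2 replicates per condition; ",
         "supply external q-values instead")
  }
  counts[, cond := conditions[sample_id]]
  ## library size per (sample, subgenome): each subgenome's count matrix is
  ## analyzed separately
  libs <- counts[, .(lib = sum(count)), by = .(sample_id, subgenome, cond)]
  libc <- libs[, .(lib = sum(lib)), by = .(subgenome, cond)]
  g <- counts[, .(n = sum(count)), by = .(group_id, subgenome, cond)]
  gw <- data.table::dcast(g, group_id + subgenome ~ cond, value.var = "n",
                          fill = 0)
  lw <- data.table::dcast(libc, subgenome ~ cond, value.var = "lib")
  c1 <- cond_levels[1]; c2 <- cond_levels[2]
  gw <- merge(gw, lw, by = "subgenome", suffixes = c("", ".lib"))
  x1 <- round(gw[[c1]]); x2 <- round(gw[[c2]])
  p0 <- gw[[paste0(c1, ".lib")]] /
    (gw[[paste0(c1, ".lib")]] + gw[[paste0(c2, ".lib")]])
  pv <- vapply(seq_along(x1), function(i) {
    n <- x1[i] + x2[i]
    if (n == 0) return(1)
    stats::binom.test(x1[i], n, p = p0[i])$p.value
  }, numeric(1))
  out <- data.table::data.table(group_id = gw$group_id,
                                subgenome = gw$subgenome, pvalue = pv)
  out[, qvalue := stats::p.adjust(pvalue, method = "BH"), by = subgenome]
  out[]
}

#' Fisher's exact test on a homeolog ratio shift
#'
#' Two-sided Fisher's exact test on the 2x2 table
#' `[[focal_c1, rest_c1], [focal_c2, rest_c2]]` of combined (replicate-
#' summed) read counts, plus the fold change of the ratio as the
#' symmetrized odds ratio `max(OR, 1/OR)` with a Haldane 0.5 correction
#' applied when the table contains a zero.
#'
#' @param focal_c1,rest_c1 focal-subgenome and remaining counts, condition 1.
#' @param focal_c2,rest_c2 the same for condition 2.
#' @return list with `p` and `fold_change`.
#' @export
fisher_ratio_test <- function(focal_c1, rest_c1, focal_c2, rest_c2) {
  x <- c(focal_c1, rest_c1, focal_c2, rest_c2)
  if (any(x < 0) || any(x != round(x))) {
    stop("counts must be non-negative integers")
  }
  if (all(x == 0)) return(list(p = 1, fold_change = 1))
  tab <- matrix(as.integer(round(x)), 2, 2, byrow = TRUE)
  p <- stats::fisher.test(tab)$p.value
  h <- if (any(tab == 0L)) 0.5 else 0
  or <- ((tab[1, 1] + h) * (tab[2, 2] + h)) /
    ((tab[1, 2] + h) * (tab[2, 1] + h))
  list(p = p, fold_change = max(or, 1 / or))
}

#' Call differentially expressed homeologs
#'
#' A group is DEH iff its minimum DE q-value across subgenomes is at or
#' below `alpha_de` AND at least one ratio contrast has Fisher
#' `p < alpha_ratio` (ploidy 2) or `p < alpha_ratio / 3` (ploidy 3,
#' Bonferroni over the three contrasts) with fold change >= `fc_min`.
#'
#' @param de_q DE filter output (group_id, subgenome, qvalue).
#' @param fisher_results data.table group_id, contrast, p, fold_change; the
#'   ploidy-3 contrasts are named "A_vs_BD" style and all three must be
#'   present per group.
#' @param ploidy 2 or 3.
#' @param alpha_de,alpha_ratio,fc_min thresholds (defaults 0.05, 0.05, 2).
#' @return data.table group_id, min_qvalue, best_p, best_fc, is_deh plus
#'   per-contrast columns.
#' @export
call_deh <- function(de_q, fisher_results, ploidy = 2,
                     alpha_de = 0.05, alpha_ratio = 0.05, fc_min = 2) {
  de_q <- data.table::as.data.table(de_q)
  fr <- data.table::as.data.table(fisher_results)
  n_contrasts <- if (ploidy == 3) 3L else 1L
  chk <- fr[, .N, by = group_id]
  if (any(chk$N != n_contrasts)) {
    stop("expected ", n_contrasts, " ratio contrast(s) per group")
  }
  thresh <- if (ploidy == 3) alpha_ratio / 3 else alpha_ratio
  fr[, hit := p < thresh & fold_change >= fc_min]
  frs <- fr[, .(best_p = min(p), best_fc = max(fold_change),
                ratio_hit = any(hit)), by = group_id]
  qs <- de_q[, .(min_qvalue = min(qvalue)), by = group_id]
  out <- merge(qs, frs, by = "group_id", all = TRUE)
  out[is.na(ratio_hit), ratio_hit := FALSE]
  out[, is_deh := !is.na(min_qvalue) & min_qvalue <= alpha_de & ratio_hit]
  out[]
}

#' Differential homeolog expression analysis
#'
#' End-to-end driver: runs the DE filter, builds the ratio contrasts from
#' replicate-combined counts (focal subgenome vs the rest: H vs L for
#' ploidy 2; A vs BD, B vs AD and D vs AB for ploidy 3), applies the Fisher
#' tests and the decision rule.
#'
#' @inheritParams de_filter
#' @param ploidy 2 or 3 (defaults to the number of subgenomes in `counts`).
#' @inheritParams call_deh
#' @param de_method,external_q forwarded to [de_filter()].
#' @return data.table as [call_deh()], plus attribute `fisher` with the
#'   per-contrast table.
#' @export
deh_analysis <- function(counts, conditions, ploidy = NULL,
                         alpha_de = 0.05, alpha_ratio = 0.05, fc_min = 2,
                         de_method = "builtin", external_q = NULL) {
  counts <- data.table::as.data.table(counts)
  subs <- unique(counts$subgenome)
  if (is.null(ploidy)) ploidy <- length(subs)
  qtab <- de_filter(counts, conditions, method = de_method,
                    external_q = external_q)
  counts[, cond := conditions[sample_id]]
  cond_levels <- unique(conditions)
  comb <- counts[, .(n = round(sum(count))),
                 by = .(group_id, subgenome, cond)]
  cw <- data.table::dcast(comb, group_id + cond ~ subgenome, value.var = "n",
                          fill = 0)
  fr <- list()
  for (s in subs) {
    rest <- setdiff(subs, s)
    cw[, focal := cw[[s]]]
    cw[, other := rowSums(as.matrix(cw[, rest, with = FALSE]))]
    w <- data.table::dcast(cw, group_id ~ cond,
                           value.var = c("focal", "other"))
    res <- lapply(seq_len(nrow(w)), function(i) {
      fisher_ratio_test(w[[paste0("focal_", cond_levels[1])]][i],
                        w[[paste0("other_", cond_levels[1])]][i],
                        w[[paste0("focal_", cond_levels[2])]][i],
                        w[[paste0("other_", cond_levels[2])]][i])
    })
    fr[[s]] <- data.table::data.table(
      group_id = w$group_id,
      contrast = paste0(s, "_vs_", paste0(rest, collapse = "")),
      p = vapply(res, `[[`, numeric(1), "p"),
      fold_change = vapply(res, `[[`, numeric(1), "fold_change"))
    if (ploidy == 2) break   # H vs L and L vs H are the same 2x2 table
  }
  fisher_tab <- data.table::rbindlist(fr)
  out <- call_deh(qtab, fisher_tab, ploidy = ploidy, alpha_de = alpha_de,
                  alpha_ratio = alpha_ratio, fc_min = fc_min)
  data.table::setattr(out, "fisher", fisher_tab)
  out
}

#' Overlap of DEH sets across methods
#'
#' @param results_by_method named list of DEH group-id character vectors (or
#'   [call_deh()] tables, from which `is_deh` groups are taken).
#' @return list with `pairwise` (data.table method1, method2, intersection)
#'   and `supported` (named fraction of each method's DEHs found by at least
#'   one other method).
#' @export
deh_overlap <- function(results_by_method) {
  sets <- lapply(results_by_method, function(r) {
    if (is.data.frame(r)) {
      r <- data.table::as.data.table(r)
      r[is_deh == TRUE, group_id]
    } else as.character(r)
  })
  if (length(sets) < 2L) stop("need >= 2 DEH result sets")
  nm <- names(sets)
  pw <- data.table::rbindlist(lapply(utils::combn(seq_along(sets), 2,
                                                  simplify = FALSE),
    function(ij) {
      data.table::data.table(method1 = nm[ij[1]], method2 = nm[ij[2]],
                             intersection = length(intersect(sets[[ij[1]]],
                                                             sets[[ij[2]]])))
    }))
  supported <- setNames(vapply(seq_along(sets), function(i) {
    others <- unique(unlist(sets[-i]))
    if (length(sets[[i]]) == 0L) return(NA_real_)
    mean(sets[[i]] %in% others)
  }, numeric(1)), nm)
  list(pairwise = pw, supported = supported)
}
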