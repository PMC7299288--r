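## Ground-truth and cross-method evaluation: classification error rates,
## concordance (RMSD, r-squared) and expression-stratified comparisons.

#' Classification error against read-origin truth
#'
#' Computes per-direction error percentages (e.g. H to L, L to H) under a
#' declared denominator: `mapped` (all mapped fragments), `classified`
#' (fragments assigned to a subgenome) or `quantified` (fragments that
#' entered the count table, passed via `quantified_ids`). COMMON and
#' UNKNOWN fragments never count as errors; they are part of the
#' denominator only in `mapped` mode.
#'
#' @param classifications a `read_classification` (or data.table with
#'   read_id and label).
#' @param truth truth table (read_id, subgenome).
#' @param denominator `"classified"`, `"mapped"` or `"quantified"`.
#' @param quantified_ids read ids retained by quantification (required for
#'   the `quantified` denominator).
#' @return list of class `error_report`: `error_by_direction` (data.table
#'   true_sub, assigned, pct), `overall_error_pct`, `denominator`,
#'   `n_denominator`, `classified_pct` and `mapped_pct` (NA when the total
#'   sequenced count is unknown).
#' @export
classification_error <- function(classifications, truth,
                                 denominator = c("classified", "mapped",
                                                 "quantified"),
                                 quantified_ids = NULL) {
  denominator <- match.arg(denominator)
  truth <- data.table::as.data.table(truth)
  if (nrow(truth) == 0L) stop("empty truth table")
  cls <- data.table::as.data.table(classifications)[, .(read_id, label)]
  ## the label space is the union of true origins and assigned subgenomes,
  ## so single-origin designs (pure parental samples) still expose wrong
  ## assignments to the other subgenome
  subs <- sort(union(unique(truth$subgenome),
                     setdiff(unique(cls$label),
                             c(LABEL_COMMON, LABEL_UNKNOWN))))
  m <- merge(cls, truth[, .(read_id, true_sub = subgenome)], by = "read_id")
  if (denominator == "quantified") {
    if (is.null(quantified_ids)) {
      stop("quantified denominator requires quantified_ids")
    }
    m_assigned <- m[read_id %in% quantified_ids & label %in% subs]
    denom <- length(unique(quantified_ids))
  } else if (denominator == "classified") {
    m_assigned <- m[label %in% subs]
    denom <- nrow(m_assigned)
  } else {
    m_assigned <- m[label %in% subs]
    denom <- nrow(m)
  }
  dirs <- data.table::CJ(true_sub = subs, assigned = subs)[true_sub != assigned]
  wrong <- m_assigned[label != true_sub, .N, by = .(true_sub, assigned = label)]
  dirs <- merge(dirs, wrong, by = c("true_sub", "assigned"), all.x = TRUE)
  dirs[is.na(N), N := 0L]
  dirs[, pct := if (denom > 0) 100 * N / denom else NA_real_]
  structure(list(
    error_by_direction = dirs[, .(true_sub, assigned, n = N, pct)],
    overall_error_pct = if (denom > 0) 100 * sum(dirs$N) / denom else NA_real_,
    denominator = denominator,
    n_denominator = denom,
    classified_pct = 100 * sum(m$label %in% subs) / nrow(m)),
    class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("classification error (%% of %s reads, n = %d): %.3f%% overall\n",
              x$denominator, x$n_denominator, x$overall_error_pct))
  for (i in seq_len(nrow(x$error_by_direction))) {
    d <- x$error_by_direction[i]
    cat(sprintf("  %s to %s: %.3f%%\n", d$true_sub, d$assigned, d$pct))
  }
  invisible(x)
}

#' Root-mean-squared distance between two vectors
#'
#' `sqrt(sum((x_i - y_i)^2) / n)`; NA pairs are dropped pairwise.
#'
#' @param x,y equal-length numeric vectors.
#' @return the RMSD, or NA if no complete pair remains.
#' @export
rmsd <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1L)
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) return(NA_real_)
  sqrt(mean((x[ok] - y[ok])^2))
}

#' Squared sample correlation between two vectors
#'
#' The proportion of variability in one variable explained by the other:
#' `(sum((x - mean x)(y - mean y)))^2 / (sum((x - mean x)^2) sum((y - mean y)^2))`.
#'
#' @param x,y equal-length numeric vectors (>= 3 complete pairs).
#' @return r-squared, or NA with a warning when either variance is zero.
#' @export
r_squared <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need >= 3 complete pairs")
  sx <- sum((x - mean(x))^2)
  sy <- sum((y - mean(y))^2)
  if (sx == 0 || sy == 0) {
    warning("zero variance; r-squared undefined")
    return(NA_real_)
  }
  (sum((x - mean(x)) * (y - mean(y))))^2 / (sx * sy)
}

#' Expression-stratified concordance between methods
#'
#' Partitions homeolog groups into a low-expression stratum (total read
#' count <= `low_max`) and a high-expression stratum (total > `high_min`),
#' then computes the pairwise RMSD of the expression proportions within
#' each stratum, and a paired t-test across the method pairs comparing the
#' two strata.
#'
#' @param ratio_tables named list (one per method) of ratio tables
#'   (group_id, phat; a sample_id column, if present, is averaged over).
#' @param counts data.table group_id, count: the stratifying total counts.
#' @param low_max,high_min stratum boundaries (defaults 100 and 200).
#' @return list with `low` and `high` RMSD matrices (methods x methods) and
#'   `paired_t_p` (NA when fewer than two method pairs are complete).
#' @export
stratified_concordance <- function(ratio_tables, counts, low_max = 100,
                                   high_min = 200) {
  counts <- data.table::as.data.table(counts)
  nm <- names(ratio_tables)
  if (length(nm) < 2L) stop("need >= 2 methods")
  avg <- lapply(ratio_tables, function(r) {
    r <- data.table::as.data.table(r)
    r[, .(phat = mean(phat, na.rm = TRUE)), by = group_id]
  })
  strata <- list(low = counts[count <= low_max, group_id],
                 high = counts[count > high_min, group_id])
  mats <- lapply(strata, function(gids) {
    m <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
    for (i in seq_along(nm)) for (j in seq_along(nm)) {
      if (i >= j) next
      a <- avg[[i]][group_id %in% gids]
      b <- avg[[j]][group_id %in% gids]
      ab <- merge(a, b, by = "group_id", suffixes = c(".a", ".b"))
      m[i, j] <- if (nrow(ab) > 0) rmsd(ab$phat.a, ab$phat.b) else NA_real_
      m[j, i] <- m[i, j]
    }
    m
  })
  lo <- mats$low[upper.tri(mats$low)]
  hi <- mats$high[upper.tri(mats$high)]
  ok <- !is.na(lo) & !is.na(hi)
  p <- if (sum(ok) >= 2L && stats::sd(lo[ok] - hi[ok]) > 0) {
    stats::t.test(lo[ok], hi[ok], paired = TRUE)$p.value
  } else NA_real_
  list(low = mats$low, high = mats$high, paired_t_p = p)
}
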