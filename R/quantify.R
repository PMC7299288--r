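## Counting classified fragments per homeolog per subgenome and the derived
## homeolog expression proportions.

#' Count classified fragments per homeolog
#'
#' A fragment increments the count of the homeolog member on its assigned
#' subgenome iff its alignment overlaps that transcript's exons by at least
#' one base. Fragments overlapping more than one feature on the assigned
#' subgenome are dropped (transcript-level counting without multi-feature
#' rescue); UNKNOWN fragments are dropped; COMMON fragments are held aside
#' in a separate table for [distribute_common()].
#'
#' @param classifications a `read_classification` (or a data.table with
#'   read_id and label).
#' @param aln alignment table covering all subgenomes.
#' @param catalog a `homeolog_catalog`.
#' @param transcripts,exons transcript model tables ([read_gff3()] layout);
#'   when NULL, alignments are taken to be in transcript coordinates
#'   (contig = transcript id) and every alignment overlaps its transcript.
#' @param sample_id sample name stamped on the output.
#' @return list with `counts` (data.table group_id, sample_id, subgenome,
#'   count; zero-filled over the catalog cross-product) and `common`
#'   (data.table group_id, sample_id, count of subgenome-common fragments).
#' @export
count_reads <- function(classifications, aln, catalog, transcripts = NULL,
                        exons = NULL, sample_id = "s1") {
  cls <- data.table::as.data.table(classifications)[, .(read_id, label)]
  aln <- data.table::as.data.table(aln)[is_secondary == FALSE]
  subs <- catalog$subgenomes
  members <- catalog$members
  unknown_groups <- setdiff(unique(cls$label),
                            c(subs, LABEL_COMMON, LABEL_UNKNOWN))
  if (length(unknown_groups) > 0L) {
    stop("classification labels outside the catalog subgenomes: ",
         paste(unknown_groups, collapse = ", "))
  }

  ## features overlapped per (fragment, subgenome); transcript space has
  ## contig == transcript_id, genomic space goes through the exon table
  if (is.null(transcripts)) {
    feat <- merge(aln, members[, .(contig = transcript_id, group_id, subgenome)],
                  by = c("contig", "subgenome"))
    feat[, transcript_id := contig]
    hits <- unique(feat[, .(read_id, subgenome, transcript_id, group_id)])
  } else {
    tr <- data.table::as.data.table(transcripts)
    ex <- merge(data.table::as.data.table(exons),
                tr[, .(transcript_id, contig, subgenome)],
                by = "transcript_id")
    a <- aln[, .(read_id, subgenome, contig, pos,
                 pos_end = pos + cigar_ref_span(cigar))]
    j <- merge(a, ex, by = c("contig", "subgenome"),
               allow.cartesian = TRUE)
    j <- j[start < pos_end & end > pos]
    j <- merge(j, members[, .(transcript_id, group_id)], by = "transcript_id")
    hits <- unique(j[, .(read_id, subgenome, transcript_id, group_id)])
  }

  ## drop fragments hitting >1 feature on a subgenome
  nfeat <- hits[, .(nf = data.table::uniqueN(transcript_id)),
                by = .(read_id, subgenome)]
  hits <- merge(hits, nfeat, by = c("read_id", "subgenome"))[nf == 1L]

  assigned <- merge(cls[label %in% subs],
                    hits, by.x = c("read_id", "label"),
                    by.y = c("read_id", "subgenome"))
  base <- assigned[, .(count = as.numeric(.N)), by = .(group_id, label)]
  data.table::setnames(base, "label", "subgenome")

  ## COMMON fragments: attribute to the group via any member they overlap
  common_cls <- cls[label == LABEL_COMMON]
  common_hits <- unique(merge(common_cls, hits, by = "read_id")[,
    .(read_id, group_id)])
  common <- common_hits[, .(count = as.numeric(.N)), by = group_id]

  grid <- data.table::CJ(group_id = catalog$groups$group_id, subgenome = subs)
  counts <- merge(grid, base, by = c("group_id", "subgenome"), all.x = TRUE)
  counts[is.na(count), count := 0]
  counts[, sample_id := sample_id]
  common[, sample_id := sample_id]
  list(counts = counts[, .(group_id, sample_id, subgenome, count)],
       common = common[, .(group_id, sample_id, count)])
}

#' Distribute subgenome-common fragments proportionally
#'
#' Each group's common fragments are split across subgenomes in proportion
#' to its classified base counts; when all base counts are zero the split is
#' equal. Output counts are real-valued.
#'
#' @param base_counts count table (group_id, sample_id, subgenome, count).
#' @param common_counts common-fragment table (group_id, sample_id, count).
#' @return count table with the common mass added.
#' @export
distribute_common <- function(base_counts, common_counts) {
  base <- data.table::as.data.table(base_counts)
  com <- data.table::as.data.table(common_counts)
  if (any(base$count < 0) || any(com$count < 0)) {
    stop("negative counts")
  }
  if (nrow(com) == 0L) return(data.table::copy(base))
  base[, total := sum(count), by = .(group_id, sample_id)]
  m <- merge(base, com[, .(group_id, sample_id, common = count)],
             by = c("group_id", "sample_id"), all.x = TRUE)
  m[is.na(common), common := 0]
  nsub <- data.table::uniqueN(base$subgenome)
  m[, share := ifelse(total > 0, count / total, 1 / nsub)]
  m[, count := count + common * share]
  m[, .(group_id, sample_id, subgenome, count)]
}

#' Homeolog expression proportion
#'
#' The focal subgenome's read count over the total across all subgenomes of
#' the homeolog group (e.g. H / (H + L) for a tetraploid, A / (A + B + D)
#' for a hexaploid); NA when the total is zero.
#'
#' @param counts count table (group_id, sample_id, subgenome, count).
#' @param focal the focal subgenome label.
#' @return ratio table: data.table group_id, sample_id, phat.
#' @export
phat <- function(counts, focal) {
  counts <- data.table::as.data.table(counts)
  if (any(counts$count < 0)) stop("negative counts")
  counts[, .(phat = {
    tot <- sum(count)
    if (tot > 0) sum(count[subgenome == focal]) / tot else NA_real_
  }), by = .(group_id, sample_id)]
}

#' Percentage of expressed homeologs per subgenome
#'
#' A group is expressed on a subgenome when its count exceeds `min_reads`
#' ("more than one read" at the default) in any sample.
#'
#' @param counts count table (group_id, sample_id, subgenome, count).
#' @param catalog a `homeolog_catalog` (defines the denominator); when NULL
#'   the groups present in `counts` define it.
#' @param min_reads expression threshold; count must be strictly greater.
#' @return named numeric vector: percentage of catalog groups per subgenome.
#' @export
expressed_homeologs <- function(counts, catalog = NULL, min_reads = 1) {
  counts <- data.table::as.data.table(counts)
  all_groups <- if (is.null(catalog)) unique(counts$group_id) else
    catalog$groups$group_id
  if (length(all_groups) == 0L) stop("empty homeolog catalog")
  expr <- counts[, .(expressed = any(count > min_reads)),
                 by = .(group_id, subgenome)]
  subs <- unique(counts$subgenome)
  setNames(vapply(subs, function(s) {
    100 * sum(expr[subgenome == s & expressed == TRUE,
                   data.table::uniqueN(group_id)]) / length(all_groups)
  }, numeric(1)), subs)
}
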