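## Readers and writers for the formats the pipeline consumes and emits.
## All internal coordinates are 0-based half-open; GFF3 (1-based inclusive)
## and SAM (1-based) are converted here and nowhere else.

#' Read a FASTA file
#'
#' @param path path to a FASTA file.
#' @return named character vector of upper-cased sequences; names are the
#'   full header lines without the leading `>`. Non-ACGT characters are
#'   preserved.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    warning("empty FASTA file: ", path)
    return(setNames(character(0), character(0)))
  }
  if (!startsWith(lines[nonblank[1]], ">")) {
    stop("malformed FASTA header at line ", nonblank[1], " of ", path,
         ": expected '>'")
  }
  x <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param records named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (length(records) == 0L) stop("no records to write")
  x <- Biostrings::BStringSet(records)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read transcript models from a GFF3 file
#'
#' Parses gene/mRNA/exon features linked through `Parent` attributes into a
#' transcript model table. GFF3 1-based inclusive coordinates are converted
#' to the internal 0-based half-open convention.
#'
#' @param path path to a GFF3 file.
#' @param subgenome optional subgenome label recorded on every transcript.
#' @return list with `transcripts` (data.table: gene_id, transcript_id,
#'   subgenome, contig, strand, spliced_length) and `exons` (data.table:
#'   transcript_id, start, end; 0-based half-open, sorted in genomic order).
#' @export
read_gff3 <- function(path, subgenome = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("no features in GFF3 file: ", path)
  f <- data.table::as.data.table(
    do.call(rbind, strsplit(lines, "\t", fixed = TRUE)))
  if (ncol(f) != 9L) stop("malformed GFF3 (expected 9 columns): ", path)
  data.table::setnames(f, c("contig", "source", "type", "start1", "end1",
                            "score", "strand", "phase", "attr"))
  f[, start := as.integer(start1) - 1L]   # 0-based half-open
  f[, end := as.integer(end1)]
  attr_field <- function(a, key) {
    m <- regmatches(a, regexpr(paste0("(^|;)", key, "=[^;]+"), a))
    out <- rep(NA_character_, length(a))
    hit <- lengths(regmatches(a, gregexpr(paste0("(^|;)", key, "=[^;]+"), a))) > 0
    out[hit] <- sub(paste0("^;?", key, "="), "", m)
    out
  }
  f[, id := attr_field(attr, "ID")]
  f[, parent := attr_field(attr, "Parent")]

  mrna <- f[type %in% c("mRNA", "transcript")]
  exon <- f[type == "exon"]
  if (nrow(mrna) == 0L) stop("no mRNA/transcript features in ", path)
  orphan <- exon[!parent %in% mrna$id]
  if (nrow(orphan) > 0L) {
    stop("exon feature(s) without parent mRNA: ",
         paste(unique(orphan$parent), collapse = ", "))
  }
  exons <- exon[, .(transcript_id = parent, start, end)]
  data.table::setorder(exons, transcript_id, start)
  ## overlapping exons within a transcript violate the model
  bad <- exons[, any(start[-1] < end[-.N]), by = transcript_id][V1 == TRUE]
  if (nrow(bad) > 0L) {
    stop("overlapping exons in transcript(s): ",
         paste(bad$transcript_id, collapse = ", "))
  }
  lens <- exons[, .(spliced_length = sum(end - start)), by = transcript_id]
  transcripts <- mrna[, .(gene_id = ifelse(is.na(parent), id, parent),
                          transcript_id = id, contig, strand)]
  transcripts <- merge(transcripts, lens, by = "transcript_id", sort = FALSE)
  transcripts[, subgenome := subgenome]
  data.table::setcolorder(transcripts, c("gene_id", "transcript_id",
                                         "subgenome", "contig", "strand",
                                         "spliced_length"))
  list(transcripts = transcripts[], exons = exons[])
}

#' Write transcript models to a GFF3 file
#'
#' Inverse of [read_gff3()]: internal 0-based half-open exon coordinates are
#' written back as GFF3 1-based inclusive.
#'
#' @param transcripts,exons tables as returned by [read_gff3()].
#' @param path output path.
#' @export
write_gff3 <- function(transcripts, exons, path) {
  tr <- data.table::as.data.table(transcripts)
  ex <- data.table::as.data.table(exons)
  lines <- c("##gff-version 3")
  genes <- tr[, .(start = NA_integer_, end = NA_integer_), by = gene_id]
  for (g in unique(tr$gene_id)) {
    trg <- tr[gene_id == g]
    exg <- ex[transcript_id %in% trg$transcript_id]
    gstart <- min(exg$start) + 1L
    gend <- max(exg$end)
    lines <- c(lines, paste(trg$contig[1], "homeoquant", "gene", gstart,
                            gend, ".", trg$strand[1], ".",
                            paste0("ID=", g), sep = "\t"))
    for (i in seq_len(nrow(trg))) {
      tid <- trg$transcript_id[i]
      ext <- ex[transcript_id == tid]
      lines <- c(lines,
        paste(trg$contig[i], "homeoquant", "mRNA", min(ext$start) + 1L,
              max(ext$end), ".", trg$strand[i], ".",
              paste0("ID=", tid, ";Parent=", g), sep = "\t"),
        paste(trg$contig[i], "homeoquant", "exon", ext$start + 1L, ext$end,
              ".", trg$strand[i], ".", paste0("Parent=", tid), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

## mismatches from an MD tag: count substitution letters outside deletion runs
md_mismatches <- function(md) {
  vapply(md, function(m) {
    if (is.na(m)) return(NA_integer_)
    m <- gsub("\\^[A-Z]+", "", m)          # drop deletion runs
    sum(gregexpr("[A-Z]", m)[[1]] > 0)
  }, integer(1), USE.NAMES = FALSE)
}

#' Read alignments from a SAM or BAM file
#'
#' Converts SAM text to BAM internally (via Rsamtools) and extracts one
#' record per alignment. Unmapped records are excluded (tallied in the
#' `n_unmapped` attribute); records below `mapq_min` are excluded when the
#' threshold is set; secondary alignments are retained and flagged.
#' Mismatch counts come from the NM tag, else are derived from the MD tag.
#'
#' @param path path to a SAM or BAM file.
#' @param mapq_min optional minimum mapping quality (alignments with
#'   MAPQ < mapq_min are dropped). The upstream analyses used 20.
#' @param subgenome optional subgenome label stored on every record.
#' @return data.table with columns read_id, mate (1, 2 or 0 for unpaired),
#'   subgenome, contig, pos (0-based), cigar, mismatches, mapq, seq, qual,
#'   is_secondary; attribute `n_unmapped` counts skipped unmapped records.
#' @export
read_sam <- function(path, mapq_min = NULL, subgenome = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  is_bam <- grepl("\\.bam$", path, ignore.case = TRUE)
  bam <- if (is_bam) path else {
    dest <- tempfile(fileext = "")
    Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "mapq", "seq", "qual"),
    tag = c("NM", "MD")))[[1]]
  flag <- res$flag
  unmapped <- bitwAnd(flag, 4L) > 0L
  n_unmapped <- sum(unmapped)
  keep <- !unmapped
  if (!is.null(mapq_min)) keep <- keep & res$mapq >= mapq_min
  nm <- res$tag$NM
  md <- res$tag$MD
  if (is.null(nm)) nm <- rep(NA_integer_, length(flag))
  if (is.null(md)) md <- rep(NA_character_, length(flag))
  mm <- nm
  need <- is.na(mm) & keep
  if (any(need)) {
    if (all(is.na(md[need]))) {
      stop("alignments carry neither NM nor MD tags; recompute tags ",
           "(e.g. samtools calmd) before import")
    }
    mm[need] <- md_mismatches(md[need])
  }
  if (any(is.na(mm) & keep)) {
    stop("alignments carry neither NM nor MD tags; recompute tags ",
         "(e.g. samtools calmd) before import")
  }
  mate <- ifelse(bitwAnd(flag, 1L) == 0L, 0L,
                 ifelse(bitwAnd(flag, 64L) > 0L, 1L, 2L))
  out <- data.table::data.table(
    read_id = res$qname,
    mate = mate,
    subgenome = subgenome,
    contig = as.character(res$rname),
    pos = res$pos - 1L,                    # 0-based internal
    cigar = res$cigar,
    mismatches = as.integer(mm),
    mapq = res$mapq,
    seq = as.character(res$seq),
    qual = as.character(res$qual),
    is_secondary = bitwAnd(flag, 256L) > 0L)[keep]
  data.table::setattr(out, "n_unmapped", n_unmapped)
  out[]
}

#' Write an alignment table as SAM
#'
#' @param aln alignment table in the layout produced by [read_sam()].
#' @param seq_lengths named integer vector of reference sequence lengths.
#' @param path output path.
#' @export
write_sam <- function(aln, seq_lengths, path) {
  aln <- data.table::as.data.table(aln)
  header <- c("@HD\tVN:1.6\tSO:unknown",
              paste0("@SQ\tSN:", names(seq_lengths), "\tLN:", seq_lengths))
  flag <- ifelse(aln$mate == 0L, 0L,
                 ifelse(aln$mate == 1L, 1L + 64L, 1L + 128L))
  flag <- flag + ifelse(aln$is_secondary, 256L, 0L)
  body <- paste(aln$read_id, flag, aln$contig, aln$pos + 1L, aln$mapq,
                aln$cigar, "*", 0L, 0L, aln$seq, aln$qual,
                paste0("NM:i:", aln$mismatches), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write reads to FASTQ
#'
#' @param reads data.table with read_id, mate, seq, qual.
#' @param path output path (single file; mate is appended to the read name
#'   as `/1`, `/2` for paired data).
#' @export
write_fastq <- function(reads, path) {
  reads <- data.table::as.data.table(reads)
  nm <- ifelse(reads$mate == 0L, reads$read_id,
               paste0(reads$read_id, "/", reads$mate))
  writeLines(as.vector(rbind(paste0("@", nm), reads$seq, "+", reads$qual)),
             path)
  invisible(path)
}

#' Write / read a homeolog count table as TSV
#'
#' The wide layout has one row per homeolog group and one column per
#' `<sample>:<subgenome>` combination.
#'
#' @param counts long count table (group_id, sample_id, subgenome, count).
#' @param path file path.
#' @export
write_count_table <- function(counts, path) {
  counts <- data.table::as.data.table(counts)
  wide <- data.table::dcast(counts, group_id ~ sample_id + subgenome,
                            value.var = "count", sep = ":", fill = 0)
  data.table::setnames(wide, "group_id", "homeolog_id")
  data.table::fwrite(wide, path, sep = "\t")
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  wide <- data.table::fread(path, sep = "\t")
  data.table::setnames(wide, "homeolog_id", "group_id")
  long <- data.table::melt(wide, id.vars = "group_id",
                           variable.name = "key", value.name = "count")
  long[, c("sample_id", "subgenome") := data.table::tstrsplit(key, ":")]
  long[, key := NULL]
  if (any(long$count < 0)) stop("negative counts in ", path)
  long[, .(group_id, sample_id, subgenome, count = as.numeric(count))]
}

#' Write / read a read-origin truth table
#'
#' @param truth data.table with read_id and subgenome (true origin).
#' @param path file path.
#' @export
write_truth_table <- function(truth, path) {
  data.table::fwrite(data.table::as.data.table(truth)[,
    .(read_id, subgenome)], path, sep = "\t")
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  data.table::fread(path, sep = "\t",
                    colClasses = c(read_id = "character",
                                   subgenome = "character"))
}
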