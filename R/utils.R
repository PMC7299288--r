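## small shared helpers: cigar parsing, phred conversion, sequence utilities

#' Parse CIGAR strings into operation/length pairs
#'
#' @param cigar character vector of CIGAR strings (ops in M, I, D, N, S).
#' @return list of data.frames with columns `op` and `len`.
#' @keywords internal
parse_cigar <- function(cigar) {
  lapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") {
      return(data.frame(op = character(), len = integer()))
    }
    lens <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
    ops <- regmatches(cg, gregexpr("[MIDNS]", cg))[[1]]
    if (length(ops) != length(lens)) {
      stop("malformed CIGAR string: ", cg)
    }
    data.frame(op = ops, len = lens, stringsAsFactors = FALSE)
  })
}

## reference span consumed by a cigar (M, D, N); vectorized, fast path for pure-M
cigar_ref_span <- function(cigar) {
  out <- integer(length(cigar))
  simple <- grepl("^[0-9]+M$", cigar)
  out[simple] <- as.integer(sub("M$", "", cigar[simple]))
  if (any(!simple)) {
    out[!simple] <- vapply(parse_cigar(cigar[!simple]), function(d) {
      sum(d$len[d$op %in% c("M", "D", "N")])
    }, integer(1))
  }
  out
}

## query span consumed by a cigar (M, I, S)
cigar_query_span <- function(cigar) {
  out <- integer(length(cigar))
  simple <- grepl("^[0-9]+M$", cigar)
  out[simple] <- as.integer(sub("M$", "", cigar[simple]))
  if (any(!simple)) {
    out[!simple] <- vapply(parse_cigar(cigar[!simple]), function(d) {
      sum(d$len[d$op %in% c("M", "I", "S")])
    }, integer(1))
  }
  out
}

## map 0-based reference offsets (relative to alignment start) to 0-based read
## offsets for one alignment; NA where the reference base is deleted/skipped.
## `ref_off` must be within the reference span of the cigar.
cigar_ref2query <- function(cigar, ref_off) {
  if (grepl("^[0-9]+M$", cigar)) {
    return(ref_off)
  }
  d <- parse_cigar(cigar)[[1]]
  qpos <- 0L
  rpos <- 0L
  out <- rep(NA_integer_, length(ref_off))
  for (i in seq_len(nrow(d))) {
    op <- d$op[i]
    len <- d$len[i]
    if (op == "M") {
      hit <- ref_off >= rpos & ref_off < rpos + len
      out[hit] <- qpos + (ref_off[hit] - rpos)
      rpos <- rpos + len
      qpos <- qpos + len
    } else if (op %in% c("D", "N")) {
      rpos <- rpos + len
    } else if (op %in% c("I", "S")) {
      qpos <- qpos + len
    }
  }
  out
}

## phred character -> error probability
qual_to_err <- function(qual_chars) {
  10^(-(utf8ToInt(paste0(qual_chars, collapse = "")) - 33L) / 10)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## count per-position differences between two equal-length character scalars,
## vectorized over pairs by concatenation (single C-level utf8ToInt call)
str_mismatch_counts <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) == 0L) return(integer(0))
  widths <- nchar(a)
  if (any(nchar(b) != widths)) stop("sequences must have equal lengths pairwise")
  ai <- utf8ToInt(paste0(a, collapse = ""))
  bi <- utf8ToInt(paste0(b, collapse = ""))
  idx <- rep.int(seq_along(a), widths)
  diff <- ai != bi
  out <- integer(length(a))
  if (any(diff)) {
    tab <- tabulate(idx[diff], nbins = length(a))
    out <- tab
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
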