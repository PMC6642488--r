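#' Screen reads that may contain a VR of a candidate TR
#'
#' A read is a candidate when adenine-wildcard seeds of the TR hit it on
#' a common diagonal at least `min_support` times, in either orientation
#' (the dependency-free replacement for a BLASTN read screen;
#' wildcarding TR adenines keeps recall even when every adenine has
#' mutated, while the informative-position and diagonal-support
#' requirements keep the background candidate rate low).
#'
#' @param tr_seq TR sequence (its own reading orientation).
#' @param reads Named character vector of read sequences.
#' @param seed_k Seed length (default 8).
#' @param seed_step Step between template seed offsets (default 4).
#' @param min_informative Minimum non-A positions per usable seed.
#' @param min_support Minimum seed hits on one diagonal (default 3;
#'   neighboring seeds overlap, so two same-diagonal hits are highly
#'   correlated and a pair is weak evidence).
#' @return The candidate subset of `reads`.
#' @export
screen_reads <- function(tr_seq, reads, seed_k = 8L, seed_step = 4L,
                         min_informative = 4L, min_support = 3L) {
  if (length(reads) == 0L) return(reads)
  hit <- .cpp_screen_reads(tr_seq, unname(reads), as.integer(seed_k),
                           as.integer(seed_step), TRUE,
                           as.integer(min_informative),
                           as.integer(min_support))
  reads[hit]
}

#' Confirm VRs from candidate reads
#'
#' Each candidate read is aligned to the TR with [adenine_aware_align()]
#' (better of the two orientations). Read-level VR calls passing the
#' read-support filters (at most `max_non_a` non-A-to-N substitutions,
#' alignment longer than 30 columns, identity above 0.60) are grouped by
#' their footprint on the TR (single-linkage interval overlap); groups
#' supported by at least `min_reads` reads yield confirmed evidence.
#'
#' @param tr_seq TR sequence.
#' @param reads Candidate reads (from [screen_reads()]).
#' @param min_reads Minimum supporting reads (default 2).
#' @param max_non_a Maximum non-A-to-N substitutions per read (default 3).
#' @return Data frame of confirmed footprints: `tr_start`, `tr_end`
#'   (0-based half-open on the TR), `n_reads`, and a `read_ids` list
#'   column; zero rows when nothing is confirmed.
#' @export
confirm_vrs_from_reads <- function(tr_seq, reads, min_reads = 2L,
                                   max_non_a = 3L) {
  empty <- data.frame(tr_start = integer(0), tr_end = integer(0),
                      n_reads = integer(0))
  empty$read_ids <- list()
  if (length(reads) == 0L) return(empty)
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read", seq_along(reads))
  calls <- list()
  for (i in seq_along(reads)) {
    fwd <- adenine_aware_align(tr_seq, reads[[i]])
    rev <- adenine_aware_align(tr_seq, reverse_complement(reads[[i]]))
    al <- if (fwd$score >= rev$score) fwd else rev
    st <- alignment_stats(al$tr_aln, al$sub_aln)
    if (st$non_a_to_n <= max_non_a && st$length > 30 &&
        st$identity > 0.60) {
      calls[[length(calls) + 1L]] <-
        data.frame(tr_start = al$tr_start, tr_end = al$tr_end,
                   id = ids[i], stringsAsFactors = FALSE)
    }
  }
  if (length(calls) == 0L) return(empty)
  cl <- do.call(rbind, calls)
  cl <- cl[order(cl$tr_start, cl$tr_end), , drop = FALSE]
  grp <- cumsum(c(1L, cl$tr_start[-1L] >=
                    cummax(cl$tr_end[-nrow(cl)])))
  out <- list()
  for (g in unique(grp)) {
    sub <- cl[grp == g, , drop = FALSE]
    if (nrow(sub) < min_reads) next
    ev <- data.frame(tr_start = min(sub$tr_start),
                     tr_end = max(sub$tr_end),
                     n_reads = nrow(sub))
    ev$read_ids <- list(sub$id)
    out[[length(out) + 1L]] <- ev
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Coverage depth convention
#'
#' `100 * n_matched_reads / sequence_length` — the read-count-based
#' coverage convention used for DGR loci (equal to true depth for 100 bp
#' reads).
#'
#' @param n_matched_reads Number of reads matched to the locus.
#' @param sequence_length Locus length in nt (> 0).
#' @return Numeric coverage value.
#' @export
coverage_depth <- function(n_matched_reads, sequence_length) {
  if (sequence_length <= 0) stop("sequence_length must be > 0")
  if (n_matched_reads < 0) stop("n_matched_reads must be >= 0")
  100 * n_matched_reads / sequence_length
}

#' Count matched reads for a locus from a SAM file
#'
#' Minimal import path for users who map reads with an external aligner:
#' counts primary mapped reads whose alignment overlaps the interval by
#' at least `min_frac` of the read length, and returns the coverage
#' value under the [coverage_depth()] convention. Only the mandatory SAM
#' columns are consulted; the reference-consumed length is derived from
#' the CIGAR string.
#'
#' @param sam_path Path to a SAM (text) file with or without header.
#' @param contig_id Reference name of the locus.
#' @param start,end Locus interval, 0-based half-open.
#' @param min_frac Minimum fraction of the read overlapping the locus
#'   (default 0.5).
#' @return List with `n_reads` and `coverage`.
#' @export
sam_coverage <- function(sam_path, contig_id, start, end,
                         min_frac = 0.5) {
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  n <- 0L
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 11L) next
    flag <- as.integer(f[2L])
    if (bitwAnd(flag, 4L) != 0L || bitwAnd(flag, 256L) != 0L ||
        bitwAnd(flag, 2048L) != 0L) next
    if (f[3L] != contig_id) next
    pos <- as.integer(f[4L]) - 1L
    cig <- f[6L]
    ops <- gregexpr("[0-9]+[MIDNSHP=X]", cig)[[1L]]
    rlen <- 0L
    if (ops[1L] != -1L) {
      for (m in regmatches(cig, gregexpr("[0-9]+[MIDNSHP=X]", cig))[[1L]]) {
        op <- substr(m, nchar(m), nchar(m))
        k <- as.integer(substr(m, 1L, nchar(m) - 1L))
        if (op %in% c("M", "D", "N", "=", "X")) rlen <- rlen + k
      }
    }
    if (rlen == 0L) rlen <- nchar(f[10L])
    ov <- min(end, pos + rlen) - max(start, pos)
    if (ov >= min_frac * rlen) n <- n + 1L
  }
  list(n_reads = n, coverage = coverage_depth(n, end - start))
}
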