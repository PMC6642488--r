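# Column-wise statistics of a TR/VR alignment. Gap columns are neither
# matches nor substitutions; identity counts identical non-gap columns
# over ALL columns (gaps count in the denominator).
alignment_stats <- function(tr_aln, vr_aln) {
  a <- strsplit(tr_aln, "")[[1L]]
  b <- strsplit(vr_aln, "")[[1L]]
  stopifnot(length(a) == length(b))
  gap <- a == "-" | b == "-"
  ident <- !gap & a == b
  subst <- !gap & a != b
  runs <- rle(ident)
  ccs <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  list(length = length(a),
       identity = sum(ident) / length(a),
       a_to_n = sum(subst & a == "A"),
       non_a_to_n = sum(subst & a != "A"),
       gap_cols = sum(gap),
       identical_cols = sum(ident),
       longest_ccs = as.integer(ccs))
}

#' Adenine-aware local alignment
#'
#' Smith-Waterman local alignment with affine gaps in which a mismatch at
#' a template-adenine column is free: DGR mutagenesis rewrites TR
#' adenines, so a VR differing from its TR at adenine positions should
#' score as well as a faithful copy. Default scores: match +2, TR-A
#' mismatch 0, other mismatch -3, gap open -5, gap extend -2 (a gap of
#' length g costs 5 + 2g). Setting `mism_a = mism_other` collapses to a
#' textbook local aligner.
#'
#' @param tr_seq Template (TR) nucleotide string.
#' @param window Subject nucleotide string.
#' @param match,mism_a,mism_other,gap_open,gap_ext Scoring parameters.
#' @return List with `score`, `tr_aln`, `sub_aln` (gapped rows),
#'   `tr_start`, `tr_end`, `sub_start`, `sub_end` (0-based half-open).
#' @export
adenine_aware_align <- function(tr_seq, window, match = 2, mism_a = 0,
                                mism_other = -3, gap_open = -5,
                                gap_ext = -2) {
  stopifnot(nzchar(tr_seq), nzchar(window))
  al <- .cpp_local_align(tr_seq, window, match, mism_a, mism_other,
                         gap_open, gap_ext)
  list(score = al$score, tr_aln = al$pattern_aln,
       sub_aln = al$subject_aln,
       tr_start = al$pattern_start, tr_end = al$pattern_end,
       sub_start = al$subject_start, sub_end = al$subject_end)
}

#' VR retention filter
#'
#' A TR-VR pair is kept iff the alignment is longer than 30 columns, the
#' identity is higher than 60%, and the number of non-A-to-N
#' substitutions is under four. Comparisons are strict.
#'
#' @param pair A one-row pair data frame or list with `length`,
#'   `identity`, `non_a_to_n`.
#' @return Logical.
#' @export
filter_vr <- function(pair) {
  isTRUE(pair$length > 30) && isTRUE(pair$identity > 0.60) &&
    isTRUE(pair$non_a_to_n < 4)
}

#' Longest continuous consistent segment (CCS)
#'
#' The longest run of consecutive identical, ungapped aligned columns
#' between TR and VR. Short CCS is what defeats exact-seed homology
#' search on heavily mutated repeats.
#'
#' @param pair A pair (list or one-row data frame) with `tr_aln` and
#'   `vr_aln` gapped alignment rows.
#' @return Integer run length.
#' @export
longest_ccs <- function(pair) {
  alignment_stats(as.character(pair$tr_aln),
                  as.character(pair$vr_aln))$longest_ccs
}

empty_pairs <- function() {
  df <- data.frame(contig_id = character(0), tr_start = integer(0),
                   tr_end = integer(0), tr_strand = character(0),
                   vr_start = integer(0), vr_end = integer(0),
                   vr_strand = character(0), score = numeric(0),
                   length = integer(0), identity = numeric(0),
                   a_to_n = integer(0), non_a_to_n = integer(0),
                   n_subs = integer(0), longest_ccs = integer(0),
                   tr_aln = character(0), vr_aln = character(0),
                   stringsAsFactors = FALSE)
  df
}

#' Find variable repeats for a candidate TR
#'
#' Scans both strands of every contig for VR copies of the TR. Candidate
#' loci come from adenine-wildcard k-mer seeding (template adenines match
#' anything, so even VRs whose longest identical segment is far below the
#' BLAST seed length are seeded); each candidate window is then extended
#' with [adenine_aware_align()], the hit overlapping the TR's own locus
#' is discarded, and surviving pairs are passed through [filter_vr()].
#'
#' @param tr One-row data frame (from [scan_elements()]) with
#'   `contig_id`, `start`, `end`, `strand`.
#' @param contigs Named character vector of contig sequences.
#' @param seed_k Seed length (default 8).
#' @param seed_step Offset step between template seeds (default 4).
#' @param min_informative Minimum non-A positions per usable seed
#'   (default 5): near-all-A seeds of an AAC-rich template match
#'   everywhere and carry no signal.
#' @param min_support Minimum seed hits on the best diagonal of a
#'   candidate locus (default 3); substitution-only VR copies put every
#'   seed hit on one diagonal, random collisions rarely reach three.
#' @param apply_filter Apply [filter_vr()] (default TRUE).
#' @return Pair data frame (one row per retained TR-VR pair) with
#'   coordinates, alignment statistics and the gapped alignment rows.
#' @export
find_vrs <- function(tr, contigs, seed_k = 8L, seed_step = 4L,
                     min_informative = 5L, min_support = 3L,
                     apply_filter = TRUE) {
  tr_seq <- interval_seq(contigs, tr$contig_id, tr$start, tr$end,
                         tr$strand)
  tr_len <- nchar(tr_seq)
  out <- list()
  for (cid in names(contigs)) {
    cseq <- contigs[[cid]]
    L <- nchar(cseq)
    for (strand in c("+", "-")) {
      subject <- if (strand == "+") cseq else reverse_complement(cseq)
      proj <- .cpp_seed_project(tr_seq, subject, as.integer(seed_k),
                                as.integer(seed_step), TRUE,
                                as.integer(min_informative))
      if (length(proj) == 0L) next
      # weigh diagonal support, then chain nearby diagonals into loci;
      # each locus is anchored at its best-supported diagonal
      cnt <- table(proj)
      diag <- as.integer(names(cnt))
      support <- as.integer(cnt)
      grp <- cumsum(c(1L, diff(diag) > tr_len %/% 2L))
      centers <- integer(0)
      for (g in unique(grp)) {
        sel <- grp == g
        if (max(support[sel]) < min_support) next
        d <- diag[sel]
        s <- support[sel]
        centers <- c(centers, d[order(-s, d)][1L])
      }
      for (ctr in centers) {
        ws <- max(0L, ctr - tr_len %/% 2L)
        we <- min(L, ctr + tr_len + tr_len %/% 2L)
        if (we - ws < 10L) next
        al <- adenine_aware_align(tr_seq, substr(subject, ws + 1L, we))
        if (al$score <= 0) next
        # subject-footprint in forward coordinates
        ss <- ws + al$sub_start
        se <- ws + al$sub_end
        if (strand == "-") {
          tmp <- L - se
          se <- L - ss
          ss <- tmp
        }
        st <- alignment_stats(al$tr_aln, al$sub_aln)
        pair <- data.frame(contig_id = cid, tr_start = tr$start,
                           tr_end = tr$end, tr_strand = tr$strand,
                           vr_start = ss, vr_end = se,
                           vr_strand = strand, score = al$score,
                           length = st$length, identity = st$identity,
                           a_to_n = st$a_to_n,
                           non_a_to_n = st$non_a_to_n,
                           n_subs = st$a_to_n + st$non_a_to_n,
                           longest_ccs = st$longest_ccs,
                           tr_aln = al$tr_aln, vr_aln = al$sub_aln,
                           stringsAsFactors = FALSE)
        out[[length(out) + 1L]] <- pair
      }
    }
  }
  if (length(out) == 0L) return(empty_pairs())
  pairs <- do.call(rbind, out)
  # self-hit: any overlap with the TR's own interval on its contig
  self <- pairs$contig_id == tr$contig_id &
    pmin(pairs$vr_end, tr$end) - pmax(pairs$vr_start, tr$start) > 0
  pairs <- pairs[!self, , drop = FALSE]
  key <- paste(pairs$contig_id, pairs$vr_strand, pairs$vr_start,
               pairs$vr_end)
  pairs <- pairs[!duplicated(key), , drop = FALSE]
  if (apply_filter && nrow(pairs) > 0) {
    keep <- vapply(seq_len(nrow(pairs)),
                   function(i) filter_vr(pairs[i, ]), logical(1))
    pairs <- pairs[keep, , drop = FALSE]
  }
  rownames(pairs) <- NULL
  pairs
}

#' Exact-seed control search
#'
#' The BLAST-like control: reports projected candidate starts found with
#' plain exact k-mers (default k = 11, the BLASTN default seed length).
#' Used to demonstrate which highly mutated VRs exact seeding misses.
#'
#' @param tr_seq Template sequence.
#' @param subject Subject sequence.
#' @param k Seed length (default 11).
#' @return Integer vector of projected 0-based template-start positions
#'   (empty when no exact seed matches).
#' @export
exact_seed_hits <- function(tr_seq, subject, k = 11L) {
  unique(.cpp_seed_project(tr_seq, subject, as.integer(k), 1L, FALSE, 0L))
}

#' Merge overlapping VR intervals
#'
#' VR footprints on the same contig and strand overlapping by >= 1 bp are
#' unioned; each merged interval records its contributing pair rows.
#'
#' @param pairs Pair data frame from [find_vrs()].
#' @return Data frame with `contig_id`, `start`, `end`, `strand`,
#'   `n_pairs` and a `pair_rows` list column of contributing row indices.
#' @export
merge_vrs <- function(pairs) {
  if (nrow(pairs) == 0L) {
    out <- data.frame(contig_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      n_pairs = integer(0))
    out$pair_rows <- list()
    return(out)
  }
  out <- list()
  for (key in unique(paste(pairs$contig_id, pairs$vr_strand))) {
    idx <- which(paste(pairs$contig_id, pairs$vr_strand) == key)
    sub <- pairs[idx, , drop = FALSE]
    ir <- IRanges::IRanges(start = sub$vr_start + 1L, end = sub$vr_end)
    red <- IRanges::reduce(ir)
    hit <- IRanges::findOverlaps(ir, red)
    for (j in seq_along(red)) {
      rows <- idx[S4Vectors::queryHits(hit)[S4Vectors::subjectHits(hit) == j]]
      m <- data.frame(contig_id = sub$contig_id[1L],
                      start = IRanges::start(red)[j] - 1L,
                      end = IRanges::end(red)[j],
                      strand = sub$vr_strand[1L],
                      n_pairs = length(rows))
      m$pair_rows <- list(rows)
      out[[length(out) + 1L]] <- m
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$contig_id, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
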