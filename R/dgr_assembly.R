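#' Assemble element hits into DGR records
#'
#' Elements on one contig whose pairwise gaps are at most `locus_window`
#' are grouped into a locus by single-linkage chaining. A locus with at
#' least one TR and one RT becomes a record: `intact` when at least one
#' retained (filtered) VR is present, `partial` otherwise. Loci lacking a
#' TR or an RT are dropped.
#'
#' @param hits Element table from [scan_elements()] (TR and RT rows).
#' @param pairs Pair table from [find_vrs()] (already filtered).
#' @param orfs Optional ORF table from [find_orfs()] used to attach
#'   target genes to each record's VRs.
#' @param locus_window Maximum gap between neighboring elements of one
#'   locus, in nt (default 20000).
#' @return List of DGR records: each a list with `dgr_id`, `contig_id`,
#'   `trs`, `rts` (element rows), `pairs`, `vrs` (merged VR intervals
#'   with target assignment), `targets` (ORF rows), `status`,
#'   `cassette_signature`.
#' @export
assemble_dgrs <- function(hits, pairs, orfs = NULL,
                          locus_window = 20000L) {
  records <- list()
  elements <- list()
  add_el <- function(contig, start, end, kind, row) {
    data.frame(contig_id = contig, start = start, end = end, kind = kind,
               row = row, stringsAsFactors = FALSE)
  }
  if (nrow(hits) > 0) {
    for (i in seq_len(nrow(hits))) {
      elements[[length(elements) + 1L]] <-
        add_el(hits$contig_id[i], hits$start[i], hits$end[i],
               hits$element_type[i], i)
    }
  }
  merged <- merge_vrs(pairs)
  if (!is.null(orfs)) merged <- assign_targets(merged, orfs)
  if (nrow(merged) > 0) {
    for (i in seq_len(nrow(merged))) {
      elements[[length(elements) + 1L]] <-
        add_el(merged$contig_id[i], merged$start[i], merged$end[i],
               "VR", i)
    }
  }
  if (length(elements) == 0L) return(records)
  el <- do.call(rbind, elements)
  counter <- 0L
  for (cid in unique(el$contig_id)) {
    sub <- el[el$contig_id == cid, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    gap_break <- c(FALSE, sub$start[-1L] -
                     cummax(sub$end[-nrow(sub)]) > locus_window)
    locus <- cumsum(gap_break)
    for (l in unique(locus)) {
      ls <- sub[locus == l, , drop = FALSE]
      tr_rows <- ls$row[ls$kind == "TR"]
      rt_rows <- ls$row[ls$kind == "RT"]
      vr_rows <- ls$row[ls$kind == "VR"]
      if (length(tr_rows) == 0L || length(rt_rows) == 0L) next
      counter <- counter + 1L
      vrs <- merged[vr_rows, , drop = FALSE]
      pr <- if (length(vr_rows) > 0)
        pairs[unique(unlist(vrs$pair_rows)), , drop = FALSE]
      else pairs[0, , drop = FALSE]
      targets <- if (!is.null(orfs) && nrow(vrs) > 0 &&
                     any(!is.na(vrs$orf_row)))
        orfs[unique(vrs$orf_row[!is.na(vrs$orf_row)]), , drop = FALSE]
      else if (!is.null(orfs)) orfs[0, , drop = FALSE]
      else NULL
      rec <- list(dgr_id = sprintf("DGR_%04d", counter),
                  contig_id = cid,
                  trs = hits[tr_rows, , drop = FALSE],
                  rts = hits[rt_rows, , drop = FALSE],
                  pairs = pr, vrs = vrs, targets = targets,
                  status = if (nrow(vrs) > 0) "intact" else "partial")
      rec$cassette_signature <- cassette_signature(rec)$signature
      records[[length(records) + 1L]] <- rec
    }
  }
  records
}

#' Cassette-pattern signature of a DGR record
#'
#' Elements (TRs, merged VRs, RTs) are sorted by start coordinate and
#' written left to right as `label` plus orientation (`>` forward, `<`
#' reverse), with consecutive identical tokens run-length encoded
#' (`VR>x2`). The locus is canonicalized so the highest-scoring RT reads
#' `>`: when it reads `<`, the element order is reversed and every
#' orientation flipped, making the signature invariant under a global
#' strand flip.
#'
#' @param record A DGR record from [assemble_dgrs()].
#' @return List with `signature` (string) and `tokens` (character
#'   vector, canonical order).
#' @export
cassette_signature <- function(record) {
  el <- rbind(
    data.frame(start = record$trs$start, kind = "TR",
               strand = record$trs$strand, stringsAsFactors = FALSE),
    if (nrow(record$vrs) > 0)
      data.frame(start = record$vrs$start, kind = "VR",
                 strand = record$vrs$strand, stringsAsFactors = FALSE),
    data.frame(start = record$rts$start, kind = "RT",
               strand = record$rts$strand, stringsAsFactors = FALSE))
  el <- el[order(el$start), , drop = FALSE]
  ref_rt <- which.max(record$rts$score)
  flip <- record$rts$strand[ref_rt] == "-"
  if (flip) {
    el <- el[rev(seq_len(nrow(el))), , drop = FALSE]
    el$strand <- ifelse(el$strand == "+", "-", "+")
  }
  tokens <- paste0(el$kind, ifelse(el$strand == "+", ">", "<"))
  r <- rle(tokens)
  sig <- paste(ifelse(r$lengths > 1L,
                      paste0(r$values, "x", r$lengths), r$values),
               collapse = ",")
  list(signature = sig, tokens = tokens)
}

#' Greedy identity clustering of RT sequences
#'
#' cd-hit-style non-redundancy: sequences are sorted by length
#' (descending, ties by input order); each joins the first existing
#' cluster whose representative (founder) aligns at global identity
#' >= `threshold` (identity = matches / alignment length, gaps counted),
#' otherwise it founds a new cluster.
#'
#' @param rt_sequences Character vector of nucleotide sequences.
#' @param threshold Identity threshold in (0, 1], default 0.90.
#' @return List with `cluster` (integer vector, input order) and
#'   `representative` (index of each cluster's founder).
#' @export
cluster_rts <- function(rt_sequences, threshold = 0.90) {
  stopifnot(threshold > 0, threshold <= 1)
  n <- length(rt_sequences)
  if (n == 0L) return(list(cluster = integer(0), representative = integer(0)))
  ord <- order(-nchar(rt_sequences), seq_len(n))
  cluster <- integer(n)
  reps <- integer(0)
  for (i in ord) {
    assigned <- FALSE
    for (ci in seq_along(reps)) {
      if (global_identity(rt_sequences[reps[ci]],
                          rt_sequences[i]) >= threshold) {
        cluster[i] <- ci
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, i)
      cluster[i] <- length(reps)
    }
  }
  list(cluster = cluster, representative = reps)
}
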