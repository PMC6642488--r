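# log-transition matrix with -Inf for forbidden moves
ghmm_ltrans <- function(model) {
  lt <- suppressWarnings(log(model$transition))
  lt[model$transition <= 0] <- -Inf
  lt
}

# gap distributions in the list-of-logp form the C++ decoder expects
ghmm_lgaps <- function(model) {
  lapply(model$gap_dists, function(g) {
    if (is.null(g)) return(NULL)
    list(dmin = as.integer(g$dmin), logp = log(g$prob))
  })
}

# nominal span of a full-path hit: motif widths plus modal spacers
ghmm_span <- function(model) {
  K <- length(model$motif_states)
  span <- sum(vapply(model$motif_states, function(p) p$width, integer(1)))
  if (K > 1L) {
    for (i in seq_len(K - 1L)) {
      g <- model$gap_dists[[(i - 1L) * K + i + 1L]]
      if (!is.null(g)) span <- span + g$dmax
    }
  }
  span
}

#' Decode the best motif-state path in a sequence
#'
#' Duration-explicit Viterbi over one GHMM submodel: paths run
#' begin -> (subset of motif states in model order) -> end, scoring PWM
#' log-odds per motif window, log transition probabilities, and the log
#' probability of each inter-motif spacer length. The first motif may sit
#' at any offset. Returns score `-Inf` and an empty path when no feasible
#' placement exists. Score ties are broken leftmost-start, then
#' shortest-span.
#'
#' @param model A `dgr_ghmm`.
#' @param seq Nucleotide string.
#' @return List with `score`, `states` (integer vector), `offsets`
#'   (0-based motif start offsets).
#' @export
viterbi_decode <- function(model, seq) {
  widths <- vapply(model$motif_states, function(p) p$width, integer(1))
  if (nchar(seq) < min(widths)) {
    return(list(score = -Inf, states = integer(0), offsets = integer(0)))
  }
  lodds <- lapply(model$motif_states, pwm_lodds_matrix)
  .cpp_viterbi(seq, lodds, ghmm_ltrans(model), ghmm_lgaps(model))
}

# greedy resolution of overlapping same-type hits: descending score,
# ties leftmost then lower subgroup id
resolve_overlaps <- function(hits) {
  if (nrow(hits) < 2L) return(hits)
  ord <- order(-hits$score, hits$start, hits$subgroup_id)
  hits <- hits[ord, , drop = FALSE]
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ok <- TRUE
    if (any(keep)) {
      prev <- hits[keep, , drop = FALSE]
      same <- prev$contig_id == hits$contig_id[i]
      if (any(same)) {
        ov <- pmin(prev$end[same], hits$end[i]) -
          pmax(prev$start[same], hits$start[i])
        if (any(ov > 0)) ok <- FALSE
      }
    }
    keep[i] <- ok
  }
  out <- hits[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Scan a contig for TR and RT elements
#'
#' Each submodel slides over both strands in overlapping windows
#' (window = 4 x nominal model span, step = half a window); the best
#' Viterbi path per window is kept when its score reaches the model's
#' threshold. Duplicate calls from overlapping windows are collapsed and
#' overlapping same-type hits are resolved greedily by descending score
#' (ties: leftmost, then lower subgroup id). Reverse-strand hits are
#' reported in forward coordinates with strand `"-"`.
#'
#' @param models List of `dgr_ghmm` submodels (any mix of TR and RT).
#' @param contig_seq Nucleotide string.
#' @param contig_id Contig identifier for the output table.
#' @param min_score Optional global floor overriding each model's
#'   `score_threshold`.
#' @return Data frame with columns `contig_id`, `element_type`,
#'   `subgroup_id`, `start`, `end` (0-based half-open, forward strand),
#'   `strand`, `score`, plus `motif_starts`/`motif_ends` list columns.
#' @export
scan_elements <- function(models, contig_seq, contig_id = "contig",
                          min_score = NULL) {
  L <- nchar(contig_seq)
  empty <- data.frame(contig_id = character(0), element_type = character(0),
                      subgroup_id = integer(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      score = numeric(0))
  empty$motif_starts <- list()
  empty$motif_ends <- list()
  out <- list()
  rc <- if (L > 0) reverse_complement(contig_seq) else ""
  for (model in models) {
    widths <- vapply(model$motif_states, function(p) p$width, integer(1))
    if (L < min(widths)) next
    thr <- if (is.null(min_score)) model$score_threshold else min_score
    span <- ghmm_span(model)
    win <- max(4L * span, span + 10L)
    step <- max(1L, win %/% 2L)
    lodds <- lapply(model$motif_states, pwm_lodds_matrix)
    lt <- ghmm_ltrans(model)
    lg <- ghmm_lgaps(model)
    starts <- seq(0L, max(0L, L - 1L), by = step)
    starts <- starts[starts == 0L | starts + win <= L + step]
    for (strand in c("+", "-")) {
      subject <- if (strand == "+") contig_seq else rc
      for (ws in starts) {
        we <- min(L, ws + win)
        if (we - ws < min(widths)) next
        dec <- .cpp_viterbi(substr(subject, ws + 1L, we), lodds, lt, lg)
        if (!is.finite(dec$score) || dec$score < thr) next
        ms <- ws + dec$offsets
        me <- ms + widths[dec$states]
        if (strand == "-") {
          fs <- L - rev(me)
          fe <- L - rev(ms)
          ms <- fs; me <- fe
        }
        hit <- data.frame(contig_id = contig_id,
                          element_type = model$element_type,
                          subgroup_id = model$subgroup_id,
                          start = min(ms), end = max(me),
                          strand = strand, score = dec$score)
        hit$motif_starts <- list(ms)
        hit$motif_ends <- list(me)
        out[[length(out) + 1L]] <- hit
      }
    }
  }
  if (length(out) == 0L) return(empty)
  hits <- do.call(rbind, out)
  # collapse duplicate calls of the same placement from overlapping windows
  key <- paste(hits$element_type, hits$subgroup_id, hits$start, hits$end,
               hits$strand)
  hits <- hits[!duplicated(key), , drop = FALSE]
  res <- lapply(split(hits, hits$element_type), resolve_overlaps)
  hits <- do.call(rbind, res)
  rownames(hits) <- NULL
  hits[order(hits$start, hits$element_type), , drop = FALSE]
}

#' Calibrate a submodel's score threshold on synthetic negatives
#'
#' Scans `n` random sequences of `len` bases drawn at the background
#' composition and sets the threshold to the empirical `1 - fpr` quantile
#' (type 1) of the per-sequence best window scores, so that the expected
#' false positive rate is at most `fpr` per `len`-base sequence.
#'
#' @param model A `dgr_ghmm`.
#' @param background Length-4 base composition.
#' @param n Number of negative sequences (default 200).
#' @param len Sequence length (default 2000, the paper-style negative
#'   sequence length).
#' @param fpr Target per-sequence false positive rate (default 0.001).
#' @param seed RNG seed.
#' @return The model with `score_threshold` set.
#' @export
calibrate_threshold <- function(model, background = dgr_background(),
                                n = 200L, len = 2000L, fpr = 0.001,
                                seed = 1L) {
  negs <- generate_negative_set(n, len, background, seed = seed)
  best <- vapply(negs, function(s) {
    h <- scan_elements(list(model), s, min_score = -Inf)
    if (nrow(h) == 0L) -Inf else max(h$score)
  }, numeric(1))
  best <- best[is.finite(best)]
  thr <- if (length(best) == 0L) 0 else
    as.numeric(stats::quantile(best, probs = 1 - fpr, type = 1))
  model$score_threshold <- thr + 1e-9
  model
}
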