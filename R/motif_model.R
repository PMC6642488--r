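BASES <- c("A", "C", "G", "T")

#' Build a position weight matrix from aligned segments
#'
#' Laplace-smoothed per-column base probabilities:
#' `P(b | j) = (count(b, j) + pseudocount) / (n + 4 * pseudocount)`.
#' Columns containing `N` drop the offending segments from that column's
#' count (with a warning); the smoothing keeps every entry positive.
#'
#' @param aligned_segments Character vector (>= 2) of equal-length
#'   nucleotide strings over `A`, `C`, `G`, `T` (plus tolerated `N`).
#' @param pseudocount Positive smoothing constant, default 0.5.
#' @param background Length-4 base frequency vector (A, C, G, T) summing
#'   to 1; defaults to [dgr_background()].
#' @return An object of class `dgr_pwm`: list with `width`, `probs`
#'   (width x 4 matrix), `background`, `pseudocount`.
#' @export
build_pwm <- function(aligned_segments, pseudocount = 0.5,
                      background = dgr_background()) {
  if (length(aligned_segments) < 2L) stop("need at least 2 segments")
  lens <- nchar(aligned_segments)
  if (length(unique(lens)) != 1L) stop("segments must have equal length")
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  stopifnot(abs(sum(background) - 1) < 1e-6, all(background > 0))
  w <- lens[1L]
  chars <- do.call(rbind, strsplit(aligned_segments, ""))
  if (any(!chars %in% c(BASES, "N"))) stop("invalid base in segments")
  if (any(chars == "N")) warning("N bases dropped from PWM columns")
  probs <- matrix(0, nrow = w, ncol = 4L, dimnames = list(NULL, BASES))
  for (j in seq_len(w)) {
    col <- chars[, j]
    col <- col[col != "N"]
    cnt <- table(factor(col, levels = BASES))
    probs[j, ] <- (as.numeric(cnt) + pseudocount) /
      (length(col) + 4 * pseudocount)
  }
  structure(list(width = w, probs = probs,
                 background = stats::setNames(background, BASES),
                 pseudocount = pseudocount),
            class = "dgr_pwm")
}

#' Log-odds score of a window under a PWM
#'
#' `sum_j log(P(base_j | j) / background(base_j))`; an `N` contributes 0.
#'
#' @param pwm A `dgr_pwm`.
#' @param window Nucleotide string of length `pwm$width`.
#' @return Numeric score.
#' @export
pwm_log_odds <- function(pwm, window) {
  if (nchar(window) != pwm$width) stop("window length != PWM width")
  chars <- strsplit(window, "")[[1L]]
  s <- 0
  for (j in seq_along(chars)) {
    b <- chars[j]
    if (b == "N") next
    s <- s + log(pwm$probs[j, b] / pwm$background[[b]])
  }
  unname(s)
}

# width x 4 log-odds matrix used by the C++ Viterbi
pwm_lodds_matrix <- function(pwm) {
  log(sweep(pwm$probs, 2, pwm$background, "/"))
}

# global-alignment identity (matches / alignment columns, gaps count)
global_identity <- function(a, b) {
  al <- .cpp_global_align(a, b, 2, -3, -5, -2)
  pa <- strsplit(al$pattern_aln, "")[[1L]]
  pb <- strsplit(al$subject_aln, "")[[1L]]
  sum(pa == pb & pa != "-") / length(pa)
}

#' Partition a training set into subgroups
#'
#' Average-linkage hierarchical clustering on pairwise global-alignment
#' identity (distance = 1 - identity), cut to `k` clusters. Deterministic
#' given input order.
#'
#' @param segments Character vector of nucleotide strings.
#' @param k Number of groups (default 3, the number of element submodels).
#' @return Integer vector of group labels in `1..k`, one per segment,
#'   renumbered by first occurrence.
#' @export
partition_training_set <- function(segments, k = 3L) {
  n <- length(segments)
  if (k < 1L) stop("k must be >= 1")
  if (n < k) stop("fewer segments than groups")
  if (k == 1L) return(rep(1L, n))
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      d[i, j] <- d[j, i] <- 1 - global_identity(segments[i], segments[j])
    }
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  grp <- stats::cutree(hc, k = k)
  # renumber by first appearance so labeling is order-deterministic
  as.integer(factor(grp, levels = unique(grp)))
}

#' Estimate GHMM transition and spacer-length parameters
#'
#' Maximum-likelihood counts from annotated training examples. Each
#' example annotates a subset of the motif states, in model order, with
#' 0-based half-open coordinates. Transitions get +1 smoothing over the
#' successors observed for each state; spacer-length histograms get a
#' floor of `1e-6` over their (slightly padded) support.
#'
#' @param examples List; each element a list with `states` (integer
#'   vector, increasing), `starts`, `ends` (parallel integer vectors) and
#'   optionally `seq`.
#' @param motif_states List of `dgr_pwm`, one per state.
#' @param element_type `"TR"` or `"RT"`.
#' @param subgroup_id Integer submodel label.
#' @param support_pad Non-negative integer; spacer supports are widened by
#'   this much on both sides (clamped at 0) before the floor is applied,
#'   so spacer values just outside the observed range are penalized, not
#'   forbidden. Default 2.
#' @return An object of class `dgr_ghmm`.
#' @export
estimate_ghmm_params <- function(examples, motif_states,
                                 element_type = "TR", subgroup_id = 1L,
                                 support_pad = 2L) {
  K <- length(motif_states)
  widths <- vapply(motif_states, function(p) p$width, integer(1))
  trans_counts <- matrix(0, K + 2L, K + 2L)
  state_names <- c("begin", paste0("M", seq_len(K)), "end")
  dimnames(trans_counts) <- list(state_names, state_names)
  gap_obs <- vector("list", K * K)

  for (ex in examples) {
    st <- as.integer(ex$states)
    if (is.unsorted(st, strictly = TRUE))
      stop("states must be strictly increasing within an example")
    starts <- as.integer(ex$starts); ends <- as.integer(ex$ends)
    if (any(ends - starts != widths[st]))
      stop("annotated width does not match motif width")
    if (any(starts < 0)) stop("coordinates out of bounds")
    if (length(st) > 1L && any(diff(starts) <= 0))
      stop("motif coordinates out of order")
    prev <- 1L # begin row
    for (i in seq_along(st)) {
      cur <- st[i] + 1L
      trans_counts[prev, cur] <- trans_counts[prev, cur] + 1
      if (prev > 1L) {
        d <- starts[i] - ends[i - 1L]
        if (d < 0) stop("overlapping motif annotations")
        key <- (st[i - 1L] - 1L) * K + st[i]
        gap_obs[[key]] <- c(gap_obs[[key]], d)
      }
      prev <- cur
    }
    trans_counts[prev, K + 2L] <- trans_counts[prev, K + 2L] + 1
  }

  transition <- matrix(0, K + 2L, K + 2L, dimnames = dimnames(trans_counts))
  for (i in seq_len(K + 1L)) {
    succ <- which(trans_counts[i, ] > 0)
    if (length(succ) == 0L) {
      transition[i, K + 2L] <- 1 # never-observed state: exit directly
      next
    }
    n_i <- sum(trans_counts[i, ])
    transition[i, succ] <- (trans_counts[i, succ] + 1) /
      (n_i + length(succ))
  }

  gap_dists <- vector("list", K * K)
  for (key in seq_len(K * K)) {
    obs <- gap_obs[[key]]
    if (is.null(obs)) next
    dmin <- max(0L, min(obs) - support_pad)
    dmax <- max(obs) + support_pad
    support <- dmin:dmax
    h <- tabulate(obs - dmin + 1L, nbins = length(support))
    p <- h + 1e-6
    p <- p / sum(p)
    gap_dists[[key]] <- list(dmin = dmin, dmax = dmax, prob = p)
  }

  structure(list(element_type = element_type,
                 subgroup_id = as.integer(subgroup_id),
                 motif_states = motif_states,
                 transition = transition,
                 gap_dists = gap_dists,
                 score_threshold = -Inf),
            class = "dgr_ghmm")
}

#' Extract the most conserved fixed-width window from an alignment
#'
#' Helper for users whose training data is a full-length alignment rather
#' than trimmed motifs: slides a window over the alignment columns and
#' keeps the one maximizing total information content (2 - column
#' entropy, in bits).
#'
#' @param aligned Character vector of equal-length aligned sequences
#'   (gaps `-` allowed; gap-containing columns score 0).
#' @param width Window width.
#' @return List with `start` (0-based column offset) and `segments`
#'   (the window's rows, for [build_pwm()]).
#' @export
extract_conserved_window <- function(aligned, width) {
  chars <- do.call(rbind, strsplit(aligned, ""))
  L <- ncol(chars)
  if (L < width) stop("alignment shorter than window")
  ic <- vapply(seq_len(L), function(j) {
    col <- chars[, j]
    if (any(col == "-" | col == "N")) return(0)
    p <- as.numeric(table(factor(col, levels = BASES))) / length(col)
    p <- p[p > 0]
    2 + sum(p * log2(p))
  }, numeric(1))
  tot <- vapply(seq_len(L - width + 1L),
                function(s) sum(ic[s:(s + width - 1L)]), numeric(1))
  s <- which.max(tot)
  list(start = s - 1L,
       segments = apply(chars[, s:(s + width - 1L), drop = FALSE], 1L,
                        paste, collapse = ""))
}

#' Write GHMM submodels to a JSON file
#'
#' @param models List of `dgr_ghmm` objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_models <- function(models, path) {
  ser <- lapply(models, function(m) {
    list(element_type = m$element_type,
         subgroup_id = m$subgroup_id,
         pwms = lapply(m$motif_states, function(p)
           list(width = p$width, probs = unname(p$probs),
                background = unname(p$background),
                pseudocount = p$pseudocount)),
         transition = unname(m$transition),
         gap_dists = lapply(m$gap_dists, function(g)
           if (is.null(g)) NULL else
             list(dmin = g$dmin, dmax = g$dmax, prob = g$prob)),
         score_threshold = m$score_threshold)
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read GHMM submodels from a JSON file written by [write_models()]
#'
#' @param path JSON model file.
#' @return List of `dgr_ghmm` objects.
#' @export
read_models <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = TRUE)
  lapply(raw, function(m) {
    pwms <- lapply(m$pwms, function(p) {
      probs <- matrix(unlist(p$probs), nrow = p$width, byrow = FALSE)
      if (is.matrix(p$probs)) probs <- p$probs
      colnames(probs) <- BASES
      structure(list(width = as.integer(p$width), probs = probs,
                     background = stats::setNames(as.numeric(p$background),
                                                  BASES),
                     pseudocount = p$pseudocount),
                class = "dgr_pwm")
    })
    K <- length(pwms)
    trans <- m$transition
    if (!is.matrix(trans)) trans <- do.call(rbind, m$transition)
    dimnames(trans) <- list(c("begin", paste0("M", seq_len(K)), "end"),
                            c("begin", paste0("M", seq_len(K)), "end"))
    gaps <- lapply(m$gap_dists, function(g) {
      if (is.null(g)) return(NULL)
      list(dmin = as.integer(g$dmin), dmax = as.integer(g$dmax),
           prob = as.numeric(g$prob))
    })
    if (length(gaps) < K * K) gaps <- c(gaps, vector("list", K * K - length(gaps)))
    structure(list(element_type = m$element_type,
                   subgroup_id = as.integer(m$subgroup_id),
                   motif_states = pwms, transition = trans,
                   gap_dists = gaps,
                   score_threshold = as.numeric(m$score_threshold)),
              class = "dgr_ghmm")
  })
}
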