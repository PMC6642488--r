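# Independent oracles and small generators shared across test files.

# Brute-force duration-explicit Viterbi: enumerate every ordered subset
# of motif states and every feasible offset tuple; accumulate the score
# in the same left-to-right order as the decoder so ties are exact.
brute_force_viterbi <- function(model, seq) {
  K <- length(model$motif_states)
  widths <- vapply(model$motif_states, function(p) p$width, integer(1))
  L <- nchar(seq)
  lt <- suppressWarnings(log(model$transition))
  lt[model$transition <= 0] <- -Inf
  emit <- function(k, o) { # o is 0-based
    pwm_log_odds(model$motif_states[[k]],
                 substr(seq, o + 1L, o + widths[k]))
  }
  gap_lp <- function(k1, k2, d) {
    g <- model$gap_dists[[(k1 - 1L) * K + k2]]
    if (is.null(g)) return(-Inf)
    if (d < g$dmin || d > g$dmax) return(-Inf)
    log(g$prob[d - g$dmin + 1L])
  }
  # per-state emission lookup over every offset
  emits <- lapply(seq_len(K), function(k) {
    if (L < widths[k]) return(numeric(0))
    vapply(0:(L - widths[k]), function(o) emit(k, o), numeric(1))
  })
  best <- list(score = -Inf, states = integer(0), offsets = integer(0),
               start = NA_integer_, end = NA_integer_)
  subsets <- list()
  for (k in 1:K) subsets <- c(subsets, utils::combn(K, k, simplify = FALSE))
  for (st in subsets) {
    n <- length(st)
    offs <- lapply(st, function(k) {
      if (L < widths[k]) integer(0) else 0:(L - widths[k])
    })
    if (any(lengths(offs) == 0L)) next
    grid <- as.matrix(expand.grid(offs, KEEP.OUT.ATTRS = FALSE))
    v <- rep(lt[1L, st[1L] + 1L], nrow(grid)) +
      emits[[st[1L]]][grid[, 1L] + 1L]
    if (n > 1L) for (i in 2:n) {
      d <- grid[, i] - (grid[, i - 1L] + widths[st[i - 1L]])
      g <- vapply(d, function(dd) gap_lp(st[i - 1L], st[i], dd),
                  numeric(1))
      v <- v + lt[st[i - 1L] + 1L, st[i] + 1L] + g +
        emits[[st[i]]][grid[, i] + 1L]
    }
    v <- v + lt[st[n] + 1L, K + 2L]
    keep <- is.finite(v)
    if (!any(keep)) next
    vmax <- max(v[keep])
    if (vmax < best$score) next
    idx <- which(keep & v >= vmax - 1e-9)
    starts <- grid[idx, 1L]
    ends <- grid[idx, n] + widths[st[n]]
    pick <- idx[order(starts, ends)][1L]
    cand_start <- grid[pick, 1L]
    cand_end <- grid[pick, n] + widths[st[n]]
    better <- vmax > best$score + 1e-9 ||
      (abs(vmax - best$score) <= 1e-9 &&
         (cand_start < best$start ||
            (cand_start == best$start && cand_end < best$end)))
    if (better) {
      best <- list(score = vmax, states = st,
                   offsets = as.integer(grid[pick, ]),
                   start = cand_start, end = cand_end)
    }
  }
  best
}

# random GHMM instance for property tests (small, decodable by brute force)
random_small_ghmm <- function(K = NULL) {
  if (is.null(K)) K <- sample(1:3, 1L)
  widths <- sample(3:5, K, replace = TRUE)
  pwms <- lapply(seq_len(K), function(k) {
    p <- matrix(stats::runif(widths[k] * 4, 0.05, 1), ncol = 4)
    p <- p / rowSums(p)
    colnames(p) <- c("A", "C", "G", "T")
    structure(list(width = widths[k], probs = p,
                   background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                   pseudocount = 0.5),
              class = "dgr_pwm")
  })
  nm <- c("begin", paste0("M", seq_len(K)), "end")
  trans <- matrix(0, K + 2L, K + 2L, dimnames = list(nm, nm))
  for (i in seq_len(K + 1L)) {
    succ <- if (i == 1L) 2:(K + 2L) else if (i <= K) (i + 1L):(K + 2L)
            else K + 2L
    w <- stats::runif(length(succ), 0.1, 1)
    trans[i, succ] <- w / sum(w)
  }
  gaps <- vector("list", K * K)
  if (K > 1L) {
    for (i in 1:(K - 1L)) for (j in (i + 1L):K) {
      dmin <- sample(0:3, 1L)
      len <- sample(1:4, 1L)
      p <- stats::runif(len, 0.1, 1)
      gaps[[(i - 1L) * K + j]] <-
        list(dmin = dmin, dmax = dmin + len - 1L, prob = p / sum(p))
    }
  }
  structure(list(element_type = "TR", subgroup_id = 1L,
                 motif_states = pwms, transition = trans,
                 gap_dists = gaps, score_threshold = -Inf),
            class = "dgr_ghmm")
}

random_dna <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# run-length longest identical ungapped stretch, computed independently
ccs_oracle <- function(tr_aln, vr_aln) {
  a <- strsplit(tr_aln, "")[[1L]]
  b <- strsplit(vr_aln, "")[[1L]]
  best <- 0L
  run <- 0L
  for (i in seq_along(a)) {
    if (a[i] != "-" && b[i] != "-" && a[i] == b[i]) {
      run <- run + 1L
      if (run > best) best <- run
    } else {
      run <- 0L
    }
  }
  best
}

# a realistic template-repeat sequence (120 bp, family-1 motifs, no noise)
sim_tr_fixture <- function() {
  dgrfinder:::sim_tr_instance(dgr_default_motifs()$TR[[1]],
                              divergence = 0)$seq
}

# shared trained models for pipeline-level tests (trained once per run)
trained_models <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- train_models(
        simulate_training_set("TR", n = 60, seed = 1),
        simulate_training_set("RT", n = 60, seed = 2),
        calibrate = TRUE, n_neg = 200, seed = 99)
    }
    cache
  }
})
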