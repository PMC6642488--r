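test_that("build_pwm applies Laplace smoothing per column", {
  pwm <- build_pwm(c("AAC", "AAC", "ATC"), pseudocount = 1,
                   background = rep(0.25, 4))
  expect_equal(unname(pwm$probs[1, "A"]), 4 / 7)
  expect_equal(unname(pwm$probs[2, "A"]), 3 / 7)
  expect_equal(unname(pwm$probs[2, "T"]), 2 / 7)
  expect_equal(unname(pwm$probs[3, "C"]), 4 / 7)
  expect_true(all(abs(rowSums(pwm$probs) - 1) < 1e-9))
  expect_true(all(pwm$probs > 0))

  near <- build_pwm(rep("ACGT", 5), pseudocount = 0.01,
                    background = rep(0.25, 4))
  expect_equal(unname(near$probs[1, "A"]), 5.01 / 5.04)

  expect_error(build_pwm(c("AA", "AAA")), "equal length")
  expect_error(build_pwm(character(0)), "at least 2")
  expect_error(build_pwm(c("AC", "AC"), pseudocount = 0), "pseudocount")
})

test_that("build_pwm is permutation-invariant", {
  set.seed(2)
  segs <- vapply(1:8, function(i) random_dna(10), character(1))
  p1 <- build_pwm(segs)
  p2 <- build_pwm(sample(segs))
  expect_equal(p1$probs, p2$probs)
})

test_that("pwm_log_odds is a sum of table lookups; uniform PWM scores 0", {
  uni <- structure(list(width = 4L,
                        probs = matrix(0.25, 4, 4,
                                       dimnames = list(NULL, c("A","C","G","T"))),
                        background = c(A = .25, C = .25, G = .25, T = .25),
                        pseudocount = 0.5), class = "dgr_pwm")
  expect_equal(pwm_log_odds(uni, "ACGT"), 0)
  expect_equal(pwm_log_odds(uni, "TTTT"), 0)

  pwm <- build_pwm(c("ACG", "ACG", "ATG"), pseudocount = 0.5,
                   background = c(0.3, 0.2, 0.2, 0.3))
  w <- "ATG"
  manual <- log(unname(pwm$probs[1, "A"]) / 0.3) +
    log(unname(pwm$probs[2, "T"]) / 0.3) +
    log(unname(pwm$probs[3, "G"]) / 0.2)
  expect_equal(pwm_log_odds(pwm, w), manual)
  expect_equal(pwm_log_odds(pwm, "ANG"),
               log(unname(pwm$probs[1, "A"]) / 0.3) +
                 log(unname(pwm$probs[3, "G"]) / 0.2))
  expect_error(pwm_log_odds(pwm, "ACGT"), "width")
})

test_that("partition_training_set separates obvious groups deterministically", {
  set.seed(4)
  x <- random_dna(60)
  y <- random_dna(60)
  grp <- partition_training_set(c(x, x, y, y), k = 2)
  expect_equal(grp, c(1L, 1L, 2L, 2L))
  expect_equal(partition_training_set(c(x, y), k = 1), c(1L, 1L))
  expect_error(partition_training_set(c(x, y), k = 3), "fewer")
})

test_that("partition_training_set recovers mutation families", {
  set.seed(9)
  anc <- vapply(1:3, function(i) random_dna(80), character(1))
  mut <- function(s, rate) {
    ch <- strsplit(s, "")[[1]]
    hit <- which(runif(length(ch)) < rate)
    for (i in hit) ch[i] <- sample(setdiff(c("A","C","G","T"), ch[i]), 1)
    paste(ch, collapse = "")
  }
  segs <- unlist(lapply(1:3, function(f)
    vapply(1:3, function(i) mut(anc[f], 0.05), character(1))))
  fam <- rep(1:3, each = 3)
  grp <- partition_training_set(segs, k = 3)
  # groups must coincide with families up to relabeling
  expect_equal(length(unique(grp)), 3L)
  for (f in 1:3) expect_equal(length(unique(grp[fam == f])), 1L)
})

test_that("estimate_ghmm_params matches ML counts with smoothing", {
  pwm <- build_pwm(c("ACGT", "ACGT"), background = rep(0.25, 4))
  two <- list(pwm, pwm)
  # all examples: M1 -> M2 at distance 5
  exs <- lapply(1:6, function(i)
    list(states = c(1L, 2L), starts = c(0L, 9L), ends = c(4L, 13L)))
  m <- estimate_ghmm_params(exs, two, support_pad = 0L)
  expect_equal(m$transition["M1", "M2"], 1)
  expect_equal(m$transition["begin", "M1"], 1)
  g <- m$gap_dists[[2]] # (1 -> 2) at index (1-1)*2 + 2
  expect_equal(g$dmin, 5L)
  expect_equal(g$dmax, 5L)
  expect_equal(g$prob, 1)

  # 50/50 between M1 -> M2 and M1 -> end
  exs2 <- c(lapply(1:5, function(i)
    list(states = c(1L, 2L), starts = c(0L, 6L), ends = c(4L, 10L))),
    lapply(1:5, function(i)
      list(states = 1L, starts = 0L, ends = 4L)))
  m2 <- estimate_ghmm_params(exs2, two)
  expect_equal(m2$transition["M1", "M2"], (5 + 1) / (10 + 2))
  expect_equal(m2$transition["M1", "end"], (5 + 1) / (10 + 2))
  expect_true(all(abs(rowSums(m2$transition)[1:3] - 1) < 1e-9))

  # adjacent motifs: d = 0 is in support
  exs3 <- lapply(1:3, function(i)
    list(states = c(1L, 2L), starts = c(0L, 4L), ends = c(4L, 8L)))
  m3 <- estimate_ghmm_params(exs3, two, support_pad = 2L)
  expect_equal(m3$gap_dists[[2]]$dmin, 0L)

  expect_error(estimate_ghmm_params(list(
    list(states = c(2L, 1L), starts = c(0L, 9L), ends = c(4L, 13L))),
    two), "increasing")
  expect_error(estimate_ghmm_params(list(
    list(states = c(1L, 2L), starts = c(9L, 0L), ends = c(13L, 4L))),
    two), "order|increasing|bounds")
})

test_that("ML estimates converge on synthetic training data", {
  set.seed(21)
  pwm <- build_pwm(c("ACGT", "ACGT"), background = rep(0.25, 4))
  two <- list(pwm, pwm)
  # generator: always M1 -> M2, spacer uniform on {4,5,6}
  exs <- lapply(1:2000, function(i) {
    d <- sample(4:6, 1)
    list(states = c(1L, 2L), starts = c(0L, 4L + d), ends = c(4L, 8L + d))
  })
  m <- estimate_ghmm_params(exs, two, support_pad = 0L)
  expect_equal(m$transition["M1", "M2"], 1)
  g <- m$gap_dists[[2]]
  expect_equal(g$dmin, 4L)
  expect_true(all(abs(g$prob - 1 / 3) < 0.05))
})

test_that("gap distributions and transition rows are normalized after training", {
  models <- trained_models()
  expect_length(models, 6L)
  for (m in models) {
    K <- length(m$motif_states)
    expect_true(all(abs(rowSums(m$transition)[1:(K + 1)] - 1) < 1e-9))
    for (g in m$gap_dists) {
      if (!is.null(g)) expect_equal(sum(g$prob), 1, tolerance = 1e-9)
    }
    for (p in m$motif_states) {
      expect_true(all(abs(rowSums(p$probs) - 1) < 1e-9))
    }
  }
})

test_that("model JSON round-trip preserves every parameter", {
  models <- trained_models()
  f <- withr::local_tempfile(fileext = ".json")
  write_models(models, f)
  back <- read_models(f)
  expect_length(back, length(models))
  for (i in seq_along(models)) {
    expect_equal(back[[i]]$element_type, models[[i]]$element_type)
    expect_equal(unname(back[[i]]$transition),
                 unname(models[[i]]$transition))
    expect_equal(back[[i]]$score_threshold, models[[i]]$score_threshold)
    for (k in seq_along(models[[i]]$motif_states)) {
      expect_equal(unname(back[[i]]$motif_states[[k]]$probs),
                   unname(models[[i]]$motif_states[[k]]$probs))
    }
    for (k in seq_along(models[[i]]$gap_dists)) {
      expect_equal(back[[i]]$gap_dists[[k]]$prob,
                   models[[i]]$gap_dists[[k]]$prob)
    }
  }
})

test_that("extract_conserved_window finds the conserved block", {
  set.seed(31)
  core <- "GGTCCGTTCG"
  segs <- vapply(1:6, function(i)
    paste0(random_dna(7), core, random_dna(5)), character(1))
  w <- extract_conserved_window(segs, 10L)
  expect_equal(w$start, 7L)
  expect_true(all(w$segments == core))
})
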