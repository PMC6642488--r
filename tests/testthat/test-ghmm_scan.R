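# near-deterministic 2-state toy model with a fixed spacer distribution
toy_model <- function(m1 = "GGTCCA", m2 = "TTCGAC", dmin = 4L, dmax = 6L,
                      threshold = -Inf) {
  pwms <- list(build_pwm(rep(m1, 20), pseudocount = 0.01),
               build_pwm(rep(m2, 20), pseudocount = 0.01))
  nm <- c("begin", "M1", "M2", "end")
  trans <- matrix(0, 4, 4, dimnames = list(nm, nm))
  trans["begin", "M1"] <- 1
  trans["M1", "M2"] <- 1
  trans["M2", "end"] <- 1
  gaps <- vector("list", 4)
  n <- dmax - dmin + 1L
  gaps[[2]] <- list(dmin = dmin, dmax = dmax, prob = rep(1 / n, n))
  structure(list(element_type = "TR", subgroup_id = 1L,
                 motif_states = pwms, transition = trans,
                 gap_dists = gaps, score_threshold = threshold),
            class = "dgr_ghmm")
}

test_that("viterbi_decode recovers planted motif placements", {
  set.seed(10)
  m <- toy_model()
  gap <- random_dna(5)
  seq <- paste0(random_dna(30), "GGTCCA", gap, "TTCGAC", random_dna(25))
  dec <- viterbi_decode(m, seq)
  expect_equal(dec$states, c(1L, 2L))
  expect_equal(dec$offsets, c(30L, 30L + 6L + 5L))
  expect_gt(dec$score, 10)
})

test_that("viterbi_decode equals exhaustive enumeration (property)", {
  set.seed(123)
  for (i in 1:50) {
    m <- random_small_ghmm()
    s <- random_dna(sample(10:30, 1))
    dec <- viterbi_decode(m, s)
    bf <- brute_force_viterbi(m, s)
    expect_equal(dec$score, bf$score, tolerance = 1e-9)
    expect_identical(as.integer(dec$states), as.integer(bf$states))
    expect_identical(as.integer(dec$offsets), as.integer(bf$offsets))
  }
})

test_that("degenerate uniform model ties break leftmost", {
  uni <- structure(list(width = 4L,
                        probs = matrix(0.25, 4, 4,
                                       dimnames = list(NULL, c("A","C","G","T"))),
                        background = c(A = .25, C = .25, G = .25, T = .25),
                        pseudocount = .5), class = "dgr_pwm")
  nm <- c("begin", "M1", "end")
  trans <- matrix(0, 3, 3, dimnames = list(nm, nm))
  trans["begin", "M1"] <- 1
  trans["M1", "end"] <- 1
  m <- structure(list(element_type = "TR", subgroup_id = 1L,
                      motif_states = list(uni), transition = trans,
                      gap_dists = vector("list", 1),
                      score_threshold = -Inf), class = "dgr_ghmm")
  dec <- viterbi_decode(m, "ACGTACGTACGT")
  expect_equal(dec$offsets, 0L) # every placement scores 0; leftmost wins
  expect_equal(dec$score, 0)
})

test_that("no-hit decoding yields -Inf, short contigs scan to empty", {
  m <- toy_model()
  dec <- viterbi_decode(m, "ACG")
  expect_identical(dec$score, -Inf)
  expect_length(dec$states, 0)
  hits <- scan_elements(list(m), "ACG", "tiny")
  expect_equal(nrow(hits), 0L)
})

test_that("scan_elements finds planted elements on both strands", {
  set.seed(14)
  m <- toy_model(threshold = 8)
  inst <- paste0("GGTCCA", random_dna(5), "TTCGAC")
  contig <- paste0(random_dna(300), inst, random_dna(300),
                   reverse_complement(inst), random_dna(300))
  hits <- scan_elements(list(m), contig, "c")
  expect_equal(nrow(hits), 2L)
  expect_setequal(hits$strand, c("+", "-"))
  fwd <- hits[hits$strand == "+", ]
  expect_equal(fwd$start, 300L)
  expect_equal(fwd$end, 300L + nchar(inst))
  rev <- hits[hits$strand == "-", ]
  expect_equal(rev$start, 300L + nchar(inst) + 300L)
  expect_equal(rev$end, rev$start + nchar(inst))
})

test_that("scanning the reverse complement mirrors hits (strand symmetry)", {
  set.seed(15)
  m <- toy_model(threshold = 8)
  inst <- paste0("GGTCCA", random_dna(4), "TTCGAC")
  contig <- paste0(random_dna(200), inst, random_dna(150))
  L <- nchar(contig)
  h1 <- scan_elements(list(m), contig, "c")
  h2 <- scan_elements(list(m), reverse_complement(contig), "c")
  expect_equal(nrow(h1), nrow(h2))
  expect_equal(sort(L - h1$end), sort(h2$start))
  expect_equal(sort(L - h1$start), sort(h2$end))
  expect_setequal(paste(h1$strand), c("+"))
  expect_setequal(paste(h2$strand), c("-"))
})

test_that("raising the threshold never adds hits (monotonicity)", {
  set.seed(16)
  m <- toy_model()
  contig <- paste0(random_dna(400), "GGTCCA", random_dna(5), "TTCGAC",
                   random_dna(400))
  lo <- scan_elements(list(m), contig, "c", min_score = -5)
  hi <- scan_elements(list(m), contig, "c", min_score = 5)
  expect_lte(nrow(hi), nrow(lo))
  key <- function(h) paste(h$start, h$end, h$strand)
  expect_true(all(key(hi) %in% key(lo)))
})

test_that("overlapping same-type hits resolve to the higher score", {
  set.seed(17)
  good <- toy_model(threshold = -Inf)
  # same consensus but blurrier PWMs -> strictly lower score at the locus
  worse <- toy_model(threshold = -Inf)
  worse$subgroup_id <- 2L
  for (k in 1:2) {
    p <- worse$motif_states[[k]]$probs
    worse$motif_states[[k]]$probs <- 0.9 * p + 0.1 * 0.25
  }
  contig <- paste0(random_dna(250), "GGTCCA", random_dna(5), "TTCGAC",
                   random_dna(250))
  hits <- scan_elements(list(good, worse), contig, "c", min_score = 8)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$subgroup_id, 1L)
})

test_that("calibrated thresholds keep the negative-set rate in check", {
  models <- trained_models()
  for (m in models) expect_true(is.finite(m$score_threshold))
  negs <- generate_negative_set(300, 2000, seed = 4242)
  n_hits <- 0
  for (s in negs) {
    h <- scan_elements(models, s)
    n_hits <- n_hits + nrow(h)
  }
  # 6 models calibrated at 0.1% per 2 kb on an independent draw;
  # allow generous sampling slack
  expect_lt(n_hits / 300, 0.25)
})
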