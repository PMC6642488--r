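mk_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(contig_id = r[[1]], element_type = r[[2]],
               subgroup_id = 1L, start = as.integer(r[[3]]),
               end = as.integer(r[[4]]), strand = r[[5]],
               score = as.numeric(r[[6]]), stringsAsFactors = FALSE)))
}

mk_pair <- function(contig, tr_s, tr_e, vr_s, vr_e, strand = "+") {
  data.frame(contig_id = contig, tr_start = as.integer(tr_s),
             tr_end = as.integer(tr_e), tr_strand = "+",
             vr_start = as.integer(vr_s), vr_end = as.integer(vr_e),
             vr_strand = strand, score = 100, length = 120L,
             identity = 0.9, a_to_n = 12L, non_a_to_n = 1L,
             n_subs = 13L, longest_ccs = 20L,
             tr_aln = strrep("A", 10), vr_aln = strrep("A", 10),
             stringsAsFactors = FALSE)
}

test_that("assemble_dgrs assigns intact/partial status and windows loci", {
  hits <- mk_hits(list("c", "TR", 1000, 1120, "+", 30),
                  list("c", "RT", 4000, 4400, "+", 50))
  pair <- mk_pair("c", 1000, 1120, 2000, 2120)

  recs <- assemble_dgrs(hits, pair)
  expect_length(recs, 1L)
  expect_equal(recs[[1]]$status, "intact")

  recs2 <- assemble_dgrs(hits, dgrfinder:::empty_pairs())
  expect_length(recs2, 1L)
  expect_equal(recs2[[1]]$status, "partial")

  # TR and RT 100 kb apart: two loci, both incomplete, both dropped
  far <- mk_hits(list("c", "TR", 1000, 1120, "+", 30),
                 list("c", "RT", 101000, 101400, "+", 50))
  expect_length(assemble_dgrs(far, dgrfinder:::empty_pairs()), 0L)

  # locus missing an RT is dropped even with VRs
  tronly <- mk_hits(list("c", "TR", 1000, 1120, "+", 30))
  expect_length(assemble_dgrs(tronly, pair), 0L)
})

test_that("intact records retain only filtered VRs; partial have none", {
  hits <- mk_hits(list("c", "TR", 1000, 1120, "+", 30),
                  list("c", "RT", 3000, 3400, "+", 50))
  pair <- mk_pair("c", 1000, 1120, 1500, 1620)
  recs <- assemble_dgrs(hits, pair)
  for (r in recs) {
    if (r$status == "intact") {
      expect_gt(nrow(r$vrs), 0)
      expect_true(all(vapply(seq_len(nrow(r$pairs)), function(i)
        filter_vr(r$pairs[i, ]), logical(1))))
    } else {
      expect_equal(nrow(r$vrs), 0L)
    }
  }
})

test_that("cassette_signature canonicalizes and encodes multiplicity", {
  rec <- function(vr_starts, vr_strands, tr, rt, tr_strand, rt_strand) {
    list(trs = data.frame(start = tr, strand = tr_strand, score = 1),
         vrs = if (length(vr_starts))
           data.frame(start = vr_starts, strand = vr_strands)
         else data.frame(start = integer(0), strand = character(0)),
         rts = data.frame(start = rt, strand = rt_strand, score = 2))
  }
  # BPP-1-like layout
  g1 <- rec(100, "+", 400, 800, "+", "+")
  expect_equal(cassette_signature(g1)$signature, "VR>,TR>,RT>")
  # same locus on the complementary strand: mirrored order, flipped strands
  g1_flip <- rec(900, "-", 600, 100, "-", "-")
  expect_equal(cassette_signature(g1_flip)$signature, "VR>,TR>,RT>")
  # multiplicity distinguishes multi-VR cassettes
  g2 <- rec(c(100, 250), c("+", "+"), 400, 800, "+", "+")
  expect_equal(cassette_signature(g2)$signature, "VR>x2,TR>,RT>")
  expect_false(cassette_signature(g2)$signature ==
                 cassette_signature(g1)$signature)
  # inverted RT flips the whole locus reading
  g5 <- rec(100, "+", 400, 800, "+", "-")
  expect_equal(cassette_signature(g5)$signature, "RT>,TR<,VR<")
})

test_that("global strand flip never changes a signature (property)", {
  set.seed(55)
  for (i in 1:50) {
    n_el <- sample(3:6, 1)
    kinds <- c("TR", "RT", sample(c("TR", "VR", "RT"), n_el - 2, TRUE))
    starts <- sort(sample(seq(0, 20000, by = 10), n_el))
    strands <- sample(c("+", "-"), n_el, TRUE)
    mkdf <- function(k) {
      sel <- kinds == k
      data.frame(start = starts[sel], strand = strands[sel],
                 score = seq_len(sum(sel)))
    }
    rec <- list(trs = mkdf("TR"), vrs = mkdf("VR"), rts = mkdf("RT"))
    L <- 30000L
    flip <- function(df) {
      if (nrow(df) == 0) return(df)
      data.frame(start = L - (df$start + 10L),
                 strand = ifelse(df$strand == "+", "-", "+"),
                 score = df$score)
    }
    rec2 <- list(trs = flip(rec$trs), vrs = flip(rec$vrs),
                 rts = flip(rec$rts))
    expect_equal(cassette_signature(rec)$signature,
                 cassette_signature(rec2)$signature)
  }
})

test_that("cluster_rts groups by global identity like cd-hit", {
  set.seed(56)
  x <- random_dna(300)
  expect_equal(cluster_rts(c(x, x))$cluster, c(1L, 1L))

  # two sequences at ~80% identity split at threshold 0.90
  ch <- strsplit(x, "")[[1]]
  pos <- sample(300, 60)
  for (i in pos) ch[i] <- sample(setdiff(c("A","C","G","T"), ch[i]), 1)
  y <- paste(ch, collapse = "")
  cl <- cluster_rts(c(x, y), threshold = 0.90)
  expect_equal(length(cl$representative), 2L)

  # 10 light mutants of one RT form one cluster led by the longest
  base <- random_dna(240)
  fam <- vapply(1:10, function(i) {
    ch <- strsplit(base, "")[[1]]
    pos <- sample(240, sample(3:10, 1))
    for (j in pos) ch[j] <- sample(setdiff(c("A","C","G","T"), ch[j]), 1)
    paste(ch, collapse = "")
  }, character(1))
  fam[4] <- paste0(fam[4], "ACGTAC") # make one the longest
  cl2 <- cluster_rts(fam, threshold = 0.90)
  expect_equal(length(cl2$representative), 1L)
  expect_equal(cl2$representative, 4L)
  expect_true(all(cl2$cluster == 1L))

  expect_equal(cluster_rts(character(0))$cluster, integer(0))
})

test_that("cluster count is monotone in the identity threshold", {
  set.seed(57)
  seqs <- vapply(1:12, function(i) random_dna(150), character(1))
  seqs <- c(seqs, vapply(1:6, function(i) {
    ch <- strsplit(seqs[i], "")[[1]]
    pos <- sample(150, 10)
    for (j in pos) ch[j] <- sample(setdiff(c("A","C","G","T"), ch[j]), 1)
    paste(ch, collapse = "")
  }, character(1)))
  thresholds <- c(0.5, 0.7, 0.9, 0.99)
  counts <- vapply(thresholds, function(t)
    length(cluster_rts(seqs, t)$representative), integer(1))
  expect_true(all(diff(counts) >= 0))
})
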