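# mutate chosen positions of a sequence to a fixed different base
sub_at <- function(seq, pos, to = "G") {
  ch <- strsplit(seq, "")[[1]]
  ch[pos] <- ifelse(ch[pos] == to, "C", to)
  paste(ch, collapse = "")
}

test_that("adenine_aware_align worked examples", {
  al <- adenine_aware_align("AACAAC", "AACAAC")
  expect_equal(al$score, 12)
  expect_equal(al$tr_aln, "AACAAC")

  al <- adenine_aware_align("AAAA", "GGGG")
  expect_equal(al$score, 0)
  expect_equal(nchar(al$tr_aln), 4) # neutral A-columns align end-to-end

  # 3 lookups by hand: match 2 + A-mismatch 0 + match 2
  al <- adenine_aware_align("TAG", "TCG")
  expect_equal(al$score, 4)
})

test_that("collapsing the adenine asymmetry gives a textbook local aligner", {
  set.seed(77)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  for (i in 1:50) {
    a <- random_dna(sample(20:60, 1))
    b <- random_dna(sample(20:60, 1))
    ours <- adenine_aware_align(a, b, mism_a = -3)$score
    ref <- Biostrings::pairwiseAlignment(
      a, b, type = "local", substitutionMatrix = mat,
      gapOpening = 5, gapExtension = 2, scoreOnly = TRUE)
    expect_equal(ours, ref, tolerance = 1e-9)
  }
})

test_that("filter_vr boundary behavior matches the published thresholds", {
  p <- function(len, id, nonA) list(length = len, identity = id,
                                    non_a_to_n = nonA)
  expect_false(filter_vr(p(30, 0.9, 0)))  # not > 30
  expect_false(filter_vr(p(100, 0.60, 0))) # not > 60%
  expect_false(filter_vr(p(100, 0.95, 4))) # not under four
  expect_true(filter_vr(p(31, 0.61, 3)))
})

test_that("longest_ccs follows the run-length definition", {
  p <- function(a, b) list(tr_aln = a, vr_aln = b)
  expect_equal(longest_ccs(p(strrep("A", 50), strrep("A", 50))), 50L)
  a <- strrep("C", 100)
  b <- paste(vapply(1:100, function(i) if (i %% 10 == 0) "T" else "C",
                    character(1)), collapse = "")
  expect_equal(longest_ccs(p(a, b)), 9L)
  a2 <- paste0(strrep("C", 12), "-", strrep("C", 8))
  b2 <- paste0(strrep("C", 12), "C", strrep("C", 8))
  expect_equal(longest_ccs(p(a2, b2)), 12L)
  # random-alignment oracle
  set.seed(8)
  for (i in 1:20) {
    a <- random_dna(60)
    b <- sub_at(a, sample(60, 6))
    expect_equal(longest_ccs(p(a, b)), ccs_oracle(a, b))
  }
})

test_that("find_vrs locates a planted VR with correct statistics", {
  set.seed(19)
  tr_seq <- sim_tr_fixture()
  apos <- which(strsplit(tr_seq, "")[[1]] == "A")
  vr <- sub_at(tr_seq, apos[seq(2, 24, 2)], to = "G") # 12 A->G
  contig <- c(ctg = paste0(random_dna(500), tr_seq, random_dna(700), vr,
                           random_dna(500)))
  tr <- data.frame(contig_id = "ctg", start = 500L,
                   end = 500L + nchar(tr_seq), strand = "+",
                   stringsAsFactors = FALSE)
  pairs <- find_vrs(tr, contig)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$a_to_n, 12L)
  expect_equal(pairs$non_a_to_n, 0L)
  expect_equal(pairs$vr_strand, "+")
  expect_equal(pairs$vr_start, 500L + nchar(tr_seq) + 700L)
  expect_equal(pairs$identity, 1 - 12 / nchar(tr_seq))
  # counting oracle: re-derive the stats column by column
  a <- strsplit(pairs$tr_aln, "")[[1]]
  b <- strsplit(pairs$vr_aln, "")[[1]]
  gap <- a == "-" | b == "-"
  expect_equal(pairs$a_to_n, sum(!gap & a == "A" & a != b))
  expect_equal(pairs$non_a_to_n, sum(!gap & a != "A" & a != b & a != "-"))
  expect_equal(pairs$identity, sum(!gap & a == b) / length(a))
  expect_equal(pairs$a_to_n + pairs$non_a_to_n + sum(gap) +
                 sum(!gap & a == b), pairs$length)
})

test_that("reverse-strand VRs are found with identical statistics", {
  set.seed(20)
  tr_seq <- sim_tr_fixture()
  apos <- which(strsplit(tr_seq, "")[[1]] == "A")
  vr <- sub_at(tr_seq, apos[seq(1, 19, 2)], to = "T")
  contig <- c(ctg = paste0(random_dna(400), tr_seq, random_dna(600),
                           reverse_complement(vr), random_dna(400)))
  tr <- data.frame(contig_id = "ctg", start = 400L,
                   end = 400L + nchar(tr_seq), strand = "+",
                   stringsAsFactors = FALSE)
  pairs <- find_vrs(tr, contig)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$vr_strand, "-")
  expect_equal(pairs$a_to_n, 10L)
  expect_equal(pairs$vr_start, 400L + nchar(tr_seq) + 600L)
})

test_that("self-hits are excluded, perfect copies retained", {
  set.seed(22)
  tr_seq <- sim_tr_fixture()
  contig <- c(ctg = paste0(random_dna(300), tr_seq, random_dna(500),
                           tr_seq, random_dna(300)))
  tr <- data.frame(contig_id = "ctg", start = 300L,
                   end = 300L + nchar(tr_seq), strand = "+",
                   stringsAsFactors = FALSE)
  pairs <- find_vrs(tr, contig)
  expect_equal(nrow(pairs), 1L) # the self-hit is dropped
  expect_equal(pairs$vr_start, 300L + nchar(tr_seq) + 500L)
  expect_equal(pairs$n_subs, 0L)
  expect_equal(pairs$identity, 1)
})

test_that("planted VRs are recovered reliably (200 replicates)", {
  set.seed(23)
  found <- 0L
  for (i in 1:200) {
    tr_seq <- sim_tr_fixture()
    apos <- which(strsplit(tr_seq, "")[[1]] == "A")
    nsub <- min(length(apos), sample(8:20, 1))
    vr <- sub_at(tr_seq, sample(apos, nsub), to = "G")
    off <- sample(200:1500, 1)
    contig <- c(ctg = paste0(random_dna(200), tr_seq, random_dna(off), vr,
                             random_dna(200)))
    tr <- data.frame(contig_id = "ctg", start = 200L,
                     end = 200L + nchar(tr_seq), strand = "+",
                     stringsAsFactors = FALSE)
    pairs <- find_vrs(tr, contig)
    vs <- 200L + nchar(tr_seq) + off
    if (nrow(pairs) > 0 &&
        any(pmin(pairs$vr_end, vs + nchar(vr)) - pmax(pairs$vr_start, vs) >=
              0.8 * nchar(vr))) found <- found + 1L
  }
  expect_gte(found / 200, 0.95)
})

test_that("merge_vrs unions overlapping same-strand intervals", {
  mk <- function(s, e, strand) {
    data.frame(contig_id = "c", vr_start = as.integer(s),
               vr_end = as.integer(e), vr_strand = strand,
               stringsAsFactors = FALSE)
  }
  pairs <- rbind(mk(10, 50, "+"), mk(40, 90, "+"))
  m <- merge_vrs(pairs)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(10L, 90L))
  expect_equal(m$n_pairs, 2L)

  pairs2 <- rbind(mk(10, 50, "+"), mk(40, 90, "-"))
  m2 <- merge_vrs(pairs2)
  expect_equal(nrow(m2), 2L)

  # 21 staggered overlapping VRs collapse to one span
  many <- do.call(rbind, lapply(0:20, function(i)
    mk(100 + 30 * i, 100 + 30 * i + 120, "+")))
  m3 <- merge_vrs(many)
  expect_equal(nrow(m3), 1L)
  expect_equal(c(m3$start, m3$end), c(100L, 100L + 30L * 20L + 120L))
  expect_equal(m3$n_pairs, 21L)
})
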