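# Seeded evaluation of `expr` that restores the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Reference DGR background base composition
#'
#' The AT-leaning composition used as the package default wherever a
#' background model is needed (PWM log-odds, negative sequence sets,
#' random flanks). Order A, C, G, T.
#'
#' @return Named numeric vector summing to 1.
#' @export
dgr_background <- function() {
  c(A = 0.30, C = 0.20, G = 0.20, T = 0.30)
}

# codons that can never truncate an ORF
safe_codons <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      all <- as.vector(outer(as.vector(outer(BASES, BASES, paste0)),
                             BASES, paste0))
      cache <<- setdiff(all, STOP_CODONS)
    }
    cache
  }
})

# AAC-biased codon filler of `n_codons` codons (the "AAC tandem repeat"
# signal characteristic of template repeats)
aac_filler <- function(n_codons, aac_weight = 0.5) {
  if (n_codons == 0L) return("")
  pick <- ifelse(stats::runif(n_codons) < aac_weight, "AAC",
                 sample(safe_codons(), n_codons, replace = TRUE))
  paste(pick, collapse = "")
}

random_seq <- function(n, background = dgr_background()) {
  if (n == 0L) return("")
  paste(sample(BASES, n, replace = TRUE, prob = background),
        collapse = "")
}

# substitute each position independently with prob `rate`, drawing the
# replacement uniformly from the other three bases
mutate_uniform <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1L]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) {
    ch[i] <- sample(setdiff(BASES, ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

#' Fixed motif set of the synthetic DGR world
#'
#' Three TR motif families (3 motifs of width 12 each, AAC-enriched,
#' stop-free in frame 0 so template repeats can sit inside target ORFs)
#' and three RT motif families (4 motifs of width 18). The set is a
#' deterministic constant: synthetic genomes and training sets are
#' co-generated from it so that fixtures are detectable by the trained
#' models.
#'
#' @return List with elements `TR` and `RT`; each a list of 3 families,
#'   each family a character vector of motif consensus strings.
#' @export
dgr_default_motifs <- function() {
  # anchor codons without adenine (and stop-free): they survive
  # adenine-specific mutagenesis and make motifs informative against an
  # AT-leaning background
  anchors <- setdiff(as.vector(outer(as.vector(outer(
    c("C", "G", "T"), c("C", "G", "T"), paste0)),
    c("C", "G", "T"), paste0)), STOP_CODONS)
  with_seed(20190719L, {
    tr <- lapply(1:3, function(f) {
      vapply(1:3, function(m) {
        cods <- c("AAC", sample(anchors, 3L))
        paste(sample(cods), collapse = "")
      }, character(1))
    })
    rt <- lapply(1:3, function(f) {
      vapply(1:4, function(m)
        paste(sample(safe_codons(), 6L, replace = TRUE), collapse = ""),
        character(1))
    })
    list(TR = tr, RT = rt)
  })
}

# One TR element instance: lead(6) m1 g1 m2 g2 m3 tail(6), g1 + g2 = 72,
# g1 in {30,33,...,42}; total length 120, everything codon-aligned and
# stop-free at divergence 0. Returns seq + motif-state annotation.
sim_tr_instance <- function(motifs, divergence = 0.05) {
  g1 <- sample(seq(30L, 42L, by = 3L), 1L)
  g2 <- 72L - g1
  parts <- c(aac_filler(2L), mutate_uniform(motifs[1L], divergence),
             aac_filler(g1 %/% 3L), mutate_uniform(motifs[2L], divergence),
             aac_filler(g2 %/% 3L), mutate_uniform(motifs[3L], divergence),
             aac_filler(2L))
  lens <- nchar(parts)
  starts <- cumsum(c(0L, lens[-length(lens)]))
  list(seq = paste(parts, collapse = ""), states = 1:3,
       starts = starts[c(2L, 4L, 6L)],
       ends = starts[c(2L, 4L, 6L)] + 12L)
}

# One RT coding-region instance: 4 motifs of 18 nt separated by safe-codon
# spacers of 12..24 nt (multiples of 3).
sim_rt_instance <- function(motifs, divergence = 0.05) {
  sp <- sample(seq(12L, 24L, by = 3L), 3L, replace = TRUE)
  parts <- c(mutate_uniform(motifs[1L], divergence),
             aac_filler(sp[1L] %/% 3L, aac_weight = 0),
             mutate_uniform(motifs[2L], divergence),
             aac_filler(sp[2L] %/% 3L, aac_weight = 0),
             mutate_uniform(motifs[3L], divergence),
             aac_filler(sp[3L] %/% 3L, aac_weight = 0),
             mutate_uniform(motifs[4L], divergence))
  lens <- nchar(parts)
  starts <- cumsum(c(0L, lens[-length(lens)]))
  list(seq = paste(parts, collapse = ""), states = 1:4,
       starts = starts[c(1L, 3L, 5L, 7L)],
       ends = starts[c(1L, 3L, 5L, 7L)] + 18L)
}

#' Generate an annotated training set for one element type
#'
#' Training examples are element instances (motifs mutated at
#' `divergence`) with short random flanks, annotated with per-motif-state
#' coordinates — the synthetic stand-in for repeat/RT fragments extracted
#' from a curated DGR reference.
#'
#' @param element_type `"TR"` or `"RT"`.
#' @param n Number of examples (spread round-robin over the 3 motif
#'   families).
#' @param divergence Per-base substitution rate applied to motif
#'   consensi (default 0.05).
#' @param seed RNG seed.
#' @param motifs Motif set (default [dgr_default_motifs()]).
#' @return List of examples: each `list(seq, states, starts, ends,
#'   family)`.
#' @export
simulate_training_set <- function(element_type = c("TR", "RT"), n = 60L,
                                  divergence = 0.05, seed = 1L,
                                  motifs = dgr_default_motifs()) {
  element_type <- match.arg(element_type)
  fams <- motifs[[element_type]]
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      f <- ((i - 1L) %% length(fams)) + 1L
      inst <- if (element_type == "TR")
        sim_tr_instance(fams[[f]], divergence)
      else sim_rt_instance(fams[[f]], divergence)
      lf <- sample(10:30, 1L)
      rf <- sample(10:30, 1L)
      list(seq = paste0(random_seq(lf), inst$seq, random_seq(rf)),
           states = inst$states, starts = inst$starts + lf,
           ends = inst$ends + lf, family = f)
    })
  })
}

#' Train the six GHMM submodels from annotated training sets
#'
#' Each element type's training set is partitioned into `k` subgroups by
#' [partition_training_set()]; per subgroup, motif-state PWMs are built
#' from the annotated windows, transition and spacer parameters are
#' estimated by maximum likelihood, and the score threshold is
#' calibrated on synthetic negatives. Singleton subgroups are folded
#' into the largest subgroup (a PWM needs at least two segments).
#'
#' @param tr_training,rt_training Annotated example lists (see
#'   [simulate_training_set()] for the layout).
#' @param k Subgroups per element type (default 3).
#' @param pseudocount PWM pseudocount (default 0.5).
#' @param background Base composition for PWMs and calibration.
#' @param calibrate Calibrate thresholds on negatives (default TRUE).
#' @param n_neg Negative sequences per model for calibration.
#' @param seed Seed for calibration negatives.
#' @return List of `dgr_ghmm` submodels (TR then RT subgroups).
#' @export
train_models <- function(tr_training, rt_training, k = 3L,
                         pseudocount = 0.5,
                         background = dgr_background(),
                         calibrate = TRUE, n_neg = 200L, seed = 99L) {
  train_one <- function(training, element_type) {
    segs <- vapply(training, `[[`, character(1), "seq")
    grp <- partition_training_set(segs, k = min(k, length(segs)))
    # fold singletons into the largest group
    sizes <- table(grp)
    if (any(sizes < 2L)) {
      big <- as.integer(names(sizes)[which.max(sizes)])
      grp[grp %in% as.integer(names(sizes)[sizes < 2L])] <- big
      grp <- as.integer(factor(grp, levels = unique(grp)))
    }
    models <- list()
    for (g in sort(unique(grp))) {
      exs <- training[grp == g]
      K <- max(unlist(lapply(exs, `[[`, "states")))
      pwms <- lapply(seq_len(K), function(s) {
        wins <- unlist(lapply(exs, function(e) {
          i <- match(s, e$states)
          if (is.na(i)) return(NULL)
          substr(e$seq, e$starts[i] + 1L, e$ends[i])
        }))
        build_pwm(wins, pseudocount = pseudocount,
                  background = background)
      })
      m <- estimate_ghmm_params(exs, pwms, element_type = element_type,
                                subgroup_id = g)
      models[[length(models) + 1L]] <- m
    }
    models
  }
  models <- c(train_one(tr_training, "TR"), train_one(rt_training, "RT"))
  if (calibrate) {
    models <- lapply(seq_along(models), function(i)
      calibrate_threshold(models[[i]], background = background,
                          n = n_neg, seed = seed + i))
  }
  models
}

# apply the DGR mutation model to a TR copy; returns the VR string and
# the substituted positions
mutate_vr <- function(tr_seq, a_rate, nonA_rate, kernel) {
  ch <- strsplit(tr_seq, "")[[1L]]
  subs <- integer(0)
  for (i in seq_along(ch)) {
    b <- ch[i]
    rate <- if (b == "A") a_rate else nonA_rate
    if (stats::runif(1L) < rate) {
      ch[i] <- sample(BASES, 1L, prob = kernel[b, ])
      subs <- c(subs, i)
    }
  }
  list(seq = paste(ch, collapse = ""), positions = subs)
}

#' Default substitution-direction kernel of the mutation model
#'
#' Rows are the original (TR) base, columns the replacement; the
#' diagonal is zero and each row sums to 1. The adenine row sends half
#' of replaced adenines to guanine; the non-A rows encode the reported
#' qualitative biases (G most likely of the non-A bases to become A,
#' C least likely, T preferring C).
#'
#' @return 4x4 numeric matrix with dimnames A, C, G, T.
#' @export
dgr_direction_kernel <- function() {
  k <- rbind(A = c(0, 0.25, 0.50, 0.25),
             C = c(0.15, 0, 0.425, 0.425),
             G = c(0.50, 0.25, 0, 0.25),
             T = c(0.25, 0.50, 0.25, 0))
  colnames(k) <- BASES
  k
}

#' Generate a genome with one implanted DGR cassette
#'
#' Builds a contig containing a template repeat (AAC-enriched, carrying
#' the TR motif consensi), `n_vrs` variable repeats embedded at the
#' 3' end of generated target ORFs, and an RT ORF carrying the RT motif
#' consensi, laid out per `layout` and separated by random spacers, all
#' inside random background. Each VR is the TR copy rewritten by the
#' adenine-specific mutation model: A positions substituted at
#' `a_mut_rate` (default: calibrated per TR so 15 A-to-N substitutions
#' are expected per VR), other positions at `nonA_mut_rate` (default:
#' calibrated so 1.5 non-A-to-N substitutions are expected per VR, the
#' reported cohort average), with replacement bases drawn from
#' `direction_bias`.
#'
#' @param tr_length TR length (fixed at 120 by the element design).
#' @param n_vrs Number of VR copies (default 1).
#' @param a_mut_rate Per-adenine substitution probability, or NULL to
#'   target 15 expected A-to-N per VR.
#' @param nonA_mut_rate Per-non-A substitution probability, or NULL to
#'   target 1.5 expected non-A-to-N per VR.
#' @param direction_bias 4x4 substitution kernel
#'   (default [dgr_direction_kernel()]).
#' @param layout Character vector of element tokens in genome order:
#'   `"TR"`, `"VR"`, `"RT"` with strand suffix `+`/`-` (e.g.
#'   `c("VR+", "TR+", "RT+")`, the BPP-1-like layout). NULL derives the
#'   BPP-1-like layout from `n_vrs`.
#' @param family Motif family (1-3) used for TR and RT instances.
#' @param divergence Per-base noise on motif instances (default 0.02).
#' @param flank_length Background flank on each side (default 2000).
#' @param total_length If non-NULL, flanks are sized so the contig has
#'   exactly this length (error if the cassette does not fit).
#' @param contig_id Contig id of the output.
#' @param seed RNG seed; output is byte-identical given a seed.
#' @param motifs Motif set (default [dgr_default_motifs()]).
#' @return List with `contig` (named character vector of length 1) and
#'   `truth`: `elements` data frame (kind, start, end, strand), `pairs`
#'   data frame (TR and VR coordinates plus planted substitution
#'   counts), and `tr_seq`.
#' @export
generate_dgr_genome <- function(tr_length = 120L, n_vrs = 1L,
                                a_mut_rate = NULL, nonA_mut_rate = NULL,
                                direction_bias = dgr_direction_kernel(),
                                layout = NULL, family = 1L,
                                divergence = 0.02,
                                flank_length = 2000L,
                                total_length = NULL,
                                contig_id = "synthetic_contig",
                                seed = 1L,
                                motifs = dgr_default_motifs()) {
  stopifnot(tr_length == 120L) # element design is fixed-width
  if (is.null(layout)) layout <- c(rep("VR+", n_vrs), "TR+", "RT+")
  n_vrs <- sum(startsWith(layout, "VR"))
  with_seed(seed, {
    tr_inst <- sim_tr_instance(motifs$TR[[family]], divergence)
    tr_seq <- tr_inst$seq
    n_a <- sum(strsplit(tr_seq, "")[[1L]] == "A")
    a_rate <- if (is.null(a_mut_rate)) min(1, 15 / max(1L, n_a))
              else a_mut_rate
    nonA_rate <- if (is.null(nonA_mut_rate))
      min(1, 1.5 / max(1L, nchar(tr_seq) - n_a)) else nonA_mut_rate
    rt_inst <- sim_rt_instance(motifs$RT[[family]], divergence)
    rt_orf <- paste0("ATG", aac_filler(6L, 0), rt_inst$seq,
                     aac_filler(6L, 0), "TAA")

    vrs <- lapply(seq_len(n_vrs), function(i)
      mutate_vr(tr_seq, a_rate, nonA_rate, direction_bias))

    pieces <- character(0)
    elements <- list()
    pos <- 0L
    vi <- 0L
    push <- function(s) {
      pieces[[length(pieces) + 1L]] <<- s
      pos <<- pos + nchar(s)
    }
    for (tok in layout) {
      kind <- substr(tok, 1L, 2L)
      strand <- substr(tok, nchar(tok), nchar(tok))
      push(random_seq(sample(100:300, 1L)))
      if (kind == "TR") {
        s <- if (strand == "+") tr_seq else reverse_complement(tr_seq)
        elements[[length(elements) + 1L]] <-
          data.frame(kind = "TR", start = pos, end = pos + nchar(s),
                     strand = strand, stringsAsFactors = FALSE)
        push(s)
      } else if (kind == "RT") {
        s <- if (strand == "+") rt_orf else reverse_complement(rt_orf)
        elements[[length(elements) + 1L]] <-
          data.frame(kind = "RT", start = pos, end = pos + nchar(s),
                     strand = strand, stringsAsFactors = FALSE)
        push(s)
      } else {
        vi <- vi + 1L
        vr <- vrs[[vi]]
        orf <- paste0("ATG", aac_filler(20L, 0), vr$seq,
                      aac_filler(4L, 0), "TAA")
        vr_off <- 3L + 60L
        s <- if (strand == "+") orf else reverse_complement(orf)
        vs <- if (strand == "+") pos + vr_off
              else pos + nchar(orf) - vr_off - nchar(vr$seq)
        elements[[length(elements) + 1L]] <-
          data.frame(kind = "VR", start = vs, end = vs + nchar(vr$seq),
                     strand = strand, stringsAsFactors = FALSE)
        elements[[length(elements) + 1L]] <-
          data.frame(kind = "target_gene", start = pos,
                     end = pos + nchar(orf), strand = strand,
                     stringsAsFactors = FALSE)
        push(s)
      }
    }
    push(random_seq(sample(100:300, 1L)))
    cassette <- paste(pieces, collapse = "")
    clen <- nchar(cassette)

    if (!is.null(total_length)) {
      if (clen > total_length)
        stop("cassette (", clen, " nt) exceeds total_length")
      lf <- (total_length - clen) %/% 2L
      rf <- total_length - clen - lf
    } else {
      lf <- rf <- flank_length
    }
    contig <- paste0(random_seq(lf), cassette, random_seq(rf))
    el <- do.call(rbind, elements)
    el$start <- el$start + lf
    el$end <- el$end + lf

    tr_el <- el[el$kind == "TR", , drop = FALSE]
    vr_el <- el[el$kind == "VR", , drop = FALSE]
    pairs <- if (nrow(vr_el) > 0)
      data.frame(tr_start = tr_el$start[1L], tr_end = tr_el$end[1L],
                 vr_start = vr_el$start, vr_end = vr_el$end,
                 vr_strand = vr_el$strand,
                 n_subs = vapply(vrs, function(v) length(v$positions),
                                 integer(1)),
                 a_to_n = vapply(vrs, function(v) {
                   ch <- strsplit(tr_seq, "")[[1L]]
                   sum(ch[v$positions] == "A")
                 }, integer(1)),
                 non_a_to_n = vapply(vrs, function(v) {
                   ch <- strsplit(tr_seq, "")[[1L]]
                   sum(ch[v$positions] != "A")
                 }, integer(1)))
    else data.frame()
    contig_v <- stats::setNames(contig, contig_id)
    list(contig = contig_v,
         truth = list(elements = el, pairs = pairs, tr_seq = tr_seq,
                      vr_seqs = vapply(vrs, `[[`, character(1), "seq"),
                      a_mut_rate = a_rate))
  })
}

#' Generate a gold-negative random sequence set
#'
#' I.i.d. sequences at a given base composition — the negative control
#' for false-positive-rate measurement. Presets mirror the four standard
#' lengths 200 bp, 2 kb, 10 kb and 100 kb.
#'
#' @param n Number of sequences.
#' @param length Sequence length in nt.
#' @param background Length-4 composition (A, C, G, T) summing to 1.
#' @param seed RNG seed.
#' @return Named character vector (`neg00001`, ...).
#' @export
generate_negative_set <- function(n, length, background = dgr_background(),
                                  seed = 1L) {
  stopifnot(n >= 1L, length >= 1L)
  if (abs(sum(background) - 1) > 1e-6 || any(background < 0))
    stop("background must be a probability vector over A,C,G,T")
  with_seed(seed, {
    draws <- sample(BASES, n * length, replace = TRUE, prob = background)
    m <- matrix(draws, nrow = n, byrow = TRUE)
    seqs <- apply(m, 1L, paste, collapse = "")
    stats::setNames(seqs, sprintf("neg%05d", seq_len(n)))
  })
}

#' Standard negative-set lengths
#'
#' @return Integer vector `c(200, 2000, 10000, 100000)`.
#' @export
negative_set_lengths <- function() c(200L, 2000L, 10000L, 100000L)

#' Simulate shotgun reads from a contig
#'
#' Uniformly placed fixed-length reads on both strands at the requested
#' expected depth, with independent per-base substitution errors.
#'
#' @param contig_seq Template sequence.
#' @param depth Expected coverage depth (> 0).
#' @param read_length Read length (<= contig length), default 100.
#' @param error_rate Per-base substitution error rate, default 0.
#' @param seed RNG seed.
#' @return List with `reads` (named character vector) and `truth` (data
#'   frame of read start, strand).
#' @export
generate_reads <- function(contig_seq, depth, read_length = 100L,
                           error_rate = 0, seed = 1L) {
  L <- nchar(contig_seq)
  stopifnot(depth > 0, read_length <= L)
  n <- max(1L, as.integer(round(depth * L / read_length)))
  with_seed(seed, {
    starts <- sample.int(L - read_length + 1L, n, replace = TRUE) - 1L
    strands <- sample(c("+", "-"), n, replace = TRUE)
    reads <- character(n)
    for (i in seq_len(n)) {
      s <- substr(contig_seq, starts[i] + 1L, starts[i] + read_length)
      if (error_rate > 0) s <- mutate_uniform(s, error_rate)
      if (strands[i] == "-") s <- reverse_complement(s)
      reads[i] <- s
    }
    names(reads) <- sprintf("read%06d", seq_len(n))
    list(reads = reads,
         truth = data.frame(start = starts, strand = strands))
  })
}
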