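STOP_CODONS <- c("TAA", "TAG", "TGA")

# ORFs in one forward frame of `seq`; coordinates are frame-local nt
# offsets (0-based half-open over the codon span INCLUDING the stop when
# complete). Longest-per-stop: only the first ATG after the previous stop
# opens an ORF.
orfs_one_frame <- function(seq, frame, min_len) {
  n <- nchar(seq)
  usable <- n - frame
  ncod <- usable %/% 3L
  if (ncod < 1L) return(NULL)
  codons <- substring(seq, frame + 1L + 3L * (seq_len(ncod) - 1L),
                      frame + 3L * seq_len(ncod))
  is_stop <- codons %in% STOP_CODONS
  is_atg <- codons == "ATG"
  out <- list()
  prev_stop <- 0L # codon index of previous stop (0 = before start)
  stops <- c(which(is_stop), ncod + 1L) # sentinel: contig edge
  for (sp in stops) {
    if (sp <= prev_stop) next
    cand <- which(is_atg[seq_len(ncod)])
    cand <- cand[cand > prev_stop & cand < sp]
    if (length(cand) > 0L) {
      a <- cand[1L]
      complete <- sp <= ncod
      coding_cod <- sp - a # codons excluding stop (or to edge)
      if (coding_cod * 3L >= min_len) {
        nt_start <- frame + (a - 1L) * 3L
        nt_end <- frame + (sp - 1L) * 3L + if (complete) 3L else 0L
        out[[length(out) + 1L]] <- list(
          start = nt_start, end = nt_end, complete = complete,
          coding_len = coding_cod * 3L,
          protein = paste(vapply(codons[a:(sp - 1L)], codon_aa,
                                 character(1)), collapse = ""))
      }
    }
    prev_stop <- sp
  }
  out
}

codon_aa <- local({
  tab <- NULL
  function(codon) {
    if (is.null(tab)) tab <<- Biostrings::GENETIC_CODE
    aa <- tab[codon]
    if (is.na(aa)) "X" else unname(aa)
  }
})

#' Find open reading frames by six-frame translation
#'
#' `ATG` is the only start codon; each ORF runs from the first `ATG`
#' after the previous in-frame stop to the next stop (longest-ORF-per-
#' stop), or to the contig edge (`complete = FALSE`). ORFs with coding
#' length (stop excluded) of at least `min_len` nucleotides are reported.
#'
#' @param contig_seq Nucleotide string.
#' @param contig_id Contig id for the output table.
#' @param min_len Minimum coding length in nt (default 120, i.e. 40 aa);
#'   must be a positive multiple of 3.
#' @return Data frame with `contig_id`, `start`, `end` (0-based
#'   half-open, forward coordinates, stop codon included when complete),
#'   `strand`, `frame` (0-5; 3-5 are reverse frames), `coding_len`,
#'   `complete`, `protein`.
#' @export
find_orfs <- function(contig_seq, contig_id = "contig", min_len = 120L) {
  stopifnot(min_len >= 3L, min_len %% 3L == 0L)
  L <- nchar(contig_seq)
  res <- list()
  add <- function(o, strand, frame) {
    if (strand == "+") {
      start <- o$start; end <- o$end
    } else {
      start <- L - o$end; end <- L - o$start
    }
    data.frame(contig_id = contig_id, start = start, end = end,
               strand = strand, frame = frame,
               coding_len = o$coding_len, complete = o$complete,
               protein = o$protein, stringsAsFactors = FALSE)
  }
  rc <- if (L > 0) reverse_complement(contig_seq) else ""
  for (f in 0:2) {
    for (o in orfs_one_frame(contig_seq, f, min_len)) {
      res[[length(res) + 1L]] <- add(o, "+", f)
    }
    for (o in orfs_one_frame(rc, f, min_len)) {
      res[[length(res) + 1L]] <- add(o, "-", f + 3L)
    }
  }
  if (length(res) == 0L) {
    return(data.frame(contig_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      frame = integer(0), coding_len = integer(0),
                      complete = logical(0), protein = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign each merged VR its putative target gene
#'
#' The longest ORF overlapping a VR by >= 1 bp (any strand) is its
#' target; VRs without an overlapping ORF get `NA`. The overlap category
#' distinguishes a VR fully inside the ORF's 3'-terminal third
#' (`"three_prime_end"`, the canonical cassette geometry), elsewhere
#' inside (`"internal"`), or only partially overlapping
#' (`"partial_overlap"`).
#'
#' @param vrs Data frame of merged VR intervals ([merge_vrs()] output).
#' @param orfs Data frame from [find_orfs()] on the same contigs.
#' @return `vrs` with added columns `orf_row` (row index into `orfs` or
#'   `NA`), `orf_len` and `category`.
#' @export
assign_targets <- function(vrs, orfs) {
  n <- nrow(vrs)
  vrs$orf_row <- rep(NA_integer_, n)
  vrs$orf_len <- rep(NA_integer_, n)
  vrs$category <- rep(NA_character_, n)
  if (n == 0L || nrow(orfs) == 0L) return(vrs)
  for (i in seq_len(n)) {
    same <- which(orfs$contig_id == vrs$contig_id[i])
    if (length(same) == 0L) next
    ov <- pmin(orfs$end[same], vrs$end[i]) -
      pmax(orfs$start[same], vrs$start[i])
    cand <- same[ov > 0]
    if (length(cand) == 0L) next
    lens <- orfs$end[cand] - orfs$start[cand]
    best <- cand[order(-lens, orfs$start[cand])][1L]
    vrs$orf_row[i] <- best
    vrs$orf_len[i] <- orfs$end[best] - orfs$start[best]
    inside <- vrs$start[i] >= orfs$start[best] &&
      vrs$end[i] <= orfs$end[best]
    if (!inside) {
      vrs$category[i] <- "partial_overlap"
    } else {
      olen <- orfs$end[best] - orfs$start[best]
      # strand-aware 3' terminal third of the ORF
      if (orfs$strand[best] == "+") {
        in3 <- vrs$start[i] >= orfs$end[best] - ceiling(olen / 3)
      } else {
        in3 <- vrs$end[i] <= orfs$start[best] + ceiling(olen / 3)
      }
      vrs$category[i] <- if (in3) "three_prime_end" else "internal"
    }
  }
  vrs
}
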