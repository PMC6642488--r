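#' @useDynLib dgrfinder, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Internal coordinate convention: 0-based half-open [start, end) on the
# forward strand of the containing contig. Conversion to 1-based inclusive
# happens only when GTF is written.

#' Read a FASTA file of contigs
#'
#' Loads an assembly (or any nucleotide FASTA) into a named character
#' vector of uppercase sequences. `U` is converted to `T`; IUPAC ambiguity
#' codes other than `N` are rejected so that corrupt inputs surface early.
#' Record ids are the header token up to the first whitespace and must be
#' unique.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector; names are contig ids, values are
#'   uppercase sequences over `A`, `C`, `G`, `T`, `N`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  ids <- vapply(strsplit(names(set), "[ \t]"), `[[`, character(1), 1L)
  if (any(!nzchar(ids))) stop("empty FASTA record id")
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("sequence(s) with characters outside {A,C,G,T,N,U}: ",
         paste(ids[bad], collapse = ", "))
  }
  names(seqs) <- ids
  seqs
}

#' Read sequencing reads from FASTA or FASTQ
#'
#' Qualities are ignored; reads are normalized exactly like contigs.
#'
#' @param path Path to a FASTA or FASTQ file.
#' @param format `"auto"` (sniff the first character), `"fasta"` or
#'   `"fastq"`.
#' @return Named character vector of uppercase read sequences.
#' @export
read_reads <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readChar(path, 1L)
    format <- if (identical(first, "@")) "fastq" else "fasta"
  }
  if (format == "fasta") return(read_fasta(path))
  set <- Biostrings::readBStringSet(path, format = "fastq")
  ids <- vapply(strsplit(names(set), "[ \t]"), `[[`, character(1), 1L)
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  if (any(grepl("[^ACGTN]", seqs))) stop("non-ACGTN base in reads")
  names(seqs) <- ids
  seqs
}

#' Reverse complement of a nucleotide string
#'
#' @param seq Character scalar over `A`, `C`, `G`, `T`, `N`.
#' @return The reverse complement; `N` maps to `N`.
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) return(seq)
  if (grepl("[^ACGTN]", seq)) stop("invalid base in sequence")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Translate a nucleotide string in one forward frame
#'
#' Standard genetic code; stops are `*`, codons containing `N` become `X`.
#' `ATG` is the methionine codon; frame selection drops the first
#' `frame` bases and any trailing partial codon.
#'
#' @param seq Nucleotide string.
#' @param frame Integer 0, 1 or 2.
#' @return Amino-acid string of `floor((nchar(seq) - frame) / 3)` residues.
#' @export
translate_seq <- function(seq, frame = 0L) {
  stopifnot(frame %in% 0:2)
  n <- nchar(seq)
  usable <- n - frame
  if (usable < 3L) return("")
  len <- (usable %/% 3L) * 3L
  sub <- substr(seq, frame + 1L, frame + len)
  aa <- Biostrings::translate(Biostrings::DNAString(sub),
                              if.fuzzy.codon = "X")
  as.character(aa)
}

# --- interval helpers (0-based half-open) ------------------------------

new_interval <- function(contig_id, start, end, strand = "+") {
  stopifnot(end > start, start >= 0, strand %in% c("+", "-"))
  list(contig_id = contig_id, start = as.integer(start),
       end = as.integer(end), strand = strand)
}

interval_overlap <- function(s1, e1, s2, e2) {
  max(0L, min(e1, e2) - max(s1, s2))
}

# extract the element sequence in its own reading orientation
interval_seq <- function(contigs, contig_id, start, end, strand = "+") {
  s <- substr(contigs[[contig_id]], start + 1L, end)
  if (strand == "-") s <- reverse_complement(s)
  s
}

#' Write DGR annotations as GTF
#'
#' One line per element (`TR`, `VR`, `RT`, `target_gene`), 1-based
#' inclusive coordinates. VR lines carry the pair statistics as
#' attributes.
#'
#' @param records List of DGR records from [assemble_dgrs()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_gtf <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 2", con)
  q <- function(x) sprintf('"%s"', x)
  for (rec in records) {
    base_attr <- sprintf('dgr_id %s; status %s; cassette_group %s;',
                         q(rec$dgr_id), q(rec$status),
                         q(rec$cassette_signature))
    emit <- function(feature, start, end, strand, score = ".", extra = "") {
      line <- paste(rec$contig_id, "dgrfinder", feature,
                    start + 1L, end, score, strand, ".",
                    paste0(base_attr, extra), sep = "\t")
      writeLines(line, con)
    }
    if (nrow(rec$trs) > 0) {
      for (i in seq_len(nrow(rec$trs))) {
        h <- rec$trs[i, ]
        emit("TR", h$start, h$end, h$strand, format(h$score))
      }
    }
    if (!is.null(rec$pairs) && nrow(rec$pairs) > 0) {
      for (i in seq_len(nrow(rec$pairs))) {
        p <- rec$pairs[i, ]
        extra <- sprintf(
          ' identity %s; a_to_n %s; non_a_to_n %s; longest_ccs %s;',
          q(format(p$identity)), q(p$a_to_n), q(p$non_a_to_n),
          q(p$longest_ccs))
        emit("VR", p$vr_start, p$vr_end, p$vr_strand, format(p$score),
             extra)
      }
    }
    if (nrow(rec$rts) > 0) {
      for (i in seq_len(nrow(rec$rts))) {
        h <- rec$rts[i, ]
        emit("RT", h$start, h$end, h$strand, format(h$score))
      }
    }
    if (!is.null(rec$targets) && nrow(rec$targets) > 0) {
      for (i in seq_len(nrow(rec$targets))) {
        o <- rec$targets[i, ]
        emit("target_gene", o$start, o$end, o$strand)
      }
    }
  }
  invisible(path)
}
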