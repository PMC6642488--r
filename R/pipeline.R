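#' Pipeline configuration
#'
#' Bundles models and thresholds. The defaults reproduce the canonical
#' filter settings: VR alignment length > 30, identity > 60%,
#' non-A-to-N < 4; locus window 20 kb; RT clustering identity 0.90;
#' read confirmation with >= 2 reads each carrying <= 3 non-A-to-N;
#' minimum ORF coding length 120 nt.
#'
#' @param models List of `dgr_ghmm` submodels (or a path readable by
#'   [read_models()]).
#' @param min_score Optional global score floor overriding per-model
#'   thresholds.
#' @param locus_window Locus chaining window in nt.
#' @param cluster_threshold RT clustering identity threshold.
#' @param orf_min_len Minimum ORF coding length (nt).
#' @param seed_k,seed_step VR seeding parameters.
#' @param min_reads,max_non_a_reads Read-confirmation thresholds.
#' @param seed Pipeline seed (recorded in the run log).
#' @return List of class `dgr_config`.
#' @export
dgr_config <- function(models, min_score = NULL, locus_window = 20000L,
                       cluster_threshold = 0.90, orf_min_len = 120L,
                       seed_k = 8L, seed_step = 4L, min_reads = 2L,
                       max_non_a_reads = 3L, seed = 1L) {
  if (is.character(models)) models <- read_models(models)
  structure(list(models = models, min_score = min_score,
                 locus_window = locus_window,
                 cluster_threshold = cluster_threshold,
                 orf_min_len = orf_min_len, seed_k = seed_k,
                 seed_step = seed_step, min_reads = min_reads,
                 max_non_a_reads = max_non_a_reads, seed = seed),
            class = "dgr_config")
}

#' Run the DGR detection pipeline on an assembly
#'
#' Stages, in order: GHMM element scan (TR + RT, both strands) ->
#' VR search and filtering per TR -> ORF finding -> locus assembly with
#' intact/partial status -> cassette signatures -> RT clustering ->
#' substitution summary. Empty input yields empty outputs (absence of
#' DGRs is a finding, not an error).
#'
#' @param config A `dgr_config`.
#' @param contigs Named character vector of contig sequences, or a FASTA
#'   path.
#' @param out_dir Optional directory: writes `dgrs.gtf`, `pairs.tsv`,
#'   `cassettes.tsv` and `run_log.txt`.
#' @param find_orfs_stage Run the ORF/target stage (default TRUE; the
#'   negative-control screen can skip it for speed).
#' @return List with `records`, `hits`, `pairs`, `orfs`, `clusters`,
#'   `summary`, `counts` (per-stage survivor counts).
#' @export
run_pipeline <- function(config, contigs, out_dir = NULL,
                         find_orfs_stage = TRUE) {
  stopifnot(inherits(config, "dgr_config"))
  if (is.character(contigs) && length(contigs) == 1L &&
      file.exists(contigs) && is.null(names(contigs))) {
    contigs <- read_fasta(contigs)
  }
  counts <- list()

  hits_list <- lapply(names(contigs), function(cid)
    scan_elements(config$models, contigs[[cid]], contig_id = cid,
                  min_score = config$min_score))
  hits <- do.call(rbind, hits_list)
  if (is.null(hits)) hits <- scan_elements(config$models, "", "empty")
  counts$tr_hits <- sum(hits$element_type == "TR")
  counts$rt_hits <- sum(hits$element_type == "RT")

  trs <- hits[hits$element_type == "TR", , drop = FALSE]
  pairs_list <- lapply(seq_len(nrow(trs)), function(i)
    find_vrs(trs[i, ], contigs, seed_k = config$seed_k,
             seed_step = config$seed_step))
  pairs <- if (length(pairs_list) > 0) do.call(rbind, pairs_list)
           else empty_pairs()

  # a TR call covered by a retained VR of a higher-scoring TR is that
  # TR's variable repeat, not an independent template: demote it and
  # discard its mirror pairs
  if (nrow(pairs) > 0 && nrow(trs) > 1) {
    hit_score <- function(cid, s, e) {
      i <- which(trs$contig_id == cid & trs$start == s & trs$end == e)
      if (length(i) == 0L) -Inf else trs$score[i[1L]]
    }
    demote <- rep(FALSE, nrow(trs))
    for (i in seq_len(nrow(trs))) {
      ov <- pairs$contig_id == trs$contig_id[i] &
        pmin(pairs$vr_end, trs$end[i]) - pmax(pairs$vr_start, trs$start[i]) >=
          0.5 * (trs$end[i] - trs$start[i])
      if (!any(ov)) next
      owners <- vapply(which(ov), function(j)
        hit_score(pairs$contig_id[j], pairs$tr_start[j], pairs$tr_end[j]),
        numeric(1))
      if (any(owners > trs$score[i])) demote[i] <- TRUE
    }
    if (any(demote)) {
      gone <- trs[demote, , drop = FALSE]
      keep_pair <- !(paste(pairs$contig_id, pairs$tr_start, pairs$tr_end) %in%
                       paste(gone$contig_id, gone$start, gone$end))
      pairs <- pairs[keep_pair, , drop = FALSE]
      keep_hit <- !(hits$element_type == "TR" &
                      paste(hits$contig_id, hits$start, hits$end) %in%
                        paste(gone$contig_id, gone$start, gone$end))
      hits <- hits[keep_hit, , drop = FALSE]
      counts$tr_hits <- sum(hits$element_type == "TR")
    }
  }
  counts$filtered_pairs <- nrow(pairs)

  orfs <- NULL
  if (find_orfs_stage) {
    orfs_list <- lapply(names(contigs), function(cid)
      find_orfs(contigs[[cid]], contig_id = cid,
                min_len = config$orf_min_len))
    orfs <- do.call(rbind, orfs_list)
    counts$orfs <- if (is.null(orfs)) 0L else nrow(orfs)
  }

  records <- assemble_dgrs(hits, pairs, orfs = orfs,
                           locus_window = config$locus_window)
  counts$records <- length(records)
  counts$intact <- sum(vapply(records, function(r)
    r$status == "intact", logical(1)))
  counts$partial <- counts$records - counts$intact

  rt_seqs <- unlist(lapply(records, function(r) {
    vapply(seq_len(nrow(r$rts)), function(i)
      interval_seq(contigs, r$rts$contig_id[i], r$rts$start[i],
                   r$rts$end[i], r$rts$strand[i]), character(1))
  }))
  clusters <- cluster_rts(if (is.null(rt_seqs)) character(0) else rt_seqs,
                          threshold = config$cluster_threshold)
  counts$rt_clusters <- length(clusters$representative)

  all_pairs <- do.call(rbind, c(list(empty_pairs()),
                                lapply(records, `[[`, "pairs")))
  summary <- summarize_substitutions(all_pairs)

  result <- list(records = records, hits = hits, pairs = pairs,
                 orfs = orfs, clusters = clusters, summary = summary,
                 counts = counts)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_gtf(records, file.path(out_dir, "dgrs.gtf"))
    utils::write.table(pairs[, setdiff(names(pairs),
                                       c("tr_aln", "vr_aln"))],
                       file.path(out_dir, "pairs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    sigs <- vapply(records, `[[`, character(1), "cassette_signature")
    cas <- as.data.frame(table(signature = sigs),
                         stringsAsFactors = FALSE)
    utils::write.table(cas, file.path(out_dir, "cassettes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log <- c(sprintf("dgrfinder %s",
                     as.character(utils::packageVersion("dgrfinder"))),
             sprintf("R %s", getRversion()),
             sprintf("seed %d", config$seed),
             sprintf("locus_window %d", config$locus_window),
             sprintf("cluster_threshold %g", config$cluster_threshold),
             vapply(names(counts), function(k)
               sprintf("count %s %d", k, as.integer(counts[[k]])),
               character(1)))
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }
  result
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic DGR genome + truth GTF),
#' `train` (train and write models from synthetic training sets),
#' `scan` (run the pipeline on a FASTA), `validate-reads` (confirm a
#' TR's VRs from reads), `cluster` (cluster RT sequences from a FASTA),
#' `stats` (substitution summary for a pairs TSV with alignments).
#' Run with no arguments for usage.
#'
#' @param args Character vector of command-line arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Invisibly, the subcommand result; called for side effects.
#' @export
dgr_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: dgrfinder <command> [options]",
    "  simulate --out DIR [--seed N] [--n-vrs N] [--total-length N]",
    "  train    --out FILE [--seed N] [--n N]",
    "  scan     --fasta FILE --models FILE --out DIR [--min-score X]",
    "  validate-reads --fasta FILE --reads FILE --tr contig:start-end",
    "  cluster  --fasta FILE [--threshold X]",
    sep = "\n")
  if (length(args) == 0L) {
    message(usage)
    return(invisible(NULL))
  }
  cmd <- args[[1L]]
  opts <- list()
  rest <- args[-1L]
  i <- 1L
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[[i]])
    opts[[key]] <- if (i + 1L <= length(rest)) rest[[i + 1L]] else NA
    i <- i + 2L
  }
  geti <- function(k, d) if (!is.null(opts[[k]])) as.integer(opts[[k]]) else d
  getn <- function(k, d) if (!is.null(opts[[k]])) as.numeric(opts[[k]]) else d

  if (cmd == "simulate") {
    out <- opts[["out"]]
    if (is.null(out)) stop(usage)
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    g <- generate_dgr_genome(seed = geti("seed", 1L),
                             n_vrs = geti("n-vrs", 1L),
                             total_length = if (!is.null(opts[["total-length"]]))
                               geti("total-length", NULL) else NULL)
    writeLines(c(paste0(">", names(g$contig)), unname(g$contig)),
               file.path(out, "genome.fasta"))
    el <- g$truth$elements
    lines <- sprintf("%s\tdgrfinder_truth\t%s\t%d\t%d\t.\t%s\t.\t.",
                     names(g$contig), el$kind, el$start + 1L, el$end,
                     el$strand)
    writeLines(c("##gff-version 2", lines), file.path(out, "truth.gtf"))
    message("wrote ", out)
    return(invisible(g))
  }
  if (cmd == "train") {
    out <- opts[["out"]]
    if (is.null(out)) stop(usage)
    seed <- geti("seed", 1L)
    n <- geti("n", 60L)
    models <- train_models(
      simulate_training_set("TR", n = n, seed = seed),
      simulate_training_set("RT", n = n, seed = seed + 1L),
      seed = seed + 2L)
    write_models(models, out)
    message("wrote ", out)
    return(invisible(models))
  }
  if (cmd == "scan") {
    if (is.null(opts[["fasta"]]) || is.null(opts[["models"]]) ||
        is.null(opts[["out"]])) stop(usage)
    cfg <- dgr_config(opts[["models"]],
                      min_score = if (!is.null(opts[["min-score"]]))
                        getn("min-score", NULL) else NULL)
    res <- run_pipeline(cfg, opts[["fasta"]], out_dir = opts[["out"]])
    message(sprintf("%d intact, %d partial DGRs", res$counts$intact,
                    res$counts$partial))
    return(invisible(res))
  }
  if (cmd == "validate-reads") {
    if (is.null(opts[["fasta"]]) || is.null(opts[["reads"]]) ||
        is.null(opts[["tr"]])) stop(usage)
    contigs <- read_fasta(opts[["fasta"]])
    m <- regmatches(opts[["tr"]],
                    regexec("^(.+):([0-9]+)-([0-9]+)$", opts[["tr"]]))[[1L]]
    if (length(m) != 4L) stop("--tr must be contig:start-end")
    tr_seq <- interval_seq(contigs, m[2L], as.integer(m[3L]),
                           as.integer(m[4L]))
    reads <- read_reads(opts[["reads"]])
    cand <- screen_reads(tr_seq, reads)
    ev <- confirm_vrs_from_reads(tr_seq, cand)
    message(nrow(ev), " confirmed VR footprint(s) from ",
            length(cand), " candidate reads")
    return(invisible(ev))
  }
  if (cmd == "cluster") {
    if (is.null(opts[["fasta"]])) stop(usage)
    seqs <- read_fasta(opts[["fasta"]])
    cl <- cluster_rts(unname(seqs), threshold = getn("threshold", 0.9))
    message(length(cl$representative), " clusters for ", length(seqs),
            " sequences")
    return(invisible(cl))
  }
  stop("unknown command: ", cmd, "\n", usage)
}
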