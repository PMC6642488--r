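#' Summarize the substitution spectrum of TR-VR pairs
#'
#' Walks the aligned columns of every pair (gap columns skipped),
#' accumulating a 4x4 direction matrix (rows = TR base, columns = VR
#' base, diagonal zero) and per-pair counts. The per-pair non-A-to-N
#' frequency is `non_a_to_n / aligned (gap-free) columns`, in percent.
#'
#' @param pairs Pair data frame from [find_vrs()] (needs `tr_aln`,
#'   `vr_aln`).
#' @return List of class `dgr_mutation_summary`: `direction_counts` (4x4
#'   matrix), `per_pair` data frame (`a_to_n`, `non_a_to_n`,
#'   `aligned_length`, `nonA_freq_pct`), `mean_a_to_n`,
#'   `mean_non_a_to_n`, `mean_nonA_freq_pct`, `frac_pairs_with_nonA`,
#'   `frac_pairs_only_nonA`.
#' @export
summarize_substitutions <- function(pairs) {
  dir <- matrix(0L, 4L, 4L, dimnames = list(BASES, BASES))
  n <- nrow(pairs)
  per <- data.frame(a_to_n = integer(n), non_a_to_n = integer(n),
                    aligned_length = integer(n),
                    nonA_freq_pct = numeric(n))
  for (i in seq_len(n)) {
    a <- strsplit(pairs$tr_aln[i], "")[[1L]]
    b <- strsplit(pairs$vr_aln[i], "")[[1L]]
    ok <- a %in% BASES & b %in% BASES
    a <- a[ok]; b <- b[ok]
    subs <- a != b
    if (any(subs)) {
      t <- table(factor(a[subs], levels = BASES),
                 factor(b[subs], levels = BASES))
      dir <- dir + as.matrix(t)
    }
    per$a_to_n[i] <- sum(subs & a == "A")
    per$non_a_to_n[i] <- sum(subs & a != "A")
    per$aligned_length[i] <- length(a)
    per$nonA_freq_pct[i] <-
      if (length(a) > 0) 100 * per$non_a_to_n[i] / length(a) else 0
  }
  structure(list(
    direction_counts = dir,
    per_pair = per,
    mean_a_to_n = if (n > 0) mean(per$a_to_n) else NA_real_,
    mean_non_a_to_n = if (n > 0) mean(per$non_a_to_n) else NA_real_,
    mean_nonA_freq_pct = if (n > 0) mean(per$nonA_freq_pct) else NA_real_,
    frac_pairs_with_nonA = if (n > 0) mean(per$non_a_to_n > 0) else NA_real_,
    frac_pairs_only_nonA = if (n > 0)
      mean(per$non_a_to_n > 0 & per$a_to_n == 0) else NA_real_),
    class = "dgr_mutation_summary")
}

#' Pearson chi-square test of independence
#'
#' `sum((O - E)^2 / E)` with expected counts from the marginals and
#' `df = (r - 1)(c - 1)`. For 2x2 tables the Yates continuity correction
#' is applied by default (matching the R default the field uses); the
#' upper-tail chi-square distribution supplies the p-value.
#'
#' @param table Numeric matrix of counts (>= 2 rows and columns).
#' @param correct Apply the continuity correction for 2x2 tables
#'   (default TRUE).
#' @return List with `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_square_independence <- function(table, correct = TRUE) {
  x <- as.matrix(table)
  if (nrow(x) < 2L || ncol(x) < 2L) stop("need at least a 2x2 table")
  if (any(x < 0) || any(!is.finite(x))) stop("counts must be >= 0")
  rs <- rowSums(x); cs <- colSums(x)
  if (any(rs == 0) || any(cs == 0))
    stop("zero marginal row or column")
  E <- outer(rs, cs) / sum(x)
  yates <- if (correct && nrow(x) == 2L && ncol(x) == 2L)
    min(0.5, abs(x - E)) else 0
  stat <- sum((abs(x - E) - yates)^2 / E)
  df <- (nrow(x) - 1L) * (ncol(x) - 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       expected = E)
}

#' Test a cassette pattern's association with taxonomy
#'
#' Splits records into the focal signature vs all others, builds the
#' taxon x {focal, other} contingency table and tests independence; the
#' full taxon x signature table gives the omnibus test.
#'
#' @param records Data frame with columns `taxon` and `signature`, one
#'   row per (non-redundant) DGR.
#' @param focal_signature Signature string defining the focal group.
#' @param correct Continuity correction for the 2x2 case (default TRUE).
#' @return List with `focal` and `omnibus` test results (each as
#'   returned by [chi_square_independence()]) and the focal `table`.
#' @export
cassette_vs_group_test <- function(records, focal_signature,
                                   correct = TRUE) {
  stopifnot(all(c("taxon", "signature") %in% names(records)))
  if (length(unique(records$taxon)) < 2L)
    stop("need at least two taxa")
  grp <- ifelse(records$signature == focal_signature, "focal", "other")
  tab <- table(records$taxon, factor(grp, levels = c("focal", "other")))
  if (any(colSums(tab) == 0))
    stop("focal signature absent or universal: degenerate table")
  focal <- chi_square_independence(as.matrix(tab), correct = correct)
  omni <- table(records$taxon, records$signature)
  omnibus <- if (ncol(omni) >= 2L)
    chi_square_independence(as.matrix(omni), correct = correct)
  else NULL
  list(focal = focal, omnibus = omnibus, table = tab)
}
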