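# Position-specific scoring profile standing in for the published HMM screen.

#' Build a log-odds scoring profile from an alignment
#'
#' Columns with more than 50% gaps are dropped; each remaining column gets
#' per-residue log-odds
#' `log((count + pseudocount * background) / (n + pseudocount) / background)`,
#' where n is the number of sequences contributing a residue (gaps in a kept
#' column contribute nothing). The pseudocount keeps every score finite.
#' This ungapped profile (PSSM) is a deliberately simple, fully testable
#' replacement for a profile HMM: it has no insert/delete states.
#'
#' @param msa named character vector (or AAStringSet) of equal-length
#'   aligned sequences; `-` and `.` are gaps.
#' @param background named numeric vector of residue frequencies over the
#'   20 standard amino acids, summing to 1 (default uniform).
#' @param pseudocount positive pseudocount weight (default 1).
#' @param max_gap_fraction columns with a larger gap fraction are dropped
#'   (default 0.5).
#' @return object of class `profile_model`: list with `log_odds`
#'   (20 x L matrix, rows named by residue), `length`, `background`,
#'   `pseudocount`, `source_n`, `kept_columns`.
#' @export
build_profile <- function(msa, background = NULL, pseudocount = 1,
                          max_gap_fraction = 0.5) {
  msa <- as.character(msa)
  if (length(msa) < 2L) stop("profile needs at least 2 aligned sequences")
  widths <- nchar(msa)
  if (length(unique(widths)) != 1L)
    stop("ragged alignment: sequence lengths differ")
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20), AA_STANDARD)
  } else {
    background <- background[AA_STANDARD]
    if (anyNA(background) || abs(sum(background) - 1) > 1e-9)
      stop("background must cover the 20 standard residues and sum to 1")
  }
  mat <- do.call(rbind, strsplit(toupper(msa), "", fixed = TRUE))
  is_gap <- mat == "-" | mat == "."
  gap_frac <- colMeans(is_gap)
  keep <- which(gap_frac <= max_gap_fraction)
  if (!length(keep)) stop("all columns exceed the gap-fraction limit")
  L <- length(keep)
  lo <- matrix(NA_real_, nrow = 20, ncol = L, dimnames = list(AA_STANDARD, NULL))
  for (j in seq_len(L)) {
    col <- mat[, keep[j]]
    col <- col[!(col %in% c("-", "."))]
    counts <- table(factor(col, levels = AA_STANDARD))
    n <- length(col)
    p <- (as.numeric(counts) + pseudocount * background) / (n + pseudocount)
    lo[, j] <- log(p / background)
  }
  structure(list(log_odds = lo, length = L, background = background,
                 pseudocount = pseudocount, source_n = length(msa),
                 kept_columns = keep),
            class = "profile_model")
}

#' @export
print.profile_model <- function(x, ...) {
  cat(sprintf("<profile_model> %d columns from %d sequences (pseudocount %g)\n",
              x$length, x$source_n, x$pseudocount))
  invisible(x)
}

#' Score a sequence against a profile
#'
#' Slides the profile over every ungapped window of the sequence and sums
#' per-column log-odds; residues outside the 20 standard letters score the
#' column minimum. Ties are broken leftmost.
#'
#' @param profile a `profile_model`.
#' @param seq protein string, at least as long as the profile.
#' @return list(best_score, best_start) with `best_start` 1-based.
#' @export
score_sequence <- function(profile, seq) {
  s <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  L <- profile$length
  if (length(s) < L)
    stop(sprintf("sequence length %d shorter than profile length %d",
                 length(s), L))
  idx <- match(s, AA_STANDARD)
  col_min <- apply(profile$log_odds, 2, min)
  n_win <- length(s) - L + 1L
  scores <- numeric(n_win)
  for (w in seq_len(n_win)) {
    ii <- idx[w:(w + L - 1L)]
    sc <- ifelse(is.na(ii), col_min,
                 profile$log_odds[cbind(ii, seq_len(L))])
    scores[w] <- sum(sc)
  }
  best <- which.max(scores)
  list(best_score = scores[best], best_start = as.integer(best),
       window_scores = scores)
}

#' Screen a sequence collection with a profile
#'
#' Scores every sequence, ranks by descending best-window score, and applies
#' the published alignment-length rule to the profile match region (the
#' ungapped window, whose length equals the profile length). Sequences
#' shorter than the profile are reported with score `-Inf`.
#'
#' @param fasta path to FASTA or named character vector.
#' @param profile a `profile_model`.
#' @param score_threshold minimum best score to be listed as a candidate.
#' @param length_rule a [filter_config()] in "profile" mode supplying
#'   `min_alignment_length` and `min_query_coverage`.
#' @return data.frame ranked by descending score: seq_id, score, start, end,
#'   window_length, query_coverage, passes_length_rule, candidate.
#' @export
screen_candidates <- function(fasta, profile, score_threshold = 0,
                              length_rule = filter_config("profile")) {
  seqs <- if (is.character(fasta) && length(fasta) == 1L && is.null(names(fasta))) {
    read_fasta(fasta)
  } else stats::setNames(as.character(fasta), names(fasta))
  if (!length(seqs)) {
    return(data.frame(seq_id = character(), score = numeric(),
                      start = integer(), end = integer(),
                      window_length = integer(), query_coverage = numeric(),
                      passes_length_rule = logical(), candidate = logical(),
                      stringsAsFactors = FALSE))
  }
  L <- profile$length
  rows <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    if (nchar(s) < L) {
      return(data.frame(seq_id = names(seqs)[i], score = -Inf,
                        start = NA_integer_, end = NA_integer_,
                        window_length = 0L, query_coverage = 0,
                        stringsAsFactors = FALSE))
    }
    sc <- score_sequence(profile, s)
    data.frame(seq_id = names(seqs)[i], score = sc$best_score,
               start = sc$best_start, end = sc$best_start + L - 1L,
               window_length = L, query_coverage = 100 * L / L,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$query_coverage <- 100 * tab$window_length / L
  tab$passes_length_rule <-
    tab$window_length > length_rule$min_alignment_length &
    tab$query_coverage > length_rule$min_query_coverage
  tab$candidate <- is.finite(tab$score) & tab$score >= score_threshold &
    tab$passes_length_rule
  tab <- tab[order(-tab$score), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
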