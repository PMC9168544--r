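# Homology-hit filtering with the published tblastn / profile thresholds.

#' Build a hit-filter configuration
#'
#' Two modes mirror the two published screens. `tblastn` applies the
#' nucleotide-database filter: query coverage strictly > 60%, e-value
#' cutoff inclusive at 1e-40, identity strictly > 30%. `profile` applies
#' the genome/transcriptome profile-screen rule: alignment length strictly
#' > 175 residues and query coverage strictly > 30%. The ">" thresholds are
#' strict and the e-value "cutoff" is inclusive, following the printed
#' wording literally.
#'
#' @param mode "tblastn" or "profile".
#' @param min_query_coverage coverage threshold (strict >); default 60 for
#'   tblastn, 30 for profile.
#' @param max_evalue inclusive e-value ceiling (tblastn mode only).
#' @param min_identity identity threshold, strict > (tblastn mode only).
#' @param min_alignment_length length threshold, strict > (profile mode only).
#' @return list of class `filter_config`.
#' @export
filter_config <- function(mode = c("tblastn", "profile"),
                          min_query_coverage = NULL,
                          max_evalue = 1e-40,
                          min_identity = 30,
                          min_alignment_length = 175) {
  mode <- match.arg(mode)
  if (is.null(min_query_coverage))
    min_query_coverage <- if (mode == "tblastn") 60 else 30
  structure(list(mode = mode,
                 min_query_coverage = min_query_coverage,
                 max_evalue = max_evalue,
                 min_identity = min_identity,
                 min_alignment_length = min_alignment_length),
            class = "filter_config")
}

validate_hits <- function(hits) {
  need <- c("query_id", "subject_id", "percent_identity",
            "alignment_length", "evalue", "query_coverage")
  miss <- setdiff(need, names(hits))
  if (length(miss)) stop("hit table missing columns: ", paste(miss, collapse = ", "))
  for (col in c("percent_identity", "alignment_length", "evalue", "query_coverage")) {
    v <- hits[[col]]
    if (!is.numeric(v)) {
      coerced <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(coerced) & !is.na(v))
      if (length(bad))
        stop(sprintf("non-numeric value in column '%s' at row %d", col, bad[1]))
      hits[[col]] <- coerced
    }
  }
  if (any(hits$percent_identity < 0 | hits$percent_identity > 100, na.rm = TRUE))
    stop("percent_identity outside [0, 100]")
  if (any(hits$query_coverage < 0 | hits$query_coverage > 100, na.rm = TRUE))
    stop("query_coverage outside [0, 100]")
  if (any(hits$evalue < 0, na.rm = TRUE)) stop("negative e-value")
  if (any(hits$alignment_length < 0, na.rm = TRUE)) stop("negative alignment length")
  hits
}

#' Filter homology hits with the configured thresholds
#'
#' Keeps the hits that satisfy every criterion active in the configured
#' mode; input order is preserved. Rejected rows get a reason string
#' listing each failed criterion, returned as attribute `"reasons"`
#' (empty string for survivors).
#'
#' @param hits data.frame as returned by [read_hits()].
#' @param config a [filter_config()].
#' @return the surviving rows, with attribute `"reasons"` (length =
#'   nrow(hits)) on the result.
#' @export
filter_hits <- function(hits, config = filter_config("tblastn")) {
  hits <- validate_hits(hits)
  n <- nrow(hits)
  reasons <- character(n)
  add_reason <- function(reasons, fail, msg) {
    reasons[fail] <- ifelse(nzchar(reasons[fail]),
                            paste(reasons[fail], msg, sep = "; "), msg)
    reasons
  }
  if (config$mode == "tblastn") {
    f <- !(hits$query_coverage > config$min_query_coverage)
    reasons <- add_reason(reasons, f, sprintf("query_coverage <= %g",
                                              config$min_query_coverage))
    f <- !(hits$evalue <= config$max_evalue)
    reasons <- add_reason(reasons, f, sprintf("evalue > %g", config$max_evalue))
    f <- !(hits$percent_identity > config$min_identity)
    reasons <- add_reason(reasons, f, sprintf("identity <= %g", config$min_identity))
  } else {
    f <- !(hits$alignment_length > config$min_alignment_length)
    reasons <- add_reason(reasons, f, sprintf("alignment_length <= %g",
                                              config$min_alignment_length))
    f <- !(hits$query_coverage > config$min_query_coverage)
    reasons <- add_reason(reasons, f, sprintf("query_coverage <= %g",
                                              config$min_query_coverage))
  }
  keep <- !nzchar(reasons)
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "reasons") <- reasons
  out
}
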