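# Standard-format readers/writers used across the pipeline.

#' Read a (possibly gzipped) FASTA file
#'
#' @param path file path.
#' @return named character vector of uppercase sequences, input order kept.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width residues per line (default 60).
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    n <- nchar(s)
    starts <- seq.int(1L, max(n, 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Read a tab-separated homology hit table
#'
#' Column order: query_id, subject_id, percent_identity, alignment_length,
#' evalue, query_coverage (BLAST tabular plus a coverage column). A header
#' row is detected and skipped automatically.
#'
#' @param path file path.
#' @return validated data.frame of hits.
#' @export
read_hits <- function(path) {
  if (!file.exists(path)) stop("hit table not found: ", path)
  first <- readLines(path, n = 1L)
  has_header <- grepl("query_id", first, fixed = TRUE)
  tab <- utils::read.delim(path, header = has_header,
                           stringsAsFactors = FALSE)
  if (!has_header) {
    if (ncol(tab) < 6L) stop("hit table needs 6 columns, found ", ncol(tab))
    names(tab)[1:6] <- c("query_id", "subject_id", "percent_identity",
                         "alignment_length", "evalue", "query_coverage")
  }
  validate_hits(tab)
}

#' Write a data.frame as a UTF-8 tab-separated table with header
#'
#' @param x data.frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a two-column leaf-to-class label map
#'
#' @param path tab-separated file with columns leaf, class (header optional).
#' @return named character vector: class keyed by leaf label.
#' @export
read_labels <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("^leaf\t", first)
  tab <- utils::read.delim(path, header = has_header,
                           stringsAsFactors = FALSE)
  if (!has_header) names(tab)[1:2] <- c("leaf", "class")
  stats::setNames(tab$class, tab$leaf)
}

#' Read a Newick tree
#' @param path file path.
#' @return an `ape` "phylo" object.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(suppressWarnings(ape::read.tree(path)),
                 error = function(e) stop("Newick parse error in ", path,
                                          ": ", conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error in ", path)
  tr
}

#' Write a tree in Newick format (branch lengths to 6 decimals)
#' @param tree "phylo" object.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}
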