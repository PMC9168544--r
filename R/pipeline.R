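# End-to-end orchestration: hit filtering -> profile screen -> triad
# classification, and alignment -> NJ -> midpoint root -> bootstrap ->
# HGT test. Configuration comes from an R list or a YAML file.

#' Read a pipeline configuration file (YAML)
#'
#' Unknown top-level keys are rejected to catch typos early.
#'
#' @param path YAML file.
#' @return named list of configuration values.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("fasta", "hits", "msa", "labels", "out_dir", "seed",
             "min_motifs", "enforce_order", "filter_mode", "score_threshold",
             "pseudocount", "bootstrap", "correction", "ingroup",
             "min_query_coverage", "max_evalue", "min_identity",
             "min_alignment_length")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg
}

#' Run the candidate-screening pipeline
#'
#' Executes the published screening order: threshold filtering of homology
#' hits, profile scoring of the sequences, then acidic-triad
#' classification. Any of the three inputs may be omitted; the
#' corresponding stage is skipped. Tables are written to `out_dir` when
#' given.
#'
#' @param fasta named character vector of sequences or FASTA path (for the
#'   profile and triad stages).
#' @param hits hit data.frame or TSV path (for the filter stage).
#' @param profile optional `profile_model`; when NULL and `msa` is given,
#'   one is built from `msa`.
#' @param msa optional aligned sequences used to build the profile.
#' @param config list of options: filter_mode, min_motifs, enforce_order,
#'   score_threshold, pseudocount (all optional).
#' @param out_dir optional output directory for TSV artifacts.
#' @return list(classification, survivors, candidates) - any stage not run
#'   is NULL.
#' @export
run_screen <- function(fasta = NULL, hits = NULL, profile = NULL, msa = NULL,
                       config = list(), out_dir = NULL) {
  getopt <- function(name, default) {
    if (!is.null(config[[name]])) config[[name]] else default
  }
  survivors <- NULL
  if (!is.null(hits)) {
    if (is.character(hits)) hits <- read_hits(hits)
    fc <- filter_config(getopt("filter_mode", "tblastn"))
    survivors <- filter_hits(hits, fc)
  }
  seqs <- NULL
  if (!is.null(fasta)) {
    seqs <- if (is.character(fasta) && length(fasta) == 1L &&
                is.null(names(fasta))) read_fasta(fasta) else fasta
    if (!length(seqs)) warning("empty sequence input; outputs will be empty")
  }
  candidates <- NULL
  if (!is.null(seqs) && (!is.null(profile) || !is.null(msa))) {
    if (is.null(profile))
      profile <- build_profile(msa, pseudocount = getopt("pseudocount", 1))
    candidates <- screen_candidates(seqs, profile,
                                    score_threshold = getopt("score_threshold", 0))
  }
  classification <- NULL
  if (!is.null(seqs)) {
    classification <- classify_collection(
      seqs, min_motifs = getopt("min_motifs", 2L),
      enforce_order = getopt("enforce_order", TRUE))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(survivors))
      write_tsv(survivors, file.path(out_dir, "surviving_hits.tsv"))
    if (!is.null(candidates))
      write_tsv(candidates, file.path(out_dir, "profile_candidates.tsv"))
    if (!is.null(classification)) {
      write_tsv(classification, file.path(out_dir, "triad_classification.tsv"))
      jsonlite::write_json(classification,
                           file.path(out_dir, "triad_classification.json"),
                           dataframe = "rows", auto_unbox = TRUE, digits = NA)
    }
  }
  list(classification = classification, survivors = survivors,
       candidates = candidates)
}

#' Run the phylogenetic pipeline
#'
#' Distance matrix -> neighbor joining -> midpoint rooting -> bootstrap
#' supports -> HGT topology test, writing the Newick tree (with supports as
#' internal node labels) and a JSON report when `out_dir` is given. The
#' report records that distances + NJ stand in for maximum-likelihood
#' inference.
#'
#' @param msa aligned sequences (named character vector or FASTA path).
#' @param labels named character vector tip -> class, or a two-column TSV
#'   path.
#' @param n_bootstrap bootstrap replicates (default 100).
#' @param seed RNG seed for the bootstrap (default 1).
#' @param correction distance correction (default "poisson").
#' @param ingroup class treated as the transferred clade (default "plant").
#' @param out_dir optional output directory.
#' @return list(tree, support, clade_test).
#' @export
run_phylo <- function(msa, labels, n_bootstrap = 100L, seed = 1L,
                      correction = "poisson", ingroup = "plant",
                      out_dir = NULL) {
  if (is.character(msa) && length(msa) == 1L && is.null(names(msa)))
    msa <- read_fasta(msa)
  if (length(msa) < 3L) stop("phylogenetic pipeline needs >= 3 sequences")
  if (is.character(labels) && length(labels) == 1L && is.null(names(labels)))
    labels <- read_labels(labels)
  bs <- bootstrap_support(msa, n_replicates = n_bootstrap, seed = seed,
                          correction = correction)
  rooted <- midpoint_root(bs$tree)
  ct <- hgt_consistency(rooted, labels, ingroup = ingroup)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_newick(rooted, file.path(out_dir, "tree_midpoint_rooted.nwk"))
    jsonlite::write_json(
      list(method = "p-distance/Poisson + neighbor joining (stand-in for ML)",
           n_bootstrap = n_bootstrap, seed = seed, correction = correction,
           ingroup = ingroup,
           monophyletic = ct$monophyletic, nesting = ct$nesting,
           support = ct$support, n_ingroup = ct$n_ingroup,
           n_outgroup = ct$n_outgroup),
      file.path(out_dir, "hgt_report.json"), auto_unbox = TRUE, digits = NA)
  }
  list(tree = rooted, support = bs$support, clade_test = ct)
}
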