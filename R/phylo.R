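# Distance-based phylogenetics: pairwise alignment, p-distances, neighbor
# joining, midpoint rooting, bootstrap support, and the HGT topology test.

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch alignment via Biostrings, returning the optimal score
#' and the percent identity over all alignment columns (gapped columns
#' count in the denominator).
#'
#' @param a,b protein sequences (non-empty strings).
#' @param substitution_matrix name of a built-in scoring matrix (default
#'   "BLOSUM62") or a numeric matrix.
#' @param gap_open,gap_extend positive gap penalties (default 10, 0.5).
#' @return list(score, identity, aligned_a, aligned_b).
#' @export
global_align <- function(a, b, substitution_matrix = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  list(score = Biostrings::score(aln),
       identity = Biostrings::pid(aln, type = "PID1"),
       aligned_a = as.character(Biostrings::alignedPattern(aln)),
       aligned_b = as.character(Biostrings::alignedSubject(aln)))
}

#' Pairwise distance matrix from an alignment
#'
#' p-distance over shared non-gap columns with pairwise deletion; the
#' Poisson correction transforms p to -ln(1 - p).
#'
#' @param msa named character vector (or AAStringSet) of equal-length
#'   aligned sequences.
#' @param correction "none" (p-distance) or "poisson".
#' @return symmetric numeric matrix with sequence names as dimnames.
#' @export
distance_matrix <- function(msa, correction = c("none", "poisson")) {
  correction <- match.arg(correction)
  nm <- names(msa)
  msa <- stats::setNames(as.character(msa), nm)
  if (length(msa) < 2L) stop("need at least 2 sequences")
  if (length(unique(nchar(msa))) != 1L) stop("ragged alignment")
  if (is.null(names(msa))) names(msa) <- paste0("s", seq_along(msa))
  mat <- do.call(rbind, strsplit(toupper(msa), "", fixed = TRUE))
  is_res <- !(mat == "-" | mat == ".")
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- is_res[i, ] & is_res[j, ]
      ns <- sum(shared)
      if (ns == 0L)
        stop(sprintf("no shared non-gap columns between '%s' and '%s'",
                     names(msa)[i], names(msa)[j]))
      p <- sum(mat[i, shared] != mat[j, shared]) / ns
      if (correction == "poisson") {
        if (p >= 1)
          stop(sprintf("saturated pair '%s'/'%s' (p = 1): Poisson distance undefined",
                       names(msa)[i], names(msa)[j]))
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic NJ agglomeration with two deterministic conventions: ties in the
#' Q criterion are broken by the lexicographically smallest pair of subtree
#' representative labels, and a negative branch length arising at a join is
#' clamped to 0 with the deficit shifted onto the sister branch so the pair
#' still spans their distance. Additive matrices are recovered exactly.
#'
#' @param D symmetric distance matrix with unique dimnames (or a `dist`).
#' @return unrooted "phylo" object; attribute `"clamped"` counts clamped
#'   branches.
#' @export
neighbor_joining <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  labels <- rownames(D)
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs at least 3 leaves")
  if (is.null(labels) || anyDuplicated(labels))
    stop("distance matrix needs unique row/column names")
  if (any(!is.finite(D)) || any(D < 0)) stop("distances must be finite and >= 0")
  if (any(abs(D - t(D)) > 1e-12)) stop("distance matrix must be symmetric")

  nwk <- labels            # growing Newick substrings per active node
  rep_lab <- labels        # representative (smallest) leaf label per node
  clamped <- 0L
  fmt <- function(x) sprintf("%.10f", x)

  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- paste(pmin(rep_lab[cand[, 1]], rep_lab[cand[, 2]]),
                 pmax(rep_lab[cand[, 1]], rep_lab[cand[, 2]]))
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]

    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0; clamped <- clamped + 1L }
    if (bj < 0) { bi <- bi + bj; bj <- 0; clamped <- clamped + 1L }
    bi <- max(bi, 0); bj <- max(bj, 0)

    newd <- (D[i, ] + D[j, ] - D[i, j]) / 2
    newd <- pmax(newd, 0)
    merged <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(bi), nwk[j], fmt(bj))
    merged_rep <- min(rep_lab[i], rep_lab[j])

    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    nwk <- c(nwk[keep], merged)
    rep_lab <- c(rep_lab[keep], merged_rep)
    dimnames(D) <- list(rep_lab, rep_lab)
  }

  # final three-node star: closed-form three-point branch lengths
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  for (b in c("b1", "b2", "b3")) {
    if (get(b) < 0) { assign(b, 0); clamped <- clamped + 1L }
  }
  text <- sprintf("(%s:%s,%s:%s,%s:%s);",
                  nwk[1], fmt(b1), nwk[2], fmt(b2), nwk[3], fmt(b3))
  tree <- ape::read.tree(text = text)
  attr(tree, "clamped") <- clamped
  tree
}

#' Midpoint-root a tree
#'
#' Places the root halfway along the longest leaf-to-leaf path. Leaf-to-leaf
#' path lengths are unchanged by rooting.
#'
#' @param tree "phylo" object (rooted or unrooted).
#' @return rooted "phylo" object.
#' @export
midpoint_root <- function(tree) {
  phangorn::midpoint(tree)
}

#' Bootstrap support for the bipartitions of an NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the
#' distance + NJ tree for each replicate, and reports, for every internal
#' node of the reference tree, the proportion of replicate trees containing
#' the corresponding bipartition. Reproducible for a fixed seed.
#'
#' @param msa named character vector of equal-length aligned sequences.
#' @param n_replicates number of bootstrap replicates (>= 1).
#' @param seed integer RNG seed.
#' @param correction distance correction passed to [distance_matrix()].
#' @return list(tree, support): the reference NJ tree with `node.label` set
#'   to supports, and the numeric support vector (one per internal node,
#'   in node-number order), values in [0, 1].
#' @export
bootstrap_support <- function(msa, n_replicates = 100L, seed = 1L,
                              correction = c("poisson", "none")) {
  correction <- match.arg(correction)
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  msa <- stats::setNames(as.character(msa), names(msa))
  ref <- neighbor_joining(distance_matrix(msa, correction))
  chars <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  rownames(chars) <- names(msa)
  L <- ncol(chars)
  boots <- vector("list", n_replicates)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    rep_msa <- apply(chars[, cols, drop = FALSE], 1, paste, collapse = "")
    boots[[b]] <- neighbor_joining(distance_matrix(rep_msa, correction))
  }
  counts <- ape::prop.clades(ref, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- counts / n_replicates
  ref$node.label <- format(support, digits = 3, trim = TRUE)
  list(tree = ref, support = support)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Test whether a taxon set is monophyletic
#'
#' TRUE iff some node of the rooted tree has exactly the query taxa as its
#' leaf set. A single taxon is trivially monophyletic.
#'
#' @param tree rooted "phylo" object.
#' @param taxa character vector of tip labels.
#' @return logical flag.
#' @export
is_monophyletic <- function(tree, taxa) {
  if (!all(taxa %in% tree$tip.label))
    stop("taxa not in tree: ",
         paste(setdiff(taxa, tree$tip.label), collapse = ", "))
  if (length(taxa) <= 1L) return(TRUE)
  if (length(taxa) == length(tree$tip.label)) return(TRUE)
  ape::is.monophyletic(tree, taxa)
}

#' Test the HGT nesting topology
#'
#' Evaluates the two topological conditions of a single
#' horizontal-gene-transfer origin of the ingroup (e.g. streptophyte
#' sequences) inside an outgroup radiation (e.g. bacterial sequences):
#' the ingroup must be monophyletic, and it must be *nested* - the
#' remaining (outgroup) leaves must not themselves form a single clade,
#' i.e. the ingroup is not merely the sister group of the whole radiation.
#'
#' @param rooted_tree rooted "phylo" object (midpoint-root first if needed).
#' @param labels named character vector mapping each tip label to a class.
#' @param ingroup class value marking the transferred clade (default
#'   "plant").
#' @return object of class `clade_test`: list(taxa, monophyletic, nesting,
#'   support, n_ingroup, n_outgroup).
#' @export
hgt_consistency <- function(rooted_tree, labels, ingroup = "plant") {
  tips <- rooted_tree$tip.label
  miss <- setdiff(tips, names(labels))
  if (length(miss))
    stop("unlabeled tips: ", paste(miss, collapse = ", "))
  taxa <- tips[labels[tips] == ingroup]
  other <- setdiff(tips, taxa)
  if (!length(taxa)) stop("no tips carry the ingroup label '", ingroup, "'")
  mono <- is_monophyletic(rooted_tree, taxa)
  nesting <- if (!length(other)) FALSE else !is_monophyletic(rooted_tree, other)
  support <- NA_real_
  if (mono && length(taxa) >= 2L && !is.null(rooted_tree$node.label)) {
    mrca <- ape::getMRCA(rooted_tree, taxa)
    lab <- rooted_tree$node.label[mrca - length(tips)]
    support <- suppressWarnings(as.numeric(lab))
  }
  structure(list(taxa = taxa, monophyletic = mono, nesting = nesting,
                 support = support, n_ingroup = length(taxa),
                 n_outgroup = length(other)),
            class = "clade_test")
}

#' @export
print.clade_test <- function(x, ...) {
  cat(sprintf(
    "<clade_test> %d ingroup / %d outgroup tips: monophyletic=%s, nested=%s (support %s)\n",
    x$n_ingroup, x$n_outgroup, x$monophyletic, x$nesting,
    ifelse(is.na(x$support), "NA", format(x$support))))
  invisible(x)
}
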