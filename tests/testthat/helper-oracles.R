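# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Element-by-element window check over every (start, gap_len) combination.
oracle_scan <- function(seq, pattern) {
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(s)
  has_gap <- any(vapply(pattern$elements, function(e) e$type == "gap", logical(1)))
  gaps <- if (has_gap) pattern$gap_range[1]:pattern$gap_range[2] else 0L
  rows <- list()
  for (g in gaps) {
    total <- pattern$fixed_length + g
    if (total > n) next
    for (start in 1:(n - total + 1L)) {
      pos <- start
      ok <- TRUE
      anchor_pos <- NA_integer_
      for (k in seq_along(pattern$elements)) {
        e <- pattern$elements[[k]]
        if (e$type == "gap") { pos <- pos + g; next }
        if (k == pattern$anchor_index) anchor_pos <- pos
        if (e$type == "class" && !(s[pos] %in% e$residues)) { ok <- FALSE; break }
        pos <- pos + 1L
      }
      if (ok)
        rows[[length(rows) + 1L]] <- data.frame(
          start = start, end = start + total - 1L,
          anchor_pos = anchor_pos, gap_len = g)
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(), end = integer(),
                      anchor_pos = integer(), gap_len = integer()))
  out <- do.call(rbind, rows)
  out[order(out$start, out$gap_len), , drop = FALSE]
}

# Exhaustive maximum ordered anchor chain over motif subsets.
oracle_best_chain <- function(anchor_lists) {
  m <- length(anchor_lists)
  best <- 0L
  for (k in m:1) {
    for (sub in utils::combn(m, k, simplify = FALSE)) {
      grids <- expand.grid(lapply(anchor_lists[sub], identity))
      if (!nrow(grids)) next
      if (ncol(grids) == 1L || any(apply(grids, 1, function(r) all(diff(r) > 0))))
        return(k)
    }
  }
  best
}

# Naive per-row predicate evaluation of the hit filters.
oracle_filter <- function(hits, mode = "tblastn") {
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    keep[i] <- if (mode == "tblastn") {
      h$query_coverage > 60 && h$evalue <= 1e-40 && h$percent_identity > 30
    } else {
      h$alignment_length > 175 && h$query_coverage > 30
    }
  }
  keep
}

# Leaf sets of every internal node, by recursive edge-matrix descent.
oracle_clade_sets <- function(tree) {
  n_tip <- length(tree$tip.label)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  leaves_under <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    unlist(lapply(children[[as.character(node)]], leaves_under))
  }
  lapply((n_tip + 1L):(n_tip + tree$Nnode), leaves_under)
}

oracle_monophyletic <- function(tree, taxa) {
  if (length(taxa) <= 1L) return(TRUE)
  sets <- oracle_clade_sets(tree)
  any(vapply(sets, function(s) setequal(s, taxa), logical(1)))
}

# Exhaustive global affine-gap alignment score by recursion over edit paths.
# Gap of length L costs gap_open + L * gap_extend (Biostrings convention).
oracle_align_score <- function(a, b, submat, gap_open, gap_extend) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  rec <- function(i, j, state) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      best <- max(best, submat[av[i], bv[j]] + rec(i + 1L, j + 1L, "m"))
    }
    if (i <= length(av)) {  # a-residue against gap
      pen <- if (state == "ga") gap_extend else gap_open + gap_extend
      best <- max(best, -pen + rec(i + 1L, j, "ga"))
    }
    if (j <= length(bv)) {  # b-residue against gap
      pen <- if (state == "gb") gap_extend else gap_open + gap_extend
      best <- max(best, -pen + rec(i, j + 1L, "gb"))
    }
    best
  }
  rec(1L, 1L, "m")
}

random_protein <- function(len) paste(sample(AA20, len, replace = TRUE),
                                      collapse = "")

# Deterministic instances of the three triad motifs, for hand-built cases.
M1_INSTANCE <- "WAPEYAG"
M2_INSTANCE <- "NDAKLPYPAGDAAAAAVMAF"
M3_INSTANCE <- "NATADAHP"
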