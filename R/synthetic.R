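# Seeded generators producing fixtures with the statistical structure the
# analysis assumes: motif-planted proteins, hit tables with controlled
# pass rates, HGT tree scenarios, alignments evolved on trees, and
# Michaelis-Menten assay data.

# Run code under a fixed seed without disturbing the caller's RNG stream,
# so every generator is a pure function of (parameters, seed).
with_seed <- function(seed, code) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  force(code)
}

sample_background <- function(n, freqs = NULL) {
  if (is.null(freqs)) {
    sample(AA_STANDARD, n, replace = TRUE)
  } else {
    sample(names(freqs), n, replace = TRUE, prob = freqs)
  }
}

# Deterministic largest-remainder allocation of n items to proportions.
allocate_counts <- function(n, props) {
  props <- props / sum(props)
  raw <- n * props
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(left)]
    counts[extra] <- counts[extra] + 1L
  }
  as.integer(counts)
}

# Instantiate one motif: returns list(chars, anchor_offset, gap_len).
instantiate_motif <- function(pattern, background_freqs = NULL) {
  chars <- character(0)
  anchor_offset <- NA_integer_
  gap_len <- 0L
  for (k in seq_along(pattern$elements)) {
    e <- pattern$elements[[k]]
    if (k == pattern$anchor_index) anchor_offset <- length(chars)
    if (e$type == "class") {
      chars <- c(chars, sample(e$residues, 1L))
    } else if (e$type == "wildcard") {
      chars <- c(chars, sample_background(1L, background_freqs))
    } else {
      gap_len <- if (e$min == e$max) e$min else
        sample(seq.int(e$min, e$max), 1L)
      if (gap_len > 0)
        chars <- c(chars, sample_background(gap_len, background_freqs))
    }
  }
  list(chars = chars, anchor_offset = anchor_offset, gap_len = gap_len)
}

#' Generate protein sequences with planted acidic-triad motifs
#'
#' Each sequence embeds exactly the motifs of its planted completeness
#' class, instantiated by drawing class residues uniformly and wildcard/gap
#' residues from the background, placed in M1 < M2 < M3 order at
#' non-overlapping positions with background-sampled spacers. Class counts
#' follow `completeness_mix` by deterministic largest-remainder allocation.
#' With `clean_background = TRUE` (the default) a sequence whose classified
#' completeness differs from its planted class (a chance background motif)
#' is redrawn, so the truth table matches the classifier output exactly;
#' disable it to measure spurious-call rates on pure background.
#'
#' @param n number of sequences.
#' @param completeness_mix proportions over completeness classes 3, 2, 1, 0
#'   (in that order; default equal).
#' @param length sequence length (default 500).
#' @param background_freqs optional named residue frequencies (default
#'   uniform over the 20 standard residues).
#' @param seed integer seed.
#' @param patterns compiled motifs (default [triad_motifs()]).
#' @param clean_background redraw sequences whose classified completeness
#'   deviates from the planted class (default TRUE).
#' @return list(sequences, truth): named character vector and a truth
#'   data.frame (seq_id, planted_completeness, planted_motifs, anchor
#'   positions per motif, seed).
#' @export
gen_triad_sequences <- function(n, completeness_mix = c(0.25, 0.25, 0.25, 0.25),
                                length = 500L, background_freqs = NULL,
                                seed = 1L, patterns = triad_motifs(),
                                clean_background = TRUE) {
  stopifnot(length(completeness_mix) == 4L, all(completeness_mix >= 0))
  max_len <- sum(vapply(patterns, function(p)
    p$fixed_length + p$gap_range[2], numeric(1)))
  if (length < max_len + length(patterns))
    stop("sequence length too short to host all planted motifs")
  counts <- allocate_counts(n, completeness_mix)
  classes <- rep(c(3L, 2L, 1L, 0L), counts)
  ids <- vapply(patterns, function(p) p$id, character(1))

  with_seed(seed, {
    seqs <- character(n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      k <- classes[i]
      planted_idx <- if (k == 0L) integer(0) else
        sort(sample(seq_along(patterns), k))
      for (attempt in seq_len(1000L)) {
        inst <- lapply(planted_idx, function(j)
          instantiate_motif(patterns[[j]], background_freqs))
        motif_len <- vapply(inst, function(x) length(x$chars), integer(1))
        spare <- length - sum(motif_len)
        # random spacer composition over k+1 slots
        cuts <- sort(sample.int(spare + 1L, k, replace = TRUE) - 1L)
        spacers <- diff(c(0L, cuts, spare))
        chars <- character(0)
        anchors <- rep(NA_integer_, length(patterns))
        for (m in seq_len(k)) {
          chars <- c(chars, sample_background(spacers[m], background_freqs))
          anchors[planted_idx[m]] <-
            length(chars) + inst[[m]]$anchor_offset + 1L
          chars <- c(chars, inst[[m]]$chars)
        }
        chars <- c(chars, sample_background(spacers[k + 1L], background_freqs))
        s <- paste(chars, collapse = "")
        if (!clean_background) break
        cl <- call_triad(s, patterns = patterns)
        if (cl$completeness == k) break
        if (attempt == 1000L)
          stop("failed to generate a clean sequence after 1000 attempts")
      }
      seqs[i] <- s
      truth[[i]] <- data.frame(
        seq_id = sprintf("seq%03d", i),
        planted_completeness = k,
        planted_motifs = paste(ids[planted_idx], collapse = ";"),
        stringsAsFactors = FALSE)
      for (j in seq_along(ids))
        truth[[i]][[paste0("anchor_", ids[j])]] <- anchors[j]
    }
    names(seqs) <- sprintf("seq%03d", seq_len(n))
    truth <- do.call(rbind, truth)
    truth$seed <- as.integer(seed)
    list(sequences = seqs, truth = truth)
  })
}

#' Generate a synthetic LPR1-like protein with triad anchors at fixed positions
#'
#' Constructs a single background-sampled protein carrying the three triad
#' motifs placed so their anchor residues sit exactly at the requested
#' coordinates (defaults: the E269/D370/D462 positions of Arabidopsis LPR1).
#' This is a *synthetic stand-in* for the real protein - it shares only the
#' motif signature and anchor coordinates, not the rest of the sequence -
#' and is intended for offline coordinate tests and examples. The sequence
#' is redrawn until the classifier reports exactly the planted anchors.
#'
#' @param anchors named integer vector of anchor positions for M1, M2, M3
#'   (default c(M1 = 269, M2 = 370, M3 = 462)).
#' @param anchor_residues residues planted at the anchors (default
#'   c(M1 = "E", M2 = "D", M3 = "D"), the acidic triad).
#' @param length total sequence length (default 580).
#' @param seed integer seed.
#' @param patterns compiled motifs (default [triad_motifs()]).
#' @return named character vector of length 1 (name
#'   "LPR1_like_synthetic").
#' @export
gen_lpr1_standin <- function(anchors = c(M1 = 269L, M2 = 370L, M3 = 462L),
                             anchor_residues = c(M1 = "E", M2 = "D", M3 = "D"),
                             length = 580L, seed = 7L,
                             patterns = triad_motifs()) {
  ids <- vapply(patterns, function(p) p$id, character(1))
  stopifnot(all(ids %in% names(anchors)), all(ids %in% names(anchor_residues)))
  for (j in seq_along(patterns)) {
    cls <- patterns[[j]]$elements[[patterns[[j]]$anchor_index]]$residues
    if (!(anchor_residues[[ids[j]]] %in% cls))
      stop("anchor residue for ", ids[j], " not in its anchored class")
  }
  with_seed(seed, {
    for (attempt in seq_len(1000L)) {
      inst <- lapply(patterns, instantiate_motif)
      starts <- vapply(seq_along(patterns), function(j)
        anchors[[ids[j]]] - inst[[j]]$anchor_offset, numeric(1))
      ends <- starts + vapply(inst, function(x)
        base::length(x$chars), integer(1)) - 1L
      if (any(starts < 1) || any(ends > length) ||
          any(utils::head(ends, -1) >= utils::tail(starts, -1)))
        stop("anchor positions too close to host the motifs")
      chars <- sample_background(length)
      for (j in seq_along(patterns)) {
        chars[starts[j]:ends[j]] <- inst[[j]]$chars
        chars[anchors[[ids[j]]]] <- anchor_residues[[ids[j]]]
      }
      s <- paste(chars, collapse = "")
      cl <- call_triad(s, patterns = patterns)
      if (cl$completeness == base::length(patterns) &&
          all(cl$anchors$pos == anchors[cl$anchors$motif])) break
      if (attempt == 1000L)
        stop("failed to generate a clean stand-in after 1000 attempts")
    }
    stats::setNames(s, "LPR1_like_synthetic")
  })
}

#' Generate a homology hit table with controlled per-criterion pass rates
#'
#' Each tblastn criterion (coverage, e-value, identity) independently
#' passes with its stated probability; passing and failing values are drawn
#' uniformly from the respective side of the published threshold.
#'
#' @param n number of hits.
#' @param pass_fractions numeric length 3: P(pass) for coverage, e-value,
#'   identity (default all 0.5).
#' @param seed integer seed.
#' @return list(hits, truth): a hit data.frame compatible with
#'   [filter_hits()] and a truth table with per-criterion flags and the
#'   overall pass indicator.
#' @export
gen_hit_table <- function(n, pass_fractions = c(0.5, 0.5, 0.5), seed = 1L) {
  stopifnot(length(pass_fractions) == 3L,
            all(pass_fractions >= 0 & pass_fractions <= 1))
  with_seed(seed, {
    pass_cov <- stats::runif(n) < pass_fractions[1]
    pass_eval <- stats::runif(n) < pass_fractions[2]
    pass_id <- stats::runif(n) < pass_fractions[3]
    coverage <- ifelse(pass_cov, stats::runif(n, 60, 100), stats::runif(n, 0, 60))
    evalue <- ifelse(pass_eval, 10^stats::runif(n, -100, -40),
                     10^stats::runif(n, -39.5, 0))
    identity <- ifelse(pass_id, stats::runif(n, 30, 100), stats::runif(n, 0, 30))
    hits <- data.frame(
      query_id = "LPR1",
      subject_id = sprintf("hit%05d", seq_len(n)),
      percent_identity = identity,
      alignment_length = round(stats::runif(n, 100, 600)),
      evalue = evalue,
      query_coverage = coverage,
      stringsAsFactors = FALSE)
    truth <- data.frame(
      subject_id = hits$subject_id,
      pass_coverage = pass_cov, pass_evalue = pass_eval,
      pass_identity = pass_id,
      pass_all = pass_cov & pass_eval & pass_id,
      seed = as.integer(seed),
      stringsAsFactors = FALSE)
    list(hits = hits, truth = truth)
  })
}

# Random bifurcating Newick over the given leaf Newick substrings;
# every created edge gets length branch_scale * runif(0.2, 1).
random_join <- function(parts, branch_scale) {
  while (length(parts) > 1L) {
    pick <- sample.int(length(parts), 2L)
    b <- branch_scale * stats::runif(2, 0.2, 1)
    merged <- sprintf("(%s:%.6f,%s:%.6f)", parts[pick[1]], b[1],
                      parts[pick[2]], b[2])
    parts <- c(parts[-pick], merged)
  }
  parts
}

#' Generate a rooted HGT scenario tree
#'
#' Builds a random bacterial backbone of `n_bacterial_clades` clades
#' (random topology within and between clades) and grafts a plant clade as
#' sister to one randomly chosen bacterial clade - an internal position,
#' never the backbone root - so the plant leaves are monophyletic and
#' nested within the bacterial radiation by construction.
#'
#' @param n_bacterial_clades number of bacterial clades (>= 2).
#' @param leaves_per_clade leaves in each bacterial clade.
#' @param n_plants number of plant leaves (>= 1).
#' @param branch_scale scale of branch lengths; each edge is
#'   `branch_scale * U(0.2, 1)` substitutions/site (default 0.3, keeping
#'   per-branch substitution probability below 0.3).
#' @param plant_scale relative branch scale of the plant crown (default
#'   0.5): the transferred clade radiated more recently than the bacterial
#'   backbone, which also keeps the midpoint root inside the radiation.
#' @param seed integer seed.
#' @return list(tree, labels, host_clade): rooted "phylo", named character
#'   vector tip -> "bacteria"/"plant", and the index of the bacterial clade
#'   the plant clade attaches next to.
#' @export
gen_hgt_scenario <- function(n_bacterial_clades = 4L, leaves_per_clade = 4L,
                             n_plants = 6L, branch_scale = 0.3,
                             plant_scale = 0.5, seed = 1L) {
  if (n_bacterial_clades < 2L) stop("need at least 2 bacterial clades")
  if (n_plants < 1L) stop("need at least 1 plant leaf")
  with_seed(seed, {
    clades <- vapply(seq_len(n_bacterial_clades), function(ci) {
      leaves <- sprintf("b%d_%d", ci, seq_len(leaves_per_clade))
      random_join(leaves, branch_scale)
    }, character(1))
    plant <- random_join(sprintf("p%d", seq_len(n_plants)),
                         branch_scale * plant_scale)
    host <- sample.int(n_bacterial_clades, 1L)
    b <- branch_scale * stats::runif(2, 0.2, 1)
    clades[host] <- sprintf("(%s:%.6f,%s:%.6f)", clades[host], b[1], plant, b[2])
    text <- paste0(random_join(clades, branch_scale), ";")
    tree <- ape::read.tree(text = text)
    labels <- stats::setNames(
      ifelse(grepl("^p", tree$tip.label), "plant", "bacteria"),
      tree$tip.label)
    list(tree = tree, labels = labels, host_clade = host)
  })
}

#' Evolve a gap-free alignment along a tree
#'
#' Independent sites under the 20-state equal-rates substitution process:
#' along a branch of length t each site is replaced, with probability
#' 1 - exp(-t), by a residue drawn uniformly from the 20 standard amino
#' acids (possibly the same one). Deterministic for a fixed seed.
#'
#' @param tree "phylo" object with branch lengths.
#' @param length number of sites.
#' @param root_seq optional root sequence string (length `length`).
#' @param seed integer seed.
#' @return named character vector of aligned tip sequences.
#' @export
evolve_msa <- function(tree, length, root_seq = NULL, seed = 1L) {
  n_tip <- length(tree$tip.label)
  with_seed(seed, {
    if (is.null(root_seq)) {
      root <- sample(AA_STANDARD, length, replace = TRUE)
    } else {
      root <- strsplit(toupper(root_seq), "", fixed = TRUE)[[1]]
      if (base::length(root) != length)
        stop("root_seq length does not match 'length'")
    }
    tree <- stats::reorder(tree, "cladewise")  # parents before children
    root_node <- n_tip + 1L
    seqs <- vector("list", n_tip + tree$Nnode)
    seqs[[root_node]] <- root
    for (e in seq_len(nrow(tree$edge))) {
      parent <- tree$edge[e, 1]
      child <- tree$edge[e, 2]
      t <- tree$edge.length[e]
      s <- seqs[[parent]]
      hit <- stats::runif(length) < (1 - exp(-t))
      if (any(hit)) s[hit] <- sample(AA_STANDARD, sum(hit), replace = TRUE)
      seqs[[child]] <- s
    }
    out <- vapply(seq_len(n_tip), function(i)
      paste(seqs[[i]], collapse = ""), character(1))
    stats::setNames(out, tree$tip.label)
  })
}

#' Generate Michaelis-Menten initial-rate data with multiplicative noise
#'
#' Velocities follow v = Vmax * S / (Km + S) * (1 + e) with
#' e ~ Normal(0, noise_cv); negative draws are clamped to 0. Rows at S = 0
#' are exactly 0.
#'
#' @param km_uM generating Michaelis constant (uM).
#' @param vmax generating maximal velocity.
#' @param S_grid substrate grid in uM (default 0-200 uM assay grid).
#' @param replicates replicates per substrate level (default 3).
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (default 0.05).
#' @param seed integer seed.
#' @return list(series, truth): a [rate_series()] and the generating
#'   parameters.
#' @export
gen_kinetics <- function(km_uM, vmax,
                         S_grid = c(0, 0.5, 1, 2, 5, 10, 25, 50, 100, 200),
                         replicates = 3L, noise_cv = 0.05, seed = 1L) {
  stopifnot(km_uM > 0, vmax > 0, noise_cv >= 0, replicates >= 1L)
  with_seed(seed, {
    S <- rep(S_grid, times = replicates)
    repl <- rep(seq_len(replicates), each = length(S_grid))
    mu <- vmax * S / (km_uM + S)
    v <- mu * (1 + stats::rnorm(length(S), 0, noise_cv))
    v[v < 0] <- 0
    list(series = rate_series(S, v, repl),
         truth = list(km_uM = km_uM, vmax = vmax, noise_cv = noise_cv,
                      S_grid = S_grid, replicates = replicates,
                      seed = as.integer(seed)))
  })
}
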