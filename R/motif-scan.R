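# Scanning sequences for compiled motifs and calling triad completeness.

empty_match_table <- function() {
  data.frame(seq_id = character(), motif_id = character(),
             start = integer(), end = integer(),
             anchor_pos = integer(), anchor_residue = character(),
             gap_len = integer(), is_acidic = logical(),
             stringsAsFactors = FALSE)
}

#' Scan a protein sequence with a compiled motif
#'
#' Reports every (start, gap length) combination that satisfies the pattern;
#' overlapping matches are all reported. Coordinates are 1-based with
#' inclusive ends, matching residue numbering conventions (E269 etc.).
#' Residue-class elements accept only their listed standard letters;
#' wildcard and gap positions accept any character, so ambiguity codes
#' (B, J, O, U, Z, X) never satisfy a specific class.
#'
#' @param seq protein sequence (single uppercase string).
#' @param pattern a `motif_pattern` from [compile_pattern()].
#' @param seq_id identifier recorded in the output (default `NA`).
#' @return data.frame with columns seq_id, motif_id, start, end, anchor_pos,
#'   anchor_residue, gap_len, is_acidic, sorted by (start, gap_len). Zero
#'   rows when nothing matches.
#' @export
scan_sequence <- function(seq, pattern, seq_id = NA_character_) {
  stopifnot(inherits(pattern, "motif_pattern"))
  if (!is.character(seq) || length(seq) != 1L)
    stop("seq must be a single string")
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(s)
  out <- list()
  gaps <- if (pattern$gap_range[2] > 0L || pattern$gap_range[1] > 0L) {
    seq.int(pattern$gap_range[1], pattern$gap_range[2])
  } else 0L
  has_gap <- any(vapply(pattern$elements, function(e) e$type == "gap", logical(1)))
  if (!has_gap) gaps <- 0L
  for (g in gaps) {
    total_len <- pattern$fixed_length + g
    if (total_len > n) next
    starts <- seq_len(n - total_len + 1L)
    ok <- rep(TRUE, length(starts))
    offset <- 0L
    anchor_offset <- NA_integer_
    for (k in seq_along(pattern$elements)) {
      e <- pattern$elements[[k]]
      if (e$type == "gap") {
        offset <- offset + g
        next
      }
      if (k == pattern$anchor_index) anchor_offset <- offset
      if (e$type == "class") {
        ok <- ok & (s[starts + offset] %in% e$residues)
      }
      offset <- offset + 1L
    }
    hit <- starts[ok]
    if (length(hit)) {
      apos <- hit + anchor_offset
      out[[length(out) + 1L]] <- data.frame(
        seq_id = seq_id, motif_id = pattern$id,
        start = hit, end = hit + total_len - 1L,
        anchor_pos = apos, anchor_residue = s[apos],
        gap_len = g, is_acidic = s[apos] %in% c("D", "E"),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_match_table())
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$gap_len), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Greedy-leftmost feasibility of a strictly increasing anchor chain over the
# given motif subset; returns chosen anchor positions or NULL.
chain_anchors <- function(anchor_lists, subset) {
  prev <- -Inf
  chosen <- integer(length(subset))
  for (i in seq_along(subset)) {
    cand <- anchor_lists[[subset[i]]]
    cand <- cand[cand > prev]
    if (!length(cand)) return(NULL)
    chosen[i] <- cand[1]
    prev <- chosen[i]
  }
  chosen
}

#' Call acidic-triad completeness for one sequence
#'
#' Scans the sequence with each motif and selects the maximum-cardinality
#' set of motifs whose anchor positions can be placed in strictly increasing
#' M1 < M2 < M3 order (when `enforce_order = TRUE`). Ties are broken by
#' preferring earlier motifs and leftmost anchors, so the call is
#' deterministic. A sequence is "considered" an LPR1-type candidate when it
#' covers at least `min_motifs` of the motifs.
#'
#' @param seq protein sequence string.
#' @param patterns ordered list of compiled motifs (default the three
#'   built-in triad motifs).
#' @param min_motifs minimum motif count for the considered flag (default 2).
#' @param enforce_order require anchors in motif order (default TRUE).
#' @param seq_id identifier carried into the call.
#' @return object of class `triad_call`: list with seq_id, matched_motifs,
#'   completeness (0-3), anchors (data.frame motif/pos/residue/is_acidic),
#'   ordered, label (complete, partial_2, partial_1, absent), considered,
#'   min_motifs.
#' @export
call_triad <- function(seq, patterns = triad_motifs(), min_motifs = 2L,
                       enforce_order = TRUE, seq_id = NA_character_) {
  if (!length(patterns))
    stop("patterns must contain at least one compiled motif")
  ids <- unname(vapply(patterns, function(p) p$id, character(1)))
  scans <- lapply(patterns, function(p) scan_sequence(seq, p, seq_id = seq_id))
  anchor_lists <- lapply(scans, function(m) sort(unique(m$anchor_pos)))

  m <- length(patterns)
  if (enforce_order) {
    best <- NULL
    # subsets by decreasing cardinality, then lexicographic motif order
    for (k in rev(seq_len(m))) {
      combos <- utils::combn(m, k, simplify = FALSE)
      for (sub in combos) {
        ch <- chain_anchors(anchor_lists, sub)
        if (!is.null(ch)) { best <- list(subset = sub, anchors = ch); break }
      }
      if (!is.null(best)) break
    }
    if (is.null(best)) best <- list(subset = integer(), anchors = integer())
  } else {
    present <- which(vapply(anchor_lists, length, integer(1)) > 0L)
    best <- list(subset = present,
                 anchors = vapply(anchor_lists[present], `[`, integer(1), 1L))
  }

  sub <- best$subset
  pos <- as.integer(best$anchors)
  residues <- if (length(pos)) {
    strsplit(seq, "", fixed = TRUE)[[1]][pos]
  } else character(0)
  anchors <- data.frame(motif = ids[sub], pos = pos, residue = residues,
                        is_acidic = residues %in% c("D", "E"),
                        stringsAsFactors = FALSE)
  completeness <- length(sub)
  label <- c("absent", "partial_1", "partial_2", "complete")[
    pmin(completeness, 3L) + 1L]
  structure(list(
    seq_id = seq_id,
    matched_motifs = ids[sub],
    completeness = completeness,
    anchors = anchors,
    ordered = enforce_order,
    label = label,
    considered = completeness >= min_motifs,
    min_motifs = as.integer(min_motifs)
  ), class = "triad_call")
}

#' @export
print.triad_call <- function(x, ...) {
  cat(sprintf("<triad_call> %s: %d/3 (%s), considered=%s\n",
              x$seq_id, x$completeness, x$label, x$considered))
  if (nrow(x$anchors))
    cat(paste(sprintf("  %s anchor %s%d", x$anchors$motif,
                      x$anchors$residue, x$anchors$pos), collapse = "\n"), "\n")
  invisible(x)
}

#' Report multicopper-oxidase copper-ligand hallmarks
#'
#' Scans a sequence for the configured T1 copper-site and T2/T3
#' copper-cluster signatures and reports all positions found.
#'
#' @param seq protein sequence string.
#' @param hallmark_patterns list with `t1` and `t23` components, each a list
#'   of `motif_pattern` objects (default [mco_hallmark_patterns()]).
#' @param seq_id identifier.
#' @return list (class `hallmark_report`) with seq_id, t1_site and
#'   t23_cluster (each list(found, positions)), patterns_used.
#' @export
detect_mco_hallmarks <- function(seq, hallmark_patterns = mco_hallmark_patterns(),
                                 seq_id = NA_character_) {
  scan_group <- function(pats) {
    pos <- integer(0)
    for (p in pats) {
      hits <- scan_sequence(seq, p, seq_id = seq_id)
      pos <- c(pos, hits$start)
    }
    pos <- sort(unique(pos))
    list(found = length(pos) > 0L, positions = pos)
  }
  structure(list(
    seq_id = seq_id,
    t1_site = scan_group(hallmark_patterns$t1),
    t23_cluster = scan_group(hallmark_patterns$t23),
    patterns_used = hallmark_patterns
  ), class = "hallmark_report")
}

#' Classify every sequence in a FASTA file or named vector
#'
#' Runs [call_triad()] on each sequence and tabulates completeness, label,
#' anchors and the considered flag, preserving input order.
#'
#' @param fasta path to a FASTA file (plain or gzip) or a named character
#'   vector of sequences.
#' @inheritParams call_triad
#' @return data.frame with one row per sequence: seq_id, completeness,
#'   label, anchors (compact `motif:pos:residue` string), considered, and
#'   per-motif anchor position columns. The full `triad_call` objects are
#'   attached as attribute `"calls"`.
#' @export
classify_collection <- function(fasta, patterns = triad_motifs(),
                                min_motifs = 2L, enforce_order = TRUE) {
  seqs <- if (is.character(fasta) && length(fasta) == 1L && is.null(names(fasta))) {
    read_fasta(fasta)
  } else fasta
  if (length(seqs) && (is.null(names(seqs)) || any(!nzchar(names(seqs)))))
    stop("all sequences must be named")
  dup <- unique(names(seqs)[duplicated(names(seqs))])
  if (length(dup))
    stop("duplicate sequence identifiers: ", paste(dup, collapse = ", "))

  ids <- vapply(patterns, function(p) p$id, character(1))
  calls <- lapply(seq_along(seqs), function(i)
    call_triad(seqs[[i]], patterns = patterns, min_motifs = min_motifs,
               enforce_order = enforce_order, seq_id = names(seqs)[i]))
  anchor_cols <- lapply(ids, function(id)
    vapply(calls, function(cl) {
      j <- match(id, cl$anchors$motif)
      if (is.na(j)) NA_integer_ else cl$anchors$pos[j]
    }, integer(1)))
  names(anchor_cols) <- paste0("anchor_", ids)
  tab <- data.frame(
    seq_id = vapply(calls, function(cl) cl$seq_id, character(1)),
    completeness = vapply(calls, function(cl) cl$completeness, integer(1)),
    label = vapply(calls, function(cl) cl$label, character(1)),
    anchors = vapply(calls, function(cl) {
      if (!nrow(cl$anchors)) return("")
      paste(sprintf("%s:%d:%s", cl$anchors$motif, cl$anchors$pos,
                    cl$anchors$residue), collapse = ";")
    }, character(1)),
    considered = vapply(calls, function(cl) cl$considered, logical(1)),
    stringsAsFactors = FALSE)
  tab <- cbind(tab, as.data.frame(anchor_cols))
  rownames(tab) <- NULL
  attr(tab, "calls") <- calls
  tab
}
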