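# Degenerate consensus-motif compiler for the LPR1-type acidic-triad signature.

AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Compile a degenerate consensus motif
#'
#' Parses a PROSITE-like consensus string into an element list that the
#' scanner understands. The grammar is: `[ABC]` a residue class, a single
#' uppercase letter a literal, `X` a wildcard, and `X(m-n)` a bounded
#' wildcard gap of length m to n. Each compiled pattern carries exactly one
#' *anchor* element, the residue class holding the acidic-triad residue.
#'
#' The anchor is auto-detected as the unique residue class drawn entirely
#' from \{D, E, G, A\} that contains at least one acidic residue (D or E).
#' This selects `[EA]`, `[DE]` and `[DEG]` in the three built-in motifs while
#' skipping classes such as `[DTS]` that merely contain an acidic letter.
#' Supply `anchor_index` to override the detection.
#'
#' @param spec consensus string, e.g. `"[WVI]XP[EA][YAF]X[GA]"`.
#' @param id motif identifier (default the spec string itself).
#' @param anchor_index optional element index to force as anchor.
#' @return an object of class `motif_pattern` with fields `id`, `elements`
#'   (list of `list(type, residues, min, max)`), `anchor_index`,
#'   `fixed_length` (number of single-residue elements), `gap_range`
#'   (c(min, max) or c(0, 0)), and `source_text`.
#' @examples
#' m1 <- compile_pattern("[WVI]XP[EA][YAF]X[GA]", id = "M1")
#' m1$anchor_index  # the [EA] element
#' @export
compile_pattern <- function(spec, id = spec, anchor_index = NULL) {
  if (!is.character(spec) || length(spec) != 1L || nchar(spec) == 0L)
    stop("pattern spec must be a single non-empty string")
  chars <- strsplit(spec, "", fixed = TRUE)[[1]]
  elements <- list()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      close <- NA_integer_
      j <- i + 1L
      while (j <= n) {
        if (chars[j] == "]") { close <- j; break }
        j <- j + 1L
      }
      if (is.na(close))
        stop(sprintf("unbalanced bracket at position %d in '%s'", i, spec))
      cls <- chars[(i + 1L):(close - 1L)]
      cls <- cls[cls != ""]
      if (close == i + 1L || length(cls) == 0L)
        stop(sprintf("empty residue class at position %d in '%s'", i, spec))
      bad <- setdiff(cls, AA_STANDARD)
      if (length(bad))
        stop(sprintf("non-standard letter '%s' in class at position %d of '%s'",
                     bad[1], i, spec))
      elements[[length(elements) + 1L]] <-
        list(type = "class", residues = unique(cls), min = 1L, max = 1L)
      i <- close + 1L
    } else if (ch == "X") {
      # possible gap X(m-n)
      if (i < n && chars[i + 1L] == "(") {
        close <- NA_integer_
        j <- i + 2L
        while (j <= n) {
          if (chars[j] == ")") { close <- j; break }
          j <- j + 1L
        }
        if (is.na(close))
          stop(sprintf("unbalanced parenthesis at position %d in '%s'", i + 1L, spec))
        body <- paste(chars[(i + 2L):(close - 1L)], collapse = "")
        parts <- strsplit(body, "-", fixed = TRUE)[[1]]
        if (length(parts) != 2L || anyNA(suppressWarnings(as.integer(parts))))
          stop(sprintf("malformed gap specifier 'X(%s)' in '%s'", body, spec))
        mn <- as.integer(parts[1]); mx <- as.integer(parts[2])
        if (mn < 0L || mx < 0L || mn > mx)
          stop(sprintf("invalid gap bounds %d-%d (need 0 <= min <= max) in '%s'",
                       mn, mx, spec))
        elements[[length(elements) + 1L]] <-
          list(type = "gap", residues = NULL, min = mn, max = mx)
        i <- close + 1L
      } else {
        elements[[length(elements) + 1L]] <-
          list(type = "wildcard", residues = NULL, min = 1L, max = 1L)
        i <- i + 1L
      }
    } else if (ch %in% LETTERS) {
      if (!(ch %in% AA_STANDARD))
        stop(sprintf("non-standard literal '%s' at position %d in '%s'", ch, i, spec))
      elements[[length(elements) + 1L]] <-
        list(type = "class", residues = ch, min = 1L, max = 1L)
      i <- i + 1L
    } else {
      stop(sprintf("unexpected character '%s' at position %d in '%s'", ch, i, spec))
    }
  }
  if (length(elements) == 0L)
    stop(sprintf("pattern '%s' compiled to zero elements", spec))
  n_gap <- sum(vapply(elements, function(e) e$type == "gap", logical(1)))
  if (n_gap > 1L)
    stop(sprintf("pattern '%s' has %d gap elements; at most one is supported",
                 spec, n_gap))

  if (is.null(anchor_index)) {
    is_candidate <- vapply(elements, function(e) {
      e$type == "class" &&
        all(e$residues %in% c("D", "E", "G", "A")) &&
        any(e$residues %in% c("D", "E"))
    }, logical(1))
    if (sum(is_candidate) == 0L)
      stop(sprintf("no candidate anchor element (acidic class) in '%s'", spec))
    if (sum(is_candidate) > 1L)
      stop(sprintf("multiple candidate anchor elements in '%s'; supply anchor_index",
                   spec))
    anchor_index <- which(is_candidate)
  } else {
    anchor_index <- as.integer(anchor_index)
    if (anchor_index < 1L || anchor_index > length(elements) ||
        elements[[anchor_index]]$type != "class")
      stop("anchor_index must point at a residue-class element")
  }

  gap_el <- which(vapply(elements, function(e) e$type == "gap", logical(1)))
  gap_range <- if (length(gap_el)) {
    c(elements[[gap_el]]$min, elements[[gap_el]]$max)
  } else c(0L, 0L)

  structure(list(
    id = id,
    elements = elements,
    anchor_index = anchor_index,
    fixed_length = sum(vapply(elements, function(e)
      if (e$type == "gap") 0L else 1L, integer(1))),
    gap_range = gap_range,
    source_text = spec
  ), class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("<motif_pattern> %s: %s (%d elements, anchor at %d, gap %d-%d)\n",
              x$id, x$source_text, length(x$elements), x$anchor_index,
              x$gap_range[1], x$gap_range[2]))
  invisible(x)
}

#' Built-in acidic-triad consensus motifs
#'
#' The three degenerate motifs that flank the acidic triad of LPR1-type
#' ferroxidases (E269, D370, D462 in Arabidopsis LPR1 coordinates). M2's
#' `X(5-10)` linker separates the central anchor aspartate from the
#' conserved C-terminal block.
#'
#' @return named list of three compiled `motif_pattern` objects M1, M2, M3.
#' @export
triad_motifs <- function() {
  list(
    M1 = compile_pattern("[WVI]XP[EA][YAF]X[GA]", id = "M1"),
    M2 = compile_pattern("N[DTS][AG]XXP[YF]PXG[DE]X(5-10)[VI][ML]XF", id = "M2"),
    M3 = compile_pattern("NXTX[DEG]XHP", id = "M3")
  )
}

#' Default multicopper-oxidase copper-ligand hallmark patterns
#'
#' Generic His-rich signatures of the mononuclear T1 copper site
#' (H-C-H spacing of the ligating histidines/cysteine) and the trinuclear
#' T2/T3 cluster (tandem H-X-H pairs). These defaults are a pragmatic
#' extension for flagging MCO-like sequences; callers screening a specific
#' family should supply their own patterns.
#'
#' @return list with components `t1` and `t23`, each a list of
#'   `motif_pattern` objects (anchors forced to a His element).
#' @export
mco_hallmark_patterns <- function() {
  list(
    t1 = list(compile_pattern("HCHX(2-4)H", id = "T1", anchor_index = 1L)),
    t23 = list(compile_pattern("HXHX(1-6)HXH", id = "T23", anchor_index = 1L))
  )
}
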