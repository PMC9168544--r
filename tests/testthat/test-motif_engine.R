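# Motif compiler, scanner and triad caller.

test_that("consensus strings compile to the expected element structure", {
  m1 <- compile_pattern("[WVI]XP[EA][YAF]X[GA]", id = "M1")
  expect_length(m1$elements, 7)
  expect_equal(m1$fixed_length, 7)
  expect_equal(m1$anchor_index, 4)
  expect_equal(sort(m1$elements[[4]]$residues), c("A", "E"))

  m2 <- compile_pattern("N[DTS][AG]XXP[YF]PXG[DE]X(5-10)[VI][ML]XF", id = "M2")
  expect_equal(m2$fixed_length, 15)
  expect_equal(m2$gap_range, c(5L, 10L))
  expect_equal(m2$elements[[m2$anchor_index]]$residues, c("D", "E"))

  m3 <- compile_pattern("NXTX[DEG]XHP", id = "M3")
  expect_length(m3$elements, 8)
  expect_equal(m3$anchor_index, 5)
})

test_that("malformed pattern strings are rejected with informative errors", {
  expect_error(compile_pattern("[WVI"), "unbalanced bracket")
  expect_error(compile_pattern("A[]C[DE]"), "empty residue class")
  expect_error(compile_pattern("[DE]X(7-3)A"), "gap bounds")
  expect_error(compile_pattern("AXP"), "no candidate anchor")
  expect_error(compile_pattern("[DE]X[DE]"), "multiple candidate anchor")
  expect_error(compile_pattern("[D1E]"), "non-standard")
})

test_that("scanning finds planted motif instances at the right coordinates", {
  m <- triad_motifs()
  hit1 <- scan_sequence("AAWAPEYAGAA", m$M1)
  expect_equal(nrow(hit1), 1)
  expect_equal(hit1$start, 3)
  expect_equal(hit1$end, 9)
  expect_equal(hit1$anchor_pos, 6)
  expect_equal(hit1$anchor_residue, "E")

  hit2 <- scan_sequence("NDAKLPYPAGDAAAAAVMAF", m$M2)
  expect_equal(nrow(hit2), 1)
  expect_equal(hit2[, c("start", "end", "gap_len", "anchor_pos")],
               data.frame(start = 1L, end = 20L, gap_len = 5L,
                          anchor_pos = 11L))
  expect_equal(hit2$anchor_residue, "D")

  for (p in m) expect_equal(nrow(scan_sequence("KKKKKK", p)), 0)
})

test_that("scanner matches the brute-force window oracle on random sequences", {
  set.seed(101)
  motifs <- triad_motifs()
  for (rep in 1:150) {
    len <- sample(5:60, 1)
    # bias composition toward motif letters so matches actually occur
    seq <- paste(sample(c(AA20, "W", "P", "E", "Y", "G", "N", "T", "H", "D"),
                        len, replace = TRUE), collapse = "")
    for (p in motifs) {
      got <- scan_sequence(seq, p)
      want <- oracle_scan(seq, p)
      expect_equal(nrow(got), nrow(want))
      if (nrow(got)) {
        expect_equal(got$start, want$start)
        expect_equal(got$gap_len, want$gap_len)
        expect_equal(got$anchor_pos, want$anchor_pos)
        # anchor soundness: reported residue is in the anchored class
        cls <- p$elements[[p$anchor_index]]$residues
        expect_true(all(got$anchor_residue %in% cls))
      }
    }
  }
})

test_that("ambiguity codes satisfy wildcards but never residue classes", {
  m1 <- triad_motifs()$M1
  expect_equal(nrow(scan_sequence("WXPEYXG", m1)), 1)  # X at wildcards fine
  expect_equal(nrow(scan_sequence("XAPEYAG", m1)), 0)  # X at [WVI] class
  expect_equal(nrow(scan_sequence("WAPZYAG", m1)), 0)  # Z at [EA] class
})

test_that("triad calls select the maximal ordered motif chain", {
  m <- triad_motifs()
  pad <- function(...) paste0(..., collapse = "")

  s12 <- pad("KK", M1_INSTANCE, "KKK", M3_INSTANCE, "KK")
  cl <- call_triad(s12, m)
  expect_equal(cl$completeness, 2)
  expect_equal(cl$label, "partial_2")
  expect_true(cl$considered)
  expect_equal(cl$matched_motifs, c("M1", "M3"))

  s123 <- pad("K", M1_INSTANCE, "K", M2_INSTANCE, "K", M3_INSTANCE)
  cl3 <- call_triad(s123, m)
  expect_equal(cl3$completeness, 3)
  expect_equal(cl3$label, "complete")
  expect_true(all(diff(cl3$anchors$pos) > 0))

  # M3 before M1: ordered chain of size 1 only
  s31 <- pad("K", M3_INSTANCE, "KKK", M1_INSTANCE, "K")
  # M1 anchor sits after M3 anchor, so with order enforced only one survives
  cl31 <- call_triad(s31, m, enforce_order = TRUE)
  expect_equal(cl31$completeness,
               oracle_best_chain(list(
                 sort(scan_sequence(s31, m$M1)$anchor_pos),
                 sort(scan_sequence(s31, m$M2)$anchor_pos),
                 sort(scan_sequence(s31, m$M3)$anchor_pos))))
  cl31_free <- call_triad(s31, m, enforce_order = FALSE)
  expect_equal(cl31_free$completeness, 2)

  expect_error(call_triad("AAAA", list()), "at least one")
})

test_that("chain selection equals the exhaustive chain oracle on random cases", {
  set.seed(77)
  m <- triad_motifs()
  parts <- c(M1 = M1_INSTANCE, M2 = M2_INSTANCE, M3 = M3_INSTANCE)
  for (rep in 1:40) {
    k <- sample(0:3, 1)
    order_idx <- sample(3, k)  # deliberately scrambled order
    seq <- paste(c(random_protein(10),
                   unlist(lapply(order_idx, function(i)
                     c(parts[i], random_protein(6))))), collapse = "")
    cl <- call_triad(seq, m)
    anchor_lists <- lapply(m, function(p)
      sort(scan_sequence(seq, p)$anchor_pos))
    expect_equal(cl$completeness, oracle_best_chain(anchor_lists))
  }
})

test_that("completeness is monotone under motif deletion and insertion", {
  gen <- gen_triad_sequences(15, c(0.4, 0.3, 0.3, 0), length = 300, seed = 11)
  for (i in seq_along(gen$sequences)) {
    s <- gen$sequences[[i]]
    before <- call_triad(s)$completeness
    # appending a fresh downstream motif instance never lowers the call
    expect_gte(call_triad(paste0(s, "KK", M3_INSTANCE))$completeness, before)
    # overwriting the planted M1 with lysines never raises it
    a1 <- gen$truth$anchor_M1[i]
    if (!is.na(a1)) {
      chars <- strsplit(s, "")[[1]]
      chars[max(1, a1 - 3):min(length(chars), a1 + 3)] <- "K"
      expect_lte(call_triad(paste(chars, collapse = ""))$completeness, before)
    }
  }
})

test_that("hallmark detection reports all planted copies and nothing on poly-A", {
  hp <- mco_hallmark_patterns()
  t1_inst <- "HCHAAH"
  t23_inst <- "HAHAAHAH"
  s <- paste0("KKK", t1_inst, "KK", t23_inst, "KKK", t23_inst)
  rep1 <- detect_mco_hallmarks(s, hp)
  expect_true(rep1$t1_site$found)
  expect_equal(rep1$t1_site$positions, 4)
  expect_true(rep1$t23_cluster$found)
  # both planted copies are reported (the elastic gap may add bridges)
  expect_true(all(c(12, 23) %in% rep1$t23_cluster$positions))
  polyA <- strrep("A", 50)
  rep2 <- detect_mco_hallmarks(polyA, hp)
  expect_false(rep2$t1_site$found)
  expect_false(rep2$t23_cluster$found)
})

test_that("collection classification recovers planted classes and flags rows", {
  gen <- gen_triad_sequences(20, c(0.25, 0.25, 0.25, 0.25), length = 400,
                             seed = 7)
  tab <- classify_collection(gen$sequences)
  expect_equal(nrow(tab), 20)
  expect_equal(tab$seq_id, gen$truth$seq_id)  # input order preserved
  expect_equal(unname(table(factor(tab$label, levels = c(
    "complete", "partial_2", "partial_1", "absent")))),
    rep(5L, 4), ignore_attr = TRUE)
  expect_equal(tab$completeness, gen$truth$planted_completeness)
  expect_equal(tab$considered, tab$completeness >= 2)

  tab3 <- classify_collection(gen$sequences, min_motifs = 3)
  expect_equal(sum(tab3$considered), 5)

  dup <- gen$sequences[c(1, 1, 2)]
  expect_error(classify_collection(dup), "duplicate")

  empty <- classify_collection(character(0))
  expect_equal(nrow(empty), 0)
  expect_true(all(c("seq_id", "completeness", "label", "considered")
                  %in% names(empty)))
})

test_that("decoy-only classification agrees with the brute-force oracle", {
  gen <- gen_triad_sequences(30, c(0, 0, 0, 1), length = 300, seed = 13,
                             clean_background = FALSE)
  tab <- classify_collection(gen$sequences)
  m <- triad_motifs()
  oracle_cpl <- vapply(gen$sequences, function(s)
    oracle_best_chain(lapply(m, function(p) oracle_scan(s, p)$anchor_pos)),
    integer(1))
  expect_equal(tab$completeness, unname(oracle_cpl))
})

test_that("identical inputs yield byte-identical classifications", {
  gen <- gen_triad_sequences(8, seed = 5, length = 300)
  t1 <- classify_collection(gen$sequences)
  t2 <- classify_collection(gen$sequences)
  attr(t1, "calls") <- attr(t2, "calls") <- NULL
  expect_identical(t1, t2)
})
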