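# Alignment, distances, NJ, rooting, bootstrap, monophyly, HGT test.

test_that("global alignment scores identical sequences at 100% identity", {
  al <- global_align("HEAG", "HEAG")
  expect_equal(al$identity, 100)
  expect_equal(al$aligned_a, al$aligned_b)
  a <- "WKDEF"; b <- "WKEF"
  expect_equal(global_align(a, b)$score, global_align(b, a)$score)
  expect_error(global_align("", "AC"), "non-empty")
})

test_that("alignment scores match exhaustive path enumeration on tiny pairs", {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  set.seed(15)
  for (rep in 1:12) {
    a <- random_protein(sample(2:5, 1))
    b <- random_protein(sample(2:5, 1))
    got <- global_align(a, b, gap_open = 10, gap_extend = 0.5)$score
    want <- oracle_align_score(a, b, BLOSUM62, 10, 0.5)
    expect_equal(got, want)
  }
})

test_that("p-distances and Poisson correction match hand computation", {
  d <- distance_matrix(c(a = "AAAA", b = "AAAC"), "none")
  expect_equal(d["a", "b"], 0.25)
  dp <- distance_matrix(c(a = "AAAA", b = "AAAC"), "poisson")
  expect_equal(dp["a", "b"], -log(0.75))
  expect_equal(distance_matrix(c(a = "WKDE", b = "WKDE"))["a", "b"], 0)

  # pairwise deletion: gapped columns drop out per pair
  dg <- distance_matrix(c(a = "A-AA", b = "ACAC"), "none")
  expect_equal(dg["a", "b"], 1 / 3)
  expect_error(distance_matrix(c(a = "--AA", b = "CC--")), "shared")

  set.seed(4)
  msa <- setNames(vapply(1:5, function(i) random_protein(40), character(1)),
                  letters[1:5])
  D <- distance_matrix(msa)
  expect_equal(D, t(D))
  expect_equal(diag(D), setNames(rep(0, 5), letters[1:5]))
})

test_that("neighbor joining recovers additive matrices exactly", {
  true <- ape::read.tree(text = "((a:1,b:2):1.5,(c:0.5,d:1):1);")
  D <- ape::cophenetic.phylo(true)
  nj <- neighbor_joining(D)
  expect_equal(ape::dist.topo(ape::unroot(true), nj), 0, ignore_attr = TRUE)
  expect_equal(ape::cophenetic.phylo(nj)[rownames(D), colnames(D)], D,
               tolerance = 1e-9)

  # larger random additive matrices round-trip too, matching ape's NJ topology
  set.seed(31)
  for (rep in 1:5) {
    tr <- ape::rtree(8)
    D8 <- ape::cophenetic.phylo(tr)
    nj8 <- neighbor_joining(D8)
    expect_equal(ape::cophenetic.phylo(nj8)[rownames(D8), colnames(D8)], D8,
                 tolerance = 1e-9)
    expect_equal(ape::dist.topo(nj8, ape::nj(D8)), 0, ignore_attr = TRUE)
  }
})

test_that("three leaves resolve by the closed-form three-point formulas", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  expect_equal(sort(tr$tip.label), c("a", "b", "c"))
  cp <- ape::cophenetic.phylo(tr)
  expect_equal(cp[rownames(D), colnames(D)], D)
  expect_error(neighbor_joining(D[1:2, 1:2]), "at least 3")
})

test_that("NJ output is invariant to the row order of the matrix", {
  set.seed(8)
  tr <- ape::rtree(7)
  D <- ape::cophenetic.phylo(tr)
  perm <- sample(7)
  t1 <- neighbor_joining(D)
  t2 <- neighbor_joining(D[perm, perm])
  expect_equal(ape::dist.topo(t1, t2), 0, ignore_attr = TRUE)
  expect_equal(ape::cophenetic.phylo(t2)[rownames(D), colnames(D)],
               ape::cophenetic.phylo(t1)[rownames(D), colnames(D)],
               tolerance = 1e-9)
})

test_that("midpoint rooting halves the longest path and preserves distances", {
  two <- ape::read.tree(text = "(a:1,b:3);")
  r2 <- midpoint_root(two)
  depths <- ape::node.depth.edgelength(r2)
  expect_equal(sort(depths[1:2]), c(2, 2))

  # long pendant branch pulls the root onto itself
  cat_tree <- ape::read.tree(text = "(((a:0.1,b:0.1):0.1,c:0.1):0.1,z:5);")
  rc <- midpoint_root(cat_tree)
  dz <- ape::node.depth.edgelength(rc)[match("z", rc$tip.label)]
  diam <- max(ape::cophenetic.phylo(cat_tree))
  expect_equal(dz, diam / 2)

  set.seed(12)
  tr <- ape::rtree(9)
  rt <- midpoint_root(tr)
  expect_equal(ape::cophenetic.phylo(rt)[tr$tip.label, tr$tip.label],
               ape::cophenetic.phylo(tr)[tr$tip.label, tr$tip.label],
               tolerance = 1e-9)
  d <- ape::node.depth.edgelength(rt)[seq_along(rt$tip.label)]
  expect_equal(max(d), max(ape::cophenetic.phylo(tr)) / 2)
})

test_that("bootstrap supports are reproducible, bounded and exact on clean data", {
  # block-structured alignment: 20 columns split a/b groups, 20 columns of
  # private variation -> the group bipartition survives every resample
  grpA <- c("a1", "a2", "a3", "a4"); grpB <- c("b1", "b2", "b3", "b4")
  base <- function(tag, i) paste0(strrep(tag, 20),
                                  strrep(LETTERS[i + 2], 20))
  msa <- setNames(c(vapply(1:4, function(i) base("A", i), character(1)),
                    vapply(1:4, function(i) base("W", i + 4), character(1))),
                  c(grpA, grpB))
  bs <- bootstrap_support(msa, n_replicates = 50, seed = 9, correction = "none")
  expect_true(all(bs$support >= 0 & bs$support <= 1))
  expect_equal(bs$support[1], 1)  # root bipartition (all taxa) always present
  rooted <- midpoint_root(bs$tree)
  expect_true(is_monophyletic(rooted, grpA))
  ct <- hgt_consistency(rooted, setNames(
    ifelse(grepl("^a", names(msa)), "plant", "bacteria"), names(msa)),
    ingroup = "plant")
  expect_equal(ct$support, 1)

  bs2 <- bootstrap_support(msa, n_replicates = 50, seed = 9, correction = "none")
  expect_identical(bs$support, bs2$support)
  expect_identical(ape::write.tree(bs$tree), ape::write.tree(bs2$tree))

  one <- bootstrap_support(msa, n_replicates = 1, seed = 2, correction = "none")
  expect_true(all(one$support %in% c(0, 1)))
  expect_error(bootstrap_support(msa, 0), "n_replicates")
})

test_that("monophyly testing equals leaf-set enumeration on random trees", {
  expect_true(is_monophyletic(
    ape::read.tree(text = "((p1,p2),(b1,b2));"), c("p1", "p2")))
  expect_false(is_monophyletic(
    ape::read.tree(text = "((p1,b1),(p2,b2));"), c("p1", "p2")))
  expect_error(is_monophyletic(
    ape::read.tree(text = "((p1,p2),(b1,b2));"), c("p1", "zz")), "not in tree")

  set.seed(19)
  for (rep in 1:20) {
    tr <- ape::rtree(8)
    taxa <- sample(tr$tip.label, sample(1:7, 1))
    expect_equal(is_monophyletic(tr, taxa), oracle_monophyletic(tr, taxa))
  }
})

test_that("the HGT test distinguishes nested, sister and two-origin topologies", {
  sc <- gen_hgt_scenario(seed = 3)
  ct <- hgt_consistency(sc$tree, sc$labels)
  expect_true(ct$monophyletic)
  expect_true(ct$nesting)

  two_origin <- ape::read.tree(text = "((p1,b1),(p2,b2));")
  lab <- setNames(c("plant", "bacteria", "plant", "bacteria"),
                  c("p1", "b1", "p2", "b2"))
  ct2 <- hgt_consistency(two_origin, lab)
  expect_false(ct2$monophyletic)

  sister <- ape::read.tree(text = "((p1:1,p2:1):1,(b1:1,(b2:1,b3:1):1):1);")
  lab3 <- setNames(c("plant", "plant", "bacteria", "bacteria", "bacteria"),
                   c("p1", "p2", "b1", "b2", "b3"))
  ct3 <- hgt_consistency(sister, lab3)
  expect_true(ct3$monophyletic)
  expect_false(ct3$nesting)

  expect_error(hgt_consistency(sister, lab3[-1]), "unlabeled")
  expect_error(hgt_consistency(sister, setNames(rep("x", 5), names(lab3))),
               "ingroup")
})
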