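# p-distances, neighbor-joining against closed forms and the exhaustive
# topology + least-squares oracle, branch support, and set assignment.

test_that("p-distance follows its definition and complete deletion", {
  expect_equal(p_distance_matrix(c(a = "ACGTACGTAC", b = "ACGTACGTAC"))$d[1, 2], 0)
  pd <- p_distance_matrix(c(a = "ACGTACGTAC", b = "ACGTACGTAT"))
  expect_equal(pd$d[1, 2], 0.1)
  expect_equal(pd$positions_used, 10L)

  # 12 columns, gaps in 2 of them: distances computed over 10
  aln <- c(x = "ACGTACGTACGT", y = "AC-TACGTACGA", z = "ATGTACG-ACGA")
  # retained columns: 1,2,4,5,6,7,9,10,11,12
  pd2 <- p_distance_matrix(aln)
  expect_equal(pd2$positions_used, 10L)
  expect_equal(pd2$d["x", "y"], 1 / 10)   # column 12
  expect_equal(pd2$d["x", "z"], 2 / 10)   # columns 2 and 12
  expect_equal(pd2$d["y", "z"], 1 / 10)   # column 2

  expect_error(p_distance_matrix(c(a = "---", b = "AC-")), "all alignment")

  # symmetry, zero diagonal and range on random alignments; agreement
  # with the reference raw-distance implementation on gap-free input
  set.seed(12)
  for (i in 1:5) {
    aln3 <- vapply(1:5, function(k) random_dna_str(60), "")
    names(aln3) <- paste0("s", 1:5)
    pd3 <- p_distance_matrix(aln3)
    expect_equal(pd3$d, t(pd3$d))
    expect_true(all(diag(pd3$d) == 0))
    expect_true(all(pd3$d >= 0 & pd3$d <= 1))
    ref <- as.matrix(ape::dist.dna(ape::as.DNAbin(
      do.call(rbind, strsplit(tolower(aln3), ""))), model = "raw"))
    expect_equal(unname(pd3$d), unname(ref[rownames(pd3$d), colnames(pd3$d)]),
                 tolerance = 1e-12)
  }
})

test_that("three-taxon neighbor joining matches the closed form", {
  D <- matrix(c(0, .2, .4, .2, 0, .4, .4, .4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["A"]], 0.1)
  expect_equal(bl[["B"]], 0.1)
  expect_equal(bl[["C"]], 0.3)

  set.seed(31)
  for (i in 1:25) {
    d12 <- runif(1); d13 <- runif(1); d23 <- runif(1)
    D <- matrix(c(0, d12, d13, d12, 0, d23, d13, d23, 0), 3, 3,
                dimnames = list(letters[1:3], letters[1:3]))
    tr <- neighbor_joining(D)
    bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
    expect_equal(bl[["a"]], (d12 + d13 - d23) / 2, tolerance = 1e-10)
    expect_equal(bl[["b"]], (d12 + d23 - d13) / 2, tolerance = 1e-10)
    expect_equal(bl[["c"]], (d13 + d23 - d12) / 2, tolerance = 1e-10)
  }
})

test_that("additive matrices are recovered exactly up to six taxa", {
  skip_if_not_installed("phangorn")
  for (n in 4:6) {
    for (rep_i in 1:4) {
      gen <- random_additive_matrix(n, seed = 1000L * n + rep_i)
      tr <- neighbor_joining(gen$D)
      # path metric reproduced exactly
      C <- ape::cophenetic.phylo(tr)
      expect_equal(C[rownames(gen$D), colnames(gen$D)], gen$D,
                   tolerance = 1e-9)
      # topology identical to the generating tree
      expect_true(ape::dist.topo(ape::unroot(tr), ape::unroot(gen$tree)) == 0)
      # exhaustive enumeration + least squares finds the same topology
      # with zero residual
      oracle <- oracle_best_topology(gen$D)
      expect_lt(oracle$rss, 1e-12)
      expect_true(ape::dist.topo(ape::unroot(tr),
                                 ape::unroot(oracle$tree)) == 0)
    }
  }
})

test_that("neighbor joining agrees with the reference implementation", {
  set.seed(41)
  for (i in 1:5) {
    n <- sample(4:8, 1L)
    D <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
    v <- runif(n * (n - 1) / 2, 0.05, 1)
    D[lower.tri(D)] <- v
    D <- D + t(D)
    ours <- neighbor_joining(D)
    ref <- ape::nj(as.dist(D))
    expect_true(ape::dist.topo(ape::unroot(ours), ape::unroot(ref)) == 0)
    expect_equal(sum(ours$edge.length), sum(ref$edge.length),
                 tolerance = 1e-8)
  }
})

test_that("degenerate and invalid inputs are handled", {
  D0 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighbor_joining(D0)
  expect_equal(sum(tr$edge.length), 0)
  Dns <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 3, 0, 1, 1, 2, 0), 3, 3)),
               "symmetric")
})

test_that("two divergent clades of identical sequences get full support", {
  set.seed(51)
  blockA <- random_dna_str(200)
  blockB <- paste(rev(strsplit(random_dna_str(200), "")[[1L]]), collapse = "")
  while (blockB == blockA) blockB <- random_dna_str(200)
  aln <- c(setNames(rep(blockA, 5), paste0("a", 1:5)),
           setNames(rep(blockB, 5), paste0("b", 1:5)))
  # tiny within-clade noise so the clades resolve
  substr(aln[["a1"]], 1, 1) <- "N"
  tr <- branch_support(aln, replicates = 100L, seed = 8L)
  supp <- tr$node.label
  expect_true(any(supp[!is.na(supp)] == 100))
})

test_that("branch support is reproducible and input-order invariant", {
  set.seed(61)
  base <- random_dna_str(120)
  aln <- vapply(1:6, function(i) {
    s <- strsplit(base, "")[[1L]]
    idx <- sample(120, 12)
    s[idx] <- sample(c("A", "C", "G", "T"), 12, replace = TRUE)
    paste(s, collapse = "")
  }, "")
  names(aln) <- paste0("t", 1:6)
  t1 <- branch_support(aln, replicates = 50L, seed = 9L)
  t2 <- branch_support(aln, replicates = 50L, seed = 9L)
  expect_identical(t1$node.label, t2$node.label)
  t3 <- branch_support(rev(aln), replicates = 50L, seed = 9L)
  expect_identical(ape::write.tree(t1), ape::write.tree(t3))
  expect_error(branch_support(aln, replicates = 0L), "replicates")
})

test_that("feature tuples map to their sets, with 5/8 and 4/6 ambiguous", {
  feat <- function(cdr1, res57, w107, deleted = FALSE) {
    structure(list(cdr1_length = cdr1, residue_57 = res57, trp_107 = w107,
                   qxs_motif = TRUE, yfc_motif = TRUE, leader_length = 20L,
                   cdr2_deleted = deleted, post104_extension = 4L),
              class = "v_features")
  }
  expect_equal(assign_trdv1_set(feat(7L, "G", "absent"))$set_id, 1L)
  expect_equal(assign_trdv1_set(feat(9L, "E", "present"))$set_id, 3L)
  expect_equal(assign_trdv1_set(feat(9L, "E", "absent"))$set_id, 3L)
  expect_equal(assign_trdv1_set(feat(9L, "N", "absent"))$set_id, 6L)
  expect_equal(assign_trdv1_set(feat(5L, "A", "present"))$set_id, 7L)
  expect_equal(assign_trdv1_set(feat(10L, "V", "present"))$set_id, 7L)
  expect_equal(assign_trdv1_set(feat(7L, "N", "present"))$set_id, 10L)
  expect_equal(assign_trdv1_set(feat(7L, NA, "present", deleted = TRUE))$set_id, 9L)

  amb58 <- assign_trdv1_set(feat(9L, "Y", "present"))
  expect_equal(amb58$evidence, "ambiguous")
  expect_setequal(amb58$candidate_sets, c(5L, 8L))
  amb46 <- assign_trdv1_set(feat(9L, "Y", "absent"))
  expect_equal(amb46$evidence, "ambiguous")
  expect_setequal(amb46$candidate_sets, c(4L, 6L))

  # per-gene exceptions
  expect_equal(assign_trdv1_set(feat(8L, "Y", "present"),
                                gene = "TRDV1t")$set_id, 2L)
  expect_equal(assign_trdv1_set(feat(18L, NA, "present", deleted = TRUE),
                                gene = "TRDV1o")$set_id, 9L)
  expect_equal(assign_trdv1_set(feat(9L, "Y", "absent"),
                                gene = "TRDV1d")$set_id, 5L)

  # purity: repeated calls agree
  f <- feat(9L, "Y", "present")
  expect_identical(assign_trdv1_set(f), assign_trdv1_set(f))
})

test_that("a tree resolves feature ties through the smallest shared clade", {
  # gene g sits inside the set-5 reference clade
  txt <- "(((g:1,TRDV1aj:1):1,TRDV1ap:1):2,((TRDV1ad:1,TRDV1p:1):1,TRDV1x:1):2,out:4);"
  tree <- ape::read.tree(text = txt)
  feat <- structure(list(cdr1_length = 9L, residue_57 = "Y",
                         trp_107 = "present", qxs_motif = TRUE,
                         yfc_motif = TRUE, leader_length = 20L,
                         cdr2_deleted = FALSE, post104_extension = 4L),
                    class = "v_features")
  asg <- assign_trdv1_set(feat, tree = tree, gene = "g")
  expect_equal(asg$set_id, 5L)
  expect_equal(asg$evidence, "tree-resolved")
  expect_setequal(asg$candidate_sets, c(5L, 8L))
})
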