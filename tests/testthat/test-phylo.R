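test_that("alignment distances use pairwise deletion and JC69", {
  m <- rbind(a = c("A", "A", "A", "A"), b = c("A", "A", "A", "A"))
  expect_equal(msa_distances(m)["a", "b"], 0)
  m <- rbind(a = c("A", "A", "A", "A"), b = c("A", "A", "A", "T"))
  expect_equal(msa_distances(m, "p-distance")["a", "b"], 0.25)
  expect_equal(msa_distances(m, "JC69")["a", "b"], -0.75 * log(2 / 3),
               tolerance = 1e-12)  # ~0.3041
  # gaps/ambiguity sites are deleted pairwise
  m <- rbind(a = c("A", "-", "A", "A"), b = c("A", "A", "N", "T"))
  expect_equal(msa_distances(m, "p-distance")["a", "b"], 0.5)
  m <- rbind(a = c("-", "-"), b = c("A", "A"))
  expect_error(msa_distances(m), "no comparable sites.*a.*b")
  m <- rbind(a = c("A", "C", "G", "T"), b = c("C", "G", "T", "A"))
  expect_error(msa_distances(m, "JC69"), ">= 0.75")
})

test_that("three taxa are joined by the closed-form branch lengths", {
  d <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  expect_equal(sort(tr$tip.label), c("a", "b", "c"))
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[c("a", "b", "c")], c(a = 0, b = 2, c = 3))
})

test_that("neighbor joining needs at least three taxa", {
  d <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(nj_tree(d), "at least 3")
})

test_that("additive matrices are recovered exactly, matching ape's NJ", {
  skip_if_not_installed("phangorn")
  bgclineage:::with_seed(21, {
    for (rep in 1:25) {
      tr <- random_bl_tree(sample(5:8, 1))
      d <- stats::cophenetic(tr)
      out <- nj_tree(d)
      expect_equal(rf_distance(out, tr), 0)
      # branch lengths of an additive matrix are reproduced
      expect_equal(max(abs(stats::cophenetic(out)[rownames(d), colnames(d)]
                           - d)), 0, tolerance = 1e-9)
      # independent implementations agree on the topology
      ref <- ape::nj(d)
      expect_equal(rf_distance(out, ref), 0)
      expect_equal(as.integer(phangorn::RF.dist(ape::unroot(out),
                                                ape::unroot(ref))), 0)
    }
  })
})

test_that("taxon order does not change the inferred topology", {
  bgclineage:::with_seed(5, {
    tr <- random_bl_tree(6)
    d <- stats::cophenetic(tr)
    perm <- sample(rownames(d))
    expect_equal(rf_distance(nj_tree(d), nj_tree(d[perm, perm])), 0)
  })
})

test_that("Robinson-Foulds distance behaves as a topology metric", {
  t1 <- ape::read.tree(text = "((a,b),(c,d));")
  t2 <- ape::read.tree(text = "((a,c),(b,d));")
  star5 <- ape::read.tree(text = "(a,b,c,d,e);")
  full5 <- ape::read.tree(text = "((a,b),(c,d),e);")
  expect_equal(rf_distance(t1, t1), 0)
  expect_equal(rf_distance(t1, t2), 2)  # the two resolved quartets differ
  expect_equal(rf_distance(star5, full5), 2)
  expect_equal(rf_distance(full5, star5), rf_distance(star5, full5))
  expect_error(rf_distance(t1, full5), "leaf sets")
  # triangle inequality, spot-checked on random trees
  skip_if_not_installed("phangorn")
  bgclineage:::with_seed(31, {
    for (rep in 1:10) {
      ts <- lapply(1:3, function(i) ape::rtree(7))
      labs <- ts[[1]]$tip.label
      ts <- lapply(ts, function(t) {
        t$tip.label <- labs
        t
      })
      d12 <- rf_distance(ts[[1]], ts[[2]])
      d23 <- rf_distance(ts[[2]], ts[[3]])
      d13 <- rf_distance(ts[[1]], ts[[3]])
      expect_lte(d13, d12 + d23)
      expect_equal(d12, as.integer(phangorn::RF.dist(ape::unroot(ts[[1]]),
                                                     ape::unroot(ts[[2]]))))
    }
  })
})

test_that("bootstrap supports are reproducible and bounded", {
  tr <- ingroup_tree()
  aln <- simulate_alignment(tr, 2000, seed = 8)
  # resampled columns can give slightly negative NJ branch lengths, which
  # are clamped with a warning by design
  b1 <- suppressWarnings(bootstrap_support(aln, replicates = 50, seed = 42))
  b2 <- suppressWarnings(bootstrap_support(aln, replicates = 50, seed = 42))
  expect_identical(attr(b1, "support"), attr(b2, "support"))
  expect_true(all(attr(b1, "support") >= 0 & attr(b1, "support") <= 100))
  # a single replicate can only give 0 or 100
  b3 <- bootstrap_support(aln, replicates = 1, seed = 1)
  expect_true(all(attr(b3, "support") %in% c(0, 100)))
  # long alignments with consistent signal give uniformly high support
  aln_long <- simulate_alignment(tr, 10000, seed = 9)
  b4 <- bootstrap_support(aln_long, replicates = 100, seed = 7)
  expect_gte(min(attr(b4, "support")), 95)
})

test_that("outgroup rooting places the root on the pendant edge", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,c:2,o:4);")
  rooted <- root_with_outgroup(tr, "o")
  expect_true(ape::is.rooted(rooted))
  root_edges <- which(rooted$edge[, 1] == length(rooted$tip.label) + 1)
  expect_equal(sort(rooted$edge.length[root_edges]), c(2, 2))
  # rooting then unrooting restores the topology
  expect_equal(rf_distance(ape::unroot(rooted), tr), 0)
  # pruning the outgroup keeps the ingroup leaf set
  pruned <- root_with_outgroup(tr, "o", prune = TRUE)
  expect_setequal(pruned$tip.label, c("a", "b", "c"))
  expect_error(root_with_outgroup(tr, "zz"), "not a leaf")
})
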