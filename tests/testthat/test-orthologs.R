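test_that("domain similarity is normalized edit distance over kinds", {
  a <- parse_domain_string("C/A/T")
  expect_equal(domain_similarity(a, a), 1.0)
  expect_equal(domain_similarity(a, parse_domain_string("KS/AT/ACP")), 0.0)
  ten <- parse_domain_string("C/A/T-C/A/T-C/A/T-TE")
  one_sub <- parse_domain_string("C/A/T-C/A/T-KS/A/T-TE")
  expect_equal(domain_similarity(ten, one_sub), 0.9)
})

test_that("edit distance agrees with an independent oracle", {
  kinds <- c("C", "A", "T", "E", "MT", "KS", "AT", "DH", "ER", "KR", "ACP")
  letters_of <- stats::setNames(letters[seq_along(kinds)], kinds)
  bgclineage:::with_seed(11, {
    for (rep in 1:50) {
      x <- sample(kinds, sample(1:12, 1), replace = TRUE)
      y <- sample(kinds, sample(1:12, 1), replace = TRUE)
      expect_equal(bgclineage:::edit_distance(x, y),
                   as.integer(utils::adist(
                     paste(letters_of[x], collapse = ""),
                     paste(letters_of[y], collapse = ""))))
    }
  })
})

test_that("fixture clusters group into the published 32 pathways", {
  groups <- group_orthologs(fixture_inv())
  expect_length(groups, 32)
  sh <- classify_sharing(groups, STRAINS)
  expect_equal(sh$universal, 9)
  expect_equal(sh$partial, 8)
  expect_equal(sh$specific, 15)
  expect_equal(unname(sh$specific_by_strain), c(2, 4, 1, 2, 6))
  # every curated pathway id survives as one group
  expect_setequal(vapply(groups, function(g) g$group_id, ""),
                  unique(fixture_table()$cluster_id))
})

test_that("the pure accession+similarity criterion merges one paralog pair", {
  # pks-3 and pks-12 share a closest homolog and an identical domain
  # organization; only the curated row alignment keeps them apart
  groups <- group_orthologs(fixture_inv(), respect_curated_ids = FALSE)
  expect_length(groups, 31)
  merged <- Filter(function(g) "pks-3" %in% vapply(g$members, function(m)
    m$cluster_id, ""), groups)[[1]]
  expect_setequal(vapply(merged$members, function(m) m$cluster_id, ""),
                  c("pks-3", "pks-3", "pks-3", "pks-12"))
})

test_that("grouping is invariant to strain input order", {
  inv <- fixture_inv()
  perm <- inv[rev(seq_along(inv))]
  class(perm) <- class(inv)
  g1 <- group_orthologs(inv)
  g2 <- group_orthologs(perm)
  key <- function(gs) sort(vapply(gs, function(g)
    paste(sort(paste(names(g$members), vapply(g$members, function(m)
      m$cluster_id, ""))), collapse = ";"), ""))
  expect_equal(key(g1), key(g2))
})

test_that("presence matrix sums are consistent with the groups", {
  groups <- group_orthologs(fixture_inv())
  m <- presence_matrix(groups, STRAINS)
  expect_equal(nrow(m), 32)
  expect_equal(rowSums(m), vapply(groups, function(g)
    length(g$members), 1), ignore_attr = TRUE)
  expect_equal(unname(colSums(m)), c(15, 17, 15, 15, 18))
  expect_equal(sum(m), 80)
})

test_that("same accession below the similarity threshold is not linked", {
  mk <- function(strain, id, dom, acc) {
    g <- structure(list(orf_id = paste0(id, "-o1"), strain_id = strain,
                        cluster_id = id, tokens = parse_domain_string(dom),
                        partial_start = FALSE, partial_end = FALSE,
                        length_lower_bound = FALSE,
                        homolog_accession = acc), class = "bgc_gene")
    bgclineage:::new_cluster(id, strain, list(g))
  }
  inv <- structure(list(
    s1 = structure(list(strain_id = "s1",
                        clusters = list(a = mk("s1", "a", "C/A/T", "X1"))),
                   class = "bgc_inventory"),
    s2 = structure(list(strain_id = "s2",
                        clusters = list(b = mk("s2", "b",
                                               "C/A/T-C/A/T-C/A/T", "X1"))),
                   class = "bgc_inventory")), class = "bgc_inventory_set")
  expect_length(group_orthologs(inv, threshold = 0.8,
                                respect_curated_ids = FALSE), 2)
  # identical organizations with the same accession do link
  inv$s2$clusters$b <- mk("s2", "b", "C/A/T", "X1")
  expect_length(group_orthologs(inv, threshold = 0.8,
                                respect_curated_ids = FALSE), 1)
})

test_that("a strain contributing two clusters to one component errors", {
  mk <- function(strain, id) {
    g <- structure(list(orf_id = paste0(id, "-o1"), strain_id = strain,
                        cluster_id = id,
                        tokens = parse_domain_string("C/A/T"),
                        partial_start = FALSE, partial_end = FALSE,
                        length_lower_bound = FALSE,
                        homolog_accession = "X1"), class = "bgc_gene")
    bgclineage:::new_cluster(id, strain, list(g))
  }
  inv <- structure(list(
    s1 = structure(list(strain_id = "s1",
                        clusters = list(a = mk("s1", "a"),
                                        b = mk("s1", "b"))),
                   class = "bgc_inventory"),
    s2 = structure(list(strain_id = "s2",
                        clusters = list(c = mk("s2", "c"))),
                   class = "bgc_inventory")), class = "bgc_inventory_set")
  expect_error(group_orthologs(inv, respect_curated_ids = FALSE),
               "conflict.*s1")
})
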