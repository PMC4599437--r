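fixture_backbone <- function(strain, cluster_id)
  predict_backbone(fixture_assembly(strain, cluster_id))

test_that("peptide products are read off the assembly line", {
  expect_equal(backbone_product_string(
    fixture_backbone("H_cretacea", "nrps-1")), "x-Ser-mOrn-x-Ser-x")
  expect_equal(backbone_product_string(
    fixture_backbone("H_cretacea", "nrps-4")), "x-Lys-Asp")
  expect_equal(backbone_product_string(
    fixture_backbone("H_yilanensis", "nrps-9")), "Gly-Asn-x-Lys-Thr-x")
  expect_equal(backbone_product_string(
    fixture_backbone("H_cretacea", "pks/nrps-1")), "?-pk-x")
  expect_equal(backbone_product_string(
    fixture_backbone("H_yilanensis", "pks/nrps-3")), "Leu-Val-Leu-Ser-pk")
  # one-module identity
  g <- structure(list(orf_id = "o1", tokens = parse_domain_string(
    "C/A_gly/T"), partial_start = FALSE, partial_end = FALSE,
    length_lower_bound = FALSE), class = "bgc_gene")
  cl <- bgclineage:::new_cluster("mini", "s", list(g))
  expect_equal(backbone_product_string(
    predict_backbone(segment_modules(cl))), "Gly")
})

test_that("modifier domains decorate residues without altering them", {
  bb <- fixture_backbone("H_cretacea", "nrps-1")
  mt <- vapply(bb$units, function(u) u$n_methylated, TRUE)
  expect_equal(which(mt), c(1, 3))  # MT in modules 1 and 3; mOrn printed
  expect_true(bb$units[[6]]$epimerized)
  # epimerization never changes the printed residue
  expect_false(grepl("D", backbone_product_string(bb), fixed = TRUE))
})

test_that("unit count equals counted module count on every cluster", {
  inv <- fixture_inv()
  for (strain in STRAINS) for (cl in inv[[strain]]$clusters) {
    asm <- suppressWarnings(segment_modules(cl))
    bb <- predict_backbone(asm)
    expect_length(bb$units, count_modules(asm)$total)
  }
})

test_that("the beta-keto state is a pure function of the KR/DH/ER subset", {
  expected <- function(kr, dh, er) {
    if (kr && dh && er) "methylene"
    else if (kr && dh) "enoyl"
    else if (kr) "hydroxyl"
    else "ketone"  # DH or ER without KR is non-functional
  }
  for (kr in c(FALSE, TRUE)) for (dh in c(FALSE, TRUE))
    for (er in c(FALSE, TRUE)) {
      kinds <- c("KS", "AT", if (dh) "DH", if (er) "ER", if (kr) "KR", "ACP")
      expect_equal(bgclineage:::beta_state(kinds), expected(kr, dh, er))
    }
})

test_that("polyketide feature counts match the printed chemistry", {
  # heptaketide, C14 chain, four conjugated double bonds, one fully reduced
  s <- summarize_chemistry(fixture_backbone("H_mongoliensis", "pks-2"))
  expect_equal(s$chain_carbons, 14)
  expect_equal(s$double_bonds, 4)
  expect_equal(s$fully_reduced, 1)
  # hexaketide with 2 C-C double bonds and one hydroxyl (DH without KR inert)
  s <- summarize_chemistry(fixture_backbone("H_cretacea", "pks-7"))
  expect_equal(s$double_bonds, 2)
  expect_equal(s$hydroxyls, 1)
  # 21 modules, 6 double bonds, 11 hydroxyls
  s <- summarize_chemistry(fixture_backbone("H_mongoliensis", "pks-8"))
  expect_equal(s$double_bonds, 6)
  expect_equal(s$hydroxyls, 11)
  # nonaketide, 3 conjugated double bonds, 5 hydroxyls (first module is the
  # starter: its KR is not expressed)
  s <- summarize_chemistry(fixture_backbone("H_mongoliensis", "pks-9"))
  expect_equal(s$double_bonds, 3)
  expect_equal(s$hydroxyls, 5)
})

test_that("unreduced minimal modules give ketones only", {
  g <- structure(list(orf_id = "o1", tokens = parse_domain_string(
    "KS/AT/ACP-KS/AT/ACP-KS/AT/ACP"), partial_start = FALSE,
    partial_end = FALSE, length_lower_bound = FALSE), class = "bgc_gene")
  cl <- bgclineage:::new_cluster("mini-pks", "s", list(g))
  s <- summarize_chemistry(predict_backbone(segment_modules(cl)))
  expect_equal(s$ketones, 2)  # module 1 is the starter
  expect_equal(s$hydroxyls, 0)
  expect_equal(s$double_bonds, 0)
})

test_that("the 22-residue peptide has the printed composition", {
  s <- summarize_chemistry(fixture_backbone("H_daliensis", "nrps-12"))
  comp <- as.list(s$residue_composition)
  expect_equal(comp[c("Phe", "Asp", "Ser", "Val", "Tyr", "Asn", "x")],
               list(Phe = 2L, Asp = 7L, Ser = 1L, Val = 1L, Tyr = 3L,
                    Asn = 1L, x = 7L))
})

test_that("clusters without a collinear backbone are flagged", {
  for (x in list(c("H_cretacea", "nrps-7"), c("H_cretacea", "nrps-11"),
                 c("H_sakaeratensis", "nrps-16"), c("H_cretacea", "pks-3"),
                 c("H_mongoliensis", "pks-10"),
                 c("H_sakaeratensis", "pks-12"),
                 c("H_yilanensis", "pks-4"))) {
    expect_false(fixture_backbone(x[1], x[2])$predictable)
  }
  expect_true(fixture_backbone("H_cretacea", "nrps-1")$predictable)
})

test_that("linear notation renders thioester SMILES and residue strings", {
  # acetyl starter + one unreduced malonyl extension = 3-oxobutanethioate
  g <- structure(list(orf_id = "o1", tokens = parse_domain_string(
    "KS/AT/ACP-KS/AT/ACP"), partial_start = FALSE, partial_end = FALSE,
    length_lower_bound = FALSE), class = "bgc_gene")
  cl <- bgclineage:::new_cluster("diketide", "s", list(g))
  bb <- predict_backbone(segment_modules(cl))
  expect_equal(backbone_to_linear_notation(bb), "CC(=O)CC(=O)S")

  expect_equal(backbone_to_linear_notation(
    fixture_backbone("H_cretacea", "nrps-5")), "Gly-Asp")

  # backbone carbons in the emitted SMILES equal chain_carbons
  bb <- fixture_backbone("H_mongoliensis", "pks-2")
  expect_error(backbone_to_linear_notation(bb), "position.*5, 6")
  sm <- backbone_to_linear_notation(bb, ambiguous = "first")
  backbone_c <- nchar(gsub("[^C]", "", gsub("\\([^)]*\\)", "", sm)))
  expect_equal(backbone_c, bb$chain_carbons)
})
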