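# shared fixtures: the packaged inventory and species tree, loaded once

STRAINS <- c("H_cretacea", "H_mongoliensis", "H_yilanensis", "H_daliensis",
             "H_sakaeratensis")

.fixture_cache <- new.env(parent = emptyenv())

fixture_inv <- function() {
  if (is.null(.fixture_cache$inv))
    .fixture_cache$inv <- load_cluster_table(bgc_example_table())
  .fixture_cache$inv
}

fixture_table <- function() {
  if (is.null(.fixture_cache$tab))
    .fixture_cache$tab <- utils::read.delim(bgc_example_table(),
                                            comment.char = "#",
                                            colClasses = "character")
  .fixture_cache$tab
}

ingroup_tree <- function() {
  if (is.null(.fixture_cache$tree)) {
    full <- ape::read.tree(bgc_example_tree())
    .fixture_cache$tree <- root_with_outgroup(full, "A_corrugata",
                                              prune = TRUE)
  }
  .fixture_cache$tree
}

fixture_assembly <- function(strain, cluster_id) {
  suppressWarnings(segment_modules(find_cluster(fixture_inv(), strain,
                                                cluster_id)))
}

# random rooted tree with branch lengths, for additivity/simulation tests
random_bl_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.5)
  tr
}
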