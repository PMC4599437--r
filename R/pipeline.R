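# End-to-end orchestration: parse -> segment -> predict -> group -> tree ->
# gain/loss, with a machine-readable report.

#' Run the full cluster-inventory analysis
#'
#' Executes every stage of the pipeline on a cluster-inventory table:
#' per-strain cluster counts, assembly-line segmentation and module counts,
#' backbone prediction, ortholog grouping with sharing classes, species-tree
#' acquisition (a supplied Newick, or neighbor joining on a supplied
#' alignment) and Dollo gain/loss mapping of every ortholog group. All
#' exclusions (single-domain genes, segmentation warnings) are logged in the
#' report.
#'
#' @param config a named list or path to a JSON file with fields:
#'   `cluster_table` (TSV path; default the packaged inventory), `tree`
#'   (Newick path) and/or `msa` (FASTA path; used when no tree is given),
#'   `outgroup` (leaf to root on and prune), `threshold` (ortholog
#'   similarity threshold, default 0.8), `bootstrap` (replicates when
#'   building from an alignment, default 0), `seed` (default 1).
#' @param out_dir optional directory; when given, writes `report.json`,
#'   `groups.tsv`, `products.tsv`, `events.tsv` and `tree.nwk`.
#' @return the report: per-strain counts, module counts and predicted
#'   products per cluster, ortholog groups with sharing classes, the tree
#'   (Newick string), per-branch event table and per-group classification,
#'   plus the thresholds/seeds used and the stage log.
#' @export
run_analysis <- function(config = list(), out_dir = NULL) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  table_path <- config$cluster_table %||% bgc_example_table()
  threshold <- config$threshold %||% 0.8
  seed <- config$seed %||% 1
  bootstrap <- config$bootstrap %||% 0

  inventories <- load_cluster_table(table_path)
  strains <- names(inventories)
  counts <- inventory_summary(inventories)

  log <- character()
  assemblies <- list()
  products <- list()
  for (inv in inventories) for (cl in inv$clusters) {
    asm <- withCallingHandlers(
      segment_modules(cl),
      warning = function(w) {
        log <<- c(log, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    log <- c(log, asm$log)
    key <- paste(inv$strain_id, cl$cluster_id, sep = "/")
    assemblies[[key]] <- asm
    bb <- predict_backbone(asm)
    n <- count_modules(asm)
    products[[key]] <- data.frame(
      strain = inv$strain_id, cluster_id = cl$cluster_id,
      class = cl$cluster_class, modules = n$total, nrps_modules = n$nrps,
      pks_modules = n$pks, lower_bound = n$lower_bound,
      predictable = bb$predictable,
      product = backbone_product_string(bb), stringsAsFactors = FALSE)
  }
  products <- do.call(rbind, c(products, list(make.row.names = FALSE)))

  groups <- group_orthologs(inventories, threshold = threshold)
  sharing <- classify_sharing(groups, strains)
  pres <- presence_matrix(groups, strains)

  tree <- NULL
  tree_source <- "none"
  if (!is.null(config$tree)) {
    tree <- ape::read.tree(config$tree)
    tree_source <- "supplied"
  } else if (!is.null(config$msa)) {
    aln <- ape::read.FASTA(config$msa)
    tree <- if (bootstrap > 0)
      bootstrap_support(aln, replicates = bootstrap, seed = seed)
    else nj_tree(msa_distances(aln))
    tree_source <- "built-from-msa"
  }
  events <- NULL
  if (!is.null(tree)) {
    if (!is.null(config$outgroup) && config$outgroup %in% tree$tip.label)
      tree <- root_with_outgroup(tree, config$outgroup, prune = TRUE)
    maps <- lapply(seq_len(nrow(pres)), function(i)
      dollo_map(tree, pres[i, ], group_id = rownames(pres)[i]))
    events <- summarize_events(maps, tree)
  }

  group_table <- do.call(rbind, lapply(groups, function(g) data.frame(
    group_id = g$group_id, n_strains = length(g$members),
    sharing_class = g$sharing_class,
    strains = paste(names(g$members), collapse = ","),
    stringsAsFactors = FALSE)))

  report <- list(
    parameters = list(cluster_table = table_path, threshold = threshold,
                      seed = seed, bootstrap = bootstrap,
                      tree_source = tree_source),
    strain_counts = counts,
    products = products,
    groups = group_table,
    sharing = sharing[c("universal", "partial", "specific")],
    specific_by_strain = as.list(sharing$specific_by_strain),
    presence = pres,
    tree = if (!is.null(tree)) ape::write.tree(tree) else NULL,
    events = events,
    log = log)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      report[setdiff(names(report), "presence")],
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE, force = TRUE)
    utils::write.table(group_table, file.path(out_dir, "groups.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(products, file.path(out_dir, "products.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(events))
      utils::write.table(events$branches, file.path(out_dir, "events.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(tree))
      ape::write.tree(tree, file.path(out_dir, "tree.nwk"))
  }
  invisible(report)
}
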