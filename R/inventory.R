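# Typed inventory of modular NRPS/PKS gene clusters: gene records grouped
# into clusters, clusters grouped per strain.

new_gene <- function(orf_id, strain_id, cluster_id, length_aa,
                     length_lower_bound, tokens, partial_start, partial_end,
                     homolog_accession, identity, similarity,
                     outside_main_locus) {
  structure(list(
    orf_id = orf_id, strain_id = strain_id, cluster_id = cluster_id,
    length_aa = length_aa, length_lower_bound = length_lower_bound,
    tokens = tokens, partial_start = partial_start,
    partial_end = partial_end, homolog_accession = homolog_accession,
    identity = identity, similarity = similarity,
    outside_main_locus = outside_main_locus), class = "bgc_gene")
}

classify_cluster <- function(genes) {
  kinds <- unlist(lapply(genes, function(g) g$tokens$kind))
  has_pks <- any(kinds %in% c("KS", "CoL"))
  has_nrps <- any(kinds %in% c("C", "A"))
  if (has_pks && has_nrps) "hybrid" else if (has_pks) "PKS" else "NRPS"
}

new_cluster <- function(cluster_id, strain_id, genes) {
  structure(list(cluster_id = cluster_id, strain_id = strain_id,
                 genes = genes, cluster_class = classify_cluster(genes)),
            class = "bgc_cluster")
}

#' @export
print.bgc_cluster <- function(x, ...) {
  cat(sprintf("<%s cluster %s of %s: %d gene(s)>\n", x$cluster_class,
              x$cluster_id, x$strain_id, length(x$genes)))
  for (g in x$genes)
    cat(sprintf("  %-14s %s\n", g$orf_id,
                format_domain_string(g$tokens, g$partial_start,
                                     g$partial_end)))
  invisible(x)
}

#' Load a cluster-inventory table
#'
#' Reads a tab-delimited inventory (UTF-8, `#` comments allowed) with one row
#' per open reading frame and columns `strain`, `cluster_id`, `orf_id`,
#' `length_aa`, `domains`, `homolog_accession`, `identity`, `similarity`,
#' `flags` (optional extras such as `product` are carried along). Row order
#' within a cluster is preserved as the assembly-line hint order. A
#' `length_aa` of the form `">346"` records a lower bound and flags the gene
#' as partially sequenced, as do `"..."` truncation marks in the domain
#' string; an `outside_main_locus` flag preserves the source table's asterisk
#' marker (metadata only).
#'
#' @param path path to the TSV file.
#' @return a named list of strain inventories (class `bgc_inventory`), each
#'   holding `strain_id` and a named list of clusters in input order.
#' @export
load_cluster_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "#",
                           stringsAsFactors = FALSE, fill = TRUE,
                           colClasses = "character")
  required <- c("strain", "cluster_id", "orf_id", "length_aa", "domains",
                "homolog_accession", "identity", "similarity", "flags")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0)
    stop("inventory schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  inventories <- list()
  if (nrow(tab) == 0)
    return(structure(inventories, class = "bgc_inventory_set"))

  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    tokens <- tryCatch(parse_domain_string(row$domains), error = function(e)
      stop(sprintf("row %d (%s %s): %s", i, row$strain, row$orf_id,
                   conditionMessage(e)), call. = FALSE))
    len_raw <- trimws(row$length_aa)
    lower <- startsWith(len_raw, ">")
    len <- suppressWarnings(as.integer(sub("^>", "", len_raw)))
    flags <- strsplit(ifelse(is.na(row$flags), "", row$flags), ";")[[1]]
    gene <- new_gene(
      orf_id = row$orf_id, strain_id = row$strain,
      cluster_id = row$cluster_id, length_aa = len,
      length_lower_bound = lower, tokens = tokens,
      partial_start = attr(tokens, "partial_start"),
      partial_end = attr(tokens, "partial_end") || lower,
      homolog_accession = sub("\\.\\d+$", "", row$homolog_accession),
      identity = suppressWarnings(as.numeric(row$identity)),
      similarity = suppressWarnings(as.numeric(row$similarity)),
      outside_main_locus = "outside_main_locus" %in% flags)
    st <- row$strain
    if (is.null(inventories[[st]]))
      inventories[[st]] <- list(strain_id = st, clusters = list(),
                                products = list())
    cl <- row$cluster_id
    inv <- inventories[[st]]
    inv$clusters[[cl]] <- c(inv$clusters[[cl]], list(gene))
    prod <- if ("product" %in% names(tab)) trimws(row$product) else ""
    if (!is.na(prod) && nzchar(prod)) inv$products[[cl]] <- prod
    inventories[[st]] <- inv
  }
  inventories <- lapply(inventories, function(inv) {
    inv$clusters <- mapply(function(id, genes)
      new_cluster(id, inv$strain_id, genes),
      names(inv$clusters), inv$clusters, SIMPLIFY = FALSE)
    structure(inv, class = "bgc_inventory")
  })
  structure(inventories, class = "bgc_inventory_set")
}

#' Per-strain cluster counts by class
#'
#' @param inventories result of [load_cluster_table()].
#' @return data.frame with one row per strain: `nrps`, `hybrid`, `pks`,
#'   `total` cluster counts.
#' @export
inventory_summary <- function(inventories) {
  rows <- lapply(inventories, function(inv) {
    cls <- vapply(inv$clusters, function(cl) cl$cluster_class, "")
    data.frame(strain = inv$strain_id,
               nrps = sum(cls == "NRPS"), hybrid = sum(cls == "hybrid"),
               pks = sum(cls == "PKS"), total = length(cls),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fetch one cluster from a set of inventories
#'
#' @param inventories result of [load_cluster_table()].
#' @param strain strain id.
#' @param cluster_id cluster id within that strain.
#' @export
find_cluster <- function(inventories, strain, cluster_id) {
  inv <- inventories[[strain]]
  if (is.null(inv)) stop("unknown strain: ", strain, call. = FALSE)
  cl <- inv$clusters[[cluster_id]]
  if (is.null(cl)) stop("unknown cluster ", cluster_id, " in ", strain,
                        call. = FALSE)
  cl
}

#' Path to the packaged Herbidospora cluster inventory
#'
#' The complete inventory of modular NRPS and type-I PKS gene clusters of the
#' five Herbidospora type strains (80 clusters, 214 multidomain ORFs),
#' transcribed from the published genome analysis.
#' @export
bgc_example_table <- function() {
  system.file("extdata", "herbidospora_table2.tsv", package = "bgclineage",
              mustWork = TRUE)
}

#' Path to the packaged Herbidospora species tree
#'
#' A rooted 16S rRNA gene topology of the five type strains plus the
#' Acrocarpospora outgroup. The topology is reconstructed from the published
#' gain/loss narrative (the original figure is not machine-readable) and
#' branch lengths are nominal; the filename flags this provenance.
#' @export
bgc_example_tree <- function() {
  system.file("extdata", "herbidospora_species_tree_reconstructed.nwk",
              package = "bgclineage", mustWork = TRUE)
}
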