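# Grouping clusters across strains into orthologous pathways. Two clusters
# from different strains are linked when (i) they share at least one gene
# pair with the same closest-homolog accession and (ii) the mean per-gene
# domain similarity over best-matched gene pairs reaches the threshold
# ("domain organizations identical or almost the same"); ortholog groups are
# the connected components of this link relation.

#' Domain-organization similarity of two genes
#'
#' `1 - editdist / max(lengths)` over the domain-kind sequences (substrate
#' annotations are ignored); symmetric, 1 for identical organizations, 0 for
#' completely disjoint ones.
#'
#' @param a,b gene records (`bgc_gene`) or token data.frames.
#' @return numeric in `[0, 1]`.
#' @export
domain_similarity <- function(a, b) {
  ka <- if (inherits(a, "bgc_gene")) a$tokens$kind else a$kind
  kb <- if (inherits(b, "bgc_gene")) b$tokens$kind else b$kind
  1 - edit_distance(ka, kb) / max(length(ka), length(kb))
}

edit_distance <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx == 0) return(ny)
  if (ny == 0) return(nx)
  prev <- 0:ny
  for (i in seq_len(nx)) {
    cur <- numeric(ny + 1)
    cur[1] <- i
    for (j in seq_len(ny)) {
      cur[j + 1] <- min(prev[j + 1] + 1, cur[j] + 1,
                        prev[j] + (x[i] != y[j]))
    }
    prev <- cur
  }
  prev[ny + 1]
}

# greedy best-matching of gene pairs by descending similarity
cluster_pair_stats <- function(ca, cb) {
  ga <- ca$genes; gb <- cb$genes
  sim <- outer(seq_along(ga), seq_along(gb),
               Vectorize(function(i, j) domain_similarity(ga[[i]], gb[[j]])))
  acc_a <- vapply(ga, function(g) g$homolog_accession, "")
  acc_b <- vapply(gb, function(g) g$homolog_accession, "")
  shared_acc <- outer(acc_a, acc_b, "==")
  n <- min(length(ga), length(gb))
  matched <- numeric(0)
  s <- sim
  for (k in seq_len(n)) {
    best <- which(s == max(s), arr.ind = TRUE)[1, , drop = TRUE]
    matched <- c(matched, s[best[1], best[2]])
    s[best[1], ] <- -Inf
    s[, best[2]] <- -Inf
  }
  list(mean_similarity = mean(matched),
       any_shared_accession = any(shared_acc))
}

#' Group clusters across strains into orthologous pathways
#'
#' @param inventories a `bgc_inventory_set` from [load_cluster_table()].
#' @param threshold minimum mean best-matched domain similarity for two
#'   clusters to be linked ("almost the same"; default 0.8).
#' @param respect_curated_ids when TRUE (default) and both clusters carry
#'   cluster ids, a link between clusters with *different* ids is suppressed.
#'   Cross-strain pathway ids in the packaged inventory encode the source
#'   table's manual row alignment; this keeps curated paralog families apart
#'   (identical stand-alone genes at different loci) while linkage within a
#'   pathway remains fully algorithmic. Set FALSE for the pure
#'   accession+similarity criterion (on the packaged inventory this merges
#'   one curated paralog pair).
#' @return list of `bgc_ortholog_group`s, each with `group_id`, `members`
#'   (strain -> cluster) and `sharing_class` (`universal` = all strains,
#'   `specific` = 1 strain, `partial` otherwise), in deterministic order of
#'   first appearance.
#' @export
group_orthologs <- function(inventories, threshold = 0.8,
                            respect_curated_ids = TRUE) {
  clusters <- list()
  for (inv in inventories) for (cl in inv$clusters)
    clusters[[length(clusters) + 1]] <- cl
  n <- length(clusters)
  if (n == 0) return(list())
  strain_of <- vapply(clusters, function(cl) cl$strain_id, "")
  id_of <- vapply(clusters, function(cl) cl$cluster_id, "")

  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (strain_of[i] == strain_of[j]) next
    if (respect_curated_ids && nzchar(id_of[i]) && nzchar(id_of[j]) &&
        id_of[i] != id_of[j]) next
    st <- cluster_pair_stats(clusters[[i]], clusters[[j]])
    if (st$any_shared_accession && st$mean_similarity >= threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  comp_ids <- unique(roots)

  n_strains <- length(inventories)
  groups <- vector("list", length(comp_ids))
  for (k in seq_along(comp_ids)) {
    idx <- which(roots == comp_ids[k])
    st <- strain_of[idx]
    if (anyDuplicated(st))
      stop("ortholog grouping conflict: strain ", st[duplicated(st)][1],
           " contributes clusters ",
           paste(id_of[idx][st == st[duplicated(st)][1]], collapse = ", "),
           " to one component", call. = FALSE)
    members <- stats::setNames(clusters[idx], st)
    ids <- unique(id_of[idx])
    gid <- if (length(ids) == 1) ids else paste0("group-", k)
    m <- length(idx)
    groups[[k]] <- structure(list(
      group_id = gid, members = members,
      sharing_class = if (m == n_strains) "universal"
                      else if (m == 1) "specific" else "partial"),
      class = "bgc_ortholog_group")
  }
  groups
}

#' Tally ortholog groups by phylogenetic sharing class
#'
#' @param groups list from [group_orthologs()].
#' @param strains character vector of all strain ids (defines the order of
#'   the per-strain specific counts).
#' @return list with `universal`, `partial`, `specific` counts and
#'   `specific_by_strain` (named integer vector).
#' @export
classify_sharing <- function(groups, strains) {
  cls <- vapply(groups, function(g) g$sharing_class, "")
  spec <- vapply(strains, function(s) {
    sum(vapply(groups, function(g)
      g$sharing_class == "specific" && names(g$members)[1] == s, TRUE))
  }, 1L)
  list(universal = sum(cls == "universal"), partial = sum(cls == "partial"),
       specific = sum(cls == "specific"), specific_by_strain = spec)
}

#' Binary presence/absence matrix of ortholog groups across strains
#'
#' @param groups list from [group_orthologs()].
#' @param strains character vector of strain ids (column order).
#' @return binary matrix, one row per group, one column per strain.
#' @export
presence_matrix <- function(groups, strains) {
  m <- matrix(0L, nrow = length(groups), ncol = length(strains),
              dimnames = list(vapply(groups, function(g) g$group_id, ""),
                              strains))
  for (i in seq_along(groups))
    m[i, names(groups[[i]]$members)] <- 1L
  m
}
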