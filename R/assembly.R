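# Ordering genes into an assembly line and segmenting the concatenated
# domain sequence into modules.
#
# Module boundary grammar (chosen so that every worked module count in the
# source analysis is reproduced from the inventory alone):
#   * a new module opens immediately before every C and every KS;
#   * an A/AT that begins a gene opens a new module unless it continues an
#     open C/KS-initiated module that still lacks its A/AT (cross-gene
#     module splits);
#   * CoL at the start opens the loading module;
#   * a leading orphan T/ACP (or other tailoring token) with no open module
#     attaches to the preceding module if one exists, otherwise it is
#     discarded with a warning;
#   * TE attaches to the current module;
#   * a module consisting solely of C/KS merges forward into the next module
#     if tokens follow, otherwise it is left incomplete and not counted.

gene_is_loading_start <- function(gene) {
  kinds <- gene$tokens$kind
  if (kinds[1] == "CoL") return(TRUE)
  first_aat <- which(kinds %in% c("A", "AT"))[1]
  if (is.na(first_aat)) return(FALSE)
  first_cks <- which(kinds %in% c("C", "KS"))[1]
  is.na(first_cks) || first_aat < first_cks
}

gene_has_te <- function(gene) "TE" %in% gene$tokens$kind

#' Order a cluster's genes into assembly-line order
#'
#' The gene whose first module is a loading module (CoL-initiated, or an
#' A/AT not preceded by C/KS within the gene) is placed first; the gene
#' containing TE is placed last; all other genes keep input (table) order.
#' A gene that is both loading candidate and TE carrier is pinned last (the
#' termination invariant takes precedence). Two loading candidates or two TE
#' genes trigger an ambiguity warning and input order is kept for that role.
#'
#' @param cluster a `bgc_cluster` (single-domain genes already excluded).
#' @return character vector of orf ids in assembly order.
#' @export
order_genes <- function(cluster) {
  genes <- cluster$genes
  ids <- vapply(genes, function(g) g$orf_id, "")
  if (length(genes) <= 1) return(ids)
  te <- which(vapply(genes, gene_has_te, TRUE))
  loading <- setdiff(which(vapply(genes, gene_is_loading_start, TRUE)), te)
  if (length(te) > 1) {
    warning("cluster ", cluster$cluster_id,
            ": two TE genes; keeping input order", call. = FALSE)
    te <- integer()
  }
  if (length(loading) > 1) {
    warning("cluster ", cluster$cluster_id,
            ": two candidate loading genes; keeping input order",
            call. = FALSE)
    loading <- integer()
  }
  middle <- setdiff(seq_along(genes), c(loading, te))
  ids[c(loading, middle, te)]
}

is_bare_module <- function(kinds) all(kinds %in% c("C", "KS"))

module_substrate <- function(tokens) {
  i <- which(tokens$kind %in% c("A", "AT"))[1]
  if (is.na(i))
    return(list(value = "absent", confidence = "none",
                ambiguous = NA_character_))
  list(value = if (is.na(tokens$substrate[i])) "unknown"
       else tokens$substrate[i],
       confidence = tokens$confidence[i], ambiguous = tokens$ambiguous[i])
}

#' Segment a cluster into assembly-line modules
#'
#' Excludes single-domain genes (atypical; advisory finding
#' `exclude_single_domain`), orders the remaining genes with
#' [order_genes()], concatenates their domain tokens and applies the module
#' boundary grammar described above. Iterative enediyne-type PKS genes
#' (KR-DH pair after the ACP) are classified but not segmented into modules,
#' since they do not follow modular collinearity.
#'
#' @param cluster a `bgc_cluster`.
#' @return a `bgc_assembly`: the ordered orf ids, the module list (each with
#'   `index`, `kind` (NRPS/PKS), `role` (loading/extension/
#'   termination-bearing/incomplete), token table, `spans_genes` and resolved
#'   `substrate`), a `complete` flag (FALSE when any gene is partial, so
#'   module counts are lower bounds), plus exclusion/warning logs.
#' @export
segment_modules <- function(cluster) {
  genes <- cluster$genes
  excluded <- vapply(genes, function(g)
    "exclude_single_domain" %in% validate_gene(g), TRUE)
  log <- character()
  if (any(excluded))
    log <- c(log, paste0("excluded single-domain gene: ",
                         vapply(genes[excluded], function(g) g$orf_id, "")))
  genes <- genes[!excluded]

  assembly <- structure(list(
    cluster_id = cluster$cluster_id, strain_id = cluster$strain_id,
    cluster_class = cluster$cluster_class, ordered_genes = character(),
    modules = list(), complete = TRUE, enediyne = FALSE, log = log),
    class = "bgc_assembly")
  if (length(genes) == 0) return(assembly)

  # PksE signature: a KR-DH pair directly after an ACP (no new KS/C between)
  enediyne <- any(vapply(genes, function(g) {
    k <- g$tokens$kind
    for (acp in which(k == "ACP")) {
      tail <- k[-seq_len(acp)]
      nxt <- which(tail %in% c("KS", "C"))[1]
      if (!is.na(nxt)) tail <- tail[seq_len(nxt - 1)]
      if (all(c("KR", "DH") %in% tail)) return(TRUE)
    }
    FALSE
  }, TRUE))
  assembly$complete <- !any(vapply(genes, function(g)
    isTRUE(g$partial_start) || isTRUE(g$partial_end), TRUE))
  if (enediyne) {
    assembly$enediyne <- TRUE
    assembly$ordered_genes <- vapply(genes, function(g) g$orf_id, "")
    assembly$log <- c(assembly$log,
                      "iterative enediyne-type PKS: not segmented")
    return(assembly)
  }

  ord <- order_genes(new_cluster(cluster$cluster_id, cluster$strain_id,
                                 genes))
  genes <- genes[match(ord, vapply(genes, function(g) g$orf_id, ""))]
  assembly$ordered_genes <- ord

  # flat token stream with provenance
  stream <- do.call(rbind, lapply(genes, function(g) {
    tk <- g$tokens
    tk$orf_id <- g$orf_id
    tk$gene_start <- seq_len(nrow(tk)) == 1
    tk
  }))

  modules <- list()
  cur <- NULL
  push <- function() {
    if (!is.null(cur)) modules[[length(modules) + 1]] <<- cur
    cur <<- NULL
  }
  for (i in seq_len(nrow(stream))) {
    tok <- stream[i, ]
    k <- tok$kind
    if (k %in% c("C", "KS", "CoL")) {
      push(); cur <- tok
    } else if (k %in% c("A", "AT")) {
      if (is.null(cur)) {
        cur <- tok
      } else if (tok$gene_start &&
                 !(any(cur$kind %in% c("C", "KS")) &&
                   !any(cur$kind %in% c("A", "AT")))) {
        push(); cur <- tok
      } else {
        cur <- rbind(cur, tok)
      }
    } else {
      if (!is.null(cur)) {
        cur <- rbind(cur, tok)
      } else if (length(modules) > 0) {
        modules[[length(modules)]] <- rbind(modules[[length(modules)]], tok)
        assembly$log <- c(assembly$log, paste0(
          "orphan ", k, " at start of ", tok$orf_id,
          " attached to preceding module"))
      } else {
        assembly$log <- c(assembly$log, paste0(
          "leading orphan ", k, " of ", tok$orf_id,
          " discarded (no open module)"))
      }
    }
  }
  push()

  # merge bare C/KS leftovers forward; a trailing one stays incomplete
  merged <- list()
  pending <- NULL
  for (m in modules) {
    if (is_bare_module(m$kind)) {
      pending <- if (is.null(pending)) m else rbind(pending, m)
    } else {
      if (!is.null(pending)) {
        m <- rbind(pending, m)
        pending <- NULL
      }
      merged[[length(merged) + 1]] <- m
    }
  }
  incomplete <- pending

  records <- vector("list", length(merged))
  for (i in seq_along(merged)) {
    m <- merged[[i]]
    kinds <- m$kind
    is_pks <- any(kinds %in% c("KS", "CoL")) ||
      (i == 1 && !any(kinds == "C") && any(kinds %in% c("AT", "ACP")))
    loading <- i == 1 &&
      (any(kinds == "CoL") || is_pks ||
         (!any(kinds %in% c("C", "KS")) && any(kinds %in% c("A", "AT"))))
    role <- if (loading) "loading"
            else if ("TE" %in% kinds) "termination-bearing"
            else "extension"
    records[[i]] <- list(
      index = i, kind = if (is_pks) "PKS" else "NRPS", role = role,
      domains = m, spans_genes = unique(m$orf_id),
      substrate = module_substrate(m), counted = TRUE)
  }
  if (!is.null(incomplete)) {
    records[[length(records) + 1]] <- list(
      index = length(records) + 1,
      kind = if (any(incomplete$kind == "KS")) "PKS" else "NRPS",
      role = "incomplete", domains = incomplete,
      spans_genes = unique(incomplete$orf_id),
      substrate = module_substrate(incomplete), counted = FALSE)
  }
  assembly$modules <- records
  assembly
}

#' Count modules of a segmented assembly
#'
#' `total` counts complete (counted) modules only; `lower_bound` is set when
#' the cluster contains partially sequenced genes, giving the count "at
#' least" semantics. Enediyne-class assemblies report zero modules (they are
#' classified, not segmented).
#'
#' @param assembly a `bgc_assembly` from [segment_modules()].
#' @return list with `total`, `nrps`, `pks`, `loading`, `incomplete`,
#'   `lower_bound`, `enediyne`.
#' @export
count_modules <- function(assembly) {
  mods <- assembly$modules
  counted <- Filter(function(m) m$counted, mods)
  kinds <- vapply(counted, function(m) m$kind, "")
  roles <- vapply(counted, function(m) m$role, "")
  list(total = length(counted),
       nrps = sum(kinds == "NRPS"), pks = sum(kinds == "PKS"),
       loading = sum(roles == "loading"),
       incomplete = length(mods) - length(counted),
       lower_bound = !assembly$complete,
       enediyne = assembly$enediyne)
}

#' @export
print.bgc_assembly <- function(x, ...) {
  n <- count_modules(x)
  cat(sprintf("<assembly %s (%s): %s%d modules (%d NRPS, %d PKS)>\n",
              x$cluster_id, x$strain_id,
              if (n$lower_bound) ">=" else "", n$total, n$nrps, n$pks))
  for (m in x$modules)
    cat(sprintf("  %2d %-4s %-20s %s\n", m$index, m$kind, m$role,
                paste(m$domains$kind, collapse = "/")))
  invisible(x)
}
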