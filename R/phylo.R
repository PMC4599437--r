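# Distance-based phylogenetics: p/JC69 distances with pairwise deletion,
# neighbor-joining (Saitou-Nei agglomeration with deterministic
# lexicographic tie-breaking), nonparametric bootstrap of alignment columns,
# outgroup rooting and Robinson-Foulds topology comparison. Trees are
# ape "phylo" objects throughout.

as_char_alignment <- function(alignment) {
  if (inherits(alignment, "DNAbin"))
    alignment <- as.character(alignment)
  if (is.list(alignment))
    alignment <- do.call(rbind, alignment)
  if (!is.matrix(alignment))
    stop("alignment must be a character matrix, list or DNAbin", call. = FALSE)
  m <- toupper(alignment)
  if (is.null(rownames(m)))
    rownames(m) <- paste0("t", seq_len(nrow(m)))
  m
}

#' Pairwise distances from a multiple sequence alignment
#'
#' p-distance = mismatches / compared sites, with pairwise deletion of any
#' site that is not an unambiguous A/C/G/T in both sequences. The JC69
#' transform is `-(3/4) ln(1 - 4p/3)`, defined only for p < 0.75.
#'
#' @param alignment character matrix (taxa x sites), list of equal-length
#'   character vectors, or an ape `DNAbin`.
#' @param model `"JC69"` (default) or `"p-distance"`.
#' @return symmetric distance matrix with taxa dimnames.
#' @export
msa_distances <- function(alignment, model = c("JC69", "p-distance")) {
  model <- match.arg(model)
  m <- as_char_alignment(alignment)
  n <- nrow(m)
  taxa <- rownames(m)
  ok <- matrix(m %in% c("A", "C", "G", "T"), nrow = n)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    comp <- ok[i, ] & ok[j, ]
    nc <- sum(comp)
    if (nc == 0)
      stop("no comparable sites between ", taxa[i], " and ", taxa[j],
           call. = FALSE)
    p <- sum(m[i, comp] != m[j, comp]) / nc
    if (model == "JC69") {
      if (p >= 0.75)
        stop("JC69 undefined: p-distance ", signif(p, 3), " >= 0.75 between ",
             taxa[i], " and ", taxa[j], call. = FALSE)
      p <- -0.75 * log(1 - 4 * p / 3)
    }
    d[i, j] <- d[j, i] <- p
  }
  d
}

num_bl <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration: at each step the pair minimizing
#' `Q(i,j) = (n-2) d(i,j) - R(i) - R(j)` is joined, branch lengths are split
#' by the two-branch formulas, and the matrix is reduced. Ties are broken by
#' the first minimal pair in row-major scan order of the current (input-
#' ordered) taxa, so the result is deterministic. Exactly additive matrices
#' are recovered exactly. Negative branch lengths are clamped to zero with a
#' warning.
#'
#' @param dm symmetric distance matrix (or `dist`) over >= 3 taxa.
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  if (is.null(rownames(dm))) rownames(dm) <- colnames(dm) <-
      paste0("t", seq_len(n))
  D <- dm
  reps <- rownames(D)
  clamp <- FALSE
  bl <- function(x) {
    if (x < 0) clamp <<- TRUE
    num_bl(max(x, 0))
  }
  while (nrow(D) > 3) {
    n <- nrow(D)
    R <- rowSums(D)
    best <- c(NA, NA); bestq <- Inf
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      q <- (n - 2) * D[i, j] - R[i] - R[j]
      if (q < bestq - 1e-12) {
        bestq <- q; best <- c(i, j)
      }
    }
    i <- best[1]; j <- best[2]
    vi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (n - 2))
    vj <- D[i, j] - vi
    rep_new <- paste0("(", reps[i], ":", bl(vi), ",", reps[j], ":", bl(vj),
                      ")")
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    reps <- c(reps[keep], rep_new)
    rownames(D2) <- colnames(D2) <- NULL
    D <- D2
  }
  va <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  vb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  vc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- paste0("(", reps[1], ":", bl(va), ",", reps[2], ":", bl(vb), ",",
                reps[3], ":", bl(vc), ");")
  if (clamp)
    warning("negative neighbor-joining branch length(s) clamped to 0",
            call. = FALSE)
  ape::read.tree(text = nwk)
}

#' Non-trivial bipartitions of a tree
#'
#' Each internal edge of the unrooted tree is represented by the sorted leaf
#' set on one side, canonicalized to the side containing the
#' lexicographically first taxon, and encoded as a single string.
#'
#' @param tree a `phylo`.
#' @return character vector of canonical split encodings (possibly empty).
#' @export
tree_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- sort(tree$tip.label)
  anchor <- tips[1]
  ntip <- length(tree$tip.label)
  internal <- which(tree$edge[, 2] > ntip)
  splits <- character()
  for (e in internal) {
    node <- tree$edge[e, 2]
    side <- ape::extract.clade(tree, node)$tip.label
    if (length(side) <= 1 || length(side) >= ntip - 1) next
    if (!anchor %in% side) side <- setdiff(tree$tip.label, side)
    splits <- c(splits, paste(sort(side), collapse = "|"))
  }
  unique(splits)
}

#' Robinson-Foulds distance between two trees
#'
#' Size of the symmetric difference of the two trees' non-trivial
#' bipartition sets (unrooted comparison); 0 iff identical topologies.
#'
#' @param a,b `phylo` trees over the same leaf set.
#' @return nonnegative integer.
#' @export
rf_distance <- function(a, b) {
  if (!setequal(a$tip.label, b$tip.label))
    stop("trees have different leaf sets", call. = FALSE)
  sa <- tree_bipartitions(a)
  sb <- tree_bipartitions(b)
  length(setdiff(sa, sb)) + length(setdiff(sb, sa))
}

#' Bootstrap support for a distance tree
#'
#' Resamples alignment columns with replacement (seeded), rebuilds a tree
#' per replicate with `builder` on `model` distances, and scores each
#' internal bipartition of the full-data tree by its replicate frequency
#' (x100). Supports are attached as `node.label` on the returned full-data
#' tree and as the `support` attribute. Replicates whose distances are
#' undefined (e.g. saturated resamples) are dropped from the denominator
#' with a warning.
#'
#' @param alignment as in [msa_distances()].
#' @param replicates number of bootstrap replicates (>= 1).
#' @param seed integer RNG seed.
#' @param model distance model, see [msa_distances()].
#' @param builder tree-building function taking a distance matrix.
#' @return the full-data `phylo` with integer `node.label` supports.
#' @export
bootstrap_support <- function(alignment, replicates, seed,
                              model = "JC69", builder = nj_tree) {
  stopifnot(replicates >= 1)
  m <- as_char_alignment(alignment)
  full <- builder(msa_distances(m, model = model))
  splits <- tree_bipartitions(full)
  counts <- stats::setNames(numeric(length(splits)), splits)
  used <- 0
  with_seed(seed, {
    for (r in seq_len(replicates)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      rep_tree <- tryCatch(builder(msa_distances(m[, cols, drop = FALSE],
                                                 model = model)),
                           error = function(e) NULL)
      if (is.null(rep_tree)) next
      used <- used + 1
      hit <- splits %in% tree_bipartitions(rep_tree)
      counts[hit] <- counts[hit] + 1
    }
  })
  if (used < replicates)
    warning(replicates - used, " bootstrap replicate(s) dropped", call. = FALSE)
  support <- if (used > 0) round(100 * counts / used) else counts * NA
  # attach to internal nodes: root (unrooted basal node) gets no support
  ntip <- length(full$tip.label)
  nnode <- full$Nnode
  labs <- character(nnode)
  anchor <- sort(full$tip.label)[1]
  for (nd in seq_len(nnode) + ntip) {
    side <- ape::extract.clade(full, nd)$tip.label
    if (length(side) <= 1 || length(side) >= ntip - 1) next
    if (!anchor %in% side) side <- setdiff(full$tip.label, side)
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(support)) labs[nd - ntip] <- as.character(support[key])
  }
  full$node.label <- labs
  attr(full, "support") <- support
  full
}

#' Root a tree on an outgroup
#'
#' Places the root at the midpoint of the outgroup's pendant edge.
#'
#' @param tree an unrooted (or otherwise rooted) `phylo`.
#' @param outgroup a leaf name.
#' @param prune drop the outgroup after rooting (for gain/loss mapping on
#'   the ingroup).
#' @return a rooted `phylo`.
#' @export
root_with_outgroup <- function(tree, outgroup, prune = FALSE) {
  if (!outgroup %in% tree$tip.label)
    stop("outgroup '", outgroup, "' is not a leaf of the tree", call. = FALSE)
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  if (!is.null(rooted$edge.length)) {
    ntip <- length(rooted$tip.label)
    root_node <- ntip + 1
    kids <- which(rooted$edge[, 1] == root_node)
    og_tip <- which(rooted$tip.label == outgroup)
    og_edge <- kids[rooted$edge[kids, 2] == og_tip]
    if (length(og_edge) == 1 && length(kids) == 2) {
      tot <- sum(rooted$edge.length[kids])
      rooted$edge.length[kids] <- tot / 2
    }
  }
  if (prune) rooted <- ape::drop.tip(rooted, outgroup)
  rooted
}
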