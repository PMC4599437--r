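# Dollo parsimony mapping of presence/absence characters onto a rooted
# species tree: each character (ortholog group) is gained exactly once, on
# the branch above the most recent common ancestor of the leaves that carry
# it, and lost on the stems of the maximal all-absent subtrees below the
# gain. Branches are identified by their child node: a leaf's pendant branch
# by the leaf name, an internal branch by the sorted "+"-joined leaf set of
# its clade (the root's stem is therefore the full leaf set).

node_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  ape::extract.clade(tree, node)$tip.label
}

branch_id <- function(tree, node) {
  paste(sort(node_tips(tree, node)), collapse = "+")
}

#' All branch ids of a rooted tree
#'
#' One id per branch (identified by its child node), including the stem
#' branch above the root.
#' @param tree a rooted `phylo`.
#' @export
tree_branch_ids <- function(tree) {
  ntip <- length(tree$tip.label)
  nodes <- c(tree$edge[, 2], ntip + 1)  # all children plus the root stem
  vapply(nodes, function(nd) branch_id(tree, nd), "")
}

#' Map one presence/absence row onto a rooted tree under Dollo parsimony
#'
#' @param tree rooted `phylo` over the ingroup leaves.
#' @param presence logical or 0/1 vector named by leaf; at least one leaf
#'   must be present.
#' @param group_id optional character label carried into the result.
#' @return a `bgc_event_map`: `gain_branch`, `loss_branches`,
#'   `ancestral_states` (named `present`/`absent` over all branch ids) and
#'   `n_events` (1 gain + losses).
#' @export
dollo_map <- function(tree, presence, group_id = NA_character_) {
  tips <- tree$tip.label
  if (is.null(names(presence)))
    stop("presence row must be named by leaf", call. = FALSE)
  if (!setequal(names(presence), tips))
    stop("presence row names do not match the tree's leaves", call. = FALSE)
  pres <- as.logical(presence[tips])
  if (!any(pres)) stop("all-absent presence row", call. = FALSE)
  ntip <- length(tips)
  present_tips <- which(pres)

  gain_node <- if (length(present_tips) == 1) present_tips else
    ape::getMRCA(tree, present_tips)
  gain_branch <- branch_id(tree, gain_node)

  children <- function(nd) tree$edge[tree$edge[, 1] == nd, 2]
  all_absent <- function(nd) {
    tp <- node_tips(tree, nd)
    !any(pres[match(tp, tips)])
  }
  losses <- character()
  state <- character()
  walk <- function(nd, alive) {
    if (alive && all_absent(nd)) {
      losses <<- c(losses, branch_id(tree, nd))
      alive <- FALSE
    }
    state[branch_id(tree, nd)] <<- if (alive) "present" else "absent"
    for (ch in children(nd)) walk(ch, alive)
  }
  # outside the gain clade everything is absent; inside, walk for losses
  root <- ntip + 1
  mark_absent <- function(nd) {
    state[branch_id(tree, nd)] <<- "absent"
    for (ch in children(nd)) mark_absent(ch)
  }
  if (gain_node == root) {
    walk(root, TRUE)
  } else {
    path_up <- gain_node
    nd <- gain_node
    while (nd != root) {
      nd <- tree$edge[tree$edge[, 2] == nd, 1]
      path_up <- c(path_up, nd)
    }
    mark_absent(root)
    # re-walk the gained clade as present
    losses <- character()
    walk(gain_node, TRUE)
  }
  structure(list(group_id = group_id, gain_branch = gain_branch,
                 loss_branches = losses, ancestral_states = state,
                 n_events = 1L + length(losses)),
            class = "bgc_event_map")
}

#' Replay an event map's gains and losses into leaf states
#'
#' Utility for checking that a gain branch plus loss branches reproduce an
#' observed presence row: a leaf is present iff it descends from the gain
#' branch and from no loss branch.
#'
#' @param tree rooted `phylo`.
#' @param gain_branch,loss_branches branch ids as used by [dollo_map()].
#' @return named logical vector over leaves.
#' @export
apply_events <- function(tree, gain_branch, loss_branches = character()) {
  tips <- tree$tip.label
  in_branch <- function(id) strsplit(id, "+", fixed = TRUE)[[1]]
  pres <- tips %in% in_branch(gain_branch)
  for (l in loss_branches) pres[tips %in% in_branch(l)] <- FALSE
  stats::setNames(pres, tips)
}

#' Summarize gain/loss events over many ortholog groups
#'
#' Tallies events per branch and classifies each group by the placement of
#' its events: any loss -> `gain-then-loss`; otherwise a gain on the root's
#' stem -> `ancestral` (acquired before the radiation of the genus), a gain
#' on a terminal branch -> `recent`, and a gain on an internal branch ->
#' `clade-gain`.
#'
#' @param maps list of `bgc_event_map`s computed on one tree.
#' @param tree the rooted `phylo` the maps were computed on.
#' @return list with `branches` (data.frame: branch, gains, losses) and
#'   `classification` (named character per group).
#' @export
summarize_events <- function(maps, tree) {
  ids <- tree_branch_ids(tree)
  known <- unique(ids)
  for (m in maps) {
    if (!m$gain_branch %in% known ||
        !all(m$loss_branches %in% known))
      stop("event map '", m$group_id,
           "' refers to branches absent from this tree", call. = FALSE)
  }
  gains <- losses <- stats::setNames(integer(length(known)), known)
  root_stem <- branch_id(tree, length(tree$tip.label) + 1)
  classification <- character(length(maps))
  names(classification) <- vapply(maps, function(m)
    as.character(m$group_id), "")
  for (k in seq_along(maps)) {
    m <- maps[[k]]
    gains[m$gain_branch] <- gains[m$gain_branch] + 1L
    for (l in m$loss_branches) losses[l] <- losses[l] + 1L
    classification[k] <-
      if (length(m$loss_branches) > 0) "gain-then-loss"
      else if (m$gain_branch == root_stem) "ancestral"
      else if (!grepl("+", m$gain_branch, fixed = TRUE)) "recent"
      else "clade-gain"
  }
  list(branches = data.frame(branch = known, gains = as.integer(gains),
                             losses = as.integer(losses),
                             stringsAsFactors = FALSE),
       classification = classification)
}
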