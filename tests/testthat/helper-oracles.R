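# independent minimal-event oracle for Dollo mapping: enumerate every gain
# branch whose clade covers the present leaves and every subset of loss
# branches below it, using bitmask leaf sets; returns the minimal
# 1 gain + L losses event count
dollo_oracle <- function(tree, pres) {
  tips <- tree$tip.label
  masks <- vapply(tree_branch_ids(tree), function(id) {
    sum(2^(match(strsplit(id, "+", fixed = TRUE)[[1]], tips) - 1))
  }, 1)
  pmask <- sum(2^(which(pres[tips]) - 1))
  best <- Inf
  for (g in unique(masks)) {
    if (bitwAnd(g, pmask) != pmask) next
    need <- bitwAnd(g, bitwNot(pmask))
    cand <- unique(masks[bitwAnd(masks, need) == masks & masks != g])
    found <- Inf
    search <- function(rem, chosen, used) {
      if (rem == 0) {
        found <<- min(found, chosen)
        return()
      }
      if (chosen + 1 >= found) return()
      for (i in seq_along(used)) {
        if (!used[i] && bitwAnd(cand[i], rem) == cand[i]) {
          u <- used
          u[i] <- TRUE
          search(bitwAnd(rem, bitwNot(cand[i])), chosen + 1, u)
        }
      }
    }
    if (need == 0) found <- 0
    else if (length(cand)) search(need, 0, logical(length(cand)))
    best <- min(best, 1 + found)
  }
  best
}
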