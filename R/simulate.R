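# Seeded generators with known ground truth for every pipeline stage:
# multi-gene assembly lines with planned module structure, multi-strain
# inventories with planted ortholog groups, presence/absence characters
# evolved under a single-gain/multiple-loss process, and JC69 sequence
# alignments along a tree. All generators are pure functions of
# (parameters, seed); the caller's RNG state is left untouched.

rand_token <- function(kind, substrate = NA_character_,
                       confidence = "none", module_break = FALSE) {
  data.frame(kind = kind, substrate = substrate, confidence = confidence,
             ambiguous = NA_character_, raw_sub = NA_character_,
             tentative_domain = FALSE, module_break = module_break,
             stringsAsFactors = FALSE)
}

# one module plan -> token data.frame (first token flagged as module break)
plan_module_tokens <- function(plan) {
  rows <- list()
  add <- function(kind, substrate = NA_character_, confidence = "none")
    rows[[length(rows) + 1]] <<- rand_token(kind, substrate, confidence)
  if (plan$kind == "NRPS") {
    if (!plan$loading && !isTRUE(plan$skip_opener)) add("C")
    if (plan$has_a)
      add("A", plan$substrate,
          if (is.na(plan$substrate)) "none" else "firm")
    if (plan$mt) add("MT")
    add("T")
    if (plan$e) add("E")
  } else {
    if (plan$loading && plan$col) {
      add("CoL")
      add("ACP")
    } else {
      if (!isTRUE(plan$skip_opener)) add("KS")
      add("AT", plan$substrate, "firm")
      if ("DH" %in% plan$reduction) add("DH")
      if ("ER" %in% plan$reduction) add("ER")
      if ("KR" %in% plan$reduction) add("KR")
      add("ACP")
    }
  }
  if (plan$te) add("TE")
  tok <- do.call(rbind, rows)
  tok$module_break[1] <- TRUE
  tok
}

sim_cluster_plan <- function(class, n_modules) {
  aa <- unname(AA_SUBSTRATES)
  plans <- vector("list", n_modules)
  for (i in seq_len(n_modules)) {
    loading <- i == 1
    kind <- switch(class,
      NRPS = "NRPS", PKS = "PKS",
      hybrid = if (i <= ceiling(n_modules / 2)) "PKS" else "NRPS")
    if (kind == "NRPS") {
      plans[[i]] <- list(
        kind = "NRPS", loading = loading,
        has_a = TRUE,
        # ~40 % of A-domain substrates unpredicted, as in the real table
        substrate = if (stats::runif(1) < 0.4) NA_character_
                    else sample(aa, 1),
        mt = stats::runif(1) < 0.1, e = stats::runif(1) < 0.1,
        te = FALSE, col = FALSE, reduction = character())
    } else {
      plans[[i]] <- list(
        kind = "PKS", loading = loading,
        has_a = FALSE, substrate = sample(
          c("malonyl", "methylmalonyl", "ethylmalonyl"), 1,
          prob = c(0.6, 0.3, 0.1)),
        mt = FALSE, e = FALSE, te = FALSE,
        col = loading && class == "hybrid" && stats::runif(1) < 0.5,
        reduction = sample(list(character(), "KR", c("KR", "DH"),
                                c("KR", "DH", "ER")), 1)[[1]])
    }
  }
  plans[[n_modules]]$te <- TRUE
  plans
}

# split a planned module sequence into gene token tables; with probability
# split_shift a gene boundary cuts inside a module so the next gene starts
# with its A/AT (exercising the cross-gene merge rule)
plan_to_genes <- function(plans, max_genes = 12, split_shift = 0.3) {
  n <- length(plans)
  n_genes <- sample.int(min(max_genes, n), 1)
  cuts <- sort(sample.int(n - 1, n_genes - 1))
  bounds <- c(0, cuts, n)
  tokens_per_gene <- list()
  carry <- NULL
  for (g in seq_len(n_genes)) {
    idx <- (bounds[g] + 1):bounds[g + 1]
    toks <- do.call(rbind, lapply(plans[idx], plan_module_tokens))
    if (!is.null(carry)) {
      toks <- rbind(carry, toks)
      carry <- NULL
    }
    toks$module_break[1] <- FALSE
    # shift the opening C/KS of the *next* gene's first module back onto
    # this gene's tail
    if (g < n_genes && stats::runif(1) < split_shift) {
      nxt <- plans[[bounds[g + 1] + 1]]
      opener <- if (nxt$kind == "NRPS") "C" else "KS"
      extra <- rand_token(opener, module_break = TRUE)
      toks <- rbind(toks, extra)
      # drop that opener from the next module when it is emitted
      plans[[bounds[g + 1] + 1]]$skip_opener <- TRUE
    }
    tokens_per_gene[[g]] <- toks
  }
  tokens_per_gene
}

#' Simulate multi-strain cluster inventories with known ground truth
#'
#' Draws ortholog groups with planted sharing patterns, plans each group's
#' assembly line (loading module, extensions, terminal TE), splits modules
#' over 1-12 genes (including cross-gene splits that leave a bare C/KS at a
#' gene end, to exercise the segmentation merge rules), assigns substrates
#' and per-gene homolog accessions shared within a group, and renders
#' parseable domain strings. Cluster ids are unique per strain so ortholog
#' recovery cannot lean on curated ids.
#'
#' @param n_strains number of strains (default 5).
#' @param n_groups number of ortholog groups to plant (default 32, the
#'   scale of the real inventory).
#' @param module_count_range inclusive range of module counts per cluster.
#' @param perturb inject 0-1 domain substitutions per eligible gene between
#'   strains of a group (keeps within-group similarity above 0.85).
#' @param seed integer RNG seed.
#' @return list with `inventories` (a `bgc_inventory_set`) and `truth`
#'   (per-cluster planned module counts/kinds, cluster -> group labels,
#'   group member sets, seed).
#' @export
simulate_inventory <- function(n_strains = 5, n_groups = 32,
                               module_count_range = c(2, 9),
                               perturb = TRUE, seed = 1) {
  with_seed(seed, {
    strains <- paste0("strain", seq_len(n_strains))
    truth <- list(seed = seed, groups = character(), module_counts = list(),
                  members = list())
    inventories <- stats::setNames(lapply(strains, function(s)
      list(strain_id = s, clusters = list(), products = list())), strains)

    for (g in seq_len(n_groups)) {
      gid <- sprintf("grp%02d", g)
      class <- sample(c("NRPS", "PKS", "hybrid"), 1, prob = c(0.5, 0.38, 0.12))
      n_mod <- sample(module_count_range[1]:module_count_range[2], 1)
      n_members <- if (n_strains >= 3)
        sample(c(1, 2:(n_strains - 1), n_strains), 1,
               prob = c(0.45, rep(0.25 / (n_strains - 2), n_strains - 2),
                        0.3))
      else sample.int(n_strains, 1)
      members <- sort(sample(strains, n_members))
      plans <- sim_cluster_plan(class, n_mod)
      genes_tokens <- plan_to_genes(plans)
      accs <- sprintf("SIM%02dG%02d", g, seq_along(genes_tokens))
      truth$members[[gid]] <- members
      for (s in members) {
        toks_list <- genes_tokens
        if (perturb) {
          for (k in seq_along(toks_list)) {
            tk <- toks_list[[k]]
            # toggle a tailoring domain on long genes only (edit distance 1)
            if (nrow(tk) >= 7 && stats::runif(1) < 0.4) {
              anchor <- which(tk$kind == "T")[1]
              if (!is.na(anchor)) {
                ins <- rand_token("MT")
                toks_list[[k]] <- rbind(tk[seq_len(anchor - 1), ], ins,
                                        tk[anchor:nrow(tk), ])
              }
            }
          }
        }
        cl_id <- sprintf("c%s-%02d", s, length(inventories[[s]]$clusters) + 1)
        genes <- vector("list", length(toks_list))
        for (k in seq_along(toks_list)) {
          tk <- toks_list[[k]]
          rownames(tk) <- NULL
          genes[[k]] <- new_gene(
            orf_id = sprintf("%s-orf%02d", cl_id, k), strain_id = s,
            cluster_id = cl_id,
            length_aa = 350L * nrow(tk), length_lower_bound = FALSE,
            tokens = tk, partial_start = FALSE, partial_end = FALSE,
            homolog_accession = accs[k], identity = 80, similarity = 88,
            outside_main_locus = FALSE)
        }
        inventories[[s]]$clusters[[cl_id]] <-
          new_cluster(cl_id, s, genes)
        truth$groups[[paste(s, cl_id, sep = "/")]] <- gid
        truth$module_counts[[paste(s, cl_id, sep = "/")]] <- n_mod
      }
    }
    inventories <- lapply(inventories, function(inv)
      structure(inv, class = "bgc_inventory"))
    list(inventories = structure(inventories, class = "bgc_inventory_set"),
         truth = truth)
  })
}

#' Evolve presence/absence characters under single gain + multiple losses
#'
#' Each group gains on a uniformly chosen branch of the rooted tree
#' (including the root's stem) and is then lost independently on each
#' descendant branch with probability `loss_prob` (losses nest: a lineage
#' already lost stays lost). Groups surviving in no leaf are redrawn.
#'
#' @param tree rooted `phylo`.
#' @param n_groups number of characters.
#' @param loss_prob per-branch loss probability in `[0, 1)`.
#' @param seed integer RNG seed.
#' @return list with `matrix` (groups x leaves, 0/1) and `events` (list of
#'   true `bgc_event_map`-like records with `gain_branch`, `loss_branches`,
#'   `n_events`).
#' @export
simulate_presence_evolution <- function(tree, n_groups, loss_prob, seed) {
  stopifnot(loss_prob >= 0, loss_prob < 1)
  with_seed(seed, {
    tips <- tree$tip.label
    ntip <- length(tips)
    root <- ntip + 1
    nodes <- c(root, tree$edge[, 2])  # root stem + every edge's child
    children <- function(nd) tree$edge[tree$edge[, 1] == nd, 2]
    mat <- matrix(0L, n_groups, ntip,
                  dimnames = list(sprintf("grp%03d", seq_len(n_groups)),
                                  tips))
    events <- vector("list", n_groups)
    for (g in seq_len(n_groups)) {
      repeat {
        gain_node <- sample(nodes, 1)
        losses <- character()
        pres <- stats::setNames(logical(ntip), tips)
        walk <- function(nd, alive) {
          if (alive && nd != gain_node && stats::runif(1) < loss_prob) {
            losses <<- c(losses, branch_id(tree, nd))
            alive <- FALSE
          }
          if (nd <= ntip) {
            pres[tips[nd]] <<- alive
          } else {
            for (ch in children(nd)) walk(ch, alive)
          }
        }
        walk(gain_node, TRUE)
        if (any(pres)) break
      }
      mat[g, ] <- as.integer(pres)
      events[[g]] <- list(group_id = rownames(mat)[g],
                          gain_branch = branch_id(tree, gain_node),
                          loss_branches = losses,
                          n_events = 1L + length(losses))
    }
    list(matrix = mat, events = events)
  })
}

#' Simulate a nucleotide alignment under JC69 along a tree
#'
#' Root sequence uniform over A/C/G/T; along each branch of length b
#' (substitutions/site) every site changes to one of the three other bases
#' with total probability `(3/4)(1 - exp(-4b/3))`, independently across
#' sites (the exact JC69 site substitution probability).
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param length number of sites.
#' @param seed integer RNG seed.
#' @return character matrix (taxa x sites) with taxon rownames.
#' @export
simulate_alignment <- function(tree, length, seed) {
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    tree <- ape::reorder.phylo(tree, "cladewise")
    ntip <- base::length(tree$tip.label)
    root <- ntip + 1
    seqs <- vector("list", ntip + tree$Nnode)
    seqs[[root]] <- sample(bases, length, replace = TRUE)
    for (e in seq_len(nrow(tree$edge))) {
      parent <- tree$edge[e, 1]
      child <- tree$edge[e, 2]
      b <- tree$edge.length[e]
      p_change <- 0.75 * (1 - exp(-4 * b / 3))
      s <- seqs[[parent]]
      hit <- stats::runif(length) < p_change
      if (any(hit)) {
        cur <- s[hit]
        # draw uniformly among the three other bases
        shift <- sample.int(3, sum(hit), replace = TRUE)
        s[hit] <- bases[(match(cur, bases) - 1 + shift) %% 4 + 1]
      }
      seqs[[child]] <- s
    }
    m <- do.call(rbind, seqs[seq_len(ntip)])
    rownames(m) <- tree$tip.label
    m
  })
}
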