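# Backbone chemistry prediction by the assembly-line rule: one building
# block per module, in module order. NRPS modules contribute an amino-acid
# residue chosen by the A domain; PKS extension modules contribute a
# two-carbon ketide unit whose alpha-substituent comes from the AT substrate
# (malonyl -> H, methylmalonyl -> methyl, ethylmalonyl -> ethyl) and whose
# beta-keto state follows the reduction-domain rule: no KR -> ketone,
# KR -> hydroxyl, KR+DH -> enoyl (C=C), KR+DH+ER -> fully reduced methylene.
# DH or ER without KR is treated as non-functional (ketone). The loading
# module carries the starter unit; its reduction domains are not expressed
# in the product.

alpha_substituent <- function(substrate) {
  value <- substrate$value
  if (identical(substrate$confidence, "ambiguous-set")) {
    alts <- strsplit(substrate$ambiguous, ",")[[1]]
    return(paste(vapply(alts, alpha_substituent_one, ""), collapse = "-or-"))
  }
  if (identical(substrate$confidence, "tentative"))
    return(paste("H", alpha_substituent_one(value), sep = "-or-"))
  alpha_substituent_one(value)
}

alpha_substituent_one <- function(value) {
  switch(value, malonyl = "H", methylmalonyl = "methyl",
         ethylmalonyl = "ethyl", "unknown")
}

beta_state <- function(kinds) {
  has <- function(k) k %in% kinds
  if (has("KR") && has("DH") && has("ER")) "methylene"
  else if (has("KR") && has("DH")) "enoyl"
  else if (has("KR")) "hydroxyl"
  else "ketone"
}

residue_text <- function(substrate) {
  v <- substrate$value
  if (identical(v, "absent")) return("?")
  if (identical(v, "unknown") || is.na(v)) return("x")
  disp <- AA_DISPLAY[[v]]
  if (is.null(disp)) "x" else disp
}

#' Predict the peptide/polyketide backbone of a segmented cluster
#'
#' Applies the assembly-line rule: one unit per counted module, in order.
#' Single-module clusters and iterative enediyne-class PKSs are returned
#' with `predictable = FALSE` (no collinear backbone can be inferred), with
#' units still reported for the former.
#'
#' @param assembly a `bgc_assembly` from [segment_modules()].
#' @return a `bgc_backbone`: `kind` (peptide/polyketide/hybrid), ordered
#'   `units` (peptide residues carry `residue`, `n_methylated`, `epimerized`,
#'   `tentative`; polyketide units carry `alpha_substituent`, `beta_state`,
#'   `col_starter`), `terminus`, `chain_carbons` (2 per polyketide module,
#'   loading included) and `predictable`.
#' @export
predict_backbone <- function(assembly) {
  if (!inherits(assembly, "bgc_assembly"))
    stop("predict_backbone() expects a segmented assembly", call. = FALSE)
  mods <- Filter(function(m) m$counted, assembly$modules)
  units <- vector("list", length(mods))
  for (i in seq_along(mods)) {
    m <- mods[[i]]
    kinds <- m$domains$kind
    if (m$kind == "PKS") {
      units[[i]] <- list(
        type = "polyketide", position = i,
        alpha_substituent = alpha_substituent(m$substrate),
        beta_state = if (m$role == "loading") "starter"
                     else beta_state(kinds),
        col_starter = "CoL" %in% kinds)
    } else {
      units[[i]] <- list(
        type = "peptide", position = i,
        residue = residue_text(m$substrate),
        n_methylated = "MT" %in% kinds,
        epimerized = "E" %in% kinds,
        tentative = identical(m$substrate$confidence, "tentative"))
    }
  }
  types <- vapply(units, function(u) u$type, "")
  kind <- if (all(types == "peptide")) "peptide"
          else if (all(types == "polyketide")) "polyketide"
          else "hybrid"
  if (length(units) == 0)
    kind <- if (assembly$cluster_class == "NRPS") "peptide"
            else if (assembly$cluster_class == "PKS") "polyketide"
            else "hybrid"
  has_te <- any(vapply(assembly$modules, function(m)
    "TE" %in% m$domains$kind, TRUE))
  terminus <- if (has_te) "released-TE"
              else if (length(types) > 0 && types[length(types)] ==
                       "polyketide") "thioester-ACP"
              else "thioester-T"
  structure(list(
    cluster_id = assembly$cluster_id, strain_id = assembly$strain_id,
    kind = kind, units = units, terminus = terminus,
    chain_carbons = 2L * sum(types == "polyketide"),
    predictable = !assembly$enediyne && length(units) > 1,
    enediyne = assembly$enediyne), class = "bgc_backbone")
}

#' Render a backbone as a product string
#'
#' Uses the inventory-table notation: named residues as three-letter codes
#' (`m` prefix when the module carries a methyltransferase), `x` for an A
#' domain with unpredicted substrate, `?` for a module lacking its A domain,
#' and runs of polyketide modules collapsed to `pk` (a CoL/ACP-loaded
#' starter renders as `?`). Epimerization is tracked on the unit but does
#' not alter the printed residue.
#'
#' @param backbone a `bgc_backbone`.
#' @return a single string, e.g. `"x-Ser-mOrn-x-Ser-x"`.
#' @export
backbone_product_string <- function(backbone) {
  parts <- character()
  pk_open <- FALSE
  for (u in backbone$units) {
    if (u$type == "polyketide") {
      if (isTRUE(u$col_starter)) {
        parts <- c(parts, "?")
        pk_open <- FALSE
      } else if (!pk_open) {
        parts <- c(parts, "pk")
        pk_open <- TRUE
      }
    } else {
      r <- u$residue
      if (u$n_methylated && !r %in% c("x", "?")) r <- paste0("m", r)
      parts <- c(parts, r)
      pk_open <- FALSE
    }
  }
  paste(parts, collapse = "-")
}

#' Summarize the chemical features of a predicted backbone
#'
#' Feature counts over non-starter polyketide units: `double_bonds` counts
#' enoyl units, `hydroxyls` hydroxyl units, `fully_reduced` methylene units
#' and `ketones` unreduced units; `chain_carbons` is two per polyketide
#' module (loading included); `residue_composition` tallies named residues
#' plus `x` and `?` over peptide units.
#'
#' @param backbone a `bgc_backbone`.
#' @export
summarize_chemistry <- function(backbone) {
  units <- backbone$units
  pk <- Filter(function(u) u$type == "polyketide" &&
                 u$beta_state != "starter", units)
  beta <- vapply(pk, function(u) u$beta_state, "")
  pep <- Filter(function(u) u$type == "peptide", units)
  res <- vapply(pep, function(u) u$residue, "")
  list(modules = length(units),
       chain_carbons = backbone$chain_carbons,
       double_bonds = sum(beta == "enoyl"),
       hydroxyls = sum(beta == "hydroxyl"),
       ketones = sum(beta == "ketone"),
       fully_reduced = sum(beta == "methylene"),
       residue_composition = if (length(res)) table(res) else table(character()))
}

alpha_smiles <- function(alpha) {
  switch(alpha, H = "C", methyl = "C(C)", ethyl = "C(CC)", "C")
}

#' Linear notation for a predicted backbone
#'
#' Polyketide backbones are emitted as a SMILES string of the carbon chain,
#' written from the starter methyl end and terminated as a thioester to a
#' placeholder sulfur; the beta-keto state of each extension appears on the
#' preceding unit's carbonyl carbon (ketone `C(=O)`, hydroxyl `C(O)`, enoyl
#' `C=C`, methylene `C`). Peptide backbones are emitted as a dash-joined
#' residue string with `NMe-` and `D-` prefixes for MT/E modifications;
#' hybrid backbones use the peptide notation with polyketide stretches as
#' `pk`.
#'
#' @param backbone a `bgc_backbone`.
#' @param ambiguous how to resolve ambiguous alpha-substituents in SMILES
#'   output: `"error"` (default; reports the offending positions) or
#'   `"first"`/`"last"` to pick one alternative per ambiguity.
#' @export
backbone_to_linear_notation <- function(backbone,
                                        ambiguous = c("error", "first",
                                                      "last")) {
  ambiguous <- match.arg(ambiguous)
  units <- backbone$units
  if (backbone$kind != "polyketide") {
    parts <- vapply(units, function(u) {
      if (u$type == "polyketide") return("pk")
      r <- u$residue
      if (r %in% c("x", "?")) return(r)
      if (u$epimerized) r <- paste0("D-", r)
      if (u$n_methylated) r <- paste0("NMe-", r)
      r
    }, "")
    # collapse consecutive pk stretches as in the product notation
    keep <- c(TRUE, !(parts[-1] == "pk" & parts[-length(parts)] == "pk"))
    return(paste(parts[keep], collapse = "-"))
  }
  alphas <- vapply(units, function(u) u$alpha_substituent, "")
  amb <- grepl("-or-", alphas)
  if (any(amb)) {
    if (ambiguous == "error")
      stop("ambiguous alpha-substituent at position(s) ",
           paste(which(amb), collapse = ", "),
           "; set ambiguous = 'first' or 'last'", call. = FALSE)
    pick <- function(a) {
      alts <- strsplit(a, "-or-")[[1]]
      if (ambiguous == "first") alts[[1]] else alts[[length(alts)]]
    }
    alphas[amb] <- vapply(alphas[amb], pick, "")
  }
  smiles <- alpha_smiles(alphas[[1]])
  if (length(units) > 1) {
    for (i in 2:length(units)) {
      b <- units[[i]]$beta_state
      smiles <- paste0(smiles, switch(b, ketone = "C(=O)",
                                      hydroxyl = "C(O)", enoyl = "C=",
                                      methylene = "C", "C(=O)"))
      smiles <- paste0(smiles, alpha_smiles(alphas[[i]]))
    }
  }
  paste0(smiles, "C(=O)S")
}
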