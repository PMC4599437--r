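# Parsing and formatting of the compact NRPS/PKS domain-organization notation:
# domains separated by "/", module groups by "-", substrate subscripts on
# A/AT tokens ("A_ser", tentative "A_(lys)", ambiguous "AT_e(m)"/"AT_(m,e)",
# undetermined "AT_?"), "..." marking a truncated gene end and "(KS)" a
# tentative domain call.

DOMAIN_KINDS <- c("CoL", "ACP", "MT", "KS", "AT", "DH", "ER", "KR", "TE",
                  "C", "A", "T", "E")

# closed substrate vocabulary: subscript code -> controlled name
AA_SUBSTRATES <- c(
  ala = "alanine",    arg = "arginine",   asn = "asparagine",
  asp = "aspartate",  cys = "cysteine",   gln = "glutamine",
  glu = "glutamate",  gly = "glycine",    his = "histidine",
  ile = "isoleucine", leu = "leucine",    lys = "lysine",
  met = "methionine", phe = "phenylalanine", pro = "proline",
  ser = "serine",     thr = "threonine",  trp = "tryptophan",
  tyr = "tyrosine",   val = "valine",     orn = "ornithine")

EXTENDER_SUBSTRATES <- c(m = "methylmalonyl", e = "ethylmalonyl")

# controlled name -> three-letter display used in product strings
AA_DISPLAY <- stats::setNames(
  c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His", "Ile",
    "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp", "Tyr", "Val",
    "Orn"),
  unname(AA_SUBSTRATES))

empty_tokens <- function() {
  data.frame(kind = character(), substrate = character(),
             confidence = character(), ambiguous = character(),
             raw_sub = character(), tentative_domain = logical(),
             module_break = logical(), stringsAsFactors = FALSE)
}

parse_error <- function(symbol, position, why = "unknown domain symbol") {
  stop(sprintf("domain-string parse error: %s '%s' at token %d",
               why, symbol, position), call. = FALSE)
}

resolve_substrate <- function(kind, code, position, raw) {
  vocab <- if (kind == "A") AA_SUBSTRATES else EXTENDER_SUBSTRATES
  if (!code %in% names(vocab))
    parse_error(raw, position, "unknown substrate code in")
  unname(vocab[code])
}

parse_subscript <- function(kind, sub, position) {
  raw <- sub
  out <- list(substrate = NA_character_, confidence = "none",
              ambiguous = NA_character_)
  if (is.na(sub)) {
    # bare A: substrate unpredicted; bare AT incorporates malonyl-CoA
    if (kind == "AT") {
      out$substrate <- "malonyl"
      out$confidence <- "firm"
    }
    return(out)
  }
  if (sub == "?") {
    out$substrate <- "unknown"
    return(out)
  }
  if (grepl("^\\(.+\\)$", sub)) {
    inner <- substr(sub, 2, nchar(sub) - 1)
    codes <- strsplit(inner, ",", fixed = TRUE)[[1]]
    if (length(codes) == 1) {
      # parenthesized single code marks a tentative call
      out$substrate <- resolve_substrate(kind, codes, position, raw)
      out$confidence <- "tentative"
    } else {
      alts <- vapply(codes, resolve_substrate, "", kind = kind,
                     position = position, raw = raw)
      out$substrate <- alts[[1]]
      out$confidence <- "ambiguous-set"
      out$ambiguous <- paste(alts, collapse = ",")
    }
    return(out)
  }
  if (grepl("^[a-z]+\\(.+\\)$", sub)) {
    # "e(m)": either of the two codes (ambiguous set, first named outside)
    main <- sub("\\(.+\\)$", "", sub)
    alt <- sub("^[a-z]+\\((.+)\\)$", "\\1", sub)
    alts <- c(resolve_substrate(kind, main, position, raw),
              vapply(strsplit(alt, ",", fixed = TRUE)[[1]],
                     resolve_substrate, "", kind = kind,
                     position = position, raw = raw))
    out$substrate <- alts[[1]]
    out$confidence <- "ambiguous-set"
    out$ambiguous <- paste(alts, collapse = ",")
    return(out)
  }
  out$substrate <- resolve_substrate(kind, sub, position, raw)
  out$confidence <- "firm"
  out
}

#' Parse a domain-organization string
#'
#' Turns one gene's domain-organization string into an ordered token table,
#' one row per catalytic domain. `"-"` separators are recorded as soft module
#' hints (`module_break`) but do not create tokens; substrate subscripts on
#' A/AT are mapped into a closed controlled vocabulary (20 proteinogenic
#' amino acids plus ornithine for A; malonyl/methylmalonyl/ethylmalonyl for
#' AT) with a confidence level; `"..."` truncation marks set the
#' `partial_start`/`partial_end` attributes of the result rather than tokens.
#'
#' @param text a single domain-organization string, e.g. `"C/A_asp/T-TE"`.
#' @return a data.frame of tokens with columns `kind`, `substrate`,
#'   `confidence` (`firm`, `tentative`, `ambiguous-set`, `none`),
#'   `ambiguous` (comma-joined alternative substrates), `raw_sub` (verbatim
#'   subscript, kept so formatting round-trips byte-identically),
#'   `tentative_domain` (parenthesized domain call) and `module_break`;
#'   attributes `partial_start`/`partial_end` flag truncation marks.
#' @export
parse_domain_string <- function(text) {
  if (length(text) != 1 || is.na(text))
    stop("domain-string parse error: expected one non-NA string", call. = FALSE)
  s <- gsub("…", "...", trimws(text))
  if (!nzchar(s))
    stop("domain-string parse error: empty string", call. = FALSE)
  partial_start <- startsWith(s, "...")
  if (partial_start) s <- substring(s, 4)
  partial_end <- endsWith(s, "...")
  if (partial_end) s <- substring(s, 1, nchar(s) - 3)
  if (!nzchar(s))
    stop("domain-string parse error: only truncation marks", call. = FALSE)

  kind_re <- paste(DOMAIN_KINDS, collapse = "|")
  groups <- strsplit(s, "-", fixed = TRUE)[[1]]
  rows <- list()
  pos <- 0
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    if (!nzchar(g)) parse_error("-", pos + 1, "empty module group at")
    symbols <- strsplit(g, "/", fixed = TRUE)[[1]]
    for (si in seq_along(symbols)) {
      pos <- pos + 1
      sym <- symbols[[si]]
      tentative_domain <- FALSE
      body <- sym
      if (grepl(paste0("^\\((", kind_re, ")\\)$"), sym)) {
        tentative_domain <- TRUE
        body <- substr(sym, 2, nchar(sym) - 1)
      }
      m <- regmatches(body, regexec(paste0("^(", kind_re, ")(?:_(.+))?$"),
                                    body))[[1]]
      if (length(m) == 0) parse_error(sym, pos)
      kind <- m[[2]]
      sub <- if (length(m) >= 3 && nzchar(m[[3]])) m[[3]] else NA_character_
      if (!is.na(sub) && !kind %in% c("A", "AT"))
        parse_error(sym, pos, "substrate subscript on non-A/AT domain")
      subst <- parse_subscript(kind, sub, pos)
      rows[[pos]] <- data.frame(
        kind = kind, substrate = subst$substrate,
        confidence = subst$confidence, ambiguous = subst$ambiguous,
        raw_sub = if (is.na(sub)) NA_character_ else sub,
        tentative_domain = tentative_domain,
        module_break = (si == 1 && gi > 1),
        stringsAsFactors = FALSE)
    }
  }
  tokens <- do.call(rbind, rows)
  attr(tokens, "partial_start") <- partial_start
  attr(tokens, "partial_end") <- partial_end
  tokens
}

derive_subscript <- function(row) {
  if (!is.na(row$raw_sub)) return(row$raw_sub)
  if (row$confidence == "none" && is.na(row$substrate)) return(NA_character_)
  if (identical(row$substrate, "unknown")) return("?")
  vocab <- if (row$kind == "A") AA_SUBSTRATES else EXTENDER_SUBSTRATES
  code_of <- function(name) {
    i <- match(name, vocab)
    if (is.na(i)) stop("no subscript code for substrate: ", name,
                       call. = FALSE)
    names(vocab)[i]
  }
  if (row$confidence == "ambiguous-set") {
    codes <- vapply(strsplit(row$ambiguous, ",")[[1]], code_of, "")
    return(paste0("(", paste(codes, collapse = ","), ")"))
  }
  if (row$kind == "AT" && identical(row$substrate, "malonyl") &&
      row$confidence == "firm") return(NA_character_)  # implicit
  code <- code_of(row$substrate)
  if (row$confidence == "tentative") paste0("(", code, ")") else code
}

#' Format tokens back into the domain-organization notation
#'
#' Inverse of [parse_domain_string()]: `parse(format(x))` reproduces `x`, and
#' formatting a freshly parsed string reproduces it byte-identically (the
#' verbatim subscript is kept on each token for this purpose).
#'
#' @param tokens a token data.frame as returned by [parse_domain_string()].
#' @param partial_start,partial_end emit leading/trailing `"..."` marks.
#' @return the notation string.
#' @export
format_domain_string <- function(tokens, partial_start = FALSE,
                                 partial_end = FALSE) {
  if (is.null(tokens) || nrow(tokens) == 0)
    stop("cannot format an empty token list", call. = FALSE)
  parts <- character(nrow(tokens))
  for (i in seq_len(nrow(tokens))) {
    row <- tokens[i, ]
    sub <- derive_subscript(row)
    sym <- if (row$tentative_domain) paste0("(", row$kind, ")") else row$kind
    if (!is.na(sub)) sym <- paste0(sym, "_", sub)
    sep <- if (i == 1) "" else if (row$module_break) "-" else "/"
    parts[i] <- paste0(sep, sym)
  }
  out <- paste(parts, collapse = "")
  if (partial_start) out <- paste0("...", out)
  if (partial_end) out <- paste0(out, "...")
  out
}

#' Advisory findings for a parsed gene
#'
#' Flags genes the downstream analysis treats specially: single-domain genes
#' (excluded from assembly-line analysis as atypical), partially sequenced
#' genes, and NRPS genes with the unusual A-C-T domain order (normal NRPS
#' modules run C-A-T).
#'
#' @param gene a gene record as produced by [load_cluster_table()].
#' @return character vector drawn from `exclude_single_domain`, `partial`,
#'   `unusual_order` (possibly empty).
#' @export
validate_gene <- function(gene) {
  findings <- character()
  kinds <- gene$tokens$kind
  if (length(kinds) == 1) findings <- c(findings, "exclude_single_domain")
  if (isTRUE(gene$partial_start) || isTRUE(gene$partial_end) ||
      isTRUE(gene$length_lower_bound))
    findings <- c(findings, "partial")
  if (!"KS" %in% kinds && length(kinds) >= 3 &&
      identical(kinds[1:3], c("A", "C", "T")))
    findings <- c(findings, "unusual_order")
  findings
}
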