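#' Read a metabolic network from the TSV dialect
#'
#' Two tab-separated files describe a network.
#'
#' The metabolites file has header
#' `id  name  smiles  endogenous  toxicity  formula  side` with empty
#' fields for absent values; `endogenous` and `side` are 0/1 flags (`side`
#' marks freely-available cofactors).
#'
#' The reactions file has header `id  equation`; an equation reads
#' `"2 A + B => C | reversible | dG | EC | gene:score;gene:score"` where
#' `reversible` is 0/1 and the trailing fields may be empty. Coefficient 1
#' may be omitted.
#'
#' @param metabolites_path,reactions_path file paths.
#' @return A [metabolic_network()].
#' @export
load_network <- function(metabolites_path, reactions_path) {
  mtab <- utils::read.delim(metabolites_path, colClasses = "character",
                            check.names = FALSE, na.strings = NULL)
  need <- c("id", "name", "smiles", "endogenous", "toxicity", "formula", "side")
  if (!all(need %in% names(mtab)))
    stop("metabolites file lacks column(s): ",
         paste(setdiff(need, names(mtab)), collapse = ", "))
  mets <- lapply(seq_len(nrow(mtab)), function(i) {
    metabolite(id = mtab$id[i], name = mtab$name[i],
               smiles = if (nzchar(mtab$smiles[i])) mtab$smiles[i] else NA,
               endogenous = mtab$endogenous[i] == "1",
               toxicity = if (nzchar(mtab$toxicity[i]))
                 as.numeric(mtab$toxicity[i]) else NA,
               formula = if (nzchar(mtab$formula[i])) mtab$formula[i] else NA)
  })
  side <- mtab$id[mtab$side == "1"]
  rtab <- utils::read.delim(reactions_path, colClasses = "character",
                            check.names = FALSE, na.strings = NULL)
  if (!all(c("id", "equation") %in% names(rtab)))
    stop("reactions file lacks 'id'/'equation' columns")
  rxns <- lapply(seq_len(nrow(rtab)), function(i)
    parse_equation(rtab$id[i], rtab$equation[i]))
  metabolic_network(mets, rxns, side)
}

# "2 A + B => C | 1 | -3.5 | 1.1.1.1 | g1:0.9;g2:0.4"
#' Parse one reaction equation in the TSV dialect
#' @param id reaction id.
#' @param equation equation string (see [load_network()]).
#' @return A [reaction()].
#' @export
parse_equation <- function(id, equation) {
  fields <- trimws(strsplit(equation, "|", fixed = TRUE)[[1]])
  eq <- fields[1]
  sides <- strsplit(eq, "=>", fixed = TRUE)[[1]]
  if (length(sides) != 2)
    stop("equation of '", id, "' must contain one '=>'")
  parse_side <- function(txt, sign) {
    txt <- trimws(txt)
    if (!nzchar(txt)) stop("empty reaction side in '", id, "'")
    terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
    st <- numeric(0)
    for (t in terms) {
      m <- regmatches(t, regexec("^([0-9]+(?:\\.[0-9]+)?|[0-9]+/[0-9]+)?\\s*(\\S+)$", t))[[1]]
      if (length(m) == 0) stop("cannot parse term '", t, "' in '", id, "'")
      coef <- if (nzchar(m[2])) {
        if (grepl("/", m[2])) {
          p <- as.numeric(strsplit(m[2], "/")[[1]]); p[1] / p[2]
        } else as.numeric(m[2])
      } else 1
      met <- m[3]
      st[met] <- (if (met %in% names(st)) st[[met]] else 0) + sign * coef
    }
    st
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  stoich <- lhs
  for (met in names(rhs))
    stoich[met] <- (if (met %in% names(stoich)) stoich[[met]] else 0) + rhs[[met]]
  gfield <- if (length(fields) >= 5 && nzchar(fields[5])) fields[5] else ""
  genes <- if (nzchar(gfield)) {
    parts <- strsplit(strsplit(gfield, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    data.frame(gene = vapply(parts, `[`, "", 1),
               score = as.numeric(vapply(parts, `[`, "", 2)))
  } else NULL
  origin <- "known"; rule_id <- NA_character_
  if (length(fields) >= 6 && nzchar(fields[6])) {
    # optional 6th field "putative:<rule id>" for extended networks
    op <- strsplit(fields[6], ":", fixed = TRUE)[[1]]
    origin <- op[1]
    if (length(op) > 1) rule_id <- paste(op[-1], collapse = ":")
  }
  reaction(id = id, stoich = stoich,
           reversible = length(fields) >= 2 && fields[2] == "1",
           delta_g = if (length(fields) >= 3 && nzchar(fields[3]))
             as.numeric(fields[3]) else NA,
           ec = if (length(fields) >= 4 && nzchar(fields[4]))
             fields[4] else NA,
           genes = genes, origin = origin, rule_id = rule_id)
}

#' Format a reaction as a TSV-dialect equation string
#' @param r a [reaction()].
#' @return Equation string accepted by [parse_equation()].
#' @export
format_equation <- function(r) {
  fmt_side <- function(st) {
    ids <- names(st)
    paste(vapply(seq_along(st), function(i) {
      co <- abs(st[[i]])
      if (abs(co - 1) < 1e-12) ids[i] else paste(format(co, digits = 12), ids[i])
    }, ""), collapse = " + ")
  }
  subs <- r$stoich[r$stoich < 0]
  prods <- r$stoich[r$stoich > 0]
  gtxt <- if (nrow(r$genes) > 0)
    paste(paste0(r$genes$gene, ":", format(r$genes$score, digits = 12,
                                           trim = TRUE)), collapse = ";")
  else ""
  base <- paste(paste(fmt_side(subs), "=>", fmt_side(prods)),
                if (r$reversible) "1" else "0",
                if (is.na(r$delta_g)) "" else format(r$delta_g, digits = 12),
                if (is.na(r$ec)) "" else r$ec,
                gtxt, sep = " | ")
  if (r$origin == "putative")
    base <- paste(base, paste0("putative:", r$rule_id), sep = " | ")
  base
}

#' Write a network in the TSV dialect
#'
#' Inverse of [load_network()]; loading and re-writing a network is
#' byte-idempotent.
#'
#' @param net a [metabolic_network()].
#' @param metabolites_path,reactions_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_network <- function(net, metabolites_path, reactions_path) {
  blank <- function(x) ifelse(is.na(x), "", as.character(x))
  m <- net$metabolites
  mtab <- data.frame(
    id = names(m),
    name = vapply(m, `[[`, "", "name"),
    smiles = blank(vapply(m, `[[`, "", "smiles")),
    endogenous = ifelse(vapply(m, `[[`, TRUE, "endogenous"), "1", "0"),
    toxicity = blank(vapply(m, function(x)
      if (is.na(x$toxicity)) NA_character_ else
        format(x$toxicity, digits = 12), "")),
    formula = blank(vapply(m, `[[`, "", "formula")),
    side = ifelse(names(m) %in% net$side_compounds, "1", "0"),
    stringsAsFactors = FALSE)
  utils::write.table(mtab, metabolites_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  rtab <- data.frame(
    id = names(net$reactions),
    equation = vapply(net$reactions, format_equation, ""),
    stringsAsFactors = FALSE)
  utils::write.table(rtab, reactions_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(metabolites_path, reactions_path))
}
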