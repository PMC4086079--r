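#' Metabolites, reactions and metabolic networks
#'
#' A `MetabolicNetwork` holds an id-keyed set of metabolites and reactions
#' plus a set of side compounds: currency metabolites (ATP, NAD(P)(H), CoA,
#' water, protons, ...) treated as freely available and freely removable
#' when pathways are enumerated, while remaining real participants of the
#' chemistry (balance checks and reaction rules see them fully).
#'
#' @name MetabolicNetwork
NULL

#' Create a metabolite record
#'
#' @param id unique identifier within a network.
#' @param name human-readable name.
#' @param smiles SMILES string, or `NA` if no structure is known.
#' @param endogenous logical; `TRUE` for chassis-native metabolites. The
#'   endogenous set is the chassis input set for scope computation.
#' @param toxicity log10(IC50) toward the chassis, or `NA`. Higher is less
#'   toxic.
#' @param formula Hill formula string, or `NA`. Used for balance checks when
#'   no structure is available.
#' @return A `Metabolite` (list).
#' @export
metabolite <- function(id, name = id, smiles = NA_character_,
                       endogenous = FALSE, toxicity = NA_real_,
                       formula = NA_character_) {
  structure(list(id = id, name = name, smiles = smiles,
                 endogenous = isTRUE(endogenous),
                 toxicity = as.numeric(toxicity),
                 formula = as.character(formula)),
            class = "Metabolite")
}

#' Create a reaction record
#'
#' Stoichiometry is a named numeric vector over metabolite ids: negative
#' coefficients are substrates, positive are products.
#'
#' @param id unique identifier.
#' @param stoich named numeric vector; at least one negative and one
#'   positive entry.
#' @param reversible logical.
#' @param delta_g standard Gibbs free energy in kcal/mol, or `NA`.
#' @param ec EC number string, or `NA`.
#' @param genes data.frame with columns `gene` and `score` (each score in
#'   \[0,1\]); zero rows when no candidates are known.
#' @param origin `"known"` (database reaction) or `"putative"` (predicted by
#'   a reaction rule).
#' @param rule_id id of the generating rule for putative reactions.
#' @return A `Reaction` (list).
#' @export
reaction <- function(id, stoich, reversible = FALSE, delta_g = NA_real_,
                     ec = NA_character_, genes = NULL,
                     origin = c("known", "putative"), rule_id = NA_character_) {
  origin <- match.arg(origin)
  stoich <- stoich[stoich != 0]
  if (is.null(names(stoich)) || any(!nzchar(names(stoich))))
    stop("stoichiometry must be a named vector (reaction '", id, "')")
  if (anyDuplicated(names(stoich)))
    stop("duplicate metabolite in stoichiometry of reaction '", id, "'")
  if (!any(stoich < 0) || !any(stoich > 0))
    stop("reaction '", id, "' needs at least one substrate and one product")
  if (is.null(genes))
    genes <- data.frame(gene = character(), score = numeric())
  if (origin == "putative" && is.na(rule_id))
    stop("putative reaction '", id, "' must carry its rule_id")
  structure(list(id = id, stoich = stoich, reversible = isTRUE(reversible),
                 delta_g = as.numeric(delta_g), ec = as.character(ec),
                 genes = genes, origin = origin,
                 rule_id = as.character(rule_id)),
            class = "Reaction")
}

#' Assemble a metabolic network
#'
#' @param metabolites list of [metabolite()] records.
#' @param reactions list of [reaction()] records; every metabolite id they
#'   reference must exist.
#' @param side_compounds character vector of metabolite ids forming the
#'   freely-available cofactor pool.
#' @return A `MetabolicNetwork`.
#' @export
metabolic_network <- function(metabolites = list(), reactions = list(),
                              side_compounds = character()) {
  met_ids <- vapply(metabolites, `[[`, "", "id")
  if (anyDuplicated(met_ids))
    stop("duplicate metabolite id(s): ",
         paste(unique(met_ids[duplicated(met_ids)]), collapse = ", "))
  names(metabolites) <- met_ids
  rxn_ids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(rxn_ids))
    stop("duplicate reaction id(s): ",
         paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", "))
  names(reactions) <- rxn_ids
  bad <- Filter(function(r) !all(names(r$stoich) %in% met_ids), reactions)
  if (length(bad) > 0)
    stop("reaction(s) reference unknown metabolites: ",
         paste(vapply(bad, `[[`, "", "id"), collapse = ", "))
  if (!all(side_compounds %in% met_ids))
    stop("side compound(s) not in metabolite set: ",
         paste(setdiff(side_compounds, met_ids), collapse = ", "))
  structure(list(metabolites = metabolites, reactions = reactions,
                 side_compounds = sort(unique(side_compounds))),
            class = "MetabolicNetwork")
}

#' @export
print.MetabolicNetwork <- function(x, ...) {
  n_put <- sum(vapply(x$reactions, function(r) r$origin == "putative", TRUE))
  cat("MetabolicNetwork: ", length(x$metabolites), " metabolites, ",
      length(x$reactions), " reactions (", n_put, " putative), ",
      length(x$side_compounds), " side compounds\n", sep = "")
  invisible(x)
}

#' @export
summary.MetabolicNetwork <- function(object, ...) {
  print(object)
  endo <- sum(vapply(object$metabolites, `[[`, TRUE, "endogenous"))
  with_struct <- sum(!is.na(vapply(object$metabolites, `[[`, "", "smiles")))
  cat("  endogenous:", endo, " with structure:", with_struct, "\n")
  invisible(object)
}

# Cached parse of a metabolite's structure; NULL when absent.
.met_structure <- function(net, id, cache = NULL) {
  m <- net$metabolites[[id]]
  if (is.null(m)) stop("unknown metabolite '", id, "'")
  if (is.na(m$smiles)) return(NULL)
  parse_structure(m$smiles, "smiles", id = id)
}

# Element counts for one metabolite, from structure or formula.
.met_elements <- function(net, id) {
  m <- net$metabolites[[id]]
  if (!is.na(m$smiles)) return(molecule_formula(parse_structure(m$smiles,
                                                                "smiles", id)))
  if (!is.na(m$formula)) return(parse_formula(m$formula))
  NULL
}

#' Check a reaction for elemental balance
#'
#' A reaction is balanced when the stoichiometry-weighted element counts of
#' the substrates equal those of the products. Counts come from each
#' participant's structure (including implicit hydrogens) or, failing that,
#' its formula field. Charge is compared only when every participant with a
#' structure contributes one (element-only otherwise, the way curated
#' databases are incomplete).
#'
#' @param r a [reaction()] or a reaction id present in `net`.
#' @param net the [metabolic_network()] providing the participants.
#' @return `TRUE` or `FALSE`.
#' @export
validate_balance <- function(r, net) {
  if (is.character(r)) r <- net$reactions[[r]]
  missing <- names(r$stoich)[vapply(names(r$stoich), function(id) {
    m <- net$metabolites[[id]]
    is.na(m$smiles) && is.na(m$formula)
  }, TRUE)]
  if (length(missing) > 0)
    stop("cannot judge balance of '", r$id, "': no structure or formula for ",
         paste(missing, collapse = ", "))
  total <- list()
  for (id in names(r$stoich)) {
    counts <- .met_elements(net, id)
    for (el in names(counts)) {
      prev <- if (is.null(total[[el]])) 0 else total[[el]]
      total[[el]] <- prev + r$stoich[[id]] * counts[[el]]
    }
  }
  all(abs(unlist(total)) < 1e-9) || length(total) == 0
}

#' Drop unbalanced reactions from a network
#'
#' Removes every reaction that fails [validate_balance()] (or whose balance
#' cannot be judged). The number of removals is reported as a message.
#'
#' @param net a [metabolic_network()].
#' @return The filtered network.
#' @export
filter_balanced <- function(net) {
  ok <- vapply(net$reactions, function(r) {
    tryCatch(validate_balance(r, net), error = function(e) FALSE)
  }, TRUE)
  if (any(!ok))
    message("filter_balanced: removed ", sum(!ok), " unbalanced reaction(s): ",
            paste(names(net$reactions)[!ok], collapse = ", "))
  metabolic_network(net$metabolites, net$reactions[ok], net$side_compounds)
}

#' Search a network for a compound by name or structure
#'
#' Name queries rank case-insensitive exact matches first, then substring
#' matches. Structure queries (a [molecule()]) are ranked by multiset
#' [tanimoto()] similarity of molecular signatures at the given diameter.
#' Each hit is annotated endogenous or heterologous.
#'
#' @param query a character name or a [molecule()].
#' @param net a [metabolic_network()].
#' @param k maximum number of hits (must be positive; more than the
#'   collection size simply returns everything).
#' @param diameter signature diameter for structural search.
#' @return data.frame with columns `id`, `name`, `similarity`, `endogenous`,
#'   sorted by descending similarity.
#' @export
search_compound <- function(query, net, k = 10, diameter = 4) {
  if (k <= 0) stop("k must be positive")
  mets <- net$metabolites
  endo <- vapply(mets, `[[`, TRUE, "endogenous")
  nm <- vapply(mets, `[[`, "", "name")
  if (is.character(query)) {
    q <- tolower(query)
    exact <- tolower(nm) == q | tolower(names(mets)) == q
    sub <- grepl(q, tolower(nm), fixed = TRUE) & !exact
    sim <- ifelse(exact, 1, ifelse(sub, 0.5, 0))
  } else if (inherits(query, "Molecule")) {
    qsig <- molecular_signature(query, diameter)
    sim <- vapply(names(mets), function(id) {
      s <- .met_structure(net, id)
      if (is.null(s)) return(0)
      tanimoto(qsig, molecular_signature(s, diameter))
    }, 0)
  } else stop("query must be a name or a Molecule")
  keep <- which(sim > 0)
  ord <- keep[order(-sim[keep], names(mets)[keep])]
  ord <- utils::head(ord, k)
  data.frame(id = names(mets)[ord], name = nm[ord], similarity = sim[ord],
             endogenous = endo[ord], row.names = NULL,
             stringsAsFactors = FALSE)
}
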