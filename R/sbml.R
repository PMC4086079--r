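#' Export a pathway as an SBML Level 3 document
#'
#' Writes one species per pathway metabolite and one reaction per step
#' (substrates/products split by the step's flux direction). Gene
#' constructs, when given, are embedded in each reaction's `annotation`
#' block as machine-readable elements of a dedicated namespace
#' (`urn:emspath:construct`), carrying construct rank, gene id and score —
#' one downloadable file describes both the pathway and its construct
#' choices. The document round-trips through [read_pathway_sbml()].
#'
#' @param p a `Pathway` from [enumerate_pathways()].
#' @param net the [metabolic_network()] supplying stoichiometry and names.
#' @param constructs optional data.frame from [top_constructs()].
#' @return SBML document text (UTF-8).
#' @export
export_pathway_sbml <- function(p, net, constructs = NULL) {
  if (is.null(p$support) || length(p$support) == 0)
    stop("cannot export an empty pathway")
  ns_c <- "urn:emspath:construct"
  doc <- xml2::xml_new_root("sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    "xmlns:construct" = ns_c,
    level = "3", version = "1")
  model <- xml2::xml_add_child(doc, "model",
                               id = paste0("pathway_to_", p$target))
  comps <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "c", constant = "true")
  mets <- unique(unlist(lapply(net$reactions[p$support],
                               function(r) names(r$stoich))))
  los <- xml2::xml_add_child(model, "listOfSpecies")
  for (m in sort(mets)) {
    xml2::xml_add_child(los, "species", id = paste0("M_", m),
                        name = net$metabolites[[m]]$name, compartment = "c",
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition =
                          if (m %in% c(net$side_compounds, p$precursors) ||
                              m == p$target) "true" else "false",
                        constant = "false")
  }
  lor <- xml2::xml_add_child(model, "listOfReactions")
  for (rid in p$support) {
    r <- net$reactions[[rid]]
    st <- r$stoich * sign(p$flux[rid])  # orient along the pathway flux
    rx <- xml2::xml_add_child(lor, "reaction", id = paste0("R_", rid),
                              reversible = if (r$reversible) "true" else "false",
                              fast = "false")
    if (!is.null(constructs) && nrow(constructs) > 0 &&
        rid %in% names(constructs)) {
      ann <- xml2::xml_add_child(rx, "annotation")
      lst <- xml2::xml_add_child(ann, "construct:listOfGenes")
      for (i in seq_len(nrow(constructs))) {
        g <- constructs[[rid]][i]
        sc <- net$reactions[[rid]]$genes
        gs <- sc$score[match(g, sc$gene)]
        xml2::xml_add_child(lst, "construct:gene",
                            "construct:rank" = as.character(i),
                            "construct:id" = g,
                            "construct:score" = format(gs, digits = 10))
      }
    }
    lre <- xml2::xml_add_child(rx, "listOfReactants")
    for (m in names(st)[st < 0])
      xml2::xml_add_child(lre, "speciesReference",
                          species = paste0("M_", m),
                          stoichiometry = format(-st[[m]], digits = 12),
                          constant = "true")
    lpr <- xml2::xml_add_child(rx, "listOfProducts")
    for (m in names(st)[st > 0])
      xml2::xml_add_child(lpr, "speciesReference",
                          species = paste0("M_", m),
                          stoichiometry = format(st[[m]], digits = 12),
                          constant = "true")
  }
  as.character(doc)
}

#' Parse a pathway SBML document back into stoichiometry
#'
#' Inverse of [export_pathway_sbml()] for round-trip checks: returns the
#' species list, the per-reaction signed stoichiometry and any embedded
#' construct gene annotations.
#'
#' @param text SBML document text.
#' @return List with `species` (ids), `reactions` (named list of signed
#'   stoichiometry vectors) and `constructs` (named list of data.frames
#'   with `rank`, `gene`, `score`).
#' @export
read_pathway_sbml <- function(text) {
  doc <- xml2::read_xml(text)
  xml2::xml_ns_strip(doc)
  species <- xml2::xml_attr(xml2::xml_find_all(doc, ".//species"), "id")
  rx_nodes <- xml2::xml_find_all(doc, ".//reaction")
  reactions <- list()
  constructs <- list()
  for (rx in rx_nodes) {
    rid <- sub("^R_", "", xml2::xml_attr(rx, "id"))
    st <- numeric(0)
    for (sr in xml2::xml_find_all(rx, "./listOfReactants/speciesReference")) {
      m <- sub("^M_", "", xml2::xml_attr(sr, "species"))
      st[m] <- -as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(rx, "./listOfProducts/speciesReference")) {
      m <- sub("^M_", "", xml2::xml_attr(sr, "species"))
      st[m] <- as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    reactions[[rid]] <- st
    genes <- xml2::xml_find_all(rx, ".//*[local-name()='gene']")
    attr_of <- function(nodes, name) {
      v <- xml2::xml_attr(nodes, name)
      miss <- is.na(v)
      if (any(miss)) v[miss] <- xml2::xml_attr(nodes[miss],
                                               paste0("construct:", name))
      v
    }
    if (length(genes) > 0)
      constructs[[rid]] <- data.frame(
        rank = as.integer(attr_of(genes, "rank")),
        gene = attr_of(genes, "id"),
        score = as.numeric(attr_of(genes, "score")),
        stringsAsFactors = FALSE)
  }
  list(species = sub("^M_", "", species), reactions = reactions,
       constructs = constructs)
}
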