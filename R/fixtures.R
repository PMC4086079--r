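#' Built-in raspberry-ketone design problem
#'
#' A self-contained heterologous-pathway design problem: produce raspberry
#' ketone (4-(4-hydroxyphenyl)-butan-2-one) in an E. coli chassis. The
#' network holds the seven heterologous reactions of the classic design:
#' the natural two-step route from coumaroyl-CoA (benzalacetone synthase
#' BAS, benzalacetone reductase BAR), 4-coumarate--CoA ligase (4CL) to
#' supply coumaroyl-CoA, and three alternative supplies of 4-coumarate —
#' cinnamate 4-hydroxylase (C4H, EC 1.14.13.11), tyrosine ammonia-lyase
#' (TAL, EC 4.3.1.5), and hydroxyphenylpyruvate reductase (HPPR,
#' EC 1.1.1.237) followed by 3-(4-hydroxyphenyl)lactate dehydration. The
#' chassis supplies tyrosine, trans-cinnamate and 4-hydroxyphenylpyruvate
#' as endogenous precursors; cofactors (CoA esters, nucleotides,
#' NAD(P)(H), small inorganics) form the side-compound pool.
#'
#' Every metabolite carries a SMILES structure and every reaction is
#' exactly element-balanced: oxidized nicotinamide cofactors are written as
#' net-neutral inner salts and reduced ones fully protonated, so no free
#' proton species is needed. Gene candidate scores, toxicities and Gibbs
#' energies are synthetic annotations chosen at realistic magnitudes; they
#' are inputs to the ranking machinery, not literature values.
#'
#' @return List with elements `network` (a [metabolic_network()]),
#'   `chassis_seeds` (endogenous metabolite ids) and `target`
#'   (`"raspberry_ketone"`).
#' @examples
#' \donttest{
#' fx <- raspberry_network()
#' length(enumerate_pathways(fx$network, fx$chassis_seeds, fx$target))
#' }
#' @export
raspberry_network <- function() {
  coa_core <- paste0("CC(C)(COP(=O)(O)OP(=O)(O)OCC1OC(n2cnc3c(N)ncnc32)",
                     "C(O)C1OP(=O)(O)O)C(O)C(=O)NCCC(=O)NCC")
  nad_ox <- paste0("NC(=O)c1ccc[n+](c1)C1OC(COP(=O)(O)OP(=O)([O-])OCC2OC",
                   "(n3cnc4c(N)ncnc43)C(O)C2O%s)C(O)C1O")
  nad_red <- paste0("NC(=O)C1=CN(C=CC1)C1OC(COP(=O)(O)OP(=O)(O)OCC2OC",
                    "(n3cnc4c(N)ncnc43)C(O)C2O%s)C(O)C1O")
  mets <- list(
    metabolite("tyrosine", "L-tyrosine", "NC(Cc1ccc(O)cc1)C(=O)O",
               endogenous = TRUE, toxicity = -0.60),
    metabolite("cinnamate", "trans-cinnamate", "OC(=O)C=Cc1ccccc1",
               endogenous = TRUE, toxicity = -1.10),
    metabolite("hpp", "4-hydroxyphenylpyruvate", "OC(=O)C(=O)Cc1ccc(O)cc1",
               endogenous = TRUE, toxicity = -0.80),
    metabolite("coumarate", "4-coumarate", "OC(=O)C=Cc1ccc(O)cc1",
               toxicity = -1.05),
    metabolite("hpl", "3-(4-hydroxyphenyl)lactate", "OC(=O)C(O)Cc1ccc(O)cc1",
               toxicity = -0.95),
    metabolite("coumaroyl_coa", "4-coumaroyl-CoA",
               paste0(coa_core, "SC(=O)C=Cc1ccc(O)cc1"), toxicity = -1.00),
    metabolite("benzalacetone", "4-hydroxybenzalacetone",
               "CC(=O)C=Cc1ccc(O)cc1", toxicity = -1.20),
    metabolite("raspberry_ketone", "raspberry ketone", "CC(=O)CCc1ccc(O)cc1",
               toxicity = -1.30),
    metabolite("coa", "coenzyme A", paste0(coa_core, "S")),
    metabolite("malonyl_coa", "malonyl-CoA",
               paste0(coa_core, "SC(=O)CC(=O)O")),
    metabolite("atp", "ATP",
               "Nc1ncnc2c1ncn2C1OC(COP(=O)(O)OP(=O)(O)OP(=O)(O)O)C(O)C1O"),
    metabolite("amp", "AMP", "Nc1ncnc2c1ncn2C1OC(COP(=O)(O)O)C(O)C1O"),
    metabolite("ppi", "diphosphate", "OP(=O)(O)OP(=O)(O)O"),
    metabolite("nad", "NAD+", sprintf(nad_ox, "")),
    metabolite("nadh", "NADH", sprintf(nad_red, "")),
    metabolite("nadp", "NADP+", sprintf(nad_ox, "P(=O)(O)O")),
    metabolite("nadph", "NADPH", sprintf(nad_red, "P(=O)(O)O")),
    metabolite("nh3", "ammonia", "N"),
    metabolite("h2o", "water", "O"),
    metabolite("co2", "carbon dioxide", "O=C=O"),
    metabolite("o2", "dioxygen", "O=O"))
  gene_tab <- function(...) {
    gg <- list(...)
    data.frame(gene = vapply(gg, `[[`, "", 1),
               score = as.numeric(vapply(gg, `[[`, "", 2)))
  }
  rxns <- list(
    reaction("TAL", c(tyrosine = -1, coumarate = 1, nh3 = 1),
             delta_g = -8.2, ec = "4.3.1.5",
             genes = gene_tab(c("tal_Rg", "0.62"), c("tal_Se", "0.48"),
                              c("pal_Av", "0.33"))),
    reaction("C4H", c(cinnamate = -1, o2 = -1, nadph = -1,
                      coumarate = 1, h2o = 1, nadp = 1),
             delta_g = -23.5, ec = "1.14.13.11",
             genes = gene_tab(c("c4h_At", "0.57"), c("cyp73a", "0.41"))),
    reaction("HPPR", c(hpp = -1, nadh = -1, hpl = 1, nad = 1),
             delta_g = -5.1, ec = "1.1.1.237",
             genes = gene_tab(c("hppr_Cb", "0.66"), c("ldhA", "0.52"))),
    reaction("HPLH", c(hpl = -1, coumarate = 1, h2o = 1),
             delta_g = 1.9, ec = "4.2.1.-",
             genes = gene_tab(c("hplh_syn", "0.71"))),
    reaction("4CL", c(coumarate = -1, atp = -1, coa = -1,
                      coumaroyl_coa = 1, amp = 1, ppi = 1),
             delta_g = 2.4, ec = "6.2.1.12",
             genes = gene_tab(c("4cl1_At", "0.74"), c("4cl2_Nt", "0.55"),
                              c("4cl_Pc", "0.49"))),
    reaction("BAS", c(coumaroyl_coa = -1, malonyl_coa = -1, h2o = -1,
                      benzalacetone = 1, co2 = 2, coa = 2),
             delta_g = -12.6, ec = "2.3.1.-",
             genes = gene_tab(c("bas_Ri", "0.44"), c("chs_Ms", "0.28"))),
    reaction("BAR", c(benzalacetone = -1, nadph = -1,
                      raspberry_ketone = 1, nadp = 1),
             delta_g = -9.8, ec = "1.3.1.-",
             genes = gene_tab(c("bar_Ri", "0.39"), c("red_Zm", "0.31"))))
  side <- c("coa", "malonyl_coa", "atp", "amp", "ppi", "nad", "nadh",
            "nadp", "nadph", "nh3", "h2o", "co2", "o2")
  net <- metabolic_network(mets, rxns, side)
  list(network = net,
       chassis_seeds = c("tyrosine", "cinnamate", "hpp"),
       target = "raspberry_ketone")
}

#' Toy chassis FBA model for the raspberry problem
#'
#' A hand-solvable model whose metabolite rows include the three raspberry
#' precursors: bounded uptakes (tyrosine 2, cinnamate 1,
#' 4-hydroxyphenylpyruvate 1.5 flux units) and a biomass reaction drawing
#' 0.1 tyrosine per unit, capped at 5. At `gamma = 0` the precursor drain
#' capacities equal the uptake bounds.
#'
#' @return An [fba_model()].
#' @export
raspberry_chassis_model <- function() {
  mets <- c("tyrosine", "cinnamate", "hpp")
  rx <- c("UP_tyr", "UP_cin", "UP_hpp", "biomass")
  S <- matrix(0, length(mets), length(rx), dimnames = list(mets, rx))
  S["tyrosine", "UP_tyr"] <- 1
  S["cinnamate", "UP_cin"] <- 1
  S["hpp", "UP_hpp"] <- 1
  S["tyrosine", "biomass"] <- -0.1
  lb <- stats::setNames(rep(0, length(rx)), rx)
  ub <- stats::setNames(c(2, 1, 1.5, 5), rx)
  fba_model(S, lb, ub, "biomass")
}

#' Hand-solvable toy FBA model
#'
#' Two precursors A and B with bounded uptakes (10 and 6) and a biomass
#' reaction consuming one unit of each: the wild-type biomass optimum is 6,
#' drain capacities at `gamma = 0` are 10 for A and 6 for B.
#'
#' @return An [fba_model()].
#' @export
toy_fba_model <- function() {
  mets <- c("A", "B")
  rx <- c("UP_A", "UP_B", "biomass")
  S <- matrix(0, 2, 3, dimnames = list(mets, rx))
  S["A", "UP_A"] <- 1
  S["B", "UP_B"] <- 1
  S["A", "biomass"] <- -1
  S["B", "biomass"] <- -1
  fba_model(S, stats::setNames(c(0, 0, 0), rx),
            stats::setNames(c(10, 6, Inf), rx), "biomass")
}

#' Specification for a seeded random network
#'
#' @param name fixture name.
#' @param seed integer RNG seed; identical specs yield byte-identical
#'   networks.
#' @param n_distractors number of random decoy reactions.
#' @param planted_depth number of steps in each planted route.
#' @param n_routes number of disjoint planted precursor-to-target routes.
#' @param n_extra_metabolites pool of decoy metabolites the distractors
#'   draw on.
#' @return A `FixtureSpec` list.
#' @export
fixture_spec <- function(name = "random", seed = 1, n_distractors = 5,
                         planted_depth = 3, n_routes = 1,
                         n_extra_metabolites = 6) {
  if (planted_depth < 1 || n_routes < 1 || n_distractors < 0 ||
      n_extra_metabolites < 0)
    stop("infeasible fixture parameters")
  structure(list(name = name, seed = as.integer(seed),
                 n_distractors = n_distractors,
                 planted_depth = planted_depth, n_routes = n_routes,
                 n_extra_metabolites = n_extra_metabolites),
            class = "FixtureSpec")
}

#' Seeded random network with planted pathways
#'
#' Plants `n_routes` disjoint linear routes from an endogenous precursor to
#' the target (each of `planted_depth` irreversible steps through fresh
#' intermediates) and decorates the network with random distractor
#' reactions over a pool of decoy metabolites. Distractors never produce
#' the target or a planted intermediate, so every planted route remains an
#' elementary flux mode of the scope and is always recovered by
#' [enumerate_pathways()].
#'
#' @param spec a [fixture_spec()].
#' @return List with `network`, `chassis_seeds`, `target`.
#' @export
random_network <- function(spec) {
  stopifnot(inherits(spec, "FixtureSpec"))
  rs <- .with_seed(spec$seed)
  on.exit(rs())
  mets <- list()
  rxns <- list()
  target <- "target"
  mets[[target]] <- metabolite(target, "target compound")
  planted_ids <- character(0)
  for (r in seq_len(spec$n_routes)) {
    prec <- paste0("prec", r)
    mets[[prec]] <- metabolite(prec, prec, endogenous = TRUE)
    prev <- prec
    for (s in seq_len(spec$planted_depth)) {
      nxt <- if (s == spec$planted_depth) target else paste0("i", r, "_", s)
      if (is.null(mets[[nxt]]))
        mets[[nxt]] <- metabolite(nxt, nxt, toxicity = round(stats::runif(1, -2, 0), 3))
      rid <- paste0("R", r, "_", s)
      rxns[[rid]] <- reaction(rid, stats::setNames(c(-1, 1), c(prev, nxt)),
                              delta_g = round(stats::runif(1, -10, 3), 2),
                              genes = data.frame(
                                gene = paste0("g_", rid),
                                score = round(stats::runif(1, 0.2, 0.9), 3)))
      planted_ids <- c(planted_ids, rid)
      prev <- nxt
    }
  }
  protected <- c(target, grep("^i", names(mets), value = TRUE))
  for (k in seq_len(spec$n_extra_metabolites)) {
    id <- paste0("x", k)
    mets[[id]] <- metabolite(id, id, endogenous = stats::runif(1) < 0.3)
  }
  pool <- names(mets)
  k <- 0
  while (k < spec$n_distractors) {
    a <- sample(pool, 1)
    b <- sample(setdiff(pool, c(a, protected)), 1)
    k <- k + 1
    rid <- paste0("D", k)
    rxns[[rid]] <- reaction(rid, stats::setNames(c(-1, 1), c(a, b)),
                            reversible = stats::runif(1) < 0.3,
                            delta_g = round(stats::runif(1, -10, 5), 2))
  }
  net <- metabolic_network(unname(mets), unname(rxns), character())
  seeds <- names(net$metabolites)[vapply(net$metabolites, `[[`, TRUE,
                                         "endogenous")]
  list(network = net, chassis_seeds = seeds, target = target,
       planted = planted_ids)
}

# run code under a fixed seed, restoring the caller's RNG state
.with_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}
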