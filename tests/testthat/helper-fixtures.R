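# Small networks built in code and shared across test files.

# linear chain A -> B -> C with endogenous A
chain_network <- function() {
  metabolic_network(
    list(metabolite("A", endogenous = TRUE), metabolite("B"),
         metabolite("C")),
    list(reaction("r1", c(A = -1, B = 1)),
         reaction("r2", c(B = -1, C = 1))))
}

# diamond: A -> B -> D and A -> C -> D, endogenous A
diamond_network <- function() {
  metabolic_network(
    list(metabolite("A", endogenous = TRUE), metabolite("B"),
         metabolite("C"), metabolite("D")),
    list(reaction("ab", c(A = -1, B = 1)),
         reaction("bd", c(B = -1, D = 1)),
         reaction("ac", c(A = -1, C = 1)),
         reaction("cd", c(C = -1, D = 1))))
}

# keto-acid reduction universe: one template reduction plus a second
# keto/hydroxy pair the rule can transfer to at low diameter
keto_universe <- function() {
  nad_smi <- paste0("NC(=O)c1ccc[n+](c1)C1OC(COP(=O)(O)OP(=O)([O-])OCC2OC",
                    "(n3cnc4c(N)ncnc43)C(O)C2O)C(O)C1O")
  nadh_smi <- paste0("NC(=O)C1=CN(C=CC1)C1OC(COP(=O)(O)OP(=O)(O)OCC2OC",
                     "(n3cnc4c(N)ncnc43)C(O)C2O)C(O)C1O")
  metabolic_network(
    list(metabolite("hpp", "4-hydroxyphenylpyruvate",
                    "OC(=O)C(=O)Cc1ccc(O)cc1", endogenous = TRUE),
         metabolite("hpl", "4-hydroxyphenyllactate",
                    "OC(=O)C(O)Cc1ccc(O)cc1"),
         metabolite("pyr", "pyruvate", "CC(=O)C(=O)O", endogenous = TRUE),
         metabolite("lac", "lactate", "CC(O)C(=O)O"),
         metabolite("nad", "NAD+", nad_smi),
         metabolite("nadh", "NADH", nadh_smi)),
    list(reaction("HPPR", c(hpp = -1, nadh = -1, hpl = 1, nad = 1))),
    side_compounds = c("nad", "nadh"))
}

raspberry_cached <- local({
  fx <- NULL
  function() {
    if (is.null(fx)) fx <<- raspberry_network()
    fx
  }
})

pathways_cached <- local({
  pw <- NULL
  function() {
    if (is.null(pw)) {
      fx <- raspberry_cached()
      pw <<- enumerate_pathways(fx$network, fx$chassis_seeds, fx$target)
    }
    pw
  }
})
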