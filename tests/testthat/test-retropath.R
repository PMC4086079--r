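test_that("forward reachability is a least fixpoint with free side compounds", {
  net <- chain_network()
  expect_equal(forward_reachable(net, "A"), c("A", "B", "C"))
  expect_equal(forward_reachable(net, "B"), c("B", "C"))
  expect_error(forward_reachable(net, "Z"), "unknown seed")

  # a two-substrate reaction needs both inputs unless one is a side compound
  net2 <- metabolic_network(
    list(metabolite("A", endogenous = TRUE), metabolite("X"),
         metabolite("P")),
    list(reaction("r", c(A = -1, X = -1, P = 1))))
  expect_equal(forward_reachable(net2, "A"), "A")
  net3 <- metabolic_network(net2$metabolites, net2$reactions,
                            side_compounds = "X")
  expect_equal(forward_reachable(net3, "A"), c("A", "P"))

  # reversible reactions propagate both ways
  net4 <- metabolic_network(
    list(metabolite("A", endogenous = TRUE), metabolite("B")),
    list(reaction("r", c(B = -1, A = 1), reversible = TRUE)))
  expect_equal(forward_reachable(net4, "A"), c("A", "B"))
})

test_that("backward pruning keeps only route-relevant reactions", {
  # a dead-end branch off the diamond must not enter the scope
  net <- metabolic_network(
    c(diamond_network()$metabolites, list(metabolite("E"))),
    c(diamond_network()$reactions,
      list(reaction("be", c(B = -1, E = 1)))))
  reach <- forward_reachable(net, "A")
  expect_true(all(c("D", "E") %in% reach))
  scope <- backward_prune(net, reach, "D")
  expect_setequal(scope$reactions, c("ab", "bd", "ac", "cd"))
  expect_false("be" %in% scope$reactions)
  expect_equal(scope$precursors, "A")
  expect_equal(scope$target, "D")
  expect_error(backward_prune(net, reach, "Z"), "not in the network")
  expect_error(backward_prune(net, "A", "D"), "not reachable")
})

test_that("the stoichiometric matrix carries explicit boundary columns", {
  net <- diamond_network()
  scope <- backward_prune(net, forward_reachable(net, "A"), "D")
  mat <- build_stoichiometric_matrix(scope, net)
  expect_true("EX_A_in" %in% colnames(mat$S))
  expect_equal(mat$target_col, "SINK_D")
  expect_equal(mat$S["D", "SINK_D"], -1)
  expect_equal(mat$S["A", "EX_A_in"], 1)
  expect_false(mat$reversible[["EX_A_in"]])
  expect_true(all(mat$boundary[c("EX_A_in", "SINK_D")]))
  expect_false(any(mat$boundary[scope$reactions]))
  # every interior row balances only through its own reactions and boundaries
  expect_equal(nrow(mat$S), length(scope$metabolites))
})

test_that("pathway enumeration finds each branch of a diamond once", {
  net <- diamond_network()
  pws <- enumerate_pathways(net, "A", "D")
  expect_length(pws, 2)
  supports <- lapply(pws, `[[`, "support")
  expect_true(any(vapply(supports, identical, TRUE, c("ab", "bd"))))
  expect_true(any(vapply(supports, identical, TRUE, c("ac", "cd"))))
  for (p in pws) {
    expect_equal(p$n_steps, 2)
    expect_equal(p$n_putative, 0)
    expect_equal(p$precursors, "A")
    expect_gt(p$flux[["SINK_D"]], 0)
  }
  # deterministic lexicographic-by-support ordering
  keys <- vapply(pws, function(p) paste(p$support, collapse = "|"), "")
  expect_identical(keys, sort(keys))
})

test_that("an unproducible target reports no pathway rather than failing", {
  net <- metabolic_network(
    list(metabolite("A", endogenous = TRUE), metabolite("B"),
         metabolite("C")),
    list(reaction("r1", c(A = -1, B = 1)),
         reaction("r2", c(C = -1, B = 1))))
  expect_error(enumerate_pathways(net, "A", "C"), "not reachable")
})

test_that("raspberry ketone enumeration reproduces the published route set", {
  pws <- pathways_cached()
  expect_length(pws, 3)
  steps <- sort(vapply(pws, `[[`, 0L, "n_steps"))
  expect_equal(steps, c(4L, 4L, 5L))
  expect_true(all(vapply(pws, `[[`, 0L, "n_putative") == 0L))
  # the three routes differ in how 4-coumarate is made: deamination of
  # tyrosine (TAL), hydroxylation of cinnamate (C4H), or reduction then
  # cleavage of 4-hydroxyphenylpyruvate (HPPR + HPLH)
  entry <- lapply(pws, function(p)
    sort(intersect(p$support, c("TAL", "C4H", "HPPR", "HPLH"))))
  expect_setequal(entry, list("TAL", "C4H", c("HPLH", "HPPR")))
  # all routes share the committed downstream steps
  for (p in pws)
    expect_true(all(c("4CL", "BAS", "BAR") %in% p$support))
})

test_that("pathway tables write one row per pathway", {
  pws <- pathways_cached()
  f <- tempfile(fileext = ".tsv")
  write_pathways_tsv(pws, f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$n_steps, vapply(pws, `[[`, 0L, "n_steps"))
  expect_equal(tab$n_putative, rep(0L, 3))
})
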