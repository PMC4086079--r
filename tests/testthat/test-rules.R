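test_that("rule derivation computes the signed signature difference", {
  net <- keto_universe()
  rule <- derive_rule("HPPR", net, 2)
  expect_s3_class(rule, "ReactionRule")
  expect_equal(rule$diameter, 2L)
  expect_equal(rule$substrate_arity, 2L)
  expect_equal(rule$product_arity, 2L)
  # signed delta is conservative: coefficients sum to zero when substrate
  # and product heavy-atom counts agree (reduction adds only hydrogens)
  expect_equal(sum(rule$delta), 0)
  expect_gt(length(rule$delta), 0)
  expect_error(derive_rule("HPPR", net, 3), "even")

  # a structure-less participant is a hard error naming the metabolite
  net2 <- metabolic_network(
    list(metabolite("u"), metabolite("v", smiles = "C")),
    list(reaction("r", c(u = -1, v = 1))))
  expect_error(derive_rule("r", net2, 2), "'u'")
})

test_that("connectivity-only isomerization gives an empty rule at d=0", {
  # o-xylene -> p-xylene: identical atom-label multisets, different
  # connectivity, so the delta vanishes at d=0 but not at d>=2
  net <- metabolic_network(
    list(metabolite("oxyl", smiles = "Cc1ccccc1C"),
         metabolite("pxyl", smiles = "Cc1ccc(C)cc1")),
    list(reaction("iso", c(oxyl = -1, pxyl = 1))))
  expect_length(derive_rule("iso", net, 0)$delta, 0)
  expect_gt(length(derive_rule("iso", net, 2)$delta), 0)
})

test_that("derived rules regenerate their template reaction", {
  fx <- raspberry_cached()
  net <- fx$network
  cache <- .sig_cache()
  for (rid in names(net$reactions)) {
    r <- net$reactions[[rid]]
    rule <- derive_rule(r, net, 6, cache)
    subs <- rep(names(r$stoich)[r$stoich < 0], -r$stoich[r$stoich < 0])
    # the template itself is suppressed as an existing reaction, so apply
    # against the network minus the template
    net_minus <- metabolic_network(net$metabolites,
                                   net$reactions[setdiff(names(net$reactions),
                                                         rid)],
                                   net$side_compounds)
    put <- apply_rule(rule, subs, net_minus, cache)
    keys <- vapply(put, function(p) .stoich_key(p$stoich), "")
    expect_true(.stoich_key(r$stoich) %in% keys,
                label = paste("template regeneration for", rid))
  }
})

test_that("rule sets deduplicate identical chemistry and skip stubs", {
  net <- keto_universe()
  rules <- derive_rule_set(net, c(0, 2))
  expect_length(rules, 2)
  expect_true(all(vapply(rules, function(r) inherits(r, "ReactionRule"), TRUE)))

  # adding the second reduction with the same local chemistry merges at d=0
  net2 <- metabolic_network(net$metabolites,
    c(net$reactions,
      list(reaction("LDH", c(pyr = -1, nadh = -1, lac = 1, nad = 1)))))
  r0 <- derive_rule_set(net2, 0)
  expect_length(r0, 1)
  expect_setequal(r0[[1]]$template_reaction_ids, c("HPPR", "LDH"))

  # structure-less participants are skipped with a message, not an error
  net3 <- metabolic_network(
    c(net$metabolites, list(metabolite("ghost"))),
    c(net$reactions, list(reaction("gr", c(ghost = -1, pyr = 1)))))
  expect_message(rset <- derive_rule_set(net3, 2), "gr")
  expect_length(rset, 1)
})

test_that("a broad rule transfers to an analogous substrate", {
  net <- keto_universe()
  rule0 <- derive_rule("HPPR", net, 0)
  put <- apply_rule(rule0, c("pyr", "nadh"), net)
  st <- lapply(put, `[[`, "stoich")
  expect_true(any(vapply(st, function(s)
    identical(.stoich_key(s),
              .stoich_key(c(pyr = -1, nadh = -1, lac = 1, nad = 1))), TRUE)))
  p <- put[[1]]
  expect_equal(p$origin, "putative")
  expect_equal(p$rule_id, rule0$id)
  expect_match(p$id, "^put_")

  # at d=2 the hydroxyphenyl environment no longer matches pyruvate
  rule2 <- derive_rule("HPPR", net, 2)
  expect_length(apply_rule(rule2, c("pyr", "nadh"), net), 0)
  # wrong substrate count is a usage error
  expect_error(apply_rule(rule0, "pyr", net), "2 substrate")
})

test_that("putative reactions at smaller diameter are a superset of larger", {
  net <- keto_universe()
  keys_at <- function(d) {
    rule <- derive_rule("HPPR", net, d)
    combos <- .combinations_with_repetition(names(net$metabolites), 2)
    keys <- character(0)
    for (cmb in combos)
      for (p in apply_rule(rule, cmb, net))
        keys <- c(keys, .stoich_key(p$stoich))
    unique(keys)
  }
  k0 <- keys_at(0); k2 <- keys_at(2); k6 <- keys_at(6)
  expect_true(all(k2 %in% k0))
  expect_true(all(k6 %in% k2))
  expect_gt(length(k0), length(k2))
})

test_that("network extension reaches a fixpoint and tags its additions", {
  net <- keto_universe()
  rules <- list(derive_rule("HPPR", net, 0))
  ext <- extend_network(net, rules)
  expect_true(ext$converged)
  expect_gte(ext$iterations_used, 1)
  expect_gt(length(ext$added), 0)
  added <- ext$network$reactions[ext$added]
  expect_true(all(vapply(added, function(r) r$origin == "putative", TRUE)))
  # fixpoint: extending again adds nothing
  ext2 <- extend_network(ext$network, rules)
  expect_length(ext2$added, 0)
  expect_equal(ext2$iterations_used, 1)
})

test_that("rules round-trip through TSV", {
  net <- keto_universe()
  rules <- derive_rule_set(net, c(0, 2))
  f <- tempfile(fileext = ".tsv")
  write_rules_tsv(rules, f)
  back <- read_rules_tsv(f)
  expect_length(back, length(rules))
  for (i in seq_along(rules)) {
    expect_equal(back[[i]]$id, rules[[i]]$id)
    expect_equal(back[[i]]$diameter, rules[[i]]$diameter)
    expect_equal(back[[i]]$substrate_arity, rules[[i]]$substrate_arity)
    expect_equal(back[[i]]$delta[order(names(back[[i]]$delta))],
                 rules[[i]]$delta[order(names(rules[[i]]$delta))])
  }
})
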