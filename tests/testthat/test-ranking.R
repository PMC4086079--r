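test_that("gene score averages the best candidate per step", {
  fx <- raspberry_cached()
  pws <- pathways_cached()
  tal_route <- Filter(function(p) "TAL" %in% p$support, pws)[[1]]
  # per-step maxima: TAL 0.62, 4CL 0.74, BAS 0.44, BAR 0.39
  expect_equal(gene_score(tal_route, fx$network),
               mean(c(0.62, 0.74, 0.44, 0.39)))

  # a step without candidates contributes zero, with a message
  net <- metabolic_network(
    list(metabolite("A", endogenous = TRUE), metabolite("B"),
         metabolite("C")),
    list(reaction("r1", c(A = -1, B = 1),
                  genes = data.frame(gene = "g", score = 0.8)),
         reaction("r2", c(B = -1, C = 1))))
  p <- enumerate_pathways(net, "A", "C")[[1]]
  expect_message(gs <- gene_score(p, net), "without gene")
  expect_equal(gs, 0.4)
})

test_that("toxicity averages over true intermediates only", {
  fx <- raspberry_cached()
  pws <- pathways_cached()
  tal_route <- Filter(function(p) "TAL" %in% p$support, pws)[[1]]
  ints <- .intermediates(tal_route, fx$network)
  # tyrosine is the precursor, raspberry ketone the target, cofactors are
  # side compounds: only the carbon backbone intermediates remain
  expect_setequal(ints, c("coumarate", "coumaroyl_coa", "benzalacetone"))
  expect_equal(toxicity_score(tal_route, fx$network),
               mean(c(-1.05, -1.00, -1.20)))

  # with no annotated intermediate the score is absent, not zero
  net <- chain_network()
  p <- enumerate_pathways(net, "A", "C")[[1]]
  expect_true(is.na(suppressMessages(toxicity_score(p, net))))
})

test_that("Gibbs metrics sum energies and count unfavorable steps", {
  fx <- raspberry_cached()
  pws <- pathways_cached()
  tal_route <- Filter(function(p) "TAL" %in% p$support, pws)[[1]]
  gm <- gibbs_metrics(tal_route, fx$network)
  expect_equal(gm$gibbs_sum, -8.2 + 2.4 + -12.6 + -9.8)
  expect_equal(gm$n_unfavorable, 1)   # only 4CL is uphill
})

test_that("criterion normalization is direction-aware and NA-neutral", {
  x <- c(1, 3, 2, NA)
  up <- .normalize_criterion(x, TRUE, "minmax")
  expect_equal(up, c(0, 1, 0.5, 0.5))
  dn <- .normalize_criterion(x, FALSE, "minmax")
  expect_equal(dn, c(1, 0, 0.5, 0.5))
  # degenerate spread collapses to the neutral midpoint
  expect_equal(.normalize_criterion(c(2, 2), TRUE, "minmax"), c(0.5, 0.5))
  z <- .normalize_criterion(c(1, 3), TRUE, "zscore")
  expect_equal(mean(z), 0)
  expect_equal(.normalize_criterion(c(1, 3), TRUE, "none"), c(1, 3))
  expect_error(score_weights(w_gene = Inf), "finite")
})

test_that("total scores are invariant under pathway permutation", {
  tab <- data.frame(gene_score = c(0.5, 0.7, 0.2),
                    toxicity = c(-1, -2, NA),
                    yield = c(2, 1, 3),
                    gibbs_sum = c(-10, 5, 0))
  s <- total_score(tab, score_weights())
  perm <- c(3, 1, 2)
  s2 <- total_score(tab[perm, ], score_weights())
  expect_equal(s2, s[perm])
  # weights scale their criterion's influence
  only_gene <- total_score(tab, score_weights(1, 0, 0, 0))
  expect_equal(order(-only_gene), order(-tab$gene_score))
})

test_that("ranked raspberry table is complete, ordered and well-typed", {
  fx <- raspberry_cached()
  pws <- pathways_cached()
  ranked <- suppressMessages(
    rank_pathways(pws, fx$network, raspberry_chassis_model()))
  expect_s3_class(ranked, "RankedPathways")
  expect_equal(nrow(ranked), 3)
  expect_equal(ranked$rank, 1:3)
  expect_true(all(diff(ranked$total) <= 0))
  expect_setequal(ranked$n_steps, c(4L, 4L, 5L))
  expect_true(all(ranked$n_putative == 0L))
  expect_true(all(is.finite(ranked$yield)))
  expect_setequal(ranked$yield, c(2, 1, 1.5))
  rp <- attr(ranked, "pathways")
  expect_length(rp, 3)
  expect_equal(vapply(rp, function(p) paste(p$support, collapse = ","), ""),
               ranked$support)
  # without a model the yield criterion goes neutral but ranking still works
  r2 <- suppressMessages(rank_pathways(pws, fx$network, model = NULL))
  expect_true(all(is.na(r2$yield)))
  expect_equal(nrow(r2), 3)
  # empty input gives an empty ranking
  expect_equal(nrow(rank_pathways(list(), fx$network)), 0)
})

test_that("ranking TSV carries the summary-table columns", {
  fx <- raspberry_cached()
  ranked <- suppressMessages(
    rank_pathways(pathways_cached(), fx$network, raspberry_chassis_model()))
  f <- tempfile(fileext = ".tsv")
  write_ranking_tsv(ranked, f, header = "config: default weights")
  lines <- readLines(f)
  expect_match(lines[1], "^# config")
  hdr <- strsplit(lines[2], "\t")[[1]]
  expect_equal(hdr, c("Rank", "Total score", "Gene score", "Steps",
                      "Putatives", "Toxicity", "Yield", "Gibbs",
                      "Unfavorable"))
  expect_length(lines, 2 + 3)
})

test_that("k-best constructs match exhaustive enumeration", {
  fx <- raspberry_cached()
  pws <- pathways_cached()
  for (p in pws) {
    got <- top_constructs(p, fx$network, k = 10)
    want <- oracle_constructs(p, fx$network, k = 10)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$score, want$score)
    for (col in p$support) expect_equal(got[[col]], want[[col]])
  }
})

test_that("construct enumeration is lazy-safe on edge cases", {
  fx <- raspberry_cached()
  pws <- pathways_cached()
  p <- pws[[1]]
  # k = 1 returns exactly the per-step argmax construct
  best <- top_constructs(p, fx$network, k = 1)
  expect_equal(nrow(best), 1)
  for (rid in p$support) {
    g <- fx$network$reactions[[rid]]$genes
    expect_equal(best[[rid]], g$gene[which.max(g$score)])
  }
  # k beyond the product size returns every construct, still sorted
  total <- prod(vapply(p$support, function(rid)
    nrow(fx$network$reactions[[rid]]$genes), 0))
  all_c <- top_constructs(p, fx$network, k = total + 50)
  expect_equal(nrow(all_c), total)
  expect_true(all(diff(all_c$score) <= 1e-12))
  expect_error(top_constructs(p, fx$network, k = 0), "k must be")
})
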