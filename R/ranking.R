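#' Pathway ranking criteria
#'
#' Each enumerated pathway is summarized by eight quantities: total score,
#' gene score, number of steps, number of putative steps, mean toxicity of
#' intermediates, maximum allowable yield, summed Gibbs free energy, and
#' number of thermodynamically unfavorable steps. The total score is a
#' weighted sum of the normalized gene, toxicity, yield and Gibbs terms.
#'
#' @name ranking
NULL

#' Gene availability score of a pathway
#'
#' Mean over the pathway's steps of the best candidate-gene score of each
#' step. A step with no candidate genes contributes 0 (a message reports
#' it).
#'
#' @param p a `Pathway`.
#' @param net the [metabolic_network()] carrying the gene annotations.
#' @return Score in \[0, 1\].
#' @export
gene_score <- function(p, net) {
  per_step <- vapply(p$support, function(rid) {
    g <- net$reactions[[rid]]$genes
    if (nrow(g) == 0) return(NA_real_)
    max(g$score)
  }, 0)
  if (anyNA(per_step))
    message("gene_score: ", sum(is.na(per_step)),
            " step(s) without gene candidates contribute 0")
  mean(ifelse(is.na(per_step), 0, per_step))
}

# intermediates: produced and consumed within the support, excluding
# precursors, side compounds and the target
.intermediates <- function(p, net) {
  produced <- consumed <- character(0)
  for (rid in p$support) {
    st <- net$reactions[[rid]]$stoich * sign(p$flux[rid])
    produced <- union(produced, names(st)[st > 0])
    consumed <- union(consumed, names(st)[st < 0])
  }
  setdiff(intersect(produced, consumed),
          c(p$precursors, net$side_compounds, p$target))
}

#' Mean toxicity of pathway intermediates
#'
#' Average log10(IC50) over the pathway's intermediate metabolites
#' (compounds both produced and consumed by its steps, excluding
#' precursors, side compounds and the target). Intermediates without a
#' toxicity value are skipped with a message; if none has a value the
#' score is absent (`NA`) and ranks with a neutral contribution.
#'
#' @inheritParams gene_score
#' @return Mean log10(IC50), or `NA`.
#' @export
toxicity_score <- function(p, net) {
  ints <- .intermediates(p, net)
  vals <- vapply(ints, function(id) net$metabolites[[id]]$toxicity, 0)
  if (any(is.na(vals)))
    message("toxicity_score: no toxicity value for ",
            paste(ints[is.na(vals)], collapse = ", "))
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) return(NA_real_)
  mean(vals)
}

#' Gibbs energy metrics of a pathway
#'
#' Sum of the steps' standard Gibbs free energies (kcal/mol) and the count
#' of unfavorable steps (deltaG > 0). Steps without a value contribute 0 to
#' the sum and are excluded from the count (a message reports them).
#'
#' @inheritParams gene_score
#' @return List with `gibbs_sum` and `n_unfavorable`.
#' @export
gibbs_metrics <- function(p, net) {
  dg <- vapply(p$support, function(rid) net$reactions[[rid]]$delta_g, 0)
  if (any(is.na(dg)))
    message("gibbs_metrics: no deltaG for ",
            paste(p$support[is.na(dg)], collapse = ", "))
  list(gibbs_sum = sum(dg, na.rm = TRUE),
       n_unfavorable = sum(dg > 0, na.rm = TRUE))
}

#' Maximum allowable yield of a pathway
#'
#' For each pathway precursor the chassis' spare production capacity is
#' measured by FBA: a synthetic drain of the precursor is added to the
#' model and maximized subject to steady state, the model bounds, and
#' biomass flux at least `gamma` times the wild-type optimum. The
#' pathway's yield through that precursor is the available flux divided by
#' the pathway's stoichiometric demand for it per unit of target; the
#' pathway yield is the minimum over precursors, and the minimizing
#' precursor is the bottleneck (a precursor also consumed for biomass
#' production).
#'
#' @param p a `Pathway`.
#' @param model an [fba_model()] of the chassis; every pathway precursor
#'   must be one of its metabolite rows.
#' @param gamma fraction of the wild-type biomass optimum that must be
#'   retained while draining (default 0).
#' @return List with `yield`, `bottleneck` (precursor id), and
#'   `per_precursor` (named vector of per-precursor yields).
#' @export
max_allowable_yield <- function(p, model, gamma = 0) {
  if (length(p$precursors) == 0) stop("pathway has no precursors")
  missing <- setdiff(p$precursors, rownames(model$S))
  if (length(missing) > 0)
    stop("precursor(s) absent from the FBA model: ",
         paste(missing, collapse = ", "))
  wt <- fba_optimize(model)$objective_value
  sink_flux <- p$flux[grep("^SINK_", names(p$flux))][1]
  ys <- vapply(p$precursors, function(q) {
    avail <- .drain_capacity(model, q, gamma * wt)
    up_col <- paste0("EX_", q, "_in")
    demand <- if (up_col %in% names(p$flux)) p$flux[[up_col]] / sink_flux else 0
    if (demand <= 0) return(Inf)  # precursor not actually drawn from chassis
    avail / demand
  }, 0)
  i <- which.min(ys)
  list(yield = unname(ys[i]), bottleneck = p$precursors[i],
       per_precursor = ys)
}

# maximum flux of a synthetic drain of metabolite q, holding biomass >= min_bio
.drain_capacity <- function(model, q, min_bio) {
  S2 <- cbind(model$S, drain_q = 0)
  S2[q, "drain_q"] <- -1
  lb <- c(model$lb, drain_q = 0)
  ub <- c(model$ub, drain_q = Inf)
  if (min_bio > 0) lb[model$objective] <- min_bio
  m2 <- fba_model(S2, lb, ub, model$objective)
  fba_optimize(m2, objective = "drain_q")$objective_value
}

#' Score-normalization weights
#'
#' @param w_gene,w_tox,w_yield,w_gibbs weights of the four criteria.
#' @param normalization `"minmax"` (default), `"zscore"` or `"none"`.
#' @return A `ScoreWeights` list.
#' @export
score_weights <- function(w_gene = 1, w_tox = 1, w_yield = 1, w_gibbs = 1,
                          normalization = c("minmax", "zscore", "none")) {
  normalization <- match.arg(normalization)
  w <- c(w_gene = w_gene, w_tox = w_tox, w_yield = w_yield, w_gibbs = w_gibbs)
  if (any(!is.finite(w))) stop("weights must be finite")
  structure(list(weights = w, normalization = normalization),
            class = "ScoreWeights")
}

# normalize a criterion across the pathway set; higher_better flips sign.
# NA values take the neutral mid value.
.normalize_criterion <- function(x, higher_better, normalization) {
  dir_x <- if (higher_better) x else -x
  obs <- dir_x[!is.na(dir_x)]
  out <- switch(normalization,
    minmax = {
      if (length(obs) == 0 || diff(range(obs)) < 1e-12)
        rep(0.5, length(x))
      else (dir_x - min(obs)) / (max(obs) - min(obs))
    },
    zscore = {
      if (length(obs) < 2 || stats::sd(obs) < 1e-12) rep(0, length(x))
      else (dir_x - mean(obs)) / stats::sd(obs)
    },
    none = dir_x)
  mid <- switch(normalization, minmax = 0.5, zscore = 0, none = 0)
  ifelse(is.na(out), mid, out)
}

#' Total pathway scores
#'
#' Normalizes each criterion across the pathway set (directions fixed:
#' higher gene score, higher log10(IC50) (less toxic), higher yield and
#' lower Gibbs sum are all better) and returns the weighted sums. The
#' result is invariant under permutation of the input list.
#'
#' @param table data.frame with columns `gene_score`, `toxicity`, `yield`,
#'   `gibbs_sum` (one row per pathway; `NA` toxicity allowed).
#' @param weights a [score_weights()].
#' @return Numeric vector of total scores (empty for an empty table).
#' @export
total_score <- function(table, weights = score_weights()) {
  if (nrow(table) == 0) return(numeric(0))
  w <- weights$weights
  nrm <- weights$normalization
  w[["w_gene"]] * .normalize_criterion(table$gene_score, TRUE, nrm) +
    w[["w_tox"]] * .normalize_criterion(table$toxicity, TRUE, nrm) +
    w[["w_yield"]] * .normalize_criterion(table$yield, TRUE, nrm) +
    w[["w_gibbs"]] * .normalize_criterion(table$gibbs_sum, FALSE, nrm)
}

#' Rank pathways on all eight criteria
#'
#' Computes the per-pathway quantities (gene score, steps, putative steps,
#' toxicity, maximum allowable yield, Gibbs sum, unfavorable count),
#' normalizes and combines them into total scores, and returns the
#' pathways sorted by descending total with deterministic tie-breaking
#' (fewer steps first, then lexicographic support).
#'
#' @param pathways list of `Pathway`s from [enumerate_pathways()].
#' @param net the [metabolic_network()].
#' @param model an [fba_model()] of the chassis, or `NULL` to skip yields.
#' @param weights a [score_weights()].
#' @param gamma growth fraction passed to [max_allowable_yield()].
#' @return A `RankedPathways` data.frame with columns `rank`, `total`,
#'   `gene_score`, `n_steps`, `n_putative`, `toxicity`, `yield`,
#'   `gibbs_sum`, `n_unfavorable`, `bottleneck`, `support`; the pathway
#'   objects (ranked order) are in attribute `pathways`.
#' @export
rank_pathways <- function(pathways, net, model = NULL,
                          weights = score_weights(), gamma = 0) {
  if (length(pathways) == 0)
    return(structure(data.frame(), class = c("RankedPathways", "data.frame")))
  rows <- lapply(pathways, function(p) {
    gm <- gibbs_metrics(p, net)
    y <- if (is.null(model)) list(yield = NA_real_, bottleneck = NA_character_)
         else max_allowable_yield(p, model, gamma)
    data.frame(gene_score = gene_score(p, net), n_steps = p$n_steps,
               n_putative = p$n_putative, toxicity = toxicity_score(p, net),
               yield = y$yield, gibbs_sum = gm$gibbs_sum,
               n_unfavorable = gm$n_unfavorable, bottleneck = y$bottleneck,
               support = paste(p$support, collapse = ","),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$total <- total_score(tab, weights)
  ord <- order(-tab$total, tab$n_steps, tab$support)
  tab <- tab[ord, , drop = FALSE]
  tab <- cbind(rank = seq_len(nrow(tab)),
               tab[, c("total", "gene_score", "n_steps", "n_putative",
                       "toxicity", "yield", "gibbs_sum", "n_unfavorable",
                       "bottleneck", "support")])
  rownames(tab) <- NULL
  structure(tab, class = c("RankedPathways", "data.frame"),
            pathways = pathways[ord])
}

#' @export
print.RankedPathways <- function(x, ...) {
  cat("Ranked pathways (", nrow(x), "):\n", sep = "")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Write a ranked pathway table as TSV
#'
#' Mirrors the summary-table columns: Rank, Total score, Gene score, Steps,
#' Putatives, Toxicity, Yield, Gibbs, Unfavorable.
#'
#' @param ranked a `RankedPathways` from [rank_pathways()].
#' @param path output file.
#' @param header optional comment lines (e.g. run configuration) written
#'   with a leading `#`.
#' @return Invisibly, `path`.
#' @export
write_ranking_tsv <- function(ranked, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header) > 0) writeLines(paste0("# ", header), con)
  df <- data.frame(Rank = ranked$rank,
                   `Total score` = ranked$total,
                   `Gene score` = ranked$gene_score,
                   Steps = ranked$n_steps, Putatives = ranked$n_putative,
                   Toxicity = ranked$toxicity, Yield = ranked$yield,
                   Gibbs = ranked$gibbs_sum,
                   Unfavorable = ranked$n_unfavorable,
                   check.names = FALSE)
  utils::write.table(format(df, digits = 6, trim = TRUE), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Top-k gene constructs for a pathway
#'
#' A construct picks one candidate gene per pathway step; its score is the
#' mean of the chosen gene scores. The k best constructs are enumerated
#' lazily (best-first frontier search over the per-step sorted candidate
#' lists, never materializing the full Cartesian product), with
#' deterministic tie-breaking by the gene-id tuple.
#'
#' @param p a `Pathway`.
#' @param net the [metabolic_network()].
#' @param k number of constructs (default 10).
#' @return data.frame with one row per construct: `score` then one column
#'   per step (named by reaction id) holding the chosen gene id; descending
#'   score.
#' @export
top_constructs <- function(p, net, k = 10) {
  if (k < 1) stop("k must be >= 1")
  steps <- p$support
  cands <- lapply(steps, function(rid) {
    g <- net$reactions[[rid]]$genes
    if (nrow(g) == 0)
      stop("no construct possible: step '", rid, "' has no gene candidates")
    g[order(-g$score, g$gene), , drop = FALSE]
  })
  ns <- length(steps)
  key_of <- function(idx) paste(idx, collapse = ",")
  score_of <- function(idx) mean(vapply(seq_len(ns), function(s)
    cands[[s]]$score[idx[s]], 0))
  genes_of <- function(idx) vapply(seq_len(ns), function(s)
    cands[[s]]$gene[idx[s]], "")
  start <- rep(1L, ns)
  frontier <- list(list(idx = start, score = score_of(start)))
  seen <- key_of(start)
  out <- list()
  while (length(out) < k && length(frontier) > 0) {
    scores <- vapply(frontier, `[[`, 0, "score")
    tie_keys <- vapply(frontier, function(f)
      paste(genes_of(f$idx), collapse = "|"), "")
    best <- order(-scores, tie_keys)[1]
    node <- frontier[[best]]
    frontier <- frontier[-best]
    out[[length(out) + 1]] <- node
    for (s in seq_len(ns)) {
      idx2 <- node$idx
      if (idx2[s] < nrow(cands[[s]])) {
        idx2[s] <- idx2[s] + 1L
        kk <- key_of(idx2)
        if (!kk %in% seen) {
          seen <- c(seen, kk)
          frontier[[length(frontier) + 1]] <-
            list(idx = idx2, score = score_of(idx2))
        }
      }
    }
  }
  res <- data.frame(score = vapply(out, `[[`, 0, "score"))
  gm <- t(vapply(out, function(n) genes_of(n$idx), character(ns)))
  if (ns == 1) gm <- matrix(vapply(out, function(n) genes_of(n$idx), ""),
                            ncol = 1)
  colnames(gm) <- steps
  cbind(res, as.data.frame(gm, stringsAsFactors = FALSE))
}
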