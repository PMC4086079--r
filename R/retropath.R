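#' Forward reachability from a seed set
#'
#' Least fixpoint of the firing relation: a reaction fires when all of its
#' substrates are reachable (side compounds count as always reachable), and
#' its products then join the reachable set. Reversible reactions fire in
#' both directions.
#'
#' @param net a [metabolic_network()].
#' @param seeds character vector of metabolite ids.
#' @return Character vector of reachable metabolite ids (includes the
#'   seeds; side compounds are included only if they are seeds or get
#'   produced).
#' @export
forward_reachable <- function(net, seeds) {
  if (!all(seeds %in% names(net$metabolites)))
    stop("unknown seed metabolite(s): ",
         paste(setdiff(seeds, names(net$metabolites)), collapse = ", "))
  reach <- unique(seeds)
  free <- union(reach, net$side_compounds)
  repeat {
    grew <- FALSE
    for (r in net$reactions) {
      subs <- names(r$stoich)[r$stoich < 0]
      prods <- names(r$stoich)[r$stoich > 0]
      if (all(subs %in% free)) {
        new <- setdiff(prods, reach)
        if (length(new) > 0) { reach <- c(reach, new); grew <- TRUE }
      }
      if (r$reversible && all(prods %in% free)) {
        new <- setdiff(subs, reach)
        if (length(new) > 0) { reach <- c(reach, new); grew <- TRUE }
      }
      free <- union(reach, net$side_compounds)
    }
    if (!grew) break
  }
  sort(reach)
}

#' Retrosynthetic scope of a target
#'
#' Backward pruning step of the scope computation: starting from the
#' target, include every reaction (restricted to directions whose
#' substrates are forward-reachable) that produces a needed metabolite;
#' its substrates become needed in turn unless they are endogenous or side
#' compounds. The precursors are the needed endogenous metabolites feeding
#' the scope.
#'
#' @param net a [metabolic_network()].
#' @param reachable metabolite ids from [forward_reachable()].
#' @param target target metabolite id; must be reachable.
#' @return A `Scope`: list with `reactions` (ids), `metabolites` (ids),
#'   `precursors` (endogenous ids), `target`, and `directions` (named +1/-1
#'   per scope reaction: -1 when a reversible reaction is used in reverse).
#' @export
backward_prune <- function(net, reachable, target) {
  if (!target %in% names(net$metabolites))
    stop("target '", target, "' is not in the network")
  if (!target %in% reachable)
    stop("no pathway: target '", target, "' is not reachable from the seeds")
  free <- union(reachable, net$side_compounds)
  endo <- names(net$metabolites)[vapply(net$metabolites, `[[`, TRUE,
                                        "endogenous")]
  needed <- target
  queue <- target
  scope_rxns <- character(0)
  directions <- numeric(0)
  while (length(queue) > 0) {
    met <- queue[1]; queue <- queue[-1]
    for (r in net$reactions) {
      subs <- names(r$stoich)[r$stoich < 0]
      prods <- names(r$stoich)[r$stoich > 0]
      fire_fwd <- met %in% prods && all(subs %in% free)
      fire_rev <- r$reversible && met %in% subs && all(prods %in% free)
      if (!fire_fwd && !fire_rev) next
      dir <- if (fire_fwd) 1 else -1
      if (r$id %in% scope_rxns) {
        # keep first direction; both-direction use would be a futile cycle
        if (directions[[r$id]] != dir) next
      } else {
        scope_rxns <- c(scope_rxns, r$id)
        directions[r$id] <- dir
      }
      inputs <- if (dir > 0) subs else prods
      for (s in inputs) {
        if (s %in% net$side_compounds) next
        if (s %in% endo) { needed <- union(needed, s); next }
        if (!s %in% needed) { needed <- c(needed, s); queue <- c(queue, s) }
      }
    }
  }
  mets <- unique(unlist(lapply(net$reactions[scope_rxns],
                               function(r) names(r$stoich))))
  structure(list(reactions = sort(scope_rxns),
                 metabolites = sort(union(mets, target)),
                 precursors = sort(intersect(needed, endo)),
                 target = target,
                 directions = directions),
            class = "Scope")
}

#' @export
print.Scope <- function(x, ...) {
  cat("Scope -> ", x$target, ": ", length(x$reactions), " reactions, ",
      length(x$metabolites), " metabolites, precursors: ",
      paste(x$precursors, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Stoichiometric matrix of a scope
#'
#' Builds the metabolites-by-reactions matrix of the scope with explicit
#' boundary columns: one irreversible uptake column per precursor
#' (`EX_<id>_in`), one reversible exchange column per side compound that
#' participates (`EX_<id>`), and a single irreversible sink column for the
#' target (`SINK_<target>`, a lone -1 on the target row). Keeping the
#' boundaries as columns makes a pathway's net metabolite exchange readable
#' off its flux vector.
#'
#' @param scope a `Scope` from [backward_prune()].
#' @param net the underlying [metabolic_network()].
#' @return A `StoichiometricMatrix`: list with `S` (dense matrix, rationals
#'   as exact doubles), `reversible` (logical per column), `boundary`
#'   (logical per column), `target_col` (sink column name), `scope`.
#' @export
build_stoichiometric_matrix <- function(scope, net) {
  if (length(scope$reactions) == 0) stop("empty scope")
  mets <- scope$metabolites
  rxns <- scope$reactions
  side <- intersect(net$side_compounds, mets)
  # a precursor consumed as substrate gets an uptake; side compounds exchange
  cols <- c(rxns,
            paste0("EX_", setdiff(scope$precursors, side), "_in"),
            paste0("EX_", side),
            paste0("SINK_", scope$target))
  S <- matrix(0, nrow = length(mets), ncol = length(cols),
              dimnames = list(mets, cols))
  reversible <- logical(length(cols)); names(reversible) <- cols
  boundary <- logical(length(cols)); names(boundary) <- cols
  for (rid in rxns) {
    r <- net$reactions[[rid]]
    S[names(r$stoich), rid] <- r$stoich
    reversible[rid] <- r$reversible
  }
  for (p in setdiff(scope$precursors, side)) {
    cn <- paste0("EX_", p, "_in")
    S[p, cn] <- 1
    boundary[cn] <- TRUE
  }
  for (s in side) {
    cn <- paste0("EX_", s)
    S[s, cn] <- 1
    reversible[cn] <- TRUE
    boundary[cn] <- TRUE
  }
  sink <- paste0("SINK_", scope$target)
  S[scope$target, sink] <- -1
  boundary[sink] <- TRUE
  structure(list(S = S, reversible = reversible, boundary = boundary,
                 target_col = sink, scope = scope),
            class = "StoichiometricMatrix")
}

#' Enumerate all heterologous pathways to a target
#'
#' Full retrosynthetic pipeline: forward reachability from the chassis
#' seeds, backward pruning to the target scope, stoichiometric matrix
#' construction, and elementary flux mode enumeration. Modes with positive
#' flux through the target sink are returned as `Pathway` objects; internal
#' cycles are discarded. Pathways are ordered lexicographically by their
#' support before any ranking.
#'
#' @param net a [metabolic_network()].
#' @param chassis_seeds endogenous metabolite ids available in the chassis
#'   (defaults to all endogenous metabolites of `net`).
#' @param target target metabolite id.
#' @return List of `Pathway` objects: each has `flux` (named vector over
#'   matrix columns), `support` (non-boundary reaction ids), `target`,
#'   `precursors` (ids with positive uptake), `n_steps`, `n_putative`.
#'   Empty list (with a message) when the scope yields no target-producing
#'   mode.
#' @export
enumerate_pathways <- function(net, chassis_seeds = NULL, target) {
  if (!target %in% names(net$metabolites))
    stop("target '", target, "' is not in the network")
  if (is.null(chassis_seeds))
    chassis_seeds <- names(net$metabolites)[vapply(net$metabolites, `[[`,
                                                   TRUE, "endogenous")]
  reach <- forward_reachable(net, chassis_seeds)
  scope <- backward_prune(net, reach, target)
  mat <- build_stoichiometric_matrix(scope, net)
  modes <- elementary_flux_modes(mat)
  out <- list()
  for (v in modes) {
    if (v[mat$target_col] <= 1e-9) next
    supp_all <- names(v)[abs(v) > 1e-9]
    steps <- setdiff(supp_all, names(mat$boundary)[mat$boundary])
    n_put <- sum(vapply(net$reactions[steps], function(r)
      r$origin == "putative", TRUE))
    uptakes <- supp_all[startsWith(supp_all, "EX_") & v[supp_all] > 1e-9]
    precs <- sub("_in$", "", sub("^EX_", "", uptakes))
    precs <- intersect(precs, scope$precursors)
    out[[length(out) + 1]] <- structure(
      list(flux = v, support = sort(steps), target = target,
           precursors = sort(precs), n_steps = length(steps),
           n_putative = n_put),
      class = "Pathway")
  }
  if (length(out) == 0) {
    message("no target-producing pathway for '", target, "'")
    return(out)
  }
  keys <- vapply(out, function(p) paste(p$support, collapse = "|"), "")
  out[order(keys)]
}

#' @export
print.Pathway <- function(x, ...) {
  cat("Pathway -> ", x$target, ": ", x$n_steps, " steps (",
      x$n_putative, " putative) via ", paste(x$support, collapse = ", "),
      "\n  precursors: ", paste(x$precursors, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write pathways as a TSV table
#' @param pathways list of `Pathway`s (optionally ranked).
#' @param path output file.
#' @param scores optional data.frame of ranking scores ([rank_pathways()]).
#' @return Invisibly, `path`.
#' @export
write_pathways_tsv <- function(pathways, path, scores = NULL) {
  rows <- vapply(seq_along(pathways), function(i) {
    p <- pathways[[i]]
    flux <- p$flux[p$support]
    paste(i, paste(p$support, collapse = ","),
          paste(format(flux, digits = 10, trim = TRUE), collapse = ","),
          p$n_steps, p$n_putative, sep = "\t")
  }, "")
  writeLines(c("rank\treactions\tfluxes\tn_steps\tn_putative", rows), path)
  invisible(path)
}
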