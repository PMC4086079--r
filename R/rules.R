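#' Reaction rules from molecular signatures
#'
#' A reaction rule at diameter `d` is the net difference between the
#' molecular signatures of a reaction's products and of its substrates,
#' stoichiometry-weighted: a signed sparse vector over canonical signature
#' strings. Atom environments that are unchanged by the transformation
#' cancel out, so the rule describes only the chemistry at (and around) the
#' reaction center; the smaller `d`, the more generic the rule and the more
#' substrates it accepts — this is how enzyme promiscuity enters the model.
#'
#' @name ReactionRule
NULL

# Per-network signature cache so extension never recomputes a metabolite.
.sig_cache <- function() new.env(parent = emptyenv())

.cached_signature <- function(net, id, diameter, cache) {
  key <- paste0(diameter, "|", id)
  if (!is.null(cache[[key]])) return(cache[[key]])
  s <- .met_structure(net, id)
  if (is.null(s)) return(NULL)
  sig <- molecular_signature(s, diameter)
  cache[[key]] <- sig
  sig
}

# Signed sparse signature arithmetic: named numeric vectors, zeros dropped.
.sig_add <- function(a, b, w = 1) {
  keys <- union(names(a), names(b))
  out <- stats::setNames(numeric(length(keys)), keys)
  if (length(a)) out[names(a)] <- out[names(a)] + as.numeric(a)
  if (length(b)) out[names(b)] <- out[names(b)] + w * as.numeric(b)
  out <- out[abs(out) > 1e-9]
  out[order(names(out))]
}

#' Derive the reaction rule of one reaction
#'
#' @param r a [reaction()] or reaction id in `net`.
#' @param net the network supplying participant structures. Every
#'   participant (side compounds included) must have a structure.
#' @param diameter even signature diameter.
#' @param cache optional signature cache environment (internal reuse).
#' @return A `ReactionRule` with fields `id`, `diameter`, `delta` (named
#'   signed numeric), `substrate_arity`, `product_arity`,
#'   `template_reaction_ids`, and the template's `reversible`, `ec`,
#'   `genes`.
#' @export
derive_rule <- function(r, net, diameter, cache = .sig_cache()) {
  if (is.character(r)) r <- net$reactions[[r]]
  .check_diameter(diameter)
  delta <- stats::setNames(numeric(0), character(0))
  for (id in names(r$stoich)) {
    sig <- .cached_signature(net, id, diameter, cache)
    if (is.null(sig))
      stop("cannot derive rule for '", r$id, "': metabolite '", id,
           "' has no structure")
    delta <- .sig_add(delta, sig, w = r$stoich[[id]])
  }
  structure(list(id = paste0("rule_", r$id, "_d", diameter),
                 diameter = as.integer(diameter), delta = delta,
                 substrate_arity = as.integer(round(sum(-r$stoich[r$stoich < 0]))),
                 product_arity = as.integer(round(sum(r$stoich[r$stoich > 0]))),
                 template_reaction_ids = r$id,
                 reversible = r$reversible, ec = r$ec, genes = r$genes),
            class = "ReactionRule")
}

#' @export
print.ReactionRule <- function(x, ...) {
  cat("ReactionRule ", x$id, " (d=", x$diameter, "): ",
      length(x$delta), " signed signature terms, arity ",
      x$substrate_arity, "->", x$product_arity, ", templates: ",
      paste(x$template_reaction_ids, collapse = ","), "\n", sep = "")
  invisible(x)
}

#' Derive a deduplicated rule set from a network
#'
#' One rule per (reaction, diameter); rules with identical (diameter,
#' delta, arities) are merged, pooling their template reaction ids.
#' Reactions with structure-less participants are skipped with a message.
#'
#' @param net a [metabolic_network()].
#' @param diameters vector of even diameters.
#' @return List of `ReactionRule`s.
#' @export
derive_rule_set <- function(net, diameters) {
  cache <- .sig_cache()
  rules <- list()
  skipped <- character(0)
  for (d in diameters) {
    for (r in net$reactions) {
      rl <- tryCatch(derive_rule(r, net, d, cache), error = function(e) NULL)
      if (is.null(rl)) { skipped <- c(skipped, r$id); next }
      key <- paste0(d, "|", rl$substrate_arity, ">", rl$product_arity, "|",
                    paste(names(rl$delta), rl$delta, collapse = ";"))
      if (!is.null(rules[[key]])) {
        rules[[key]]$template_reaction_ids <-
          sort(unique(c(rules[[key]]$template_reaction_ids, r$id)))
      } else rules[[key]] <- rl
    }
  }
  if (length(skipped) > 0)
    message("derive_rule_set: skipped reaction(s) without full structures: ",
            paste(unique(skipped), collapse = ", "))
  unname(rules)
}

#' Apply a reaction rule to a substrate combination
#'
#' Adds the rule's signed delta to the summed substrate signatures; if the
#' resulting product signature has no negative counts, every multiset of
#' `product_arity` universe metabolites whose signatures sum to it exactly
#' yields one putative reaction. Products are searched only among known
#' metabolites (no de novo structures). A candidate identical in
#' stoichiometry to an existing reaction of `universe` is not re-emitted.
#'
#' @param rule a `ReactionRule`.
#' @param substrates character vector of metabolite ids, length equal to
#'   `rule$substrate_arity` (repeat an id for coefficient 2).
#' @param universe the [metabolic_network()] providing candidate products.
#' @param cache optional signature cache.
#' @return List of putative [reaction()]s (possibly empty).
#' @export
apply_rule <- function(rule, substrates, universe, cache = .sig_cache()) {
  if (length(substrates) != rule$substrate_arity)
    stop("rule '", rule$id, "' expects ", rule$substrate_arity,
         " substrate(s), got ", length(substrates))
  target <- rule$delta
  for (id in substrates) {
    sig <- .cached_signature(universe, id, rule$diameter, cache)
    if (is.null(sig)) return(list())
    target <- .sig_add(target, sig)
  }
  if (any(target < 0)) return(list())
  # candidate products: metabolites with structures
  cand <- names(universe$metabolites)[!is.na(
    vapply(universe$metabolites, `[[`, "", "smiles"))]
  cand <- sort(cand)
  sigs <- lapply(cand, function(id)
    .cached_signature(universe, id, rule$diameter, cache))
  names(sigs) <- cand
  found <- list()
  # depth-first multiset search: pick candidates in id order, allow repeats
  recurse <- function(remaining, start, chosen) {
    if (length(chosen) == rule$product_arity) {
      if (length(remaining) == 0) found[[length(found) + 1]] <<- chosen
      return()
    }
    if (start > length(cand)) return()
    for (i in start:length(cand)) {
      s <- sigs[[i]]
      # feasibility: s must fit inside remaining
      keys <- names(s)
      rem_at <- stats::setNames(numeric(length(keys)), keys)
      present <- keys %in% names(remaining)
      if (!all(present)) next
      rem_at[keys] <- remaining[keys]
      if (any(rem_at - as.numeric(s) < -1e-9)) next
      recurse(.sig_add(remaining, s, w = -1), i, c(chosen, cand[i]))
    }
  }
  if (rule$product_arity >= 1) {
    if (length(target) == 0 && rule$product_arity > 0) {
      # empty target cannot be covered by non-empty product signatures
    } else recurse(target, 1, character(0))
  }
  existing <- lapply(universe$reactions, function(r) .stoich_key(r$stoich))
  out <- list()
  for (prod in found) {
    st <- numeric(0)
    for (id in substrates)
      st[id] <- (if (id %in% names(st)) st[[id]] else 0) - 1
    for (id in prod)
      st[id] <- (if (id %in% names(st)) st[[id]] else 0) + 1
    st <- st[abs(st) > 1e-9]
    if (length(st) == 0 || !any(st < 0) || !any(st > 0)) next
    key <- .stoich_key(st)
    if (key %in% existing) next
    rid <- paste0("put_", rule$id, "_", substr(.digest_key(key), 1, 8))
    out[[length(out) + 1]] <- reaction(
      id = rid, stoich = st, reversible = rule$reversible,
      ec = rule$ec, genes = rule$genes, origin = "putative",
      rule_id = rule$id)
    existing <- c(existing, key)
  }
  out
}

.stoich_key <- function(st) {
  st <- st[order(names(st))]
  paste(names(st), format(st, digits = 10, trim = TRUE), collapse = ";")
}

# short stable id suffix without external digest dependency
.digest_key <- function(s) {
  v <- utf8ToInt(s)
  h1 <- 5381; h2 <- 52711
  for (x in v) {
    h1 <- (h1 * 33 + x) %% 2147483647
    h2 <- (h2 * 31 + x) %% 2147483629
  }
  sprintf("%08x%08x", h1, h2)
}

#' Extend a network with putative promiscuous reactions
#'
#' Repeatedly applies every rule to all combinations of known metabolites
#' (with repetition, in id order) and adds the putative reactions that
#' verify the rules, until a fixpoint is reached or `max_iterations` sweeps
#' have run. The metabolite set never grows — extension is restricted to
#' combinations of known metabolites — so the reaction count is
#' non-decreasing and the process converges.
#'
#' @param net a [metabolic_network()].
#' @param rules list of `ReactionRule`s.
#' @param max_iterations maximum number of full sweeps (>= 1).
#' @return List with elements `network`, `converged` (logical),
#'   `iterations_used`, `added` (character vector of new reaction ids).
#' @export
extend_network <- function(net, rules, max_iterations = 50) {
  stopifnot(max_iterations >= 1)
  cache <- .sig_cache()
  added_total <- character(0)
  iterations <- 0
  converged <- FALSE
  structured <- sort(names(net$metabolites)[!is.na(
    vapply(net$metabolites, `[[`, "", "smiles"))])
  repeat {
    iterations <- iterations + 1
    added_this <- list()
    for (rule in rules) {
      combos <- .combinations_with_repetition(structured, rule$substrate_arity)
      for (cmb in combos) {
        new_r <- apply_rule(rule, cmb, net, cache)
        for (r in new_r) {
          net <- metabolic_network(net$metabolites,
                                   c(net$reactions, list(r)),
                                   net$side_compounds)
          added_this[[length(added_this) + 1]] <- r$id
        }
      }
    }
    added_total <- c(added_total, unlist(added_this))
    if (length(added_this) == 0) { converged <- TRUE; break }
    if (iterations >= max_iterations) break
  }
  list(network = net, converged = converged, iterations_used = iterations,
       added = added_total)
}

.combinations_with_repetition <- function(items, k) {
  if (k == 0) return(list(character(0)))
  out <- list()
  rec <- function(start, chosen) {
    if (length(chosen) == k) { out[[length(out) + 1]] <<- chosen; return() }
    for (i in seq(start, length(items))) rec(i, c(chosen, items[i]))
  }
  if (length(items) > 0) rec(1, character(0))
  out
}

#' Write / read a rule set as TSV
#'
#' Columns: id, diameter, substrate_arity, product_arity, templates
#' (comma-separated), reversible, ec, genes (`gene:score;...`), delta
#' (`signature=coefficient` pairs joined by `\\t`-safe `" ~ "`).
#'
#' @param rules list of `ReactionRule`s.
#' @param path file path.
#' @return `read_rules_tsv` returns the rule list.
#' @export
write_rules_tsv <- function(rules, path) {
  rows <- vapply(rules, function(r) {
    delta_txt <- paste(paste0(names(r$delta), "=",
                              format(r$delta, digits = 10, trim = TRUE)),
                       collapse = " ~ ")
    gtxt <- if (nrow(r$genes) > 0)
      paste(paste0(r$genes$gene, ":", r$genes$score), collapse = ";") else ""
    paste(r$id, r$diameter, r$substrate_arity, r$product_arity,
          paste(r$template_reaction_ids, collapse = ","),
          if (r$reversible) "1" else "0",
          if (is.na(r$ec)) "" else r$ec, gtxt, delta_txt, sep = "\t")
  }, "")
  writeLines(c(paste("id", "diameter", "substrate_arity", "product_arity",
                     "templates", "reversible", "ec", "genes", "delta",
                     sep = "\t"), rows), path)
  invisible(path)
}

#' @rdname write_rules_tsv
#' @export
read_rules_tsv <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  lapply(seq_len(nrow(tab)), function(i) {
    delta <- stats::setNames(numeric(0), character(0))
    if (nzchar(tab$delta[i])) {
      parts <- strsplit(tab$delta[i], " ~ ", fixed = TRUE)[[1]]
      kv <- regmatches(parts, regexpr("=[^=]*$", parts))
      keys <- substr(parts, 1, nchar(parts) - nchar(kv))
      delta <- stats::setNames(as.numeric(sub("^=", "", kv)), keys)
      delta <- delta[order(names(delta))]
    }
    genes <- if (nzchar(tab$genes[i])) {
      gp <- strsplit(strsplit(tab$genes[i], ";", fixed = TRUE)[[1]], ":",
                     fixed = TRUE)
      data.frame(gene = vapply(gp, `[`, "", 1),
                 score = as.numeric(vapply(gp, `[`, "", 2)))
    } else data.frame(gene = character(), score = numeric())
    structure(list(id = tab$id[i], diameter = as.integer(tab$diameter[i]),
                   delta = delta,
                   substrate_arity = as.integer(tab$substrate_arity[i]),
                   product_arity = as.integer(tab$product_arity[i]),
                   template_reaction_ids =
                     strsplit(tab$templates[i], ",", fixed = TRUE)[[1]],
                   reversible = tab$reversible[i] == "1",
                   ec = if (nzchar(tab$ec[i])) tab$ec[i] else NA_character_,
                   genes = genes),
              class = "ReactionRule")
  })
}
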