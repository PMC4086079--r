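# Independent brute-force oracles used to validate the fast implementations.

# Exhaustive elementary-flux-mode oracle: enumerate every column subset of the
# split (all-irreversible) matrix, keep subsets whose restricted nullspace is
# one-dimensional and strictly positive, then keep the support-minimal ones.
# Deliberately naive; exponential in the number of columns.
oracle_efms <- function(S, reversible, tol = 1e-8) {
  n <- ncol(S)
  A <- cbind(S, -S[, reversible, drop = FALSE])
  back <- c(seq_len(n), which(reversible))
  sign_of <- c(rep(1, n), rep(-1, sum(reversible)))
  n2 <- ncol(A)
  cand <- list()
  for (mask in seq_len(2^n2 - 1)) {
    cols <- which(bitwAnd(mask, bitwShiftL(1, seq_len(n2) - 1)) != 0)
    sub <- A[, cols, drop = FALSE]
    ns <- .oracle_nullspace(sub, tol)
    if (is.null(ns) || ncol(ns) != 1) next
    v <- ns[, 1]
    if (any(abs(v) < tol)) next
    if (all(v < 0)) v <- -v
    if (any(v < 0)) next
    cand[[length(cand) + 1]] <- list(cols = cols, v = v)
  }
  if (length(cand) == 0) return(list())
  # support-minimal candidates only
  keep <- vapply(seq_along(cand), function(i) {
    !any(vapply(seq_along(cand), function(j) {
      j != i && length(cand[[j]]$cols) < length(cand[[i]]$cols) &&
        all(cand[[j]]$cols %in% cand[[i]]$cols)
    }, TRUE))
  }, TRUE)
  cand <- cand[keep]
  out <- list()
  seen <- character(0)
  for (cc in cand) {
    used <- back[cc$cols]
    if (anyDuplicated(used)) next  # futile two-cycle in split space
    full <- numeric(n)
    for (k in seq_along(cc$cols))
      full[back[cc$cols[k]]] <- full[back[cc$cols[k]]] +
        sign_of[cc$cols[k]] * cc$v[k]
    supp <- which(abs(full) > tol)
    if (length(supp) == 0) next
    if (all(reversible[supp]) && full[supp[1]] < 0) full <- -full
    key <- efm_key(full, tol)
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1]] <- stats::setNames(full, colnames(S))
  }
  out
}

.oracle_nullspace <- function(A, tol = 1e-8) {
  s <- svd(A, nu = 0, nv = ncol(A))
  d <- c(s$d, rep(0, ncol(A) - length(s$d)))
  null_idx <- which(d < tol * max(1, max(d)))
  if (length(null_idx) == 0) return(NULL)
  s$v[, null_idx, drop = FALSE]
}

# canonical comparison key for a flux vector (scale-invariant)
efm_key <- function(v, tol = 1e-8) {
  supp <- which(abs(v) > tol)
  w <- v / max(abs(v))
  paste(paste(supp, collapse = ","),
        paste(sprintf("%.6f", w[supp]), collapse = ","), sep = "|")
}

efm_key_set <- function(modes) sort(vapply(modes, efm_key, ""))

# random stoichiometric test matrix with a mix of internal and boundary columns
random_efm_matrix <- function(n_mets, n_rxns, p_rev = 0.25) {
  repeat {
    S <- matrix(0, n_mets, n_rxns)
    for (j in seq_len(n_rxns)) {
      k <- sample(1:min(3, n_mets), 1)
      rows <- sample(n_mets, k)
      S[rows, j] <- sample(c(-2, -1, 1, 2), k, replace = TRUE)
    }
    if (all(colSums(abs(S)) > 0)) break
  }
  colnames(S) <- paste0("r", seq_len(n_rxns))
  rownames(S) <- paste0("m", seq_len(n_mets))
  list(S = S, reversible = stats::setNames(stats::runif(n_rxns) < p_rev,
                                           colnames(S)))
}

# exhaustive k-best construct oracle: full Cartesian product
oracle_constructs <- function(p, net, k) {
  cands <- lapply(p$support, function(rid) net$reactions[[rid]]$genes)
  grids <- lapply(cands, function(g) seq_len(nrow(g)))
  combos <- expand.grid(grids)
  scores <- apply(combos, 1, function(idx)
    mean(vapply(seq_along(idx), function(s) cands[[s]]$score[idx[s]], 0)))
  gene_mat <- t(apply(combos, 1, function(idx)
    vapply(seq_along(idx), function(s) cands[[s]]$gene[idx[s]], "")))
  if (length(p$support) == 1) gene_mat <- matrix(gene_mat, ncol = 1)
  colnames(gene_mat) <- p$support
  tie <- apply(gene_mat, 1, paste, collapse = "|")
  ord <- order(-scores, tie)
  out <- data.frame(score = scores[ord],
                    gene_mat[ord, , drop = FALSE],
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  utils::head(out, k)
}
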