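#' Elementary flux mode enumeration
#'
#' Enumerates the complete set of elementary flux modes of a stoichiometric
#' matrix: support-minimal non-zero flux vectors `v` with `S v = 0` and
#' `v >= 0` on irreversible columns. Reversible columns are split into a
#' forward and a reverse copy, the classical tableau algorithm (pairwise
#' combination per metabolite row with a support-minimality test) runs on
#' the resulting pointed cone, and the split columns are merged back.
#' Arithmetic is integer throughout (combinations are gcd-reduced at every
#' step), so the returned vectors are exact and already scaled to smallest
#' integer form.
#'
#' @param m a `StoichiometricMatrix` from [build_stoichiometric_matrix()],
#'   or a plain list with elements `S` (metabolites x reactions matrix with
#'   column names) and `reversible` (logical per column).
#' @return List of named numeric flux vectors (full length, zeros included),
#'   one per mode; reversible-only cycles are canonicalized to make their
#'   first non-zero entry positive. Empty list when no mode exists.
#' @export
elementary_flux_modes <- function(m) {
  S <- m$S
  rev <- m$reversible
  if (is.null(S) || nrow(S) == 0 || ncol(S) == 0)
    stop("empty stoichiometric matrix")
  n <- ncol(S)
  cn <- colnames(S)
  if (is.null(cn)) cn <- paste0("r", seq_len(n))
  # split reversible columns
  S2 <- cbind(S, -S[, rev, drop = FALSE])
  back <- c(seq_len(n), which(rev))          # split col -> original col
  sign_of <- c(rep(1, n), rep(-1, sum(rev)))
  n2 <- ncol(S2)
  rays <- diag(n2)
  M <- rays %*% t(S2)  # remainders: n_rays x n_mets
  for (j in seq_len(nrow(S))) {
    col <- M[, j]
    zero <- which(abs(col) < 1e-9)
    pos <- which(col > 1e-9)
    neg <- which(col < -1e-9)
    keep_rays <- rays[zero, , drop = FALSE]
    keep_M <- M[zero, , drop = FALSE]
    if (length(pos) > 0 && length(neg) > 0) {
      combs <- vector("list", length(pos) * length(neg))
      combs_M <- vector("list", length(pos) * length(neg))
      k <- 0
      for (a in pos) for (b in neg) {
        k <- k + 1
        r <- abs(col[b]) * rays[a, ] + abs(col[a]) * rays[b, ]
        g <- .vec_gcd(r)
        if (g > 1) r <- r / g
        combs[[k]] <- r
        combs_M[[k]] <- abs(col[b]) / g * M[a, ] + abs(col[a]) / g * M[b, ]
      }
      keep_rays <- rbind(keep_rays, do.call(rbind, combs))
      keep_M <- rbind(keep_M, do.call(rbind, combs_M))
    }
    if (nrow(keep_rays) > 1) {
      minimal <- .support_minimal(keep_rays > 1e-9)
      keep_rays <- keep_rays[minimal, , drop = FALSE]
      keep_M <- keep_M[minimal, , drop = FALSE]
    }
    rays <- keep_rays
    M <- keep_M
    if (nrow(rays) == 0) break
  }
  out <- list()
  seen <- character(0)
  if (nrow(rays) > 0) for (i in seq_len(nrow(rays))) {
    r <- rays[i, ]
    # drop futile two-cycles / modes using both directions of one reaction
    used <- back[r > 1e-9]
    if (anyDuplicated(used)) next
    v <- stats::setNames(numeric(n), cn)
    for (k in which(r > 1e-9)) v[back[k]] <- v[back[k]] + sign_of[k] * r[k]
    g <- .vec_gcd(v)
    if (g > 1) v <- v / g
    # canonical sign for fully-reversible modes (they arise twice, as v and -v)
    supp <- which(abs(v) > 1e-9)
    if (length(supp) == 0) next
    if (all(rev[supp]) && v[supp[1]] < 0) v <- -v
    key <- paste(format(v, digits = 12), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1]] <- v
  }
  # deterministic order: lexicographic by support column indices
  if (length(out) > 1) {
    keys <- vapply(out, function(v)
      paste(sprintf("%04d", which(abs(v) > 1e-9)), collapse = "."), "")
    out <- out[order(keys)]
  }
  out
}

# rows of a logical support matrix that are not strict supersets of another row
.support_minimal <- function(supp) {
  nr <- nrow(supp)
  keep <- rep(TRUE, nr)
  sizes <- rowSums(supp)
  ord <- order(sizes)
  for (ii in seq_len(nr)) {
    i <- ord[ii]
    if (!keep[i]) next
    for (jj in seq_len(nr)) {
      j <- ord[jj]
      if (j == i || sizes[j] >= sizes[i]) next
      if (all(supp[j, ] <= supp[i, ])) { keep[i] <- FALSE; break }
    }
  }
  keep
}

.vec_gcd <- function(v) {
  v <- abs(v[abs(v) > 1e-9])
  if (length(v) == 0) return(1)
  if (any(abs(v - round(v)) > 1e-6)) return(1)
  g <- 0
  for (x in round(v)) g <- .gcd2(g, x)
  max(g, 1)
}

.gcd2 <- function(a, b) {
  while (b != 0) { t <- a %% b; a <- b; b <- t }
  a
}
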