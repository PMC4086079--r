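#' Flux balance analysis models
#'
#' An `FBAModel` is a stoichiometric matrix with per-reaction flux bounds
#' and a biomass objective column. [fba_optimize()] solves the usual linear
#' program: maximize the objective flux subject to steady state
#' (`S v = 0`) and the bounds.
#'
#' @param S metabolites x reactions numeric matrix with dimnames.
#' @param lb,ub named numeric vectors of lower/upper flux bounds (use
#'   `-Inf`/`Inf` for unbounded).
#' @param objective reaction (column) id to maximize, typically biomass.
#' @return An `FBAModel`.
#' @export
fba_model <- function(S, lb, ub, objective) {
  stopifnot(is.matrix(S), !is.null(colnames(S)), !is.null(rownames(S)))
  rx <- colnames(S)
  lb <- lb[rx]; ub <- ub[rx]
  if (any(is.na(lb)) || any(is.na(ub)))
    stop("bounds must cover every reaction")
  if (any(lb > ub)) stop("lower bound exceeds upper bound")
  if (!objective %in% rx) stop("objective reaction '", objective,
                               "' is not a column of S")
  structure(list(S = S, lb = lb, ub = ub, objective = objective),
            class = "FBAModel")
}

#' @export
print.FBAModel <- function(x, ...) {
  cat("FBAModel: ", nrow(x$S), " metabolites x ", ncol(x$S),
      " reactions, objective = ", x$objective, "\n", sep = "")
  invisible(x)
}

#' Solve an FBA model
#'
#' @param model an [fba_model()].
#' @param objective optional alternative objective column id.
#' @return List with `flux` (named vector), `objective_value`, `status`
#'   (`"optimal"`). Infeasible or unbounded problems raise an error.
#' @export
fba_optimize <- function(model, objective = NULL) {
  obj <- if (is.null(objective)) model$objective else objective
  rx <- colnames(model$S)
  cvec <- stats::setNames(numeric(length(rx)), rx)
  cvec[obj] <- 1
  res <- .solve_lp(model$S, model$lb, model$ub, cvec)
  if (res$status == "infeasible") stop("FBA model is infeasible")
  if (res$status == "unbounded")
    stop("FBA objective '", obj, "' is unbounded")
  list(flux = stats::setNames(res$x, rx), objective_value = res$obj,
       status = "optimal")
}

# maximize c'v  s.t.  S v = 0,  lb <= v <= ub
# shift to x = v - lb >= 0, slack rows for finite upper bounds, then
# two-phase dense simplex with Bland's rule (exact enough at toy scale).
.solve_lp <- function(S, lb, ub, cvec) {
  n <- ncol(S)
  if (any(!is.finite(lb)))
    lb_eff <- pmax(lb, -1e6) else lb_eff <- lb  # large box for free lower bounds
  shift <- lb_eff
  b_eq <- -as.numeric(S %*% shift)
  fin_ub <- which(is.finite(ub))
  d <- ub[fin_ub] - shift[fin_ub]
  n_slack <- length(fin_ub)
  m <- nrow(S) + n_slack
  A <- matrix(0, m, n + n_slack)
  A[seq_len(nrow(S)), seq_len(n)] <- S
  b <- c(b_eq, as.numeric(d))
  for (k in seq_len(n_slack)) {
    A[nrow(S) + k, fin_ub[k]] <- 1
    A[nrow(S) + k, n + k] <- 1
  }
  cc <- c(as.numeric(cvec), numeric(n_slack))
  res <- .simplex_two_phase(A, b, cc)
  if (res$status != "optimal") return(res)
  x <- res$x[seq_len(n)] + shift
  list(status = "optimal", x = x, obj = sum(cvec * x))
}

.simplex_two_phase <- function(A, b, cc, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]
  # phase 1: artificials
  T1 <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  obj1 <- c(numeric(n), rep(1, m))
  r <- .simplex_core(T1, basis, obj1, tol = tol)
  if (r$value > 1e-7) return(list(status = "infeasible"))
  # drive artificials out of the basis where possible
  T1 <- r$tab; basis <- r$basis
  for (i in seq_len(m)) {
    if (basis[i] > n) {
      piv <- which(abs(T1[i, seq_len(n)]) > tol)
      piv <- setdiff(piv, basis)
      if (length(piv) > 0) {
        T1 <- .pivot(T1, i, piv[1]); basis[i] <- piv[1]
      }
    }
  }
  # rows still basic in an artificial are redundant constraints: drop them
  rows <- which(basis <= n)
  T2 <- cbind(T1[rows, seq_len(n), drop = FALSE], T1[rows, n + m + 1])
  basis2 <- basis[rows]
  r2 <- .simplex_core(T2, basis2, -cc, tol = tol)
  if (r2$status == "unbounded") return(list(status = "unbounded"))
  x <- numeric(n)
  x[r2$basis] <- r2$tab[, ncol(r2$tab)]
  list(status = "optimal", x = x, obj = sum(cc * x))
}

# tab: rows = constraints, last column = rhs; minimize obj'x, Bland's rule
.simplex_core <- function(tab, basis, obj, tol = 1e-9) {
  m <- nrow(tab); n <- ncol(tab) - 1
  iter <- 0
  repeat {
    iter <- iter + 1
    if (iter > 10000) stop("simplex iteration limit reached")
    # reduced costs
    cb <- obj[basis]
    red <- obj[seq_len(n)] - as.numeric(t(cb) %*% tab[, seq_len(n), drop = FALSE])
    enter <- which(red < -tol)
    if (length(enter) == 0) {
      value <- sum(cb * tab[, n + 1])
      return(list(status = "optimal", tab = tab, basis = basis, value = value))
    }
    j <- min(enter)  # Bland
    col <- tab[, j]
    pos <- which(col > tol)
    if (length(pos) == 0) return(list(status = "unbounded",
                                      tab = tab, basis = basis))
    ratios <- tab[pos, n + 1] / col[pos]
    rmin <- min(ratios)
    cand <- pos[ratios <= rmin + tol]
    i <- cand[which.min(basis[cand])]  # Bland tie-break
    tab <- .pivot(tab, i, j)
    basis[i] <- j
  }
}

.pivot <- function(tab, i, j) {
  tab[i, ] <- tab[i, ] / tab[i, j]
  for (r in seq_len(nrow(tab))) {
    if (r != i && abs(tab[r, j]) > 0) tab[r, ] <- tab[r, ] - tab[r, j] * tab[i, ]
  }
  tab
}
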