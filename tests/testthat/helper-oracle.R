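# Independent LP oracle: brute-force vertex enumeration over the basic
# solutions of {Ax = b, lb <= x <= ub}. Exponential, usable only for tiny
# problems; deliberately shares no code with the package's simplex.
brute_force_lp <- function(obj, A, rhs, lb, ub, sense = "max",
                           tol = 1e-7) {
  A <- as.matrix(A)
  n <- ncol(A)
  m <- nrow(A)
  stopifnot(n <= 14)
  best <- NULL
  best_x <- NULL
  consider <- function(x) {
    v <- sum(obj * x)
    if (is.null(best) ||
        (sense == "max" && v > best) || (sense == "min" && v < best)) {
      best <<- v
      best_x <<- x
    }
  }
  combs <- utils::combn(n, min(m, n))
  for (k in seq_len(ncol(combs))) {
    B <- combs[, k]
    AB <- A[, B, drop = FALSE]
    if (nrow(AB) != length(B)) next
    if (abs(det(AB)) < 1e-12) next
    N <- setdiff(seq_len(n), B)
    # nonbasic variables sit at a finite bound
    opts <- lapply(N, function(j) {
      v <- unique(c(lb[j], ub[j]))
      v[is.finite(v)]
    })
    if (any(lengths(opts) == 0) && length(N) > 0) next
    grid <- if (length(N) == 0) list(numeric(0)) else {
      g <- do.call(expand.grid, opts)
      lapply(seq_len(nrow(g)), function(i) as.numeric(g[i, ]))
    }
    for (xN in grid) {
      rhs2 <- rhs - if (length(N) > 0) {
        as.vector(A[, N, drop = FALSE] %*% xN)
      } else 0
      xB <- tryCatch(solve(AB, rhs2), error = function(e) NULL)
      if (is.null(xB)) next
      if (any(xB < lb[B] - tol) || any(xB > ub[B] + tol)) next
      x <- numeric(n)
      x[B] <- xB
      if (length(N) > 0) x[N] <- xN
      consider(x)
    }
  }
  if (is.null(best)) {
    list(status = "infeasible", objective = NA_real_, x = NULL)
  } else {
    list(status = "optimal", objective = best, x = best_x)
  }
}

# Oracle applied to an assembled coupled problem.
brute_solve_problem <- function(prob) {
  brute_force_lp(unname(prob$objective$coef), prob$A, prob$rhs,
                 prob$vars$lb, prob$vars$ub, sense = prob$objective$sense)
}
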