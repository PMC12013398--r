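#' @title Dense two-phase simplex backend
#' @description
#' `solve_lp()` solves a small dense linear program
#' \deqn{\min / \max \; c'x \quad s.t.\; A x = b,\; l \le x \le u.}
#'
#' The coupled chemostat problems built by this package are small (tens of
#' variables), so a dense tableau simplex with Bland's anti-cycling rule is
#' both adequate and easy to verify against brute-force vertex enumeration.
#' Problems are brought to standard form by shifting variables with a finite
#' lower bound, mirroring variables bounded only from above, splitting free
#' variables, and adding one slack row per finite range.
#'
#' @param obj numeric objective coefficients, length `n`.
#' @param A dense constraint matrix (`m` rows, `n` columns); all rows are
#'   equalities.
#' @param rhs right-hand side, length `m`.
#' @param lb,ub variable bounds, length `n`; `-Inf`/`Inf` allowed.
#' @param sense `"min"` or `"max"`.
#' @param tol feasibility/optimality tolerance (applied relative to row scale).
#' @return list with `status` (`"optimal"`, `"infeasible"` or `"unbounded"`),
#'   `x` (primal solution, `NULL` unless optimal) and `objective`.
#' @keywords internal
solve_lp <- function(obj, A, rhs, lb, ub, sense = c("min", "max"),
                     tol = 1e-9) {
  sense <- match.arg(sense)
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(obj) == n, length(rhs) == m, length(lb) == n,
            length(ub) == n)
  if (any(lb > ub + tol)) {
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  }
  cvec <- if (sense == "max") -obj else obj

  # --- transform to standard form: min c'y, Ay = b, y >= 0 ------------------
  # Bookkeeping per original variable: how to recover x from y.
  cols <- list()   # list of column vectors in the standard-form A
  ccoef <- list()  # objective coefficient(s)
  map <- vector("list", n)
  const_obj <- 0
  b2 <- rhs
  range_rows <- list()  # (var-col-index, range) pairs needing y + s = range
  k <- 0
  for (j in seq_len(n)) {
    aj <- A[, j]
    if (is.finite(lb[j])) {
      # x = lb + y
      if (lb[j] != 0) {
        b2 <- b2 - aj * lb[j]
        const_obj <- const_obj + cvec[j] * lb[j]
      }
      k <- k + 1
      cols[[k]] <- aj
      ccoef[[k]] <- cvec[j]
      map[[j]] <- list(kind = "shift", col = k, off = lb[j], sgn = 1)
      if (is.finite(ub[j])) {
        range_rows[[length(range_rows) + 1]] <- c(k, ub[j] - lb[j])
      }
    } else if (is.finite(ub[j])) {
      # x = ub - y
      b2 <- b2 - aj * ub[j]
      const_obj <- const_obj + cvec[j] * ub[j]
      k <- k + 1
      cols[[k]] <- -aj
      ccoef[[k]] <- -cvec[j]
      map[[j]] <- list(kind = "shift", col = k, off = ub[j], sgn = -1)
    } else {
      # free: x = y+ - y-
      cols[[k + 1]] <- aj
      cols[[k + 2]] <- -aj
      ccoef[[k + 1]] <- cvec[j]
      ccoef[[k + 2]] <- -cvec[j]
      map[[j]] <- list(kind = "split", col = k + 1, col2 = k + 2)
      k <- k + 2
    }
  }
  A2 <- do.call(cbind, cols)
  c2 <- unlist(ccoef)
  nr <- length(range_rows)
  if (nr > 0) {
    # append rows y_col + slack = range
    extra <- matrix(0, nr, ncol(A2))
    for (i in seq_len(nr)) extra[i, range_rows[[i]][1]] <- 1
    A2 <- rbind(A2, extra)
    A2 <- cbind(A2, rbind(matrix(0, m, nr), diag(nr)))
    b2 <- c(b2, vapply(range_rows, `[`, numeric(1), 2))
    c2 <- c(c2, rep(0, nr))
  }

  res <- simplex_standard(A2, b2, c2, tol = tol)
  if (res$status != "optimal") {
    return(list(status = res$status, x = NULL, objective = NA_real_))
  }
  x <- numeric(n)
  for (j in seq_len(n)) {
    mj <- map[[j]]
    if (mj$kind == "shift") {
      x[j] <- mj$off + mj$sgn * res$x[mj$col]
    } else {
      x[j] <- res$x[mj$col] - res$x[mj$col2]
    }
  }
  objective <- sum(obj * x)
  list(status = "optimal", x = x, objective = objective)
}

# Two-phase primal simplex for min c'y s.t. Ay = b, y >= 0 (dense tableau,
# Bland's rule). Returns status plus the primal point.
simplex_standard <- function(A, b, cvec, tol = 1e-9, max_iter = 50000L) {
  m <- nrow(A)
  n <- ncol(A)
  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
  }
  scale <- max(1, abs(b), abs(A))

  # Phase 1 tableau: columns = original vars + artificials.
  Tb <- cbind(A, diag(m))
  basis <- n + seq_len(m)
  xb <- b
  run_simplex <- function(Tb, xb, basis, cost, allowed) {
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter) stop("simplex iteration limit reached", call. = FALSE)
      cb <- cost[basis]
      # reduced costs
      rc <- cost - as.vector(crossprod(Tb, cb))
      rc[basis] <- 0
      cand <- which(allowed & rc < -tol * scale)
      if (length(cand) == 0) {
        return(list(Tb = Tb, xb = xb, basis = basis, status = "optimal"))
      }
      q <- min(cand)  # Bland
      col <- Tb[, q]
      pos <- which(col > tol)
      if (length(pos) == 0) {
        return(list(Tb = Tb, xb = xb, basis = basis, status = "unbounded"))
      }
      ratio <- xb[pos] / col[pos]
      rmin <- min(ratio)
      ties <- pos[ratio <= rmin + tol * scale]
      r <- ties[which.min(basis[ties])]  # Bland tie-break
      # pivot on (r, q)
      piv <- Tb[r, q]
      Tb[r, ] <- Tb[r, ] / piv
      xb[r] <- xb[r] / piv
      other <- setdiff(seq_len(m), r)
      fac <- Tb[other, q]
      Tb[other, ] <- Tb[other, , drop = FALSE] - outer(fac, Tb[r, ])
      xb[other] <- xb[other] - fac * xb[r]
      Tb[, q] <- 0
      Tb[r, q] <- 1
      basis[r] <- q
    }
  }

  cost1 <- c(rep(0, n), rep(1, m))
  allowed1 <- rep(TRUE, n + m)
  r1 <- run_simplex(Tb, xb, basis, cost1, allowed1)
  if (r1$status != "optimal") stop("phase-1 simplex failed", call. = FALSE)
  p1 <- sum(cost1[r1$basis] * r1$xb)
  if (p1 > 1e-7 * scale) {
    return(list(status = "infeasible", x = NULL))
  }
  Tb <- r1$Tb
  xb <- r1$xb
  basis <- r1$basis
  # Drive artificials out of the basis where possible; drop redundant rows.
  keep <- rep(TRUE, m)
  for (i in seq_len(m)) {
    if (basis[i] > n) {
      cols <- which(abs(Tb[i, seq_len(n)]) > tol)
      if (length(cols) > 0) {
        q <- cols[1]
        piv <- Tb[i, q]
        Tb[i, ] <- Tb[i, ] / piv
        xb[i] <- xb[i] / piv
        other <- setdiff(seq_len(m), i)
        fac <- Tb[other, q]
        Tb[other, ] <- Tb[other, , drop = FALSE] - outer(fac, Tb[i, ])
        xb[other] <- xb[other] - fac * xb[i]
        Tb[, q] <- 0
        Tb[i, q] <- 1
        basis[i] <- q
      } else {
        keep[i] <- FALSE  # redundant constraint
      }
    }
  }
  if (!all(keep)) {
    Tb <- Tb[keep, , drop = FALSE]
    xb <- xb[keep]
    basis <- basis[keep]
    m <- sum(keep)
  }
  # Phase 2: forbid artificial columns.
  cost2 <- c(cvec, rep(0, ncol(Tb) - n))
  allowed2 <- c(rep(TRUE, n), rep(FALSE, ncol(Tb) - n))
  r2 <- run_simplex(Tb, xb, basis, cost2, allowed2)
  if (r2$status == "unbounded") {
    return(list(status = "unbounded", x = NULL))
  }
  x <- numeric(n)
  inb <- r2$basis <= n
  x[r2$basis[inb]] <- r2$xb[inb]
  x[x < 0 & x > -1e-9 * scale] <- 0
  list(status = "optimal", x = x)
}
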