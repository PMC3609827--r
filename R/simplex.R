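#' Solve a linear program with a deterministic two-phase simplex
#'
#' Minimizes `objective %*% x` subject to general linear rows
#' `A x (<=, >=, =) rhs` and box bounds `lower <= x <= upper`. The solver is
#' a dense full-tableau two-phase simplex with a fixed pivoting rule
#' (most-negative reduced cost, lowest column index on ties; ratio-test ties
#' broken by lowest basic index; Bland's rule engaged after a run of
#' degenerate pivots), so the returned vertex is reproducible for identical
#' input.
#'
#' @param objective numeric cost vector, one entry per variable.
#' @param A constraint matrix (rows are constraints). May have zero rows.
#' @param dir character vector of row directions, each one of
#'   `"<="`, `">="`, `"="`.
#' @param rhs numeric right-hand sides.
#' @param lower,upper box bounds, recycled to the number of variables.
#'   `lower` must be finite; `upper` may be `Inf`.
#' @param maximize if `TRUE`, maximize instead of minimize.
#' @param tol pivot tolerance.
#' @return a list with elements `status` (`"optimal"`, `"infeasible"` or
#'   `"unbounded"`), `x` (solution vector, `NA` unless optimal),
#'   `objective_value`, and `n_iterations`.
#' @examples
#' # min x + y  s.t.  x + 2y >= 4, x >= 0, y >= 0
#' solve_lp(c(1, 1), rbind(c(1, 2)), ">=", 4)
#' @export
solve_lp <- function(objective, A, dir, rhs, lower = 0, upper = Inf,
                     maximize = FALSE, tol = 1e-9) {
  n <- length(objective)
  if (is.null(A)) A <- matrix(0, 0L, n)
  A <- as.matrix(A)
  if (ncol(A) != n && nrow(A) > 0L)
    stop("constraint matrix has ", ncol(A), " columns but there are ",
         n, " variables")
  if (length(dir) != nrow(A) || length(rhs) != nrow(A))
    stop("dir/rhs length must equal the number of constraint rows")
  if (!all(dir %in% c("<=", ">=", "=")))
    stop("constraint directions must be one of '<=', '>=', '='")
  lower <- rep_len(lower, n)
  upper <- rep_len(upper, n)
  if (any(!is.finite(lower))) stop("lower bounds must be finite")
  if (any(upper < lower - tol)) {
    return(list(status = "infeasible", x = rep(NA_real_, n),
                objective_value = NA_real_, n_iterations = 0L))
  }

  obj <- if (maximize) -objective else objective

  # shift to y = x - lower >= 0; finite upper bounds become explicit rows
  rhs_s <- rhs - if (nrow(A)) as.numeric(A %*% lower) else numeric(0)
  ub <- upper - lower
  fin <- which(is.finite(ub))
  if (length(fin)) {
    Ub <- matrix(0, length(fin), n)
    Ub[cbind(seq_along(fin), fin)] <- 1
    A2 <- rbind(A, Ub)
    dir2 <- c(dir, rep("<=", length(fin)))
    rhs2 <- c(rhs_s, ub[fin])
  } else {
    A2 <- A; dir2 <- dir; rhs2 <- rhs_s
  }

  res <- simplex_core(obj, A2, dir2, rhs2, tol = tol)
  if (res$status != "optimal") {
    return(list(status = res$status, x = rep(NA_real_, n),
                objective_value = NA_real_, n_iterations = res$n_iterations))
  }
  x <- res$y[seq_len(n)] + lower
  # clip solver fuzz onto the box
  x <- pmin(pmax(x, lower), upper)
  val <- sum(objective * x)
  list(status = "optimal", x = x, objective_value = val,
       n_iterations = res$n_iterations)
}

# Two-phase simplex on: min c'y  s.t.  A y (dir) b, y >= 0.
# Returns list(status, y, n_iterations).
simplex_core <- function(cost, A, dir, rhs, tol = 1e-9) {
  m <- nrow(A)
  n <- ncol(A)
  if (m == 0L) {
    # unconstrained over y >= 0: bounded iff all costs >= 0
    if (any(cost < -tol))
      return(list(status = "unbounded", y = NULL, n_iterations = 0L))
    return(list(status = "optimal", y = rep(0, n), n_iterations = 0L))
  }
  # normalize rhs >= 0
  neg <- rhs < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    rhs[neg] <- -rhs[neg]
    dir[neg] <- c("<=" = ">=", ">=" = "<=", "=" = "=")[dir[neg]]
  }

  n_slack <- sum(dir != "=")
  need_art <- dir %in% c(">=", "=")
  n_art <- sum(need_art)
  ncols <- n + n_slack + n_art

  Tb <- matrix(0, m + 1L, ncols + 1L)
  Tb[seq_len(m), seq_len(n)] <- A
  Tb[seq_len(m), ncols + 1L] <- rhs
  basis <- integer(m)
  sc <- n
  ac <- n + n_slack
  for (i in seq_len(m)) {
    if (dir[i] == "<=") {
      sc <- sc + 1L
      Tb[i, sc] <- 1
      basis[i] <- sc
    } else if (dir[i] == ">=") {
      sc <- sc + 1L
      Tb[i, sc] <- -1
      ac <- ac + 1L
      Tb[i, ac] <- 1
      basis[i] <- ac
    } else {
      ac <- ac + 1L
      Tb[i, ac] <- 1
      basis[i] <- ac
    }
  }
  art_cols <- if (n_art) (n + n_slack + 1L):ncols else integer(0)
  total_iter <- 0L

  if (n_art) {
    # phase 1: minimize sum of artificials
    art_rows <- which(need_art)
    Tb[m + 1L, ] <- -colSums(Tb[art_rows, , drop = FALSE])
    Tb[m + 1L, art_cols] <- 0
    p1 <- pivot_until_optimal(Tb, basis, block = integer(0), tol = tol)
    Tb <- p1$Tb; basis <- p1$basis; total_iter <- total_iter + p1$iter
    if (p1$status == "unbounded")
      stop("phase-1 subproblem unbounded; constraint system is malformed")
    if (-Tb[m + 1L, ncols + 1L] > 1e-7 * max(1, max(abs(rhs))))
      return(list(status = "infeasible", y = NULL, n_iterations = total_iter))
    # drive artificials out of the basis where possible
    drop_rows <- integer(0)
    for (r in which(basis %in% art_cols)) {
      piv_cand <- setdiff(which(abs(Tb[r, seq_len(n + n_slack)]) > tol),
                          integer(0))
      if (length(piv_cand)) {
        pc <- piv_cand[1L]
        Tb <- do_pivot(Tb, r, pc)
        basis[r] <- pc
      } else {
        drop_rows <- c(drop_rows, r) # redundant row
      }
    }
    if (length(drop_rows)) {
      Tb <- Tb[-drop_rows, , drop = FALSE]
      basis <- basis[-drop_rows]
      m <- m - length(drop_rows)
    }
  }

  # phase 2 objective row (artificial columns blocked from entering)
  full_cost <- c(cost, rep(0, n_slack), rep(0, n_art))
  orow <- c(full_cost, 0)
  for (r in seq_len(m)) {
    cb <- full_cost[basis[r]]
    if (cb != 0) orow <- orow - cb * Tb[r, ]
  }
  Tb[m + 1L, ] <- orow
  p2 <- pivot_until_optimal(Tb, basis, block = art_cols, tol = tol)
  total_iter <- total_iter + p2$iter
  if (p2$status == "unbounded")
    return(list(status = "unbounded", y = NULL, n_iterations = total_iter))
  Tb <- p2$Tb; basis <- p2$basis
  y <- rep(0, ncols)
  y[basis] <- Tb[seq_len(m), ncols + 1L]
  list(status = "optimal", y = pmax(y[seq_len(n)], 0),
       n_iterations = total_iter)
}

do_pivot <- function(Tb, pr, pc) {
  Tb[pr, ] <- Tb[pr, ] / Tb[pr, pc]
  col <- Tb[, pc]
  col[pr] <- 0
  Tb <- Tb - outer(col, Tb[pr, ])
  Tb[, pc] <- 0
  Tb[pr, pc] <- 1
  Tb
}

# pivots Tb (objective in last row) to optimality; 'block' columns never enter
pivot_until_optimal <- function(Tb, basis, block, tol, max_iter = 50000L) {
  m <- nrow(Tb) - 1L
  nc <- ncol(Tb) - 1L
  enterable <- setdiff(seq_len(nc), block)
  degen_run <- 0L
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) stop("simplex iteration limit reached")
    red <- Tb[m + 1L, enterable]
    if (degen_run > 2L * (m + nc)) {
      # Bland's anti-cycling rule
      k <- which(red < -tol)
      if (!length(k)) break
      pc <- enterable[k[1L]]
    } else {
      k <- which.min(red)
      if (red[k] >= -tol) break
      pc <- enterable[k]
    }
    col <- Tb[seq_len(m), pc]
    pos <- which(col > tol)
    if (!length(pos))
      return(list(status = "unbounded", Tb = Tb, basis = basis, iter = iter))
    ratios <- Tb[pos, nc + 1L] / col[pos]
    rmin <- min(ratios)
    ties <- pos[ratios <= rmin + tol * (1 + abs(rmin))]
    pr <- ties[which.min(basis[ties])]
    degen_run <- if (rmin <= tol) degen_run + 1L else 0L
    Tb <- do_pivot(Tb, pr, pc)
    basis[pr] <- pc
  }
  list(status = "optimal", Tb = Tb, basis = basis, iter = iter)
}
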