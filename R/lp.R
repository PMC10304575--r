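# Linear-programming backend. All flux optimization in the package goes
# through solve_lp(), a narrow contract (objective, equality rows, box
# bounds) implemented by a dense bounded-variable two-phase primal simplex.
# Dantzig pricing with an automatic switch to Bland's rule on stalling
# guarantees finite termination; problems at the scale this package works
# with (hundreds of reactions) solve in milliseconds. Correctness is
# cross-checked in the test suite against exhaustive vertex enumeration.

#' Solve a bounded linear program
#'
#' Maximizes (or minimizes) `obj %*% x` subject to `A %*% x == rhs` and
#' `lb <= x <= ub`. This is exactly the FBA geometry: `A` is the
#' stoichiometric matrix, `rhs` is zero (steady state) and the box bounds
#' are the flux bounds.
#'
#' @param obj Numeric objective vector (length n).
#' @param A Constraint matrix (m x n), dense or `Matrix` sparse.
#' @param rhs Right-hand side (length m).
#' @param lb,ub Variable bounds; `ub` may contain `Inf`, `lb` may contain
#'   `-Inf` (handled by an internal sign flip or a wide clamp for free
#'   variables).
#' @param sense `"max"` or `"min"`.
#' @param tol Pivot/feasibility tolerance (default 1e-9).
#' @param max_iter Iteration cap; defaults to `400 * (m + n) + 2000`.
#' @return A list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `objective` and the solution vector `x` (NA unless optimal).
#' @export
solve_lp <- function(obj, A, rhs, lb, ub, sense = c("max", "min"),
                     tol = 1e-9, max_iter = NULL) {
  sense <- match.arg(sense)
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(rhs) == m, length(lb) == n, length(ub) == n)
  if (any(lb > ub)) return(list(status = "infeasible", objective = NA_real_, x = rep(NA_real_, n)))

  cvec <- if (sense == "min") -obj else obj

  # Normalize lower bounds: flip variables with lb = -Inf, finite ub;
  # clamp fully free variables to a wide box.
  BIGFREE <- 1e7
  flip <- is.infinite(lb) & lb < 0 & is.finite(ub)
  free <- is.infinite(lb) & lb < 0 & is.infinite(ub)
  if (any(flip)) {
    A[, flip] <- -A[, flip, drop = FALSE]
    cvec[flip] <- -cvec[flip]
    tmp <- lb[flip]; lb[flip] <- -ub[flip]; ub[flip] <- Inf
  }
  if (any(free)) { lb[free] <- -BIGFREE; ub[free] <- BIGFREE }

  res <- simplex_bounded(cvec, A, rhs, lb, ub, tol = tol, max_iter = max_iter)
  if (res$status == "optimal") {
    x <- res$x
    if (any(flip)) x[flip] <- -x[flip]
    objective <- sum(obj * x)
    list(status = "optimal", objective = objective, x = x)
  } else {
    list(status = res$status, objective = NA_real_, x = rep(NA_real_, n))
  }
}

# Two-phase bounded-variable primal simplex, maximization form.
# Nonbasic variables sit at a finite bound; an entering variable either
# pivots a basic variable out or flips to its opposite bound.
simplex_bounded <- function(cvec, A, rhs, lb, ub, tol = 1e-9, max_iter = NULL) {
  m <- nrow(A); n <- ncol(A)
  if (is.null(max_iter)) max_iter <- 400L * (m + n) + 2000L
  if (m == 0L) {
    # No equality rows: each variable sits at whichever bound favors it.
    x <- ifelse(cvec > 0, ub, lb)
    x[cvec == 0] <- lb[cvec == 0]
    if (any(!is.finite(x) & cvec != 0)) return(list(status = "unbounded"))
    x[!is.finite(x)] <- 0
    return(list(status = "optimal", x = x, objective = sum(cvec * x)))
  }

  # Initial point: structural variables at their lower bound.
  resid <- rhs - as.vector(A %*% lb)
  sigma <- ifelse(resid >= 0, 1, -1)

  # Augment with m artificial columns sigma_i * e_i, bounds [0, Inf).
  Aaug <- cbind(A, diag(sigma, nrow = m))
  lba <- c(lb, rep(0, m))
  uba <- c(ub, rep(Inf, m))
  ntot <- n + m

  state <- list(
    basis = (n + 1L):ntot,
    # vstat: 1 = nonbasic at lb, 2 = nonbasic at ub, 0 = basic
    vstat = c(rep(1L, n), rep(0L, m)),
    xval = c(lb, abs(resid))
  )

  run_phase <- function(cost, state, uba) {
    basis <- state$basis; vstat <- state$vstat; xval <- state$xval
    bland <- FALSE
    stall <- 0L
    last_obj <- -Inf
    for (it in seq_len(max_iter)) {
      B <- Aaug[, basis, drop = FALSE]
      Binv <- tryCatch(solve(B), error = function(e) NULL)
      if (is.null(Binv)) return(list(status = "error"))
      nb <- which(vstat != 0L)
      N <- Aaug[, nb, drop = FALSE]
      # Refresh basic values each iteration for numerical hygiene.
      xval[basis] <- as.vector(Binv %*% (rhs - N %*% xval[nb]))

      y <- as.vector(crossprod(Binv, cost[basis]))
      d <- cost[nb] - as.vector(crossprod(N, y))
      improving <- (vstat[nb] == 1L & d > tol) | (vstat[nb] == 2L & d < -tol)
      if (!any(improving)) {
        return(list(status = "optimal",
                    state = list(basis = basis, vstat = vstat, xval = xval)))
      }
      cand <- which(improving)
      q <- if (bland) nb[cand[which.min(nb[cand])]]
           else nb[cand[which.max(abs(d[cand]))]]
      s <- if (vstat[q] == 1L) 1 else -1  # moving up from lb / down from ub

      w <- as.vector(Binv %*% Aaug[, q])
      # Ratio test: largest step t >= 0 for the entering variable.
      gap <- uba[q] - lba[q]
      t_best <- if (is.finite(gap)) gap else Inf
      leave <- 0L; leave_to <- 0L
      for (i in seq_len(m)) {
        sw <- s * w[i]
        bi <- basis[i]
        ti <- NA_real_; to <- 0L
        if (sw > tol && is.finite(lba[bi])) {
          ti <- (xval[bi] - lba[bi]) / sw; to <- 1L
        } else if (sw < -tol && is.finite(uba[bi])) {
          ti <- (uba[bi] - xval[bi]) / (-sw); to <- 2L
        }
        if (is.na(ti)) next
        ti <- max(ti, 0)
        take <- if (leave == 0L) ti < t_best + 1e-12
                else ti < t_best - 1e-12 ||
                     (ti < t_best + 1e-12 && bi < basis[leave])
        if (take) { t_best <- min(t_best, ti); leave <- i; leave_to <- to }
      }
      if (!is.finite(t_best)) return(list(status = "unbounded"))

      xval[basis] <- xval[basis] - t_best * s * w
      xval[q] <- xval[q] + s * t_best
      if (leave == 0L) {
        vstat[q] <- if (vstat[q] == 1L) 2L else 1L  # bound flip
      } else {
        out <- basis[leave]
        vstat[out] <- leave_to
        xval[out] <- if (leave_to == 1L) lba[out] else uba[out]
        basis[leave] <- q
        vstat[q] <- 0L
      }

      obj <- sum(cost * xval)
      stall <- if (obj <= last_obj + 1e-12) stall + 1L else 0L
      last_obj <- obj
      if (stall >= 60L) bland <- TRUE
    }
    list(status = "iteration_limit")
  }

  # Phase 1: drive artificial variables to zero.
  cost1 <- c(rep(0, n), rep(-1, m))
  ph1 <- run_phase(cost1, state, uba)
  if (ph1$status != "optimal") return(list(status = "error"))
  art <- ph1$state$xval[(n + 1L):ntot]
  if (sum(art) > 1e-7 * max(1, max(abs(rhs)))) {
    return(list(status = "infeasible"))
  }

  # Phase 2: lock artificials at zero and optimize the true objective.
  uba[(n + 1L):ntot] <- 0
  st <- ph1$state
  st$xval[(n + 1L):ntot] <- 0
  ph2 <- run_phase(c(cvec, rep(0, m)), st, uba)
  if (ph2$status != "optimal") {
    return(list(status = if (ph2$status == "unbounded") "unbounded" else "error"))
  }
  x <- ph2$state$xval[seq_len(n)]
  x <- pmin(pmax(x, lb), ub)  # snap roundoff back into the box
  list(status = "optimal", x = x, objective = sum(cvec * x))
}
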