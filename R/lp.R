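# Internal dense linear programming solver.
#
# Two-phase primal simplex for problems with bounded variables:
#
#   maximize / minimize  c'x   subject to  A x = b,  lb <= x <= ub
#
# All bounds must be finite.  Nonbasic variables sit at either their lower or
# upper bound; the ratio test allows bound flips.  Bland's rule (lowest
# eligible index) is used for entering and leaving variables, so the pivot
# sequence -- and hence the returned vertex -- is deterministic and cycling is
# impossible.  Redundant equality rows are tolerated: phase 1 leaves their
# artificial variables basic at zero and phase 2 pins them there.
#
# The basic solution is refactorised from scratch at every iteration.  That is
# O(m^3) per pivot, which would be unacceptable for large programs but is both
# fast and numerically self-correcting for the ~25-reaction core models solved
# at every dFBA step.

LP_TOL <- 1e-9

#' @keywords internal
#' @noRd
lp_solve <- function(obj, A, b, lb, ub, maximize = TRUE, warm = NULL) {
  n <- length(obj)
  A <- as.matrix(A)
  stopifnot(ncol(A) == n, length(b) == nrow(A), length(lb) == n,
            length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("lp_solve requires finite bounds")
  if (any(ub < lb - 1e-12))
    return(list(status = "infeasible", x = rep(NA_real_, n), value = NA_real_))
  ub <- pmax(ub, lb)

  # Warm start: if the caller supplies the optimal basis of a previous solve
  # of the same program in which only the bounds differed, optimality of the
  # basis depends only on the cost vector and the bound *status* pattern, not
  # on the bound values.  Re-solving then amounts to recomputing the basic
  # values and checking primal feasibility -- a single m x m solve.
  if (!is.null(warm) && identical(warm$n, n) && identical(warm$dim_b, nrow(A))) {
    res <- lp_warm_try(if (maximize) obj else -obj, A, b, lb, ub, warm)
    if (!is.null(res)) {
      res$value <- sum(obj * res$x)
      return(res)
    }
  }

  m <- nrow(A)
  u <- ub - lb                         # x = lb + y, 0 <= y <= u
  b2 <- b - as.vector(A %*% lb)
  neg <- b2 < 0
  if (any(neg)) {                      # nonnegative rhs for artificial start
    A[neg, ] <- -A[neg, , drop = FALSE]
    b2[neg] <- -b2[neg]
  }

  TA <- cbind(A, diag(m))              # structural | artificial columns
  uu <- c(u, b2 + 1)
  basis <- n + seq_len(m)
  at_upper <- rep(FALSE, n + m)

  basic_values <- function() {
    nb <- setdiff(seq_len(n + m), basis)
    hi <- nb[at_upper[nb]]
    rhs <- b2
    if (length(hi))
      rhs <- rhs - as.vector(TA[, hi, drop = FALSE] %*% uu[hi])
    Binv <- tryCatch(solve(TA[, basis, drop = FALSE]),
                     error = function(e) stop("singular basis in lp_solve"))
    list(Binv = Binv, xb = as.vector(Binv %*% rhs))
  }

  run_simplex <- function(cost, allow) {
    it_max <- 5000L + 100L * (n + m)
    for (it in seq_len(it_max)) {
      bv <- basic_values()
      Binv <- bv$Binv; xb <- bv$xb
      lambda <- as.vector(crossprod(Binv, cost[basis]))
      nb <- setdiff(seq_len(n + m), basis)
      nb <- nb[allow[nb]]
      if (length(nb)) {
        rc <- cost[nb] - as.vector(lambda %*% TA[, nb, drop = FALSE])
        elig <- ifelse(at_upper[nb], rc < -LP_TOL, rc > LP_TOL)
      } else elig <- logical(0)
      if (!any(elig)) return("optimal")
      j <- min(nb[elig])                         # Bland: entering
      dirn <- if (at_upper[j]) -1 else 1
      d <- as.vector(Binv %*% TA[, j]) * dirn    # basic change is -d * t
      t_best <- uu[j]; leave <- 0L; leave_hi <- FALSE
      for (i in seq_len(m)) {
        if (d[i] > LP_TOL) {
          tt <- max(xb[i], 0) / d[i]             # basic hits lower (0)
          hit_hi <- FALSE
        } else if (d[i] < -LP_TOL) {
          tt <- (xb[i] - uu[basis[i]]) / d[i]    # basic hits upper
          hit_hi <- TRUE
        } else next
        if (tt < t_best - LP_TOL ||
            (tt < t_best + LP_TOL && leave != 0L && basis[i] < basis[leave])) {
          t_best <- min(t_best, max(tt, 0)); leave <- i; leave_hi <- hit_hi
        }
      }
      if (t_best > 1e30) return("unbounded")
      if (leave == 0L) {
        at_upper[j] <<- !at_upper[j]             # bound flip
      } else {
        out <- basis[leave]
        at_upper[out] <<- leave_hi
        basis[leave] <<- j
        at_upper[j] <<- FALSE
      }
    }
    stop("lp_solve iteration limit exceeded")
  }

  # phase 1: drive artificial variables to zero
  st <- run_simplex(c(rep(0, n), rep(-1, m)), allow = rep(TRUE, n + m))
  xb <- basic_values()$xb
  if (st != "optimal" || sum(abs(xb[basis > n])) > 1e-7)
    return(list(status = "infeasible", x = rep(NA_real_, n), value = NA_real_))
  uu[n + seq_len(m)] <- 0              # artificials pinned at zero

  # phase 2
  st <- run_simplex(c(if (maximize) obj else -obj, rep(0, m)),
                    allow = c(rep(TRUE, n), rep(FALSE, m)))
  if (st == "unbounded")
    return(list(status = "unbounded", x = rep(NA_real_, n), value = NA_real_))

  xb <- basic_values()$xb
  y <- numeric(n + m)
  y[basis] <- xb
  nb <- setdiff(seq_len(n + m), basis)
  y[nb] <- ifelse(at_upper[nb], uu[nb], 0)
  x <- lb + pmin(pmax(y[seq_len(n)], 0), u)

  warm_out <- NULL
  if (all(basis <= n)) {               # no artificial left basic
    nb_struct <- setdiff(seq_len(n), basis)
    warm_out <- list(n = n, dim_b = m, basic = basis,
                     nb = nb_struct, nb_at_upper = at_upper[nb_struct])
  }
  list(status = "optimal", x = x, value = sum(obj * x), warm = warm_out)
}

# Attempt to reuse a previously optimal basis (original coordinates).
# Returns a solution list, or NULL if the basis is no longer valid.
#' @keywords internal
#' @noRd
lp_warm_try <- function(obj, A, b, lb, ub, warm, tol = 1e-8) {
  B <- warm$basic; N <- warm$nb
  if (length(B) != nrow(A)) return(NULL)
  xN <- ifelse(warm$nb_at_upper, ub[N], lb[N])
  AB <- A[, B, drop = FALSE]
  rhs <- b - if (length(N)) as.vector(A[, N, drop = FALSE] %*% xN) else b * 0
  xB <- tryCatch(solve(AB, rhs), error = function(e) NULL)
  if (is.null(xB)) return(NULL)
  sc <- pmax(1, abs(xB))
  if (any(xB < lb[B] - tol * sc) || any(xB > ub[B] + tol * sc)) return(NULL)
  # optimality (maximization): reduced cost <= 0 at lower, >= 0 at upper;
  # variables with a degenerate range (lb == ub) are always acceptable.
  lam <- tryCatch(solve(t(AB), obj[B]), error = function(e) NULL)
  if (is.null(lam)) return(NULL)
  if (length(N)) {
    rc <- obj[N] - as.vector(lam %*% A[, N, drop = FALSE])
    fixedN <- (ub[N] - lb[N]) < 1e-15
    bad <- (!fixedN) &
      ifelse(warm$nb_at_upper, rc < -1e-7, rc > 1e-7)
    if (any(bad)) return(NULL)
  }
  x <- numeric(warm$n)
  x[B] <- pmin(pmax(xB, lb[B]), ub[B])
  x[N] <- xN
  list(status = "optimal", x = x, value = sum(obj * x), warm = warm)
}
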