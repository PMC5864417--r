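# Independent oracles used across the test files.

# Brute-force LP oracle: enumerate candidate vertices of
#   max c'x  s.t.  A x = b, lb <= x <= ub
# by fixing every subset of (n - m) variables at a bound combination and
# solving the remaining square system.  Exponential; only for tiny problems.
enumerate_lp <- function(obj, A, b, lb, ub) {
  n <- length(obj); m <- nrow(A)
  stopifnot(n - m <= 8)
  best <- -Inf; best_x <- NULL
  free_sets <- utils::combn(n, m, simplify = FALSE)
  for (fs in free_sets) {
    nb <- setdiff(seq_len(n), fs)
    Af <- A[, fs, drop = FALSE]
    if (abs(det(Af)) < 1e-10) next
    combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(nb)))
    for (ci in seq_len(nrow(combos))) {
      at_up <- unlist(combos[ci, ])
      xnb <- ifelse(at_up, ub[nb], lb[nb])
      rhs <- b - as.vector(A[, nb, drop = FALSE] %*% xnb)
      xf <- tryCatch(solve(Af, rhs), error = function(e) NULL)
      if (is.null(xf)) next
      if (any(xf < lb[fs] - 1e-8) || any(xf > ub[fs] + 1e-8)) next
      x <- numeric(n); x[fs] <- xf; x[nb] <- xnb
      v <- sum(obj * x)
      if (v > best + 1e-10) { best <- v; best_x <- x }
    }
  }
  list(value = best, x = best_x)
}

# short-horizon N. europaea scenario for fast tests
quick_ne_scenario <- function(t_end = 4) {
  sc <- make_fixture_scenarios()$ne_single
  sc$t_end <- t_end
  sc
}
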