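## Small damped-Newton solver for square nonlinear systems, used by the
## static-equilibrium solves and the trajectory generator.  Numeric forward
## difference Jacobian with Levenberg-style damping on failure to descend.
newton_solve <- function(fn, x0, tol = 1e-8, max_iter = 60, h = 1e-6,
                         step_max = Inf) {
  x <- x0
  r <- fn(x)
  n <- length(x)
  lambda <- 0
  for (it in seq_len(max_iter)) {
    nr <- sqrt(sum(r^2))
    if (nr < tol) return(list(x = x, residual = nr, iterations = it - 1L,
                              converged = TRUE))
    J <- matrix(0, n, n)
    for (j in seq_len(n)) {
      xp <- x; hp <- h * max(1, abs(x[j])); xp[j] <- x[j] + hp
      J[, j] <- (fn(xp) - r) / hp
    }
    improved <- FALSE
    for (trial in 0:8) {
      A <- crossprod(J) + (lambda + 1e-12) * diag(n)
      step <- tryCatch(-solve(A, crossprod(J, r)),
                       error = function(e) NULL)
      if (!is.null(step)) {
        sn <- sqrt(sum(step^2))
        if (sn > step_max) step <- step * (step_max / sn)
        xn <- x + as.numeric(step)
        rn <- tryCatch(fn(xn), error = function(e) NULL)
        if (!is.null(rn) && all(is.finite(rn)) &&
            sqrt(sum(rn^2)) < nr * (1 - 1e-10) + 1e-14) {
          x <- xn; r <- rn
          lambda <- lambda / 4
          improved <- TRUE
          break
        }
      }
      lambda <- max(lambda * 10, 1e-8)
    }
    if (!improved)
      return(list(x = x, residual = sqrt(sum(r^2)), iterations = it,
                  converged = sqrt(sum(r^2)) < tol * 100))
  }
  list(x = x, residual = sqrt(sum(fn(x)^2)), iterations = max_iter,
       converged = sqrt(sum(fn(x)^2)) < tol)
}

## natural-spline evaluation helper for knot tables
knot_spline <- function(xs, ys) stats::splinefun(xs, ys, method = "natural")

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])
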