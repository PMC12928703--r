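#' Powell's conjugate-direction minimizer
#'
#' Derivative-free minimization by successive line searches along a set of
#' directions, replacing the direction of largest decrease with the overall
#' displacement each sweep (Powell's classic update with the standard
#' parabolic acceptance test). Line minimizations use golden-section /
#' parabolic interpolation ([stats::optimize()]) over an expanding bracket.
#'
#' Non-finite objective values are treated as +Inf so the search simply backs
#' away from degenerate regions.
#'
#' @param fn Objective function of a numeric vector.
#' @param par Starting point.
#' @param tol Relative convergence tolerance on the objective.
#' @param maxit Maximum number of direction sweeps.
#' @return List with `par`, `value`, `iterations`, `converged`.
#' @export
powell_minimize <- function(fn, par, tol = 1e-6, maxit = 200) {
  safe <- function(p) {
    v <- fn(p)
    if (is.finite(v)) v else 1e300
  }
  n <- length(par)
  dirs <- diag(n)
  f <- safe(par)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(maxit)) {
    f0 <- f
    p0 <- par
    ibig <- 1L
    dbig <- 0
    for (i in seq_len(n)) {
      ls <- powell_line_min(safe, par, dirs[, i], f)
      if (f - ls$f > dbig) {
        dbig <- f - ls$f
        ibig <- i
      }
      par <- ls$par
      f <- ls$f
    }
    if (2 * (f0 - f) <= tol * (abs(f0) + abs(f)) + 1e-12) {
      converged <- TRUE
      break
    }
    # Powell's test on the extrapolated point before replacing a direction
    pe <- 2 * par - p0
    fe <- safe(pe)
    if (fe < f0) {
      t <- 2 * (f0 - 2 * f + fe) * (f0 - f - dbig)^2 - dbig * (f0 - fe)^2
      if (t < 0) {
        d <- par - p0
        nd <- sqrt(sum(d^2))
        if (nd > 0) {
          ls <- powell_line_min(safe, par, d / nd, f)
          par <- ls$par
          f <- ls$f
          dirs[, ibig] <- dirs[, n]
          dirs[, n] <- d / nd
        }
      }
    }
  }
  list(par = par, value = f, iterations = it, converged = converged)
}

# One line minimization t -> fn(par + t * d) with an expanding symmetric
# bracket; never returns a point worse than the incumbent.
powell_line_min <- function(safe, par, d, f0) {
  g <- function(t) safe(par + t * d)
  a <- 1
  repeat {
    opt <- stats::optimize(g, interval = c(-a, a), tol = 1e-8)
    if (abs(opt$minimum) < 0.9 * a || a >= 64) break
    a <- a * 4
  }
  if (opt$objective < f0) list(par = par + opt$minimum * d, f = opt$objective)
  else list(par = par, f = f0)
}
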