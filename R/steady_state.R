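# sparse N x M threshold-inverse matrices used by both solvers
edge_matrices <- function(network, params) {
  N <- n_rna(network); M <- n_mirna(network)
  e <- network$edges
  list(
    inv_mu0 = Matrix::sparseMatrix(i = e$rna, j = e$mirna,
                                   x = 1 / params$mu0_edge, dims = c(N, M)),
    inv_m0 = Matrix::sparseMatrix(i = e$rna, j = e$mirna,
                                  x = 1 / params$m0_edge, dims = c(N, M))
  )
}

#' Unrepressed reference levels
#'
#' Steady-state levels in the absence of any inhibition: m*_i = b_i / d and
#' mu*_a = beta_a / delta.
#'
#' @param params A [kinetic_params()].
#' @return List with numeric vectors `m_star` and `mu_star` (molecules).
#' @export
unrepressed_levels <- function(params) {
  list(m_star = params$b / params$d, mu_star = params$beta / params$delta)
}

#' Solve the coupled titration fixed point
#'
#' Free levels at steady state obey the coupled maps
#' `mu_a = mu*_a / (1 + sum_i m_i / m0_ia)` and
#' `m_i = m*_i / (1 + sum_a mu_a / mu0_ia)`.
#' Both maps are monotone and bounded, so a damped alternating iteration
#' (damping 0.5, halved whenever the residual grows) started from the
#' unrepressed RNA levels converges robustly. Complex levels are computed post
#' hoc from the free levels and the derived rate constants; they do not feed
#' back on the fixed point.
#'
#' @param network A `ceRNA_network`.
#' @param params A [kinetic_params()].
#' @param tol Maximum relative update at convergence (default 1e-12).
#' @param max_iter Iteration budget before a non-convergence error.
#' @return Object of class `ceRNA_steady_state`: free levels `m`, `mu`,
#'   per-edge complexes `c`, references `m_star`, `mu_star`, plus `converged`,
#'   `residual` and `iterations`.
#' @export
solve_steady_state <- function(network, params, tol = 1e-12,
                               max_iter = 100000L) {
  ref <- unrepressed_levels(params)
  m_star <- ref$m_star; mu_star <- ref$mu_star
  mats <- edge_matrices(network, params)
  t_inv_m0 <- Matrix::t(mats$inv_m0)

  m <- m_star
  mu <- as.numeric(mu_star / (1 + t_inv_m0 %*% m))
  theta <- 0.5
  res_prev <- Inf
  res <- Inf
  for (it in seq_len(max_iter)) {
    m_new <- as.numeric(m_star / (1 + mats$inv_mu0 %*% mu))
    m_next <- (1 - theta) * m + theta * m_new
    mu_new <- as.numeric(mu_star / (1 + t_inv_m0 %*% m_next))
    mu_next <- (1 - theta) * mu + theta * mu_new

    res <- max(abs(m_next - m) / pmax(m, .Machine$double.xmin),
               if (length(mu)) abs(mu_next - mu) / pmax(mu, .Machine$double.xmin) else 0)
    m <- m_next; mu <- mu_next
    if (res < tol * theta) break
    if (res > res_prev) theta <- max(theta / 2, 1 / 64)  # residual oscillation
    res_prev <- res
  }

  # fixed-point residual of the undamped maps
  m_chk <- as.numeric(m_star / (1 + mats$inv_mu0 %*% mu))
  mu_chk <- as.numeric(mu_star / (1 + t_inv_m0 %*% m))
  fp_res <- max(abs(m_chk - m) / pmax(m, .Machine$double.xmin),
                if (length(mu)) abs(mu_chk - mu) /
                  pmax(mu, .Machine$double.xmin) else 0)
  if (fp_res > max(tol, 1e-15) * 10) {
    stop(structure(class = c("ceRNA_no_convergence", "error", "condition"),
                   list(message = sprintf(
                     "fixed-point iteration did not converge: residual %.3e after %d iterations",
                     fp_res, it), call = sys.call(-1))))
  }

  # complexes: c_ia = k_on m_i mu_a / (sigma + kappa) with k_on = d / mu0_ia
  e <- network$edges
  c_edge <- (params$d / params$mu0_edge) * m[e$rna] * mu[e$mirna] /
    params$complex_decay_total

  structure(list(m = m, mu = mu, c = c_edge,
                 m_star = m_star, mu_star = mu_star,
                 converged = TRUE, residual = fp_res, iterations = it),
            class = "ceRNA_steady_state")
}

#' @export
print.ceRNA_steady_state <- function(x, ...) {
  cat("ceRNA titration steady state\n")
  cat(sprintf("  %d RNAs (total free %.3g of %.3g unrepressed), %d miRNAs\n",
              length(x$m), sum(x$m), sum(x$m_star), length(x$mu)))
  cat(sprintf("  converged in %d iterations, residual %.2e\n",
              x$iterations, x$residual))
  invisible(x)
}

#' Integrate the full mass-action kinetics
#'
#' Numerical integration of the complete ODE system for free RNAs, free
#' miRNAs and complexes (association k_on = d / mu0_ia, no unbinding,
#' catalytic and stoichiometric complex decay split by the stoichiometricity
#' ratio). Serves as an independent oracle for [solve_steady_state()].
#'
#' @param network A `ceRNA_network`.
#' @param params A [kinetic_params()].
#' @param t_end Final time (h); the default 50/delta is far beyond the slowest
#'   relaxation scale.
#' @param initial_state Optional list with `m`, `mu`, `c` starting levels;
#'   defaults to the empty cell (all zero).
#' @param n_out Number of saved time points.
#' @return Object of class `ceRNA_trajectory`: `times` and matrices `m`, `mu`,
#'   `c` (rows = time points).
#' @export
integrate_odes <- function(network, params, t_end = 50 / params$delta,
                           initial_state = NULL, n_out = 101L) {
  stopifnot(t_end > 0)
  N <- n_rna(network); M <- n_mirna(network)
  e <- network$edges; E <- nrow(e)
  k_on <- params$d / params$mu0_edge
  total <- params$complex_decay_total
  sigma <- params$lam * total
  kappa <- (1 - params$lam) * total

  agg_rna <- if (E) Matrix::sparseMatrix(i = e$rna, j = seq_len(E), x = 1,
                                         dims = c(N, E)) else NULL
  agg_mir <- if (E) Matrix::sparseMatrix(i = e$mirna, j = seq_len(E), x = 1,
                                         dims = c(M, E)) else NULL

  y0 <- c(
    if (is.null(initial_state)) rep(0, N) else initial_state$m,
    if (is.null(initial_state)) rep(0, M) else initial_state$mu,
    if (is.null(initial_state)) rep(0, E) else initial_state$c
  )

  deriv <- function(t, y, parms) {
    m <- y[seq_len(N)]
    mu <- y[N + seq_len(M)]
    cc <- if (E) y[N + M + seq_len(E)] else numeric(0)
    if (E) {
      flux <- k_on * m[e$rna] * mu[e$mirna]
      dm <- params$b - params$d * m - as.numeric(agg_rna %*% flux)
      dmu <- params$beta - params$delta * mu -
        as.numeric(agg_mir %*% flux) + as.numeric(agg_mir %*% (kappa * cc))
      dc <- flux - (kappa + sigma) * cc
    } else {
      dm <- params$b - params$d * m
      dmu <- params$beta - params$delta * mu
      dc <- numeric(0)
    }
    list(c(dm, dmu, dc))
  }

  times <- seq(0, t_end, length.out = n_out)
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-10)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed (see deSolve diagnostics)", call. = FALSE)
  structure(list(
    times = sol[, 1],
    m = sol[, 1 + seq_len(N), drop = FALSE],
    mu = sol[, 1 + N + seq_len(M), drop = FALSE],
    c = if (E) sol[, 1 + N + M + seq_len(E), drop = FALSE] else
      matrix(0, nrow(sol), 0)
  ), class = "ceRNA_trajectory")
}

#' Overall relative molecular abundances
#'
#' Fraction of unrepressed totals retained at steady state:
#' sum(m) / sum(m*) for RNAs and sum(mu) / sum(mu*) for miRNAs. The crossing
#' of the two curves as mean miRNA transcription rises delimits the
#' susceptible regime.
#'
#' @param state A converged `ceRNA_steady_state`.
#' @return Named numeric vector `c(rna_fraction, mirna_fraction)`.
#' @export
relative_abundance <- function(state) {
  stopifnot(inherits(state, "ceRNA_steady_state"), isTRUE(state$converged))
  c(rna_fraction = sum(state$m) / sum(state$m_star),
    mirna_fraction = if (sum(state$mu_star) > 0)
      sum(state$mu) / sum(state$mu_star) else NA_real_)
}
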