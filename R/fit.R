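#' Fit the steady-state crosstalk model to a network
#'
#' The central entry point: solves the titration fixed point for the free
#' molecular levels, builds the coupling matrix W and the susceptibility
#' matrix chi = (I - W)^-1 diag(m/m*), and returns everything as a classed
#' object with the usual modelling methods (`print`, `summary`, `coef`,
#' `predict`, `residuals`, `simulate`, `plot`).
#'
#' @param network A `ceRNA_network`.
#' @param params A [kinetic_params()]; if `NULL`, defaults are built from the
#'   remaining arguments.
#' @param b,beta Transcription rates forwarded to [kinetic_params()] when
#'   `params` is `NULL`.
#' @param bh A [bh_scenario()] forwarded likewise.
#' @param tol Fixed-point solver tolerance.
#' @param validate Forwarded to [compute_susceptibility()] (spectral-radius
#'   check by power iteration).
#' @param ... Further arguments to [kinetic_params()].
#' @return Object of class `ceRNA_fit` with components `network`, `params`,
#'   `state` (the `ceRNA_steady_state`), `W`, `chi`, `chi_self`.
#' @examples
#' motif <- make_motif("chain", beta = 30)
#' fit <- crosstalk_fit(motif$network, motif$params)
#' coef(fit)            # the susceptibility matrix
#' summary(fit)
#' @export
crosstalk_fit <- function(network, params = NULL, b = 8, beta = 2.7,
                          bh = bh_scenario("low"), tol = 1e-12,
                          validate = FALSE, ...) {
  if (is.null(params))
    params <- kinetic_params(network, b = b, beta = beta, bh = bh, ...)
  state <- solve_steady_state(network, params, tol = tol)
  W <- build_W(network, params, state)
  sus <- compute_susceptibility(W, state, validate = validate)
  structure(list(network = network, params = params, state = state,
                 W = W, chi = sus$chi, chi_self = sus$chi_self),
            class = "ceRNA_fit")
}

#' @export
print.ceRNA_fit <- function(x, ...) {
  N <- length(x$state$m)
  ab <- relative_abundance(x$state)
  cat("Steady-state ceRNA crosstalk fit\n")
  cat(sprintf("  %d RNAs, %d miRNAs, %d edges (BH: %s)\n",
              N, length(x$state$mu), nrow(x$network$edges),
              x$params$bh$level))
  cat(sprintf("  free RNA fraction %.3f, free miRNA fraction %.3f\n",
              ab[1], ab[2]))
  if (N >= 2) {
    st <- intensity_stats(x$chi)
    cat(sprintf("  mean chi (i != j) %.3e, max chi %.3e, mean chi_ii %.3f\n",
                st["mean_chi"], st["max_chi"], st["mean_self"]))
  }
  invisible(x)
}

#' Summarize a crosstalk fit
#'
#' Collects the full set of scalar crosstalk descriptors: intensity
#' statistics, selectivities, locality correlation, asymmetry index,
#' expression CV and relative abundances.
#'
#' @param object A `ceRNA_fit`.
#' @param ... Unused.
#' @return A `summary.ceRNA_fit` list, printable.
#' @export
summary.ceRNA_fit <- function(object, ...) {
  N <- length(object$state$m)
  out <- list(fit = object, abundance = relative_abundance(object$state))
  if (N >= 2) {
    K <- locality_matrix(object$network, object$params)
    sel <- suppressWarnings(selectivity(object$chi))
    out <- c(out, list(
      intensity = intensity_stats(object$chi),
      s_in = sel$s_in, s_out = sel$s_out,
      rho = suppressWarnings(locality_correlation(object$chi, K)),
      asymmetry = suppressWarnings(asymmetry_index(object$chi)),
      cv_expression = expression_cv(object$state)
    ))
  }
  class(out) <- "summary.ceRNA_fit"
  out
}

#' @export
print.summary.ceRNA_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$intensity)) {
    cat(sprintf("  selectivity: S_in %.3g, S_out %.3g\n", x$s_in, x$s_out))
    cat(sprintf("  locality rho %.3g, asymmetry %.3g, expression CV %.3g\n",
                x$rho, x$asymmetry, x$cv_expression))
  }
  invisible(x)
}

#' @export
coef.ceRNA_fit <- function(object, ...) object$chi

#' Linear-response prediction of expression changes
#'
#' Predicts the change in steady-state free RNA levels caused by a small
#' change in transcription rates using the fitted susceptibility matrix:
#' `dm_i = sum_j chi_ij db_j / d`. Accurate to first order; for large
#' perturbations re-solve with [crosstalk_fit()].
#'
#' @param object A `ceRNA_fit`.
#' @param db Numeric vector of transcription-rate changes (molecules/h,
#'   length N).
#' @param ... Unused.
#' @return Predicted change in free RNA levels (molecules).
#' @export
predict.ceRNA_fit <- function(object, db, ...) {
  stopifnot(length(db) == length(object$params$b))
  as.numeric(object$chi %*% (db / object$params$d))
}

#' @export
residuals.ceRNA_fit <- function(object, ...) {
  # per-species relative fixed-point residual of the two titration maps
  net <- object$network; p <- object$params; st <- object$state
  mats <- edge_matrices(net, p)
  m_chk <- as.numeric(st$m_star / (1 + mats$inv_mu0 %*% st$mu))
  mu_chk <- as.numeric(st$mu_star / (1 + Matrix::t(mats$inv_m0) %*% st$m))
  c((m_chk - st$m) / pmax(st$m, .Machine$double.xmin),
    (mu_chk - st$mu) / pmax(st$mu, .Machine$double.xmin))
}

#' Simulate transcription-heterogeneity replicates of a fit
#'
#' Draws `nsim` lognormal realizations of the transcription-rate vectors
#' around the fitted means (same CV for RNAs and miRNAs), re-solves the model
#' for each, and returns the scalar crosstalk descriptors per realization.
#'
#' @param object A `ceRNA_fit`.
#' @param nsim Number of realizations.
#' @param seed Integer seed.
#' @param cv_tr Coefficient of variation of the drawn rates (default 0.4).
#' @param ... Unused.
#' @return Data frame with one row per realization.
#' @export
simulate.ceRNA_fit <- function(object, nsim = 1, seed = NULL, cv_tr = 0.4,
                               ...) {
  run_condition(object$network,
                b_mean = mean(object$params$b),
                beta_mean = mean(object$params$beta),
                cv_tr = cv_tr, bh = object$params$bh, n_reps = nsim,
                seed = if (is.null(seed)) 1L else seed,
                d = object$params$d, delta = object$params$delta,
                lam = object$params$lam, mu0_base = object$params$mu0_base,
                aggregate = FALSE)
}

#' Diagnostic plot of a crosstalk fit
#'
#' Two panels: the distribution of non-zero pairwise susceptibilities
#' (log10 scale) and repressed versus unrepressed RNA levels.
#'
#' @param x A `ceRNA_fit`.
#' @param ... Passed to `hist`.
#' @export
plot.ceRNA_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  v <- off_diag(x$chi)
  v <- v[v > 0]
  if (length(v)) {
    graphics::hist(log10(v), main = "pairwise susceptibilities",
                   xlab = expression(log[10] ~ chi[ij]), ...)
  } else {
    plot(0, 0, type = "n", main = "pairwise susceptibilities",
         xlab = "", ylab = "")
    graphics::text(0, 0, "all zero")
  }
  plot(x$state$m_star, x$state$m, log = "xy",
       xlab = "unrepressed level m*", ylab = "free level m",
       main = "RNA repression")
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
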