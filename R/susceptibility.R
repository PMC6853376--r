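#' Coupling matrix of the linear-response expansion
#'
#' The N x N matrix with entries
#' `W_ij = (m_i^2 / m*_i) * sum_{a in i&j} (mu_a^2 / mu*_a) / (mu0_ia * m0_ja)`,
#' the sum running over miRNA species targeting both RNA i and RNA j
#' (the diagonal included: a sums over all regulators of i). W is built as a
#' sparse triple product, so its support is exactly the set of RNA pairs
#' sharing at least one regulator.
#'
#' @param network A `ceRNA_network`.
#' @param params A [kinetic_params()].
#' @param state A converged `ceRNA_steady_state`.
#' @return A sparse `Matrix` of dimension N x N with non-negative entries.
#' @export
build_W <- function(network, params, state) {
  if (!inherits(state, "ceRNA_steady_state") || !isTRUE(state$converged))
    stop("build_W requires a converged steady state", call. = FALSE)
  mats <- edge_matrices(network, params)
  mu_scale <- ifelse(state$mu_star > 0, state$mu^2 / state$mu_star, 0)
  m_scale <- state$m^2 / state$m_star
  W <- Matrix::Diagonal(x = m_scale) %*% mats$inv_mu0 %*%
    Matrix::Diagonal(x = mu_scale) %*% Matrix::t(mats$inv_m0)
  methods::as(W, "CsparseMatrix")
}

#' Susceptibility matrix from the coupling matrix
#'
#' Solves `chi = (I - W)^-1 diag(m/m*)` by sparse LU linear solves (no
#' explicit inverse). The steady state is linearly stable only when the
#' spectral radius of W is below 1; a failed solve or negative susceptibility
#' entries flag a violated stability assumption. Entry `chi_ij = d_j
#' d[m_i]/d[b_j]` is the dimensionless response of free RNA i to a small
#' change in RNA j's transcription rate; the diagonal self-susceptibility is
#' bounded by 1.
#'
#' @param W Coupling matrix from [build_W()].
#' @param state The `ceRNA_steady_state` used to build W.
#' @param validate If `TRUE`, additionally estimate the spectral radius of W
#'   by power iteration and refuse if it is >= 1.
#' @return Object of class `ceRNA_susceptibility`: dense `chi` matrix, sparse
#'   `W`, and diagonal `chi_self`.
#' @export
compute_susceptibility <- function(W, state, validate = FALSE) {
  N <- length(state$m)
  ratio <- state$m / state$m_star
  if (validate && N > 1) {
    rho <- spectral_radius(W)
    if (rho >= 1)
      stop("spectral radius of W is ", format(rho),
           " >= 1: steady-state stability assumption violated", call. = FALSE)
  }
  A <- Matrix::Diagonal(N) - W
  chi <- tryCatch(
    as.matrix(Matrix::solve(A, Matrix::Diagonal(x = ratio))),
    error = function(e) stop("(I - W) is numerically singular: ",
                             conditionMessage(e), call. = FALSE))
  if (min(chi) < -1e-8 * max(abs(chi)))
    stop("negative susceptibility entries: steady-state stability assumption ",
         "violated (spectral radius of W likely >= 1)", call. = FALSE)
  chi[chi < 0] <- 0
  dimnames(chi) <- NULL
  structure(list(chi = chi, W = W, chi_self = diag(chi)),
            class = "ceRNA_susceptibility")
}

spectral_radius <- function(W, n_iter = 200L, tol = 1e-10) {
  N <- nrow(W)
  if (N == 1L) return(abs(as.numeric(W[1, 1])))
  v <- rep(1 / sqrt(N), N)
  lambda <- 0
  for (k in seq_len(n_iter)) {
    v_new <- as.numeric(W %*% v)
    nrm <- sqrt(sum(v_new^2))
    if (nrm == 0) return(0)
    v_new <- v_new / nrm
    lambda_new <- as.numeric(crossprod(v_new, as.numeric(W %*% v_new)))
    if (abs(lambda_new - lambda) < tol * max(1, abs(lambda_new))) {
      lambda <- lambda_new; break
    }
    lambda <- lambda_new; v <- v_new
  }
  abs(lambda)
}

#' Finite-difference susceptibility oracle
#'
#' Direct numerical estimate of `chi_ij = d_j d[m_i]/d[b_j]` by central
#' differences: the steady state is re-solved at `b_j (1 +/- eps)` with a
#' tightened solver tolerance and the response read off as
#' `d_j (m_i^+ - m_i^-) / (2 b_j eps)`. Independent of the linear-response
#' matrix algebra, so it serves as a validation oracle for
#' [compute_susceptibility()].
#'
#' @param network A `ceRNA_network`.
#' @param params A [kinetic_params()].
#' @param j Index of the perturbed RNA species.
#' @param i Optional index (or vector of indices) of responding species;
#'   default all of them (the whole column chi_.j).
#' @param eps Relative perturbation of b_j (default 1e-4).
#' @param tol Solver tolerance for the two evaluations (default 1e-14, so
#'   truncation error dominates round-off).
#' @return Numeric vector of finite-difference susceptibilities, with
#'   attribute `noise_floor`: the scheme's absolute resolution limit for this
#'   column, `d * (10 * tol * max(m)) / (2 * b_j * eps)`. Entries below the
#'   floor are dominated by solver round-off in the difference and cannot be
#'   compared in relative terms.
#' @export
finite_difference_susceptibility <- function(network, params, j, i = NULL,
                                             eps = 1e-4, tol = 1e-14) {
  stopifnot(j >= 1, j <= length(params$b), eps > 0, eps < 1)
  perturb <- function(f) {
    p <- params
    p$b[j] <- params$b[j] * f
    solve_steady_state(network, p, tol = tol)$m
  }
  m_plus <- perturb(1 + eps)
  m_minus <- perturb(1 - eps)
  col <- params$d * (m_plus - m_minus) / (2 * params$b[j] * eps)
  out <- if (is.null(i)) col else col[i]
  attr(out, "noise_floor") <- params$d * (10 * tol * max(m_plus)) /
    (2 * params$b[j] * eps)
  out
}

#' Export a matrix in coordinate (i, j, value) text format
#'
#' Writes non-zero entries of a susceptibility or coupling matrix as
#' whitespace-separated triples, one per line, suitable for large sparse
#' outputs.
#'
#' @param mat A base or `Matrix` matrix.
#' @param path Destination file.
#' @param drop_below Entries with absolute value at or below this threshold
#'   are omitted (default 0: keep all stored non-zeros).
#' @export
write_matrix_coo <- function(mat, path, drop_below = 0) {
  m <- methods::as(methods::as(Matrix::Matrix(mat, sparse = TRUE),
                               "generalMatrix"), "TsparseMatrix")
  keep <- abs(m@x) > drop_below
  utils::write.table(
    data.frame(i = m@i[keep] + 1L, j = m@j[keep] + 1L, value = m@x[keep]),
    path, row.names = FALSE, col.names = TRUE, quote = FALSE, sep = "\t")
  invisible(path)
}
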