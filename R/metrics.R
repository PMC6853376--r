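off_diag <- function(chi) chi[row(chi) != col(chi)]

# ordered distinct pairs in fixed column-major order, as index matrix
ordered_pairs <- function(N) {
  idx <- which(row(diag(N)) != col(diag(N)))
  cbind(i = ((idx - 1) %% N) + 1, j = ((idx - 1) %/% N) + 1)
}

#' Crosstalk intensity statistics
#'
#' Means and maxima of the susceptibility matrix over ordered pairs of
#' distinct RNA species (cross terms) and over the diagonal (self terms).
#'
#' @param chi Susceptibility matrix (N x N, N >= 2) or a
#'   `ceRNA_susceptibility`.
#' @return Named numeric vector `mean_chi`, `max_chi`, `mean_self`,
#'   `max_self`.
#' @export
intensity_stats <- function(chi) {
  if (inherits(chi, "ceRNA_susceptibility")) chi <- chi$chi
  stopifnot(nrow(chi) >= 2)
  cross <- off_diag(chi)
  c(mean_chi = mean(cross), max_chi = max(cross),
    mean_self = mean(diag(chi)), max_self = max(diag(chi)))
}

#' Incoming and outgoing crosstalk selectivity
#'
#' Inverse-participation-ratio statistics of the susceptibility rows and
#' columns: `g_i = sum_{j != i} chi_ij^2 / (sum_{j != i} chi_ij)^2` measures
#' how concentrated the incoming regulation of RNA i is (1 = a single
#' partner, 1/(N-1) = uniform over all partners); `h_j` is the analogue over
#' columns (outgoing regulation). `S_in` and `S_out` average g and h over
#' rows/columns with a non-zero off-diagonal sum; rows or columns summing to
#' zero are undefined (0/0) and are excluded, with exclusion counts reported.
#'
#' @param chi Susceptibility matrix (N >= 2) or `ceRNA_susceptibility`.
#' @return List with `s_in`, `s_out`, vectors `g`, `h` (NA where undefined),
#'   and exclusion counts `n_excluded_in`, `n_excluded_out`. If every row
#'   (resp. column) is zero the corresponding selectivity is `NA` with a
#'   warning.
#' @export
selectivity <- function(chi) {
  if (inherits(chi, "ceRNA_susceptibility")) chi <- chi$chi
  N <- nrow(chi)
  stopifnot(N >= 2)
  chi0 <- chi; diag(chi0) <- 0
  rs <- rowSums(chi0); rs2 <- rowSums(chi0^2)
  cs <- colSums(chi0); cs2 <- colSums(chi0^2)
  g <- ifelse(rs > 0, rs2 / rs^2, NA_real_)
  h <- ifelse(cs > 0, cs2 / cs^2, NA_real_)
  if (all(is.na(g)) || all(is.na(h)))
    warning("all off-diagonal susceptibilities are zero: selectivity undefined")
  list(s_in = if (all(is.na(g))) NA_real_ else mean(g, na.rm = TRUE),
       s_out = if (all(is.na(h))) NA_real_ else mean(h, na.rm = TRUE),
       g = g, h = h,
       n_excluded_in = sum(is.na(g)), n_excluded_out = sum(is.na(h)))
}

#' Locality kernel of co-regulation
#'
#' `K_ij = (1/M) sum_a 1/(mu0_ia * mu0_ja)`, summing over miRNAs targeting
#' both i and j. K is symmetric and vanishes exactly for RNA pairs with no
#' shared regulator, so it encodes the crosstalk potential carried by the
#' local interaction structure alone.
#'
#' @param network A `ceRNA_network`.
#' @param params A [kinetic_params()] (per-edge mu0 assigned).
#' @return Sparse symmetric N x N `Matrix`.
#' @export
locality_matrix <- function(network, params) {
  mats <- edge_matrices(network, params)
  K <- Matrix::tcrossprod(mats$inv_mu0) / n_mirna(network)
  methods::as(K, "CsparseMatrix")
}

#' Correlation between susceptibility and the locality kernel
#'
#' Pearson correlation over all ordered distinct pairs (zeros included)
#' between chi_ij and K_ij. Values near 1 indicate crosstalk confined to
#' co-regulated pairs; small values indicate non-local crosstalk mediated by
#' chains of interactions. The true Pearson coefficient in [-1, 1] is
#' returned (it is positive in practice for this model but not by
#' construction).
#'
#' @param chi Susceptibility matrix or `ceRNA_susceptibility`.
#' @param K Locality kernel from [locality_matrix()].
#' @return Scalar correlation, or `NA` with a warning when either argument
#'   has zero variance over pairs.
#' @export
locality_correlation <- function(chi, K) {
  if (inherits(chi, "ceRNA_susceptibility")) chi <- chi$chi
  K <- as.matrix(K)
  stopifnot(all(dim(chi) == dim(K)), nrow(chi) >= 2)
  x <- off_diag(chi); y <- off_diag(K)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("zero variance over pairs: locality correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Crosstalk asymmetry index
#'
#' Susceptibilities are directional (chi_ij != chi_ji in general). The index
#' averages the relative difference `|chi_ij - chi_ji| / (chi_ij + chi_ji)`
#' over unordered pairs whose total susceptibility exceeds `floor`, yielding a
#' value in [0, 1]: 0 for a symmetric pattern, 1 when every active pair is
#' fully one-directional. The default floor excludes numerically-zero pairs.
#'
#' @param chi Susceptibility matrix or `ceRNA_susceptibility`.
#' @param floor Pairs with chi_ij + chi_ji <= floor are excluded; default
#'   `1e-8 * max` off-diagonal susceptibility.
#' @return Scalar in [0, 1], or `NA` with a warning if no pair is above the
#'   floor.
#' @export
asymmetry_index <- function(chi, floor = NULL) {
  if (inherits(chi, "ceRNA_susceptibility")) chi <- chi$chi
  N <- nrow(chi)
  stopifnot(N >= 2)
  up <- upper.tri(chi)
  s <- chi[up] + t(chi)[up]
  d <- abs(chi[up] - t(chi)[up])
  if (is.null(floor)) floor <- 1e-8 * max(s, 0)
  keep <- s > floor
  if (!any(keep)) {
    warning("no RNA pair above the asymmetry floor: index undefined")
    return(NA_real_)
  }
  mean(d[keep] / s[keep])
}

#' Coefficient of variation of RNA expression levels
#'
#' Sample CV (standard deviation over mean) of the free RNA levels across
#' species for a single realization; ensemble averaging over
#' transcription-rate draws is done by [run_condition()].
#'
#' @param state A `ceRNA_steady_state`, or a numeric vector of levels.
#' @return Scalar CV.
#' @export
expression_cv <- function(state) {
  m <- if (inherits(state, "ceRNA_steady_state")) state$m else as.numeric(state)
  stopifnot(length(m) >= 2)
  stats::sd(m) / mean(m)
}

#' Persistence of crosstalk ranking across heterogeneity levels
#'
#' Ranks ordered distinct RNA pairs by realization-averaged susceptibility in
#' two conditions (e.g. low and high transcriptional heterogeneity), splits
#' each ranking into `n_bins` equal-size bins (sizes differing by at most 1;
#' ties broken by fixed pair order), and reports the fraction of each
#' low-condition bin that remains in the same bin in the high condition. A
#' chance baseline is estimated by seeded random rank permutations.
#'
#' @param chi_low,chi_high Susceptibility matrices (or per-pair vectors over
#'   the same ordered pair set, in matching order).
#' @param n_bins Number of rank bins (default 6, i.e. sextiles).
#' @param n_perm Number of rank permutations for the chance baseline.
#' @param seed Seed for the permutation baseline.
#' @return List with `fractions` (per-bin conserved fraction, bin 1 = highest
#'   susceptibilities), `overall`, `chance` (per-bin permutation means) and
#'   `bin_sizes`.
#' @export
sextile_persistence <- function(chi_low, chi_high, n_bins = 6L,
                                n_perm = 1000L, seed = NULL) {
  as_pairs <- function(x) {
    if (inherits(x, "ceRNA_susceptibility")) x <- x$chi
    if (is.matrix(x)) off_diag(x) else as.numeric(x)
  }
  x <- as_pairs(chi_low); y <- as_pairs(chi_high)
  if (length(x) != length(y))
    stop("pair sets of the two conditions do not match", call. = FALSE)
  n <- length(x)
  if (n < n_bins) stop("fewer pairs than bins", call. = FALSE)

  # bin 1 holds the largest values; ties broken by stable pair index
  bin_of <- function(v) {
    r <- integer(n)
    r[order(-v, seq_len(n))] <- seq_len(n)
    sizes <- rep(n %/% n_bins, n_bins)
    extra <- n %% n_bins
    if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    rep(seq_len(n_bins), times = sizes)[r]
  }
  b_low <- bin_of(x); b_high <- bin_of(y)
  sizes <- tabulate(b_low, n_bins)
  fractions <- vapply(seq_len(n_bins), function(k)
    sum(b_low == k & b_high == k) / sizes[k], numeric(1))

  chance <- with_seed(seed, {
    acc <- matrix(0, n_perm, n_bins)
    for (p in seq_len(n_perm)) {
      bp <- b_high[sample.int(n)]
      acc[p, ] <- vapply(seq_len(n_bins), function(k)
        sum(b_low == k & bp == k) / sizes[k], numeric(1))
    }
    colMeans(acc)
  })

  list(fractions = fractions, overall = sum(b_low == b_high) / n,
       chance = chance, bin_sizes = sizes)
}

#' Susceptible region of a mean-susceptibility sweep
#'
#' Operational definition of the miRNA-transcription window where crosstalk is
#' appreciable: the smallest and largest grid values of the mean miRNA
#' transcription rate at which the mean susceptibility reaches at least
#' `frac` of its peak.
#'
#' @param beta_grid Increasing grid of mean miRNA transcription rates.
#' @param mean_chi Mean susceptibility at each grid point.
#' @param frac Fraction of the peak delimiting the region (default 0.05).
#' @return Named numeric vector `c(beta_low, beta_high)`, or `NA`s with a
#'   warning if the curve is identically zero.
#' @export
susceptible_region <- function(beta_grid, mean_chi, frac = 0.05) {
  stopifnot(length(beta_grid) == length(mean_chi), length(beta_grid) >= 3)
  peak <- max(mean_chi)
  if (peak <= 0) {
    warning("mean susceptibility identically zero: susceptible region undefined")
    return(c(beta_low = NA_real_, beta_high = NA_real_))
  }
  inside <- which(mean_chi >= frac * peak)
  c(beta_low = beta_grid[min(inside)], beta_high = beta_grid[max(inside)])
}
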