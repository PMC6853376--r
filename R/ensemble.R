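# one TH replicate: draw rates, fit, return the scalar descriptor row
replicate_metrics <- function(network, b_mean, beta_mean, cv_tr, bh, rep_seed,
                              d, delta, lam, mu0_base, tol) {
  N <- n_rna(network); M <- n_mirna(network)
  rates <- with_seed(rep_seed, {
    list(b = sample_transcription_rates(N, b_mean, cv_tr),
         beta = sample_transcription_rates(M, beta_mean, cv_tr))
  })
  params <- kinetic_params(network, b = rates$b, beta = rates$beta,
                           d = d, delta = delta, lam = lam,
                           mu0_base = mu0_base, bh = bh)
  fit <- crosstalk_fit(network, params, tol = tol)
  st <- intensity_stats(fit$chi)
  sel <- suppressWarnings(selectivity(fit$chi))
  K <- locality_matrix(network, params)
  ab <- relative_abundance(fit$state)
  data.frame(
    mean_chi = st[["mean_chi"]], max_chi = st[["max_chi"]],
    mean_self = st[["mean_self"]], max_self = st[["max_self"]],
    s_in = sel$s_in, s_out = sel$s_out,
    rho = suppressWarnings(locality_correlation(fit$chi, K)),
    asymmetry = suppressWarnings(asymmetry_index(fit$chi)),
    cv_expression = expression_cv(fit$state),
    rna_fraction = ab[["rna_fraction"]],
    mirna_fraction = ab[["mirna_fraction"]]
  )
}

#' Run one ensemble condition
#'
#' For a fixed network, BH scenario, mean transcription rates and degree of
#' transcriptional heterogeneity, draws `n_reps` independent lognormal
#' realizations of the rate vectors (replicate r uses seed `seed + r - 1`),
#' solves the model for each and aggregates every scalar crosstalk descriptor
#' into ensemble means and standard errors.
#'
#' @param network A `ceRNA_network`.
#' @param b_mean Mean RNA transcription rate (molecules/h, default 8).
#' @param beta_mean Mean miRNA transcription rate (molecules/h).
#' @param cv_tr Coefficient of variation of transcription rates across
#'   species (same for RNAs and miRNAs).
#' @param bh A [bh_scenario()].
#' @param n_reps Number of TH realizations.
#' @param seed Base integer seed for the condition.
#' @param d,delta,lam,mu0_base Kinetic constants (Table-level defaults).
#' @param tol Solver tolerance.
#' @param aggregate If `FALSE`, return only the per-replicate rows.
#' @return Data frame with one row per replicate plus (when `aggregate`)
#'   rows `"mean"` and `"sem"`; replicate seeds in attribute `seeds`,
#'   failed-replicate count in attribute `n_failed`. With `n_reps = 1` the
#'   SEM row is `NA`.
#' @export
run_condition <- function(network, b_mean = 8, beta_mean, cv_tr,
                          bh = bh_scenario("high"), n_reps = 100L, seed = 1L,
                          d = 0.08, delta = 0.027, lam = 0.2, mu0_base = 4,
                          tol = 1e-12, aggregate = TRUE) {
  stopifnot(n_reps >= 1, beta_mean >= 0, cv_tr >= 0)
  seeds <- as.integer(seed + seq_len(n_reps) - 1L)
  rows <- vector("list", n_reps)
  failed <- integer(0)
  for (r in seq_len(n_reps)) {
    rows[[r]] <- tryCatch(
      replicate_metrics(network, b_mean, beta_mean, cv_tr, bh, seeds[r],
                        d, delta, lam, mu0_base, tol),
      error = function(e) {
        warning("replicate ", r, " (seed ", seeds[r], ") failed: ",
                conditionMessage(e))
        NULL
      })
    if (is.null(rows[[r]])) failed <- c(failed, r)
  }
  ok <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(ok)) stop("all replicates failed", call. = FALSE)
  reps <- do.call(rbind, ok)
  reps$replicate <- as.character(setdiff(seq_len(n_reps), failed))

  out <- reps
  if (aggregate) {
    num <- setdiff(names(reps), "replicate")
    mu <- vapply(reps[num], function(v) mean(v, na.rm = TRUE), numeric(1))
    sem <- if (nrow(reps) > 1) {
      vapply(reps[num], function(v)
        stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))), numeric(1))
    } else stats::setNames(rep(NA_real_, length(num)), num)
    agg <- rbind(as.data.frame(as.list(mu)), as.data.frame(as.list(sem)))
    agg$replicate <- c("mean", "sem")
    out <- rbind(reps, agg)
  }
  attr(out, "seeds") <- seeds
  attr(out, "n_failed") <- length(failed)
  attr(out, "condition") <- list(b_mean = b_mean, beta_mean = beta_mean,
                                 cv_tr = cv_tr, bh = bh$level,
                                 n_reps = n_reps, seed = seed)
  out
}

#' Sweep the mean miRNA transcription rate
#'
#' Runs [run_condition()] over a grid of mean miRNA transcription rates
#' (condition k uses base seed `seed + 1000 * (k - 1)`) and collects the
#' ensemble means and SEMs into one table; the susceptible region is
#' extracted from the mean-susceptibility column.
#'
#' @param network A `ceRNA_network`.
#' @param beta_grid Increasing positive grid of mean miRNA transcription
#'   rates; default 25 log-spaced points from 0.1 to 1e4 molecules/h.
#' @param cv_tr Transcriptional heterogeneity level.
#' @param bh A [bh_scenario()].
#' @param n_reps Realizations per grid point.
#' @param seed Base seed.
#' @param ... Forwarded to [run_condition()].
#' @return Data frame of class `ceRNA_sweep`: one row per grid point with the
#'   ensemble mean of every descriptor plus `<name>_sem` columns; attributes
#'   `susceptible_region` and `condition`.
#' @export
sweep_beta <- function(network,
                       beta_grid = 10^seq(-1, 4, length.out = 25),
                       cv_tr = 0.4, bh = bh_scenario("high"),
                       n_reps = 100L, seed = 1L, ...) {
  stopifnot(all(beta_grid > 0), !is.unsorted(beta_grid))
  rows <- vector("list", length(beta_grid))
  for (k in seq_along(beta_grid)) {
    cond <- run_condition(network, beta_mean = beta_grid[k], cv_tr = cv_tr,
                          bh = bh, n_reps = n_reps,
                          seed = seed + 1000L * (k - 1L), ...)
    mu <- cond[cond$replicate == "mean", setdiff(names(cond), "replicate")]
    sem <- cond[cond$replicate == "sem", setdiff(names(cond), "replicate")]
    names(sem) <- paste0(names(sem), "_sem")
    rows[[k]] <- cbind(data.frame(beta_mean = beta_grid[k]), mu, sem)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "susceptible_region") <-
    suppressWarnings(susceptible_region(beta_grid, out$mean_chi))
  attr(out, "condition") <- list(cv_tr = cv_tr, bh = bh$level,
                                 n_reps = n_reps, seed = seed)
  class(out) <- c("ceRNA_sweep", "data.frame")
  out
}

#' @export
plot.ceRNA_sweep <- function(x, y = "mean_chi", ...) {
  plot(x$beta_mean, x[[y]], log = "x", type = "b",
       xlab = "mean miRNA transcription rate (molecules/h)", ylab = y, ...)
  reg <- attr(x, "susceptible_region")
  if (!anyNA(reg)) graphics::abline(v = reg, lty = 3)
  invisible(x)
}

#' Load an interactome edge list (alias of [read_interactome()])
#'
#' @inheritParams read_interactome
#' @export
load_interactome <- function(path, quiet = FALSE) read_interactome(path, quiet)

#' Export sweep tables and a reproducibility manifest
#'
#' Writes each table in `tables` as a tidy CSV named `<name>.csv` under
#' `out_dir`, together with `manifest.json` recording the conditions, seeds,
#' package version and any dropped-record counts. File contents are
#' deterministic for a given input.
#'
#' @param tables Named list of data frames (e.g. [sweep_beta()] outputs).
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the vector of written file paths.
#' @export
export_results <- function(tables, out_dir) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  manifest <- list(package = "ceRNAcross",
                   version = as.character(utils::packageVersion("ceRNAcross")),
                   tables = list())
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(as.data.frame(tables[[nm]]), p, row.names = FALSE)
    paths <- c(paths, p)
    manifest$tables[[nm]] <- list(
      file = basename(p),
      condition = attr(tables[[nm]], "condition"),
      seeds = attr(tables[[nm]], "seeds"),
      n_failed = attr(tables[[nm]], "n_failed"),
      susceptible_region = attr(tables[[nm]], "susceptible_region")
    )
  }
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(paths, mp))
}
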