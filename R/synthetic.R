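# run code under a local RNG seed, restoring global RNG state afterwards
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Sample i.i.d. lognormal transcription rates
#'
#' Draws rates whose population mean and coefficient of variation equal the
#' requested values exactly, via the log-scale parameterization
#' s^2 = log(1 + cv^2), location = log(mean) - s^2/2. With `cv = 0` the
#' constant vector is returned.
#'
#' @param n Number of species.
#' @param mean Population mean rate, molecules/h (> 0).
#' @param cv Population coefficient of variation (>= 0).
#' @param seed Optional integer seed; the draw is a pure function of
#'   (n, mean, cv, seed).
#' @return Numeric vector of length `n`.
#' @export
sample_transcription_rates <- function(n, mean, cv, seed = NULL) {
  if (mean <= 0) stop("mean transcription rate must be positive", call. = FALSE)
  if (cv < 0) stop("cv must be non-negative", call. = FALSE)
  if (cv == 0) return(rep(mean, n))
  s2 <- log(1 + cv^2)
  with_seed(seed, stats::rlnorm(n, meanlog = log(mean) - s2 / 2,
                                sdlog = sqrt(s2)))
}

#' Generate a CLASH-like synthetic interactome
#'
#' Bipartite configuration-style sampling: each side receives node propensities
#' drawn from a truncated discrete power law (exponent `degree_exponent`,
#' support 1..`n_edges`), and edges are sampled proportionally to propensity
#' products, rejecting duplicate pairs, until exactly `n_edges` unique edges
#' exist. This reproduces the heavy-tailed degree distributions of measured
#' miRNA interactomes without matching any particular degree sequence. Binding
#' modes are i.i.d. from `mode_freqs`; the default puts 77% of edges in the
#' non-canonical `seed-nc` class, mirroring the CLASH composition.
#'
#' Nodes left with degree zero by the sampling are retained; they decouple in
#' the titration model (their cross-susceptibilities vanish).
#'
#' @param n_rna,n_mirna Numbers of RNA and miRNA species.
#' @param n_edges Number of unique edges (<= n_rna * n_mirna).
#' @param mode_freqs Length-4 probability vector over
#'   (kmer, seed-nc, noseed-9nt, noseed); must sum to 1.
#' @param degree_exponent Power-law exponent of the propensity distribution
#'   (default 2.2).
#' @param seed Optional integer seed (bit-reproducible generation).
#' @return A `ceRNA_network`.
#' @export
generate_network <- function(n_rna, n_mirna, n_edges,
                             mode_freqs = c(0.08, 0.77, 0.05, 0.10),
                             degree_exponent = 2.2, seed = NULL) {
  if (n_edges > n_rna * n_mirna)
    stop("n_edges exceeds the number of possible pairs", call. = FALSE)
  if (length(mode_freqs) != 4L || any(mode_freqs < 0) ||
      abs(sum(mode_freqs) - 1) > 1e-8)
    stop("mode_freqs must be a length-4 probability vector", call. = FALSE)

  with_seed(seed, {
    rpl <- function(n) {  # truncated discrete power-law propensities
      k <- seq_len(max(2L, min(n_edges, 10000L)))
      sample(k, n, replace = TRUE, prob = k^(-degree_exponent))
    }
    w_rna <- rpl(n_rna)
    w_mirna <- rpl(n_mirna)

    seen <- new.env(hash = TRUE, size = 2L * n_edges)
    ri <- integer(n_edges); mi <- integer(n_edges)
    got <- 0L
    while (got < n_edges) {
      need <- n_edges - got
      batch <- max(2L * need, 64L)
      cand_r <- sample.int(n_rna, batch, replace = TRUE, prob = w_rna)
      cand_m <- sample.int(n_mirna, batch, replace = TRUE, prob = w_mirna)
      for (t in seq_len(batch)) {
        key <- as.character((cand_m[t] - 1) * n_rna + cand_r[t])
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          got <- got + 1L
          ri[got] <- cand_r[t]; mi[got] <- cand_m[t]
          if (got == n_edges) break
        }
      }
      # dense regime: duplicate rejection can stall near saturation; fill the
      # remainder uniformly from the complement
      if (got < n_edges && got >= 0.95 * n_rna * n_mirna) {
        all_keys <- seq_len(n_rna * n_mirna)
        used <- as.integer(ls(seen))
        rest <- setdiff(all_keys, used)
        fill <- sample(rest, n_edges - got)
        ri[(got + 1L):n_edges] <- ((fill - 1L) %% n_rna) + 1L
        mi[(got + 1L):n_edges] <- ((fill - 1L) %/% n_rna) + 1L
        got <- n_edges
      }
    }
    mode <- sample(binding_modes(), n_edges, replace = TRUE, prob = mode_freqs)

    interaction_network(
      sprintf("RNA%04d", seq_len(n_rna)),
      sprintf("miR%03d", seq_len(n_mirna)),
      data.frame(rna = ri, mirna = mi, mode = mode, stringsAsFactors = FALSE)
    )
  })
}

#' Closed-form test motifs
#'
#' Small networks with analytically tractable crosstalk structure:
#' \describe{
#'   \item{single_pair}{one RNA repressed by one miRNA (scalar quadratic
#'     steady state);}
#'   \item{v_motif}{two RNAs co-targeted by one miRNA (direct competition);}
#'   \item{chain}{RNA1--miRa--RNA2--miRb--RNA3: RNA1 and RNA3 share no miRNA,
#'     so their locality kernel vanishes, yet crosstalk propagates through the
#'     chain at intermediate miRNA transcription.}
#' }
#'
#' @param name Motif name.
#' @param beta Mean miRNA transcription rate used for the default parameters
#'   (molecules/h); 30 places the motifs inside the susceptible regime.
#' @return List with elements `network` (a `ceRNA_network`) and `params`
#'   (default [kinetic_params()] at the reference kinetic constants).
#' @export
make_motif <- function(name = c("single_pair", "v_motif", "chain"), beta = 30) {
  name <- match.arg(name)
  net <- switch(name,
    single_pair = interaction_network(
      "RNA1", "miRa",
      data.frame(rna = 1L, mirna = 1L, mode = "kmer")),
    v_motif = interaction_network(
      c("RNA1", "RNA2"), "miRa",
      data.frame(rna = 1:2, mirna = c(1L, 1L), mode = c("kmer", "kmer"))),
    chain = interaction_network(
      c("RNA1", "RNA2", "RNA3"), c("miRa", "miRb"),
      data.frame(rna = c(1L, 2L, 2L, 3L), mirna = c(1L, 1L, 2L, 2L),
                 mode = rep("kmer", 4)))
  )
  list(network = net, params = kinetic_params(net, b = 8, beta = beta))
}

#' Write transcription rates as a two-column CSV
#'
#' @param ids Species identifiers.
#' @param rates Numeric rates, molecules/h.
#' @param path Destination file.
#' @export
write_rates <- function(ids, rates, path) {
  utils::write.csv(data.frame(species_id = ids, rate = rates),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
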