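# shared fixture builders; everything is generated in code, seeded

random_test_network <- function(n_rna, n_mirna, n_edges, seed) {
  generate_network(n_rna, n_mirna, n_edges, seed = seed)
}

# a network with every RNA and miRNA connected (the loader's convention)
pruned_test_network <- function(n_rna, n_mirna, n_edges, seed) {
  subnetwork_by_modes(generate_network(n_rna, n_mirna, n_edges, seed = seed),
                      binding_modes())
}

table1_params <- function(network, b = 8, beta = 30,
                          bh = bh_scenario("low")) {
  kinetic_params(network, b = b, beta = beta, bh = bh)
}

# continuous peak location: log-parabola through the argmax and neighbours
interp_peak <- function(x, y) {
  k <- which.max(y)
  if (k == 1L || k == length(x)) return(x[k])
  lx <- log(x[(k - 1):(k + 1)]); ly <- log(pmax(y[(k - 1):(k + 1)], 1e-300))
  co <- stats::coef(stats::lm(ly ~ lx + I(lx^2)))
  if (co[3] >= 0) return(x[k])
  exp(-co[2] / (2 * co[3]))
}

# write a small edge-list TSV and return its path
write_fixture_tsv <- function(lines, dir = tempdir()) {
  path <- tempfile("edges", tmpdir = dir, fileext = ".tsv")
  writeLines(c("rna_id\tmirna_id\tbinding_mode", lines), path)
  path
}

ensemble_mean_chi <- function(network, betas, n_reps = 6, seed = 1,
                              cv_tr = 0.4) {
  vapply(betas, function(bb) {
    r <- run_condition(network, beta_mean = bb, cv_tr = cv_tr,
                       bh = bh_scenario("high"), n_reps = n_reps, seed = seed)
    r$mean_chi[r$replicate == "mean"]
  }, numeric(1))
}
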