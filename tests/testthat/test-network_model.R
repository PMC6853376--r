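test_that("BH scenarios map binding modes to the documented thresholds", {
  net <- interaction_network(
    c("r1", "r2", "r3", "r4"), "m1",
    data.frame(rna = 1:4, mirna = 1L,
               mode = c("kmer", "seed-nc", "noseed-9nt", "noseed")))

  expect_equal(assign_binding_strengths(net, bh_scenario("low"), 4),
               rep(8, 4))
  expect_equal(assign_binding_strengths(net, bh_scenario("medium"), 4),
               c(4, 8, 8, 8))
  expect_equal(assign_binding_strengths(net, bh_scenario("high"), 4),
               c(4, 8, 16, 32))

  # idempotent and independent of edge order
  perm <- c(3L, 1L, 4L, 2L)
  net2 <- interaction_network(net$rna_ids, net$mirna_ids,
                              net$edges[perm, ])
  expect_equal(assign_binding_strengths(net2, bh_scenario("high"), 4),
               c(4, 8, 16, 32)[perm])
  expect_identical(assign_binding_strengths(net, bh_scenario("high"), 4),
                   assign_binding_strengths(net, bh_scenario("high"), 4))

  # ladder ordering is configurable
  alt <- bh_scenario("high", multipliers = c(
    "kmer" = 1, "seed-nc" = 2, "noseed-9nt" = 8, "noseed" = 4))
  expect_equal(assign_binding_strengths(net, alt, 4), c(4, 8, 32, 16))
})

test_that("threshold tying reproduces the reference ratio and symmetry case", {
  expect_equal(compute_m0(8, d = 0.08, delta = 0.027, lam = 0.2), 13.5)
  # mu0/m0 = lam*d/delta, independent of mu0, ~0.59 at reference constants
  for (mu0 in c(4, 8, 32)) {
    expect_equal(mu0 / compute_m0(mu0, 0.08, 0.027, 0.2), 0.2 * 0.08 / 0.027)
  }
  expect_equal(round(4 / compute_m0(4, 0.08, 0.027, 0.2), 2), 0.59)
  expect_equal(compute_m0(5, d = 0.05, delta = 0.05, lam = 1), 5)
  expect_error(compute_m0(-1), "positive")
})

test_that("derived rate constants invert the threshold definitions exactly", {
  rc <- derive_rate_constants(4, d = 0.08, lam = 0.2, complex_decay_total = 1)
  expect_equal(rc$k_on, 0.02)
  expect_identical(rc$k_off, 0)
  expect_equal(rc$sigma + rc$kappa, 1)
  expect_equal(rc$sigma / (rc$sigma + rc$kappa), 0.2)
  expect_equal(derive_rate_constants(8, d = 0.08)$k_on, 0.01)

  # round-trip: substituting back gives mu0 = d/k_on (1 + k_off/(sigma+kappa))
  # and m0 = delta/k_on (1 + (k_off+kappa)/sigma)
  for (mu0 in c(2, 4, 16)) {
    rc <- derive_rate_constants(mu0, d = 0.08, lam = 0.2)
    mu0_back <- (0.08 / rc$k_on) * (1 + rc$k_off / (rc$sigma + rc$kappa))
    m0_back <- (0.027 / rc$k_on) * (1 + (rc$k_off + rc$kappa) / rc$sigma)
    expect_equal(mu0_back, mu0)
    expect_equal(m0_back, compute_m0(mu0, 0.08, 0.027, 0.2))
  }
})

test_that("kinetic_params ties m0 to mu0 on every edge in all BH scenarios", {
  net <- random_test_network(15, 4, 30, seed = 5)
  for (lev in c("low", "medium", "high")) {
    p <- kinetic_params(net, b = 8, beta = 30, bh = bh_scenario(lev))
    expect_equal(p$mu0_edge / p$m0_edge,
                 rep(p$lam * p$d / p$delta, nrow(net$edges)))
    expect_true(all(p$mu0_edge > 0))
  }
  expect_error(
    assign_binding_strengths(
      structure(list(rna_ids = "r", mirna_ids = "m",
                     edges = data.frame(rna = 1L, mirna = 1L, mode = "bogus")),
                class = "ceRNA_network"),
      bh_scenario("low")),
    "unknown binding mode")
})

test_that("network construction enforces bipartite invariants", {
  expect_error(interaction_network(character(0), "m1",
                                   data.frame(rna = integer(0),
                                              mirna = integer(0),
                                              mode = character(0))),
               "at least one")
  expect_error(interaction_network(
    c("r1", "r2"), "m1",
    data.frame(rna = c(1L, 1L), mirna = c(1L, 1L),
               mode = c("kmer", "noseed"))), "duplicate")
  expect_error(interaction_network(
    "r1", "m1", data.frame(rna = 2L, mirna = 1L, mode = "kmer")),
    "outside")
})

test_that("edge-list TSV round-trips and collapses duplicates to strongest mode", {
  net <- random_test_network(12, 4, 20, seed = 9)
  path <- tempfile(fileext = ".tsv")
  write_interactome(net, path, comment = "fixture")
  back <- read_interactome(path)
  expect_equal(length(back$rna_ids), length(unique(net$edges$rna)))
  expect_equal(nrow(back$edges), nrow(net$edges))
  # same edge set under id matching
  key <- function(n) sort(paste(n$rna_ids[n$edges$rna],
                                n$mirna_ids[n$edges$mirna], n$edges$mode))
  expect_identical(key(back), key(net))

  dup <- write_fixture_tsv(c("g1\tmA\tnoseed",
                             "g1\tmA\tkmer",
                             "g2\tmA\tseed-nc"))
  parsed <- suppressMessages(read_interactome(dup))
  expect_equal(nrow(parsed$edges), 2L)
  expect_equal(attr(parsed, "n_duplicates_dropped"), 1L)
  # strongest (lowest multiplier) mode kept
  e <- parsed$edges
  expect_equal(e$mode[parsed$rna_ids[e$rna] == "g1"], "kmer")

  expect_error(read_interactome(write_fixture_tsv("g1\t\tkmer")), "malformed")
  expect_error(read_interactome(write_fixture_tsv("g1\tmA\twobble")),
               "unknown binding mode")
})

test_that("mode subnetworks nest and can restrict to the largest component", {
  net <- interaction_network(
    paste0("r", 1:5), paste0("m", 1:3),
    data.frame(rna = c(1L, 2L, 2L, 3L, 4L, 5L),
               mirna = c(1L, 1L, 2L, 2L, 3L, 3L),
               mode = c("kmer", "kmer", "kmer", "seed-nc",
                        "noseed", "noseed")))
  sub_k <- subnetwork_by_modes(net, "kmer")
  expect_equal(nrow(sub_k$edges), 3L)
  expect_equal(length(sub_k$rna_ids), 2L)  # isolated nodes pruned

  sizes <- vapply(list("kmer", c("kmer", "seed-nc"),
                       c("kmer", "seed-nc", "noseed-9nt"),
                       binding_modes()),
                  function(m) nrow(subnetwork_by_modes(net, m)$edges),
                  numeric(1))
  expect_true(all(diff(sizes) >= 0))
  expect_equal(sizes[4], 6)

  # two components in the kmer+noseed graph; largest has 4 edges... pick it
  sub <- subnetwork_by_modes(net, c("kmer", "noseed"),
                             largest_component = TRUE)
  expect_equal(nrow(sub$edges), 3L)
  expect_error(subnetwork_by_modes(net, "noseed-9nt"), "no edges")
})

test_that("kinetic config JSON reader applies defaults", {
  path <- tempfile(fileext = ".json")
  writeLines('{"lam": 0.5, "mu0": 2}', path)
  cfg <- read_kinetic_config(path)
  expect_equal(cfg$lam, 0.5)
  expect_equal(cfg$mu0, 2)
  expect_equal(cfg$d, 0.08)
  expect_equal(cfg$b_mean, 8)
})
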