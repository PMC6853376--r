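#' Uniform topology randomization
#'
#' Re-assigns every edge slot to a (rna, mirna) pair drawn uniformly among all
#' pairs, rejecting collisions, so the randomized network keeps the node sets,
#' the edge count and the multiset of binding modes (modes travel with the
#' edge slots) while destroying degree sequences and all higher-order
#' topological correlations. Nodes isolated by the rewiring are retained:
#' they simply decouple in the titration model.
#'
#' @param network A `ceRNA_network`.
#' @param seed Optional integer seed (deterministic rewiring).
#' @return A rewired `ceRNA_network`.
#' @export
rewire_uniform <- function(network, seed = NULL) {
  N <- n_rna(network); M <- n_mirna(network)
  E <- nrow(network$edges)
  if (E > N * M) stop("edge count exceeds possible pairs", call. = FALSE)
  with_seed(seed, {
    # sequential uniform placement with collision redraw == uniform sample of
    # E distinct pairs
    slots <- sample.int(N * M, E)
    interaction_network(
      network$rna_ids, network$mirna_ids,
      data.frame(rna = ((slots - 1L) %% N) + 1L,
                 mirna = ((slots - 1L) %/% N) + 1L,
                 mode = network$edges$mode, stringsAsFactors = FALSE)
    )
  })
}

#' Degree-preserving edge-swap randomization
#'
#' Repeatedly picks two edges (a1--i1) and (a2--i2) and exchanges their RNA
#' endpoints, giving (a1--i2) and (a2--i1); swaps creating a duplicate pair
#' (or involving a repeated endpoint) are rejected. Each rewired edge
#' inherits the binding mode of the edge that contributed its miRNA endpoint,
#' so the mode multiset and both degree sequences are preserved exactly while
#' degree-degree correlations are destroyed.
#'
#' @param network A `ceRNA_network` with at least 2 edges.
#' @param n_accepted_swaps Number of accepted swaps to perform (default 10x
#'   the edge count).
#' @param seed Optional integer seed.
#' @param max_attempts Attempt budget (default 100x the edge count); if
#'   exhausted first, a warning reports the accepted count and the partially
#'   randomized network is returned.
#' @return A rewired `ceRNA_network` with attribute `n_swaps_accepted`.
#' @export
rewire_degree_preserving <- function(network,
                                     n_accepted_swaps = 10L * nrow(network$edges),
                                     seed = NULL,
                                     max_attempts = 100L * nrow(network$edges)) {
  E <- nrow(network$edges)
  if (E < 2L) stop("need at least 2 edges to swap", call. = FALSE)
  N <- n_rna(network); M <- n_mirna(network)
  rna <- network$edges$rna
  mir <- network$edges$mirna
  occupied <- logical(N * M)
  occupied[(mir - 1L) * N + rna] <- TRUE

  accepted <- 0L
  with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      if (accepted >= n_accepted_swaps) break
      pick <- sample.int(E, 2L)
      e1 <- pick[1L]; e2 <- pick[2L]
      i1 <- rna[e1]; a1 <- mir[e1]
      i2 <- rna[e2]; a2 <- mir[e2]
      if (i1 == i2 || a1 == a2) next
      k_new1 <- (a1 - 1L) * N + i2
      k_new2 <- (a2 - 1L) * N + i1
      if (occupied[k_new1] || occupied[k_new2]) next
      occupied[(a1 - 1L) * N + i1] <- FALSE
      occupied[(a2 - 1L) * N + i2] <- FALSE
      occupied[k_new1] <- TRUE
      occupied[k_new2] <- TRUE
      rna[e1] <- i2   # edge e1 keeps miRNA a1 and its mode
      rna[e2] <- i1
      accepted <- accepted + 1L
    }
  })
  if (accepted < n_accepted_swaps)
    warning("accepted only ", accepted, " of ", n_accepted_swaps,
            " requested swaps within the attempt budget")
  out <- interaction_network(
    network$rna_ids, network$mirna_ids,
    data.frame(rna = rna, mirna = mir, mode = network$edges$mode,
               stringsAsFactors = FALSE))
  attr(out, "n_swaps_accepted") <- accepted
  out
}
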