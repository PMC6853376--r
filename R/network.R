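#' Admissible miRNA-RNA binding modes
#'
#' The four interaction classes annotated in CLASH-style interactomes, ordered
#' from strongest to weakest coupling: perfect seed pairing over k nucleotides
#' (`kmer`, k = 6--9 pooled), non-canonical seed pairing with up to one
#' mismatch or bulge (`seed-nc`), a 9-nt non-seed stem (`noseed-9nt`), and
#' distributed weak non-seed pairing (`noseed`).
#'
#' @return Character vector of the four mode labels.
#' @export
binding_modes <- function() {
  c("kmer", "seed-nc", "noseed-9nt", "noseed")
}

# accept underscore spellings from code while TSV files use hyphens
normalize_mode <- function(mode) {
  m <- gsub("_", "-", as.character(mode))
  bad <- !(m %in% binding_modes())
  if (any(bad)) {
    stop("unknown binding mode(s): ", paste(unique(m[bad]), collapse = ", "),
         " (edge ", paste(which(bad)[seq_len(min(5L, sum(bad)))], collapse = ","),
         "); admissible: ", paste(binding_modes(), collapse = ", "),
         call. = FALSE)
  }
  m
}

#' Construct a bipartite miRNA-RNA interaction network
#'
#' @param rna_ids Character vector of unique RNA identifiers (length N >= 1).
#' @param mirna_ids Character vector of unique miRNA identifiers (M >= 1).
#' @param edges Data frame with columns `rna`, `mirna` (either integer indices
#'   into the id vectors or character ids) and `mode` (a binding-mode label,
#'   see [binding_modes()]). At most one edge per (rna, mirna) pair.
#'
#' @return An object of class `ceRNA_network`: a list with `rna_ids`,
#'   `mirna_ids` and an integer-indexed `edges` data frame.
#' @export
interaction_network <- function(rna_ids, mirna_ids, edges) {
  rna_ids <- as.character(rna_ids)
  mirna_ids <- as.character(mirna_ids)
  if (length(rna_ids) < 1L || length(mirna_ids) < 1L)
    stop("need at least one RNA and one miRNA species", call. = FALSE)
  if (anyDuplicated(rna_ids) || anyDuplicated(mirna_ids))
    stop("species identifiers must be unique within each side", call. = FALSE)
  stopifnot(is.data.frame(edges), all(c("rna", "mirna", "mode") %in% names(edges)))

  ri <- if (is.character(edges$rna) || is.factor(edges$rna)) {
    match(as.character(edges$rna), rna_ids)
  } else as.integer(edges$rna)
  mi <- if (is.character(edges$mirna) || is.factor(edges$mirna)) {
    match(as.character(edges$mirna), mirna_ids)
  } else as.integer(edges$mirna)
  if (anyNA(ri) || anyNA(mi) ||
      any(ri < 1L | ri > length(rna_ids)) || any(mi < 1L | mi > length(mirna_ids)))
    stop("edge endpoints outside the declared species sets", call. = FALSE)

  mode <- normalize_mode(edges$mode)
  key <- (mi - 1) * length(rna_ids) + ri
  if (anyDuplicated(key))
    stop("duplicate (rna, mirna) pairs in edge list; collapse them first ",
         "(read_interactome() does this automatically)", call. = FALSE)

  net <- list(
    rna_ids = rna_ids,
    mirna_ids = mirna_ids,
    edges = data.frame(rna = ri, mirna = mi, mode = mode,
                       stringsAsFactors = FALSE)
  )
  class(net) <- "ceRNA_network"
  net
}

#' @export
print.ceRNA_network <- function(x, ...) {
  cat("Bipartite miRNA-RNA interaction network\n")
  cat(sprintf("  %d RNA species, %d miRNA species, %d edges\n",
              length(x$rna_ids), length(x$mirna_ids), nrow(x$edges)))
  tab <- table(factor(x$edges$mode, levels = binding_modes()))
  cat("  binding modes:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

n_rna <- function(network) length(network$rna_ids)
n_mirna <- function(network) length(network$mirna_ids)

#' Node degrees of an interaction network
#'
#' @param network A `ceRNA_network`.
#' @return List with integer vectors `rna` (length N) and `mirna` (length M).
#' @export
network_degrees <- function(network) {
  list(
    rna = tabulate(network$edges$rna, nbins = n_rna(network)),
    mirna = tabulate(network$edges$mirna, nbins = n_mirna(network))
  )
}

#' Read a miRNA-RNA interactome from an edge-list TSV
#'
#' Expects a tab-separated file with header `rna_id  mirna_id  binding_mode`
#' and one interaction per row; lines starting with `#` are ignored. Duplicate
#' (rna, mirna) rows are collapsed keeping the strongest mode (the one with the
#' lowest binding-strength multiplier, i.e. earliest in [binding_modes()]);
#' species without any edge after collapsing are dropped. Counts of collapsed
#' rows are reported as attributes `n_duplicates_dropped` on the result and
#' via a message.
#'
#' @param path Path to the TSV file.
#' @param quiet Suppress the parse-summary message.
#' @return A `ceRNA_network`.
#' @export
read_interactome <- function(path, quiet = FALSE) {
  raw <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("rna_id", "mirna_id", "binding_mode")
  if (!all(need %in% names(raw)))
    stop("expected columns ", paste(need, collapse = ", "), " in ", path,
         call. = FALSE)
  bad <- which(is.na(raw$rna_id) | is.na(raw$mirna_id) | raw$rna_id == "" |
                 raw$mirna_id == "")
  if (length(bad))
    stop("malformed rows at data line(s) ", paste(bad, collapse = ", "),
         " of ", path, call. = FALSE)
  mode <- normalize_mode(raw$binding_mode)

  # collapse duplicates keeping the strongest (lowest-rank) mode
  rank <- match(mode, binding_modes())
  key <- paste(raw$rna_id, raw$mirna_id, sep = "\r")
  o <- order(key, rank)
  keep <- !duplicated(key[o])
  n_dup <- sum(!keep)
  idx <- o[keep]

  rna_ids <- sort(unique(raw$rna_id[idx]))
  mirna_ids <- sort(unique(raw$mirna_id[idx]))
  net <- interaction_network(
    rna_ids, mirna_ids,
    data.frame(rna = raw$rna_id[idx], mirna = raw$mirna_id[idx],
               mode = mode[idx], stringsAsFactors = FALSE)
  )
  attr(net, "n_duplicates_dropped") <- n_dup
  if (!quiet && n_dup > 0)
    message("collapsed ", n_dup, " duplicate (rna, mirna) row(s), keeping the ",
            "strongest binding mode")
  net
}

#' Write a network as an edge-list TSV
#'
#' @param network A `ceRNA_network`.
#' @param path Destination file.
#' @param comment Optional provenance line(s) written as `#`-prefixed header.
#' @export
write_interactome <- function(network, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(paste0("# ", comment), con)
  writeLines("rna_id\tmirna_id\tbinding_mode", con)
  e <- network$edges
  writeLines(paste(network$rna_ids[e$rna], network$mirna_ids[e$mirna], e$mode,
                   sep = "\t"), con)
  invisible(path)
}

#' Restrict a network to a subset of binding modes
#'
#' Keeps only edges whose mode belongs to `modes`, drops species left without
#' edges, and optionally restricts to the largest connected component of the
#' bipartite graph (the convention used when analysing single-class
#' subnetworks, which may be disjoint).
#'
#' @param network A `ceRNA_network`.
#' @param modes Character vector of binding-mode labels to keep.
#' @param largest_component If `TRUE`, keep only the largest connected
#'   component after filtering.
#' @return A `ceRNA_network`.
#' @export
subnetwork_by_modes <- function(network, modes, largest_component = FALSE) {
  modes <- normalize_mode(modes)
  if (length(modes) == 0L) stop("empty mode set", call. = FALSE)
  e <- network$edges[network$edges$mode %in% modes, , drop = FALSE]
  if (nrow(e) == 0L)
    stop("no edges left after restricting to modes: ",
         paste(modes, collapse = ", "), call. = FALSE)

  if (largest_component) {
    g <- igraph::graph_from_edgelist(cbind(
      paste0("r", e$rna), paste0("m", e$mirna)), directed = FALSE)
    comp <- igraph::components(g)
    big <- which.max(comp$csize)
    keep_v <- names(comp$membership)[comp$membership == big]
    keep <- paste0("r", e$rna) %in% keep_v & paste0("m", e$mirna) %in% keep_v
    e <- e[keep, , drop = FALSE]
  }

  rna_keep <- sort(unique(e$rna))
  mirna_keep <- sort(unique(e$mirna))
  interaction_network(
    network$rna_ids[rna_keep], network$mirna_ids[mirna_keep],
    data.frame(rna = match(e$rna, rna_keep), mirna = match(e$mirna, mirna_keep),
               mode = e$mode, stringsAsFactors = FALSE)
  )
}
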