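# Consensus spinglass community detection on the weighted partial-correlation
# network.

# canonical form of a membership vector: communities renumbered in order of
# first appearance, so label permutations compare equal
canonical_partition <- function(membership) {
  match(membership, unique(membership))
}

# configuration-model modularity with the signed extension (positive and
# negative parts scored separately and combined by their weight shares);
# used only to select among annealing restarts -- the spinglass object's own
# modularity slot mis-ranks partitions on small weighted graphs
signed_modularity <- function(w, memb, gamma = 1) {
  qpart <- function(wp) {
    m2 <- sum(wp)
    if (m2 == 0) return(0)
    s <- rowSums(wp)
    same <- outer(memb, memb, "==")
    (sum(wp[same]) - gamma * sum((s %o% s)[same]) / m2) / m2
  }
  wpos <- pmax(w, 0); wneg <- pmax(-w, 0)
  mp <- sum(wpos); mn <- sum(wneg)
  if (mp + mn == 0) return(0)
  (mp * qpart(wpos) - mn * qpart(wneg)) / (mp + mn)
}

#' Consensus spinglass community detection
#'
#' Runs the spin-glass community algorithm `n_iter` times with per-run seeds
#' on the weighted network of supported edges, canonicalises each partition
#' (community labels in order of first node appearance), and reports the
#' modal partition, the fraction of iterations that produced exactly it, and
#' the node co-membership frequencies. Negative edges are handled by the
#' signed-network Hamiltonian variant; disconnected components are clustered
#' separately and isolated nodes are reported as singletons. An empty edge
#' set returns the all-singleton partition with frequency 1.
#'
#' @param weighted_network symmetric k x k matrix of edge weights
#'   (posterior-mean partial correlations over supported edges; 0 = no edge).
#' @param n_iter iterations (study default 5,000; tests use fewer).
#' @param seed integer seed.
#' @param gamma spin-glass resolution parameter.
#' @param spins maximum number of communities.
#' @param restarts annealing restarts per component per iteration; the
#'   restart with the highest (signed) configuration modularity is kept.
#' @return object of class `community_result`: `modal_partition` (named
#'   integer vector), `modal_frequency`, `n_iterations`, `co_membership`
#'   (k x k fraction-of-iterations matrix).
#' @export
spinglass_consensus <- function(weighted_network, n_iter = 5000L, seed = 1L,
                                gamma = 1, spins = 13L, restarts = 2L) {
  w <- as.matrix(weighted_network)
  stopifnot(nrow(w) == ncol(w), max(abs(w - t(w))) < 1e-8)
  k <- nrow(w)
  labels <- rownames(w) %||% paste0("V", seq_len(k))
  diag(w) <- 0
  if (all(w == 0)) {
    part <- stats::setNames(seq_len(k), labels)
    return(structure(list(modal_partition = part, modal_frequency = 1,
                          n_iterations = as.integer(n_iter),
                          co_membership = diag(k)),
                     class = "community_result"))
  }
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  implementation <- if (any(w < 0)) "neg" else "orig"
  comp <- igraph::components(g)
  counts <- new.env(parent = emptyenv())
  co <- matrix(0, k, k)
  first_seen <- list()
  for (it in seq_len(n_iter)) {
    membership <- integer(k)
    offset <- 0L
    for (cm in seq_len(comp$no)) {
      nodes <- which(comp$membership == cm)
      if (length(nodes) == 1L) {
        membership[nodes] <- offset + 1L
        offset <- offset + 1L
        next
      }
      sub <- igraph::induced_subgraph(g, nodes)
      w_sub <- w[nodes, nodes, drop = FALSE]
      best <- NULL; best_q <- -Inf
      for (r in seq_len(restarts)) {
        set.seed(substream_seed(seed, "spinglass", (it * 131L + cm) * 7L + r))
        cl <- igraph::membership(
          igraph::cluster_spinglass(sub, spins = min(spins, length(nodes)),
                                    gamma = gamma,
                                    implementation = implementation))
        q <- signed_modularity(w_sub, as.integer(cl), gamma)
        if (q > best_q) { best_q <- q; best <- cl }
      }
      membership[nodes] <- offset + best
      offset <- offset + max(best)
    }
    part <- canonical_partition(membership)
    key <- paste(part, collapse = "-")
    counts[[key]] <- (counts[[key]] %||% 0L) + 1L
    if (is.null(first_seen[[key]])) first_seen[[key]] <- part
    co <- co + outer(part, part, "==")
  }
  keys <- ls(counts)
  freq <- vnapply(keys, function(kk) counts[[kk]])
  modal_key <- keys[which.max(freq)]
  structure(list(modal_partition = stats::setNames(first_seen[[modal_key]], labels),
                 modal_frequency = max(freq) / n_iter,
                 n_iterations = as.integer(n_iter),
                 co_membership = co / n_iter),
            class = "community_result")
}

#' @export
print.community_result <- function(x, ...) {
  cat(sprintf("<community_result> %d communities; modal frequency %.1f%% of %d iterations\n",
              max(x$modal_partition), 100 * x$modal_frequency, x$n_iterations))
  invisible(x)
}

#' Weighted adjacency of supported edges from edge decisions
#'
#' @param decisions an `edge_decisions` (uses `status == "associated"`) or
#'   `replication_summary` (uses `replication == "replicated_association"`,
#'   weighting by the across-cohort mean posterior rho).
#' @param labels node labels in canonical order.
#' @return symmetric weighted adjacency matrix.
#' @export
supported_adjacency <- function(decisions, labels) {
  k <- length(labels)
  w <- matrix(0, k, k, dimnames = list(labels, labels))
  if (inherits(decisions, "replication_summary")) {
    rows <- decisions[decisions$replication == "replicated_association", , drop = FALSE]
    wts <- (rows$rho_mean_a + rows$rho_mean_b) / 2
  } else {
    rows <- decisions[decisions$status == "associated", , drop = FALSE]
    wts <- rows$rho_mean
  }
  for (r in seq_len(nrow(rows))) {
    w[rows$i[r], rows$j[r]] <- w[rows$j[r], rows$i[r]] <- wts[r]
  }
  w
}

#' Write a community result as JSON (plus a co-membership CSV)
#' @param x a `community_result`.
#' @param path JSON output path; the co-membership matrix goes to the same
#'   path with extension `.csv`.
#' @return `path`, invisibly.
#' @export
write_community_json <- function(x, path) {
  jsonlite::write_json(list(modal_partition = as.list(x$modal_partition),
                            modal_frequency = x$modal_frequency,
                            n_iterations = x$n_iterations),
                       path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(x$co_membership),
                   sub("\\.json$", ".csv", path), row.names = FALSE)
  invisible(path)
}
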