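#' Symmetrically normalize a weighted adjacency matrix
#'
#' Builds the sparse weighted adjacency matrix W of a PPI network (entries
#' are edge confidences) and returns W' = D^(-1/2) W D^(-1/2), where D is
#' the diagonal matrix of weighted degrees. W' is symmetric with spectral
#' radius at most 1, the normalization under which the diffusion iteration
#' converges for any restart weight below 1. Only the largest connected
#' component is kept; nodes in smaller components (including isolated
#' nodes) are dropped with a warning.
#'
#' @param net A [ppi_network()].
#' @return A symmetric sparse `Matrix` with dimnames set to the retained
#'   node ids; attribute `dropped` lists removed nodes.
#' @examples
#' net <- ppi_network(edges = data.frame(node_a = "a", node_b = "b",
#'                                       confidence = 1))
#' as.matrix(normalize_adjacency(net))
#' @export
normalize_adjacency <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  g <- igraph::graph_from_data_frame(net$edges[, c("node_a", "node_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = net$nodes))
  comp <- igraph::components(g)
  keep <- names(comp$membership)[comp$membership == which.max(comp$csize)]
  dropped <- setdiff(net$nodes, keep)
  if (length(dropped)) {
    warning(sprintf("normalize_adjacency: dropped %d node(s) outside the largest component",
                    length(dropped)))
  }
  edges <- net$edges[net$edges$node_a %in% keep & net$edges$node_b %in% keep, ]
  nodes <- sort(keep)
  i <- match(edges$node_a, nodes)
  j <- match(edges$node_b, nodes)
  W <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                            x = rep(edges$confidence, 2),
                            dims = c(length(nodes), length(nodes)),
                            dimnames = list(nodes, nodes))
  deg <- Matrix::rowSums(W)
  d_inv_sqrt <- 1 / sqrt(deg)
  Wn <- Matrix::Diagonal(x = d_inv_sqrt) %*% W %*% Matrix::Diagonal(x = d_inv_sqrt)
  dimnames(Wn) <- list(nodes, nodes)
  attr(Wn, "dropped") <- dropped
  Wn
}

#' Diffuse a prior vector over a normalized network
#'
#' Iterates `F_t = alpha * W' %*% F_{t-1} + (1 - alpha) * Y` from `F_0 = Y`
#' until the L1 change between iterates falls below `tol` (or `max_iter`
#' is reached). `Y` is the indicator of prior (disease-relevant) proteins;
#' `alpha` weighs network smoothing against the prior. With the symmetric
#' normalization of [normalize_adjacency()] and `alpha < 1` the iteration
#' converges to `(1 - alpha) * (I - alpha W')^{-1} Y`.
#'
#' @param Wn Normalized adjacency from [normalize_adjacency()].
#' @param prior Character vector of prior node ids (ids not present in
#'   `Wn` are ignored), or a named numeric prior vector over the nodes.
#' @param alpha Restart/smoothing weight in (0, 1); default 0.8.
#' @param tol L1 convergence tolerance (default 1e-6).
#' @param max_iter Iteration cap (default 1000); hitting it flags
#'   `converged = FALSE`.
#' @return Object of class `propagation_scores`: list with `scores`
#'   (named, non-negative), `iterations`, `converged`, `alpha`, `prior`.
#' @examples
#' net <- ppi_network(edges = data.frame(node_a = "a", node_b = "b",
#'                                       confidence = 1))
#' propagate(normalize_adjacency(net), "a", alpha = 0.5)$scores
#' @export
propagate <- function(Wn, prior, alpha = 0.8, tol = 1e-6, max_iter = 1000L) {
  if (alpha <= 0 || alpha >= 1) {
    stop("configuration error: alpha must lie strictly in (0, 1)", call. = FALSE)
  }
  if (tol <= 0) stop("configuration error: tol must be > 0", call. = FALSE)
  nodes <- rownames(Wn)
  if (is.character(prior)) {
    y <- as.numeric(nodes %in% prior)
  } else {
    stopifnot(!is.null(names(prior)))
    y <- numeric(length(nodes))
    y[match(names(prior), nodes)] <- unname(prior)
  }
  if (!any(y != 0)) {
    stop("prior error: no prior protein maps to the network", call. = FALSE)
  }
  f <- y
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    f_new <- as.numeric(alpha * (Wn %*% f) + (1 - alpha) * y)
    if (sum(abs(f_new - f)) < tol) {
      f <- f_new
      converged <- TRUE
      break
    }
    f <- f_new
  }
  structure(list(scores = stats::setNames(f, nodes),
                 iterations = iter, converged = converged,
                 alpha = alpha,
                 prior = nodes[y != 0]),
            class = "propagation_scores")
}

#' @export
print.propagation_scores <- function(x, ...) {
  cat(sprintf("Propagation scores over %d nodes (%d priors), alpha = %.2f: %s after %d iterations\n",
              length(x$scores), length(x$prior), x$alpha,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  top <- utils::head(sort(x$scores, decreasing = TRUE), 5)
  cat("  top scores:", paste(sprintf("%s=%.4f", names(top), top),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Count priors directly adjacent to a node
#'
#' @param net A [ppi_network()].
#' @param neighbor Node id to examine.
#' @param priors Character vector of prior protein ids.
#' @return Number of priors sharing an edge with `neighbor` (at most
#'   `length(priors)`, and at most the node's degree).
#' @export
common_prior_count <- function(net, neighbor, priors) {
  stopifnot(inherits(net, "ppi_network"))
  adj <- c(net$edges$node_b[net$edges$node_a == neighbor],
           net$edges$node_a[net$edges$node_b == neighbor])
  length(intersect(unique(adj), priors))
}

# adjacency lookup for many nodes at once
common_prior_counts <- function(net, neighbors, priors) {
  vapply(neighbors, function(nb) common_prior_count(net, nb, priors),
         integer(1))
}

#' Rank non-prior neighbors by pooled propagation score
#'
#' Propagates the pooled prior list and ranks the non-prior nodes by
#' diffusion score. By default candidates are restricted to first-degree
#' neighbors of the prior set (nodes directly adjacent to at least one
#' prior). Ties are broken by common-prior count, then node id, so
#' rankings are reproducible.
#'
#' @param net A [ppi_network()].
#' @param priors Character vector of prior protein ids.
#' @param k Number of neighbors to return (default 50); if fewer
#'   candidates exist, all are returned with a warning.
#' @param alpha,tol,max_iter Passed to [propagate()].
#' @param first_degree_only Restrict candidates to direct neighbors of a
#'   prior (default `TRUE`).
#' @param scores Optional precomputed [propagate()] result on the pooled
#'   prior (avoids recomputation).
#' @return Data frame `neighbor_id`, `score`, `pooled_rank` (1-based,
#'   dense), `common_prior_count`.
#' @export
pooled_top_neighbors <- function(net, priors, k = 50L, alpha = 0.8,
                                 tol = 1e-6, max_iter = 1000L,
                                 first_degree_only = TRUE, scores = NULL) {
  stopifnot(inherits(net, "ppi_network"))
  if (is.null(scores)) {
    Wn <- normalize_adjacency(net)
    scores <- propagate(Wn, priors, alpha = alpha, tol = tol,
                        max_iter = max_iter)
  }
  s <- scores$scores
  cand <- setdiff(names(s), priors)
  if (first_degree_only) {
    e <- net$edges
    touching <- unique(c(e$node_b[e$node_a %in% priors],
                         e$node_a[e$node_b %in% priors]))
    cand <- intersect(cand, touching)
  }
  cpc <- common_prior_counts(net, cand, priors)
  ord <- order(-s[cand], -cpc, cand)
  cand <- cand[ord]
  if (length(cand) < k) {
    warning(sprintf("pooled_top_neighbors: only %d candidate(s) available (k = %d)",
                    length(cand), k))
  }
  top <- utils::head(cand, k)
  data.frame(neighbor_id = top,
             score = unname(s[top]),
             pooled_rank = seq_along(top),
             common_prior_count = unname(cpc[match(top, names(cpc))]),
             stringsAsFactors = FALSE)
}

#' Top neighbors of each prior propagated separately
#'
#' Runs one diffusion per prior protein (prior vector supported on that
#' single node) and records the top `k` non-seed nodes for each. Results
#' do not depend on the order of the priors. Priors absent from the
#' propagated component are skipped with a warning.
#'
#' @inheritParams pooled_top_neighbors
#' @return Named list mapping each usable prior to its character vector of
#'   top-`k` neighbor ids.
#' @export
per_protein_top_neighbors <- function(net, priors, k = 50L, alpha = 0.8,
                                      tol = 1e-6, max_iter = 1000L) {
  stopifnot(inherits(net, "ppi_network"))
  Wn <- normalize_adjacency(net)
  nodes <- rownames(Wn)
  usable <- intersect(priors, nodes)
  skipped <- setdiff(priors, usable)
  if (length(skipped)) {
    warning(sprintf("per_protein_top_neighbors: %d prior(s) absent from network, skipped",
                    length(skipped)))
  }
  out <- lapply(usable, function(p) {
    s <- propagate(Wn, p, alpha = alpha, tol = tol, max_iter = max_iter)$scores
    s <- s[setdiff(names(s), p)]
    names(utils::head(sort(s, decreasing = TRUE,
                           method = "radix"), k))
  })
  stats::setNames(out, usable)
}

#' Select the strongest common neighbors
#'
#' Intersects the pooled top-`k` list with the union of the per-prior
#' top-`k` lists and keeps the `final_k` strongest by pooled score,
#' reporting for each its pooled rank, the number of priors whose
#' individual top lists contain it, and the number of priors it touches
#' directly in the network.
#'
#' @param pooled_list Output of [pooled_top_neighbors()].
#' @param per_protein_map Output of [per_protein_top_neighbors()].
#' @param net The [ppi_network()] (for adjacency counts).
#' @param priors Character vector of prior protein ids.
#' @param final_k Number of neighbors to report (default 20).
#' @return `NeighborReport` data frame: `neighbor_id`, `pooled_rank`,
#'   `score`, `per_protein_support`, `common_prior_count`. Fewer than
#'   `final_k` rows (with a warning) when the intersection is small.
#' @export
select_top_common <- function(pooled_list, per_protein_map, net, priors,
                              final_k = 20L) {
  support_pool <- unlist(per_protein_map, use.names = FALSE)
  candidates <- pooled_list[pooled_list$neighbor_id %in% unique(support_pool), ,
                            drop = FALSE]
  if (nrow(candidates) < final_k) {
    warning(sprintf("select_top_common: intersection has %d candidate(s) (final_k = %d)",
                    nrow(candidates), final_k))
  }
  out <- utils::head(candidates[order(candidates$pooled_rank), , drop = FALSE],
                     final_k)
  out$per_protein_support <- vapply(out$neighbor_id, function(id) {
    sum(vapply(per_protein_map, function(v) id %in% v, logical(1)))
  }, integer(1))
  out <- out[, c("neighbor_id", "pooled_rank", "score",
                 "per_protein_support", "common_prior_count")]
  rownames(out) <- NULL
  out
}

#' End-to-end neighbor prioritization for a prior list
#'
#' Convenience wrapper running [pooled_top_neighbors()],
#' [per_protein_top_neighbors()] and [select_top_common()] for one prior
#' list (e.g. the up-regulated, down-regulated, or pooled consensus
#' proteins).
#'
#' @inheritParams pooled_top_neighbors
#' @param final_k Neighbors in the final report (default 20).
#' @return A `NeighborReport` data frame (see [select_top_common()]).
#' @export
propagation_report <- function(net, priors, k = 50L, final_k = 20L,
                               alpha = 0.8, tol = 1e-6, max_iter = 1000L,
                               first_degree_only = TRUE) {
  pooled <- pooled_top_neighbors(net, priors, k = k, alpha = alpha, tol = tol,
                                 max_iter = max_iter,
                                 first_degree_only = first_degree_only)
  per_prot <- per_protein_top_neighbors(net, priors, k = k, alpha = alpha,
                                        tol = tol, max_iter = max_iter)
  select_top_common(pooled, per_prot, net, priors, final_k = final_k)
}
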