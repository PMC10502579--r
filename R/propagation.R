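# Random-walk-with-restart propagation of the neighborhood literature.
#
# The walker models a mention sent by metabolite i: it FIRST takes one
# uniform step away from i, then at each subsequent point continues with
# probability alpha (the damping factor) or restarts from i (and
# immediately re-steps) with probability 1 - alpha. Counting where the
# walker is found yields
#
#   pi_i = (1 - alpha) * e_i %*% T %*% solve(I - alpha * T)
#
# with T the row-stochastic uniform-neighbor transition matrix. At
# alpha = 0 this is exactly the direct-neighbor distribution, so direct
# neighbors are the sole contributors; plain personalized PageRank
# (pi = e_i at alpha = 0) would contradict that behavior.

#' Reach probabilities of the restarting walk
#'
#' Computes the full matrix of reach probabilities \eqn{\pi_{i,k}}: row `i`
#' is the stationary distribution of a mention sent by metabolite `i`
#' walking over the compound graph with damping factor `alpha`.
#'
#' @param graph Undirected compound graph (igraph, named vertices).
#' @param alpha Damping factor, the probability of continuing the walk at
#'   each step; `0 <= alpha < 1`. At `alpha = 0` only direct neighbors are
#'   reached.
#' @param method `"auto"` picks a dense factorization below 2000 nodes and
#'   a sparse one above; `"dense"`/`"sparse"` force either (they agree to
#'   high precision).
#' @return A dense numeric matrix with dimnames (sources x targets). Rows
#'   of isolated nodes are all zero.
#' @export
#' @examples
#' g <- igraph::make_graph(~ a - b, b - c)
#' compute_reach_probabilities(g, alpha = 0)["b", ]
compute_reach_probabilities <- function(graph, alpha,
                                        method = c("auto", "dense",
                                                   "sparse")) {
  method <- match.arg(method)
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha < 0 || alpha >= 1) {
    stop("alpha must be a probability in [0, 1)")
  }
  nodes <- igraph::V(graph)$name
  M <- length(nodes)
  if (M == 0) stop("empty graph")
  A <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
  deg <- Matrix::rowSums(A)
  inv_deg <- ifelse(deg > 0, 1 / deg, 0)     # isolated nodes: zero row
  Tm <- Matrix::Diagonal(x = inv_deg) %*% A  # row-stochastic transitions
  if (method == "auto") {
    method <- if (M < 2000) "dense" else "sparse"
  }
  if (alpha == 0) {
    pi <- as.matrix(Tm)
  } else if (method == "dense") {
    Td <- as.matrix(Tm)
    # pi = (1-a) T (I - aT)^{-1}; solve on the transpose for all sources
    pi <- t((1 - alpha) * solve(diag(M) - alpha * t(Td), t(Td)))
  } else {
    # sparse LU factorization, same linear system
    lhs <- Matrix::Diagonal(M) - alpha * Matrix::t(Tm)
    pi <- t(as.matrix((1 - alpha) * Matrix::solve(lhs, Matrix::t(Tm))))
  }
  dimnames(pi) <- list(nodes, nodes)
  pi
}

#' Influence neighborhood of a source metabolite
#'
#' The set of targets a metabolite is allowed to send literature to: those
#' it reaches (self-landings discounted) with probability strictly greater
#' than a uniformly random pick among the other `M - 1` metabolites,
#' \deqn{H_i = \{k \ne i : \pi_{i,k} / (1 - \pi_{i,i}) > 1/(M-1)\}.}
#' The inequality is strict and evaluated after the division with no
#' epsilon slack, so exact ties (e.g. the center of a star at
#' `alpha = 0`) are excluded.
#'
#' @param pi_row Named reach-probability row for the source.
#' @param source Source node id.
#' @param M Number of metabolites in the network.
#' @return Character vector of target ids (possibly empty). If
#'   `pi[source] == 1` (degenerate) or the row is all zero, returns an
#'   empty set flagged with `attr(, "degenerate")`.
#' @export
influence_neighborhood <- function(pi_row, source, M) {
  stopifnot(M >= 2, !is.null(names(pi_row)))
  p_self <- if (source %in% names(pi_row)) pi_row[[source]] else 0
  if (p_self >= 1 || sum(pi_row) == 0) {
    return(structure(character(0), degenerate = TRUE))
  }
  ratio <- pi_row / (1 - p_self)
  keep <- names(pi_row)[ratio > 1 / (M - 1)]
  setdiff(keep, source)
}

#' Propagated literature contributions
#'
#' Distributes each source's corpus `n_i` over its influence neighborhood
#' proportionally to the reach probabilities:
#' \deqn{t_{i,k} = n_i \, \pi_{i,k} / \sum_{k' \in H_i} \pi_{i,k'}}
#' for `k` in `H_i`, 0 otherwise. Rows with an empty neighborhood or an
#' empty corpus are all zero; otherwise each row sums exactly to `n_i`
#' (the literature is conserved).
#'
#' @param pi Reach-probability matrix from
#'   [compute_reach_probabilities()].
#' @param H List of influence neighborhoods, one per source (named).
#' @param corpus A [mention_corpus()] aligned with the graph.
#' @return Matrix `t` of propagated mention counts (sources x targets).
#' @export
compute_contributions <- function(pi, H, corpus) {
  nodes <- rownames(pi)
  t_mat <- matrix(0, nrow(pi), ncol(pi), dimnames = dimnames(pi))
  for (i in nodes) {
    Hi <- H[[i]]
    n_i <- corpus$n[[i]]
    if (length(Hi) == 0 || n_i == 0) next
    p <- pi[i, Hi]
    t_mat[i, Hi] <- n_i * p / sum(p)
  }
  t_mat
}

#' Prior weights of the contributors
#'
#' For each target `k`, the contributor set is
#' \eqn{T_k = \{i : t_{i,k} > 0\}} and the weight of contributor `i` is its
#' share of the literature reaching `k`:
#' \deqn{w_{i,k} = t_{i,k} / \sum_{i' \in T_k} t_{i',k}.}
#' A metabolite never contributes to its own prior (`w[k, k] = 0`, which
#' holds by construction since `k` is excluded from `H_k`).
#'
#' @param t Contribution matrix from [compute_contributions()].
#' @return List with `w` (weight matrix, columns over contributors summing
#'   to 1) and `contributors` (named list of `T_k`, targets with no
#'   contributors map to an empty vector).
#' @export
compute_weights <- function(t) {
  col_tot <- colSums(t)
  w <- t
  pos <- col_tot > 0
  w[, pos] <- sweep(t[, pos, drop = FALSE], 2, col_tot[pos], "/")
  w[, !pos] <- 0
  contributors <- apply(t, 2, function(col) names(col)[col > 0],
                        simplify = FALSE)
  list(w = w, contributors = contributors)
}

#' Run the full propagation stage
#'
#' Convenience wrapper computing, for one graph and corpus, the reach
#' probabilities, influence neighborhoods, contributions and prior
#' weights.
#'
#' @param graph Undirected compound graph.
#' @param corpus A [mention_corpus()].
#' @param alpha Damping factor (default 0.4, balancing direct and
#'   indirect neighborhood contributions).
#' @return A `propagation_model`: list with `alpha`, `graph`, `nodes`,
#'   `pi`, `H`, `t`, `w`, `contributors`.
#' @export
propagate <- function(graph, corpus, alpha = 0.4) {
  nodes <- igraph::V(graph)$name
  stopifnot(identical(sort(nodes), sort(names(corpus$n))))
  pi <- compute_reach_probabilities(graph, alpha)
  M <- length(nodes)
  H <- lapply(setNames(nodes, nodes), function(i) {
    influence_neighborhood(pi[i, ], i, M)
  })
  t_mat <- compute_contributions(pi, H, corpus)
  ws <- compute_weights(t_mat)
  structure(list(alpha = alpha, graph = graph, nodes = nodes, pi = pi,
                 H = H, t = t_mat, w = ws$w,
                 contributors = ws$contributors),
            class = "propagation_model")
}

#' @export
print.propagation_model <- function(x, ...) {
  n_ctb <- lengths(x$contributors)
  cat(sprintf("propagation model: %d nodes, alpha = %g\n",
              length(x$nodes), x$alpha))
  cat(sprintf("  contributors per target: median %g, %d target(s) with none\n",
              stats::median(n_ctb), sum(n_ctb == 0)))
  invisible(x)
}

#' Cache a propagation model to TSV + JSON sidecar
#'
#' Writes the non-zero (source, target) entries of `pi`, `t` and `w` in a
#' columnar TSV, with `alpha` in a JSON sidecar, so an expensive
#' propagation can be reused across screens.
#'
#' @param model A [propagate()] result.
#' @param path Output TSV path; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_propagation <- function(model, path) {
  idx <- which(model$pi > 0 | model$t > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  df <- data.frame(source = model$nodes[idx[, 1]],
                   target = model$nodes[idx[, 2]],
                   pi = model$pi[idx], t = model$t[idx], w = model$w[idx])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  jsonlite::write_json(list(alpha = model$alpha,
                            n_nodes = length(model$nodes)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
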