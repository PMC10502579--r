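# Shared fixtures and independent oracles. Every oracle recomputes the
# quantity it checks through a different route than the implementation
# (series instead of linear solve, quadrature instead of conjugacy,
# enumeration instead of distribution functions).

path3 <- function() igraph::make_graph(~ a - b, b - c)

star5 <- function() {
  g <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(g)$name <- c("c", paste0("l", 1:4))
  g
}

# random simple graph with named nodes; guarantees at least one edge
random_graph <- function(n, p = 0.25, seed = 1) {
  g <- litprop:::with_seed(seed, {
    gg <- igraph::sample_gnp(n, p)
    while (igraph::ecount(gg) == 0) gg <- igraph::sample_gnp(n, p)
    gg
  })
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  g
}

random_corpus <- function(graph, seed = 1, max_n = 50, p_zero = 0.3) {
  nodes <- igraph::V(graph)$name
  n <- litprop:::with_seed(seed, {
    ifelse(runif(length(nodes)) < p_zero, 0,
           sample.int(max_n, length(nodes), replace = TRUE))
  })
  mention_corpus(stats::setNames(n, nodes), graph)
}

# truncated power series (1 - a) * sum_{s>=0} a^s e_i T^{s+1}: the
# walker's occupancy, independent of the closed-form linear solve
pi_series <- function(graph, alpha, tol = 1e-14) {
  A <- as.matrix(igraph::as_adjacency_matrix(graph))
  deg <- rowSums(A)
  Tm <- A / ifelse(deg > 0, deg, 1)
  Tm[deg == 0, ] <- 0
  M <- nrow(Tm)
  acc <- matrix(0, M, M, dimnames = dimnames(A))
  term <- diag(M) %*% Tm          # e_i T^{s+1} at s = 0
  coef <- (1 - alpha)
  s <- 0
  repeat {
    acc <- acc + coef * term
    s <- s + 1
    coef <- (1 - alpha) * alpha^s
    if (coef < tol || alpha == 0) break
    term <- term %*% Tm
  }
  acc
}

# exhaustive influence-neighborhood oracle over all (source, target) pairs
H_bruteforce <- function(pi) {
  nodes <- rownames(pi)
  M <- length(nodes)
  out <- list()
  for (i in nodes) {
    keep <- character(0)
    for (k in nodes) {
      if (k == i) next
      if (pi[i, k] / (1 - pi[i, i]) > 1 / (M - 1)) keep <- c(keep, k)
    }
    out[[i]] <- keep
  }
  out
}

# Bayes-rule oracle: prior density times binomial likelihood, normalized
# by adaptive quadrature; evaluated on an interior grid
posterior_grid_oracle <- function(prior, n_k, y_k, grid) {
  unnorm <- function(p) {
    mixture_density(prior, p) * stats::dbinom(y_k, n_k, p)
  }
  # panel-wise quadrature: adaptive integration over [0, 1] in one shot
  # can overlook narrow mixture modes, so sum 200 uniform panels
  cuts <- seq(0, 1, length.out = 201)
  Z <- sum(vapply(seq_len(200), function(j) {
    stats::integrate(unnorm, cuts[j], cuts[j + 1],
                     rel.tol = 1e-12, abs.tol = 1e-14)$value
  }, numeric(1)))
  unnorm(grid) / Z
}

# right-tail hypergeometric by explicit log-binomial summation
fisher_enum_oracle <- function(y, n, m, N) {
  hi <- min(n, m)
  if (y > hi) return(0)
  j <- y:hi
  sum(exp(lchoose(m, j) + lchoose(N - m, n - j) - lchoose(N, n)))
}

# AUC by exhaustive pairwise comparison (ties count 1/2)
auc_bruteforce <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# tiny end-to-end fixture exercising all four scoring scenarios:
#   path a-b-c-d plus isolated nodes e (no corpus) and f (with corpus)
scenario_fixture <- function() {
  g <- igraph::make_graph(~ a - b, b - c, c - d)
  g <- igraph::add_vertices(g, 2, name = c("e", "f"))
  corpus <- mention_corpus(c(a = 40, b = 12, d = 30, f = 20), g)
  cooc <- cooccurrence_table(
    data.frame(metabolite = c("a", "b", "d", "f"),
               descriptor = "D1",
               n_comentions = c(8, 3, 2, 1)),
    corpus)
  list(graph = g, corpus = corpus, cooc = cooc)
}
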