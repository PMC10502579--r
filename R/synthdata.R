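# Synthetic compound graphs and literature corpora. The generator's
# defaults emulate the descriptive statistics of real metabolite
# literature: 62% of network metabolites without any annotated article,
# and a top-heavy (discrete power-law) distribution of corpus sizes among
# the rest. Disease signal is planted in connected modules whose members
# co-mention a descriptor at `theta` times its background rate.

#' Simulation configuration
#'
#' All generators are pure functions of a configuration and its seed.
#'
#' @param n_nodes Number of metabolites.
#' @param graph_model One of `"scale_free"` (preferential attachment,
#'   default), `"erdos_renyi"`, `"path"`, `"star"`, `"grid"`.
#' @param zero_inflation Fraction of metabolites without any annotated
#'   article (default 0.62).
#' @param powerlaw_exponent Tail exponent of the corpus-size distribution
#'   among literature-bearing metabolites (default 2, strongly
#'   top-heavy).
#' @param corpus_xmin Minimum corpus size for literature-bearing
#'   metabolites (default 1).
#' @param corpus_cap Upper cap on corpus sizes (default 1e6).
#' @param n_descriptors Number of disease descriptors.
#' @param background_rate Background co-mention rate `P_d` (recycled over
#'   descriptors).
#' @param module_size Number of adjacent metabolites per planted module
#'   (one module per descriptor; 0 disables planting).
#' @param theta Relative co-mention risk inside planted modules
#'   (`>= 1`; 1 means no signal, the null model).
#' @param module_corpus_min Floor on module members' corpus sizes
#'   (ensures planted contributors carry enough literature to matter; 0
#'   leaves corpora untouched).
#' @param seed Mandatory integer seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_nodes = 750,
                              graph_model = c("scale_free", "erdos_renyi",
                                              "path", "star", "grid"),
                              zero_inflation = 0.62,
                              powerlaw_exponent = 2,
                              corpus_xmin = 1,
                              corpus_cap = 1e6,
                              n_descriptors = 25,
                              background_rate = 0.01,
                              module_size = 20,
                              theta = 1,
                              module_corpus_min = 0,
                              seed) {
  stopifnot(!missing(seed), n_nodes >= 2, theta >= 1,
            zero_inflation >= 0, zero_inflation <= 1,
            powerlaw_exponent > 1, corpus_xmin >= 1,
            all(background_rate > 0), all(background_rate < 1),
            n_descriptors >= 1, module_size >= 0)
  graph_model <- match.arg(graph_model)
  structure(list(n_nodes = n_nodes, graph_model = graph_model,
                 zero_inflation = zero_inflation,
                 powerlaw_exponent = powerlaw_exponent,
                 corpus_xmin = corpus_xmin, corpus_cap = corpus_cap,
                 n_descriptors = n_descriptors,
                 background_rate = rep(background_rate,
                                       length.out = n_descriptors),
                 module_size = module_size, theta = theta,
                 module_corpus_min = module_corpus_min,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# node names: single letters for toy sizes (the a-b-c fixtures), padded
# ids otherwise
node_names <- function(n) {
  if (n <= 26) letters[seq_len(n)] else sprintf("m%04d", seq_len(n))
}

#' Simulate a compound graph
#'
#' Reproducible from the config's seed. The scale-free model
#' (preferential attachment, 2 edges per arriving node) is connected by
#' construction and mimics the hub-dominated degree distribution of
#' metabolic compound graphs.
#'
#' @param config A [simulation_config()].
#' @return An undirected, simple igraph with named vertices.
#' @export
simulate_network <- function(config) {
  n <- config$n_nodes
  g <- with_seed(config$seed, switch(
    config$graph_model,
    scale_free = igraph::sample_pa(n, power = 1, m = 2, directed = FALSE),
    erdos_renyi = igraph::sample_gnp(n, p = min(1, 4 / n)),
    path = igraph::make_ring(n, circular = FALSE),
    star = igraph::make_star(n, mode = "undirected"),
    grid = {
      r <- max(1L, floor(sqrt(n)))
      cdim <- ceiling(n / r)
      gg <- igraph::make_lattice(c(r, cdim))
      igraph::induced_subgraph(gg, seq_len(n))
    }
  ))
  igraph::V(g)$name <- node_names(igraph::vcount(g))
  igraph::simplify(g)
}

# floor of a continuous Pareto draw, capped
rpowerlaw <- function(k, exponent, xmin, cap) {
  x <- floor(xmin * runif(k)^(-1 / (exponent - 1)))
  pmin(x, cap)
}

#' Simulate literature over a compound graph
#'
#' Corpus sizes `n_i` follow a zero-inflated discrete power law. For each
#' descriptor, one connected module of `module_size` nodes (grown
#' breadth-first from a random seed node) co-mentions it at rate
#' `min(theta * P_d, 0.9)`; everywhere else the rate is the background
#' `P_d`. Co-mentions are drawn as `y_i ~ Binomial(n_i, rate)`
#' independently per (metabolite, descriptor): the method consumes counts,
#' so article-level identity is not modeled.
#'
#' @param graph A compound graph (typically from [simulate_network()]).
#' @param config A [simulation_config()].
#' @return List with `corpus` ([mention_corpus()]), `cooc`
#'   ([cooccurrence_table()]), `truth` (data frame of planted
#'   metabolite-descriptor pairs) and `modules` (named list of member
#'   ids).
#' @export
simulate_literature <- function(graph, config) {
  nodes <- igraph::V(graph)$name
  n_nodes <- length(nodes)
  descs <- sprintf("D%02d", seq_len(config$n_descriptors))
  with_seed(config$seed + 1L, {
    # corpus sizes
    has_lit <- runif(n_nodes) >= config$zero_inflation
    n_i <- numeric(n_nodes)
    n_i[has_lit] <- rpowerlaw(sum(has_lit), config$powerlaw_exponent,
                              config$corpus_xmin, config$corpus_cap)
    names(n_i) <- nodes

    # planted modules: connected node sets grown breadth-first
    modules <- list()
    if (config$module_size > 0) {
      for (d in descs) {
        root <- sample(n_nodes, 1)
        ord <- igraph::bfs(graph, root = root, unreachable = FALSE)$order
        ord <- ord[!is.na(ord)]
        members <- nodes[ord[seq_len(min(config$module_size,
                                         length(ord)))]]
        modules[[d]] <- members
        if (config$module_corpus_min > 0) {
          n_i[members] <- pmax(n_i[members], config$module_corpus_min)
        }
      }
    }

    # co-mentions
    pairs <- vector("list", length(descs))
    for (j in seq_along(descs)) {
      d <- descs[j]
      rate <- rep(config$background_rate[j], n_nodes)
      names(rate) <- nodes
      if (!is.null(modules[[d]])) {
        r_mod <- config$theta * config$background_rate[j]
        if (r_mod > 0.9) {
          warning(sprintf("descriptor %s: planted rate %.3g clipped to 0.9",
                          d, r_mod))
          r_mod <- 0.9
        }
        rate[modules[[d]]] <- r_mod
      }
      y <- rbinom(n_nodes, size = n_i, prob = rate)
      keep <- y > 0
      pairs[[j]] <- data.frame(metabolite = nodes[keep],
                               descriptor = rep(d, sum(keep)),
                               n_comentions = y[keep],
                               stringsAsFactors = FALSE)
    }
  })
  corpus <- mention_corpus(n_i, graph)
  cooc <- cooccurrence_table(do.call(rbind, pairs), corpus)
  truth <- if (length(modules)) {
    do.call(rbind, lapply(names(modules), function(d) {
      data.frame(metabolite = modules[[d]], descriptor = d,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(metabolite = character(0), descriptor = character(0))
  }
  list(corpus = corpus, cooc = cooc, truth = truth, modules = modules)
}

#' Frozen configurations for the recovery experiment
#'
#' `"strong"` plants clear signal (`theta = 10`, module corpora of at
#' least 200 articles); `"null"` is identical except `theta = 1`, so the
#' planted labels carry no signal and recovery should be at chance.
#'
#' @param kind `"strong"` or `"null"`.
#' @param seed Seed (default 1).
#' @return A [simulation_config()].
#' @export
recovery_config <- function(kind = c("strong", "null"), seed = 1) {
  kind <- match.arg(kind)
  simulation_config(n_nodes = 750, graph_model = "scale_free",
                    zero_inflation = 0.62, powerlaw_exponent = 2,
                    corpus_xmin = 1, corpus_cap = 1e6,
                    n_descriptors = 25, background_rate = 0.01,
                    module_size = 20,
                    theta = if (kind == "strong") 10 else 1,
                    module_corpus_min = 200, seed = seed)
}

#' Parameter-recovery experiment with masked corpora
#'
#' Generates a network and literature with planted associations, then
#' scores each planted-module member against its descriptor with its own
#' corpus masked (prior-only, the ground-truth protocol): the method must
#' recover the planted association from the neighborhood's literature
#' alone. Negative pairs are the same masked members scored against
#' descriptors whose module they do not belong to. Reports the AUC of the
#' prior-only `Log2FC` (and `LogOdds`) against the planted labels.
#'
#' @param config A [simulation_config()] with planted modules.
#' @param n_pos,n_neg Numbers of positive and negative pairs (default 500
#'   each).
#' @param alpha Damping factor.
#' @param nu Prior pseudo-sample size.
#' @return List with `auc` (Log2FC), `auc_logodds`, counts, and the
#'   per-pair `scores` data frame. Byte-reproducible from the config.
#' @export
recovery_experiment <- function(config, n_pos = 500, n_neg = 500,
                                alpha = 0.4, nu = 1000) {
  if (config$module_size == 0) stop("config has no planted modules")
  graph <- simulate_network(config)
  lit <- simulate_literature(graph, config)
  prop <- propagate(graph, lit$corpus, alpha)

  truth_key <- paste(lit$truth$metabolite, lit$truth$descriptor)
  descs <- sprintf("D%02d", seq_len(config$n_descriptors))
  # candidate negatives: module members against foreign descriptors.
  # A valid negative control must carry no planted signal in its direct
  # neighborhood: a pair whose metabolite sits next to the descriptor's
  # module receives that descriptor's elevated literature by
  # construction, so it is excluded from the negative pool.
  members <- unique(lit$truth$metabolite)
  neg_grid <- expand.grid(metabolite = members, descriptor = descs,
                          KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
  neg_grid <- neg_grid[!(paste(neg_grid$metabolite, neg_grid$descriptor)
                         %in% truth_key), ]
  nb <- igraph::adjacent_vertices(graph, neg_grid$metabolite)
  touches <- mapply(function(v, d) {
    any(names(v) %in% lit$modules[[d]])
  }, nb, neg_grid$descriptor)
  neg_grid <- neg_grid[!touches, , drop = FALSE]
  if (nrow(lit$truth) < n_pos) {
    stop(sprintf("requested %d positives but only %d planted pairs exist",
                 n_pos, nrow(lit$truth)))
  }
  if (nrow(neg_grid) < n_neg) {
    stop(sprintf("requested %d negatives but only %d candidate pairs exist",
                 n_neg, nrow(neg_grid)))
  }
  with_seed(config$seed + 2L, {
    pos <- lit$truth[sample(nrow(lit$truth), n_pos), ]
    neg <- neg_grid[sample(nrow(neg_grid), n_neg), ]
  })
  pairs <- rbind(cbind(pos, label = TRUE), cbind(neg, label = FALSE))
  rec <- lapply(seq_len(nrow(pairs)), function(r) {
    score_pair(prop, lit$corpus, lit$cooc, pairs$metabolite[r],
               pairs$descriptor[r], nu = nu, mask = TRUE)
  })
  rec <- do.call(rbind, rec)
  pairs$Log2FC <- rec$Log2FC
  pairs$LogOdds <- rec$LogOdds
  pairs$scenario <- rec$scenario
  ok <- pairs$scenario != "no_information"
  roc <- roc_auc(pairs$Log2FC[ok], pairs$label[ok])
  roc_lo <- roc_auc(pairs$LogOdds[ok], pairs$label[ok])
  list(auc = roc$auc, auc_logodds = roc_lo$auc,
       n_pos = sum(pairs$label[ok]), n_neg = sum(!pairs$label[ok]),
       n_dropped = sum(!ok), scores = pairs, seed = config$seed)
}
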