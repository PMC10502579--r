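# Diagnostics of the prior composition. Priors dominated by a single
# over-studied contributor (glucose, ethanol, ...) are flagged through the
# Shannon entropy of the contributor weights and weight-averaged summaries
# of where the contributors sit in the network and how big their corpora
# are.

#' Shannon entropy of contributor weights
#'
#' \eqn{-\sum_i w_i \log_2 w_i} with `0 log 0 = 0`. The more contributors
#' with balanced weights, the higher the entropy; in base 2 the screening
#' threshold `Entropy > 1` reads "more diverse than two equal
#' contributors". The base is configurable.
#'
#' @param weights Probability vector summing to 1 (non-empty).
#' @param base Logarithm base (default 2, entropy in bits).
#' @return Non-negative scalar, at most `log(length(weights), base)`.
#' @export
#' @examples
#' shannon_entropy(rep(0.25, 4)) # 2 bits
shannon_entropy <- function(weights, base = 2) {
  if (length(weights) == 0) stop("empty weight vector")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-6) {
    stop("weights must be non-negative and sum to 1")
  }
  w <- weights[weights > 0]
  -sum(w * log(w, base = base)) + 0   # + 0 normalizes IEEE -0
}

#' Weight-averaged contributor summaries
#'
#' `CtbAvgDistance` is the prior-weighted average shortest-path distance
#' (in reactions) from the contributors to the target; `CtbAvgCorporaSize`
#' the prior-weighted average contributor corpus size. Both diagnose how
#' local and how literature-rich the prior's support is. Contributors
#' unreachable in the graph are excluded from the distance average (with
#' the weights renormalized over the reachable ones) and counted in the
#' `n_excluded` attribute.
#'
#' @param weights Named prior weights over contributors (sum to 1).
#' @param distances Named shortest-path distances for the same
#'   contributors.
#' @param corpus_sizes Named corpus sizes `n_i` for the same contributors.
#' @return List with `CtbAvgDistance` and `CtbAvgCorporaSize`.
#' @export
contributor_stats <- function(weights, distances, corpus_sizes) {
  if (length(weights) == 0) stop("empty contributor set")
  ids <- names(weights)
  stopifnot(!is.null(ids), all(ids %in% names(distances)),
            all(ids %in% names(corpus_sizes)))
  d <- distances[ids]
  reach <- is.finite(d)
  avg_d <- if (any(reach)) {
    sum(weights[reach] * d[reach]) / sum(weights[reach])
  } else {
    NA_real_
  }
  out <- list(CtbAvgDistance = avg_d,
              CtbAvgCorporaSize = sum(weights * corpus_sizes[ids]))
  attr(out, "n_excluded") <- sum(!reach)
  out
}

#' Contributor profile for one metabolite-descriptor pair
#'
#' Assembles the explainable record behind a prediction: one row per
#' contributor with its prior weight `w_{i,k}`, posterior weight
#' `W_{i,k}`, per-contributor prior/posterior `LogOdds` and `Log2FC`, its
#' corpus size and its shortest-path distance to the target. Rows are
#' sorted by ascending prior weight. Pair-level diagnostics (`Entropy`,
#' `CtbAvgDistance`, `CtbAvgCorporaSize`) travel as attributes.
#'
#' @param target Target metabolite id.
#' @param descriptor Descriptor id.
#' @param prop A [propagate()] model.
#' @param corpus A [mention_corpus()].
#' @param cooc A [cooccurrence_table()].
#' @param nu Prior pseudo-sample size.
#' @param mask Score the target as if it had no literature.
#' @return A `contributor_profile` data frame (possibly 0-row when the
#'   target has no contributors), with attributes `target`, `descriptor`,
#'   `Entropy`, `CtbAvgDistance`, `CtbAvgCorporaSize`, `scenario`.
#' @export
build_profile <- function(target, descriptor, prop, corpus, cooc,
                          nu = 1000, mask = FALSE) {
  sc <- score_pair(prop, corpus, cooc, target, descriptor, nu = nu,
                   mask = mask, keep_mixtures = TRUE)
  prior <- attr(sc, "prior")
  post <- attr(sc, "post")
  if (is.null(prior) || prior$kind == "degenerate") {
    prof <- data.frame(contributor = character(0))
  } else {
    P <- descriptor_rate(cooc, descriptor)
    ind <- contributor_indicators(prior, post, P)
    d <- igraph::distances(prop$graph, v = ind$contributor, to = target)[, 1]
    ind$n_articles <- unname(corpus$n[ind$contributor])
    ind$distance <- unname(d)
    prof <- ind[order(ind$weight_prior, ind$contributor), , drop = FALSE]
    rownames(prof) <- NULL
  }
  structure(prof,
            target = target, descriptor = descriptor,
            scenario = sc$scenario,
            Entropy = sc$Entropy,
            CtbAvgDistance = sc$CtbAvgDistance,
            CtbAvgCorporaSize = sc$CtbAvgCorporaSize,
            class = c("contributor_profile", "data.frame"))
}

#' Serialize / restore a contributor profile
#'
#' `profile_to_json` writes the full profile (rows plus pair-level
#' diagnostics); `profile_from_json` restores it, so that profiles
#' round-trip losslessly through their JSON form.
#'
#' @param profile A [build_profile()] result.
#' @return `profile_to_json`: a JSON string; `profile_from_json`: a
#'   `contributor_profile`.
#' @export
profile_to_json <- function(profile) {
  jsonlite::toJSON(list(
    target = attr(profile, "target"),
    descriptor = attr(profile, "descriptor"),
    scenario = attr(profile, "scenario"),
    Entropy = attr(profile, "Entropy"),
    CtbAvgDistance = attr(profile, "CtbAvgDistance"),
    CtbAvgCorporaSize = attr(profile, "CtbAvgCorporaSize"),
    contributors = as.data.frame(profile)
  ), auto_unbox = TRUE, digits = NA, na = "null")
}

#' @rdname profile_to_json
#' @param json A JSON string from `profile_to_json`.
#' @export
profile_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  prof <- as.data.frame(obj$contributors)
  structure(prof,
            target = obj$target, descriptor = obj$descriptor,
            scenario = obj$scenario,
            Entropy = null2na(obj$Entropy),
            CtbAvgDistance = null2na(obj$CtbAvgDistance),
            CtbAvgCorporaSize = null2na(obj$CtbAvgCorporaSize),
            class = c("contributor_profile", "data.frame"))
}

null2na <- function(x) if (is.null(x)) NA_real_ else x

#' Export a profile as TSV (one row per contributor)
#' @param profile A [build_profile()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
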