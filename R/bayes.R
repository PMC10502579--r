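# Beta-mixture model of p_k, the probability that an article mentioning
# metabolite k also mentions a given disease descriptor. Everything is
# closed-form conjugate arithmetic; marginal likelihoods are computed in
# log space because corpora reach 1e5 articles and factorials overflow.

#' Null Beta component at the background rate
#'
#' The a-priori belief that a metabolite and a disease are independent
#' concepts in the literature: a Beta distribution parameterized by mean
#' `P` and pseudo-sample size `nu`, i.e. `Beta(P * nu, (1 - P) * nu)`.
#' `nu` controls the variance, `Var = P(1-P)/(1+nu)`: the larger `nu`, the
#' more evidence a contributor needs to move away from the background.
#'
#' @param P Background rate of the descriptor, in (0, 1).
#' @param nu Pseudo-observation count (> 0), default 1000.
#' @return A `beta_component`: list with shape parameters `a` and `b`.
#' @export
null_component <- function(P, nu = 1000) {
  if (!is.numeric(P) || length(P) != 1 || is.na(P) || P <= 0 || P >= 1) {
    stop("P must lie strictly inside (0, 1)")
  }
  if (!is.numeric(nu) || length(nu) != 1 || nu <= 0) {
    stop("nu must be positive")
  }
  beta_component(P * nu, (1 - P) * nu)
}

beta_component <- function(a, b) {
  stopifnot(a > 0, b > 0)
  structure(list(a = a, b = b), class = "beta_component")
}

#' @export
print.beta_component <- function(x, ...) {
  cat(sprintf("Beta(%.6g, %.6g), mean %.6g\n", x$a, x$b, x$a / (x$a + x$b)))
  invisible(x)
}

#' Shrink a contributor's rate toward the background
#'
#' Conjugate Beta-binomial update of the null component with a
#' contributor's own counts: `Beta(a0 + y, b0 + n - y)`. For contributors
#' with few articles this acts as a shrinkage procedure, pulling an
#' unreliable raw rate `y/n` toward the background rate; as `n` grows the
#' mean converges to `y/n`.
#'
#' @param n_i Articles mentioning the contributor (>= 0).
#' @param y_i Articles co-mentioning contributor and descriptor
#'   (`0 <= y_i <= n_i`).
#' @param null The [null_component()] for the descriptor.
#' @return A `beta_component`.
#' @export
shrink_component <- function(n_i, y_i, null) {
  stopifnot(n_i >= 0, y_i >= 0)
  if (y_i > n_i) stop("y_i exceeds n_i")
  beta_component(null$a + y_i, null$b + (n_i - y_i))
}

# internal constructor; components sorted by contributor id so serialized
# outputs are byte-stable
beta_mixture <- function(contributors, weights, a, b,
                         kind = c("prior", "posterior", "degenerate")) {
  kind <- match.arg(kind)
  stopifnot(length(contributors) == length(weights),
            length(weights) == length(a), length(a) == length(b))
  if (length(weights) == 0) stop("a mixture needs at least one component")
  if (anyDuplicated(contributors)) stop("contributor ids must be unique")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    stop("weights must be non-negative and sum to 1")
  }
  ord <- order(contributors)
  structure(list(contributors = contributors[ord],
                 weights = weights[ord] / sum(weights),
                 a = a[ord], b = b[ord], kind = kind),
            class = "beta_mixture")
}

#' @export
print.beta_mixture <- function(x, ...) {
  cat(sprintf("beta mixture (%s): %d component(s), mean %.6g\n",
              x$kind, length(x$weights), mixture_mean(x)))
  invisible(x)
}

#' Build the prior mixture for a target metabolite
#'
#' The prior on `p_k` is the mixture of the contributors' shrunken Beta
#' components, weighted by their share `w_{i,k}` of the literature that
#' reached the target. With no contributors the prior degenerates to the
#' bare null component (`kind = "degenerate"`).
#'
#' @param weights Named vector of prior weights `w_{i,k}` over
#'   contributors (sums to 1); may be empty.
#' @param evidence Data frame with columns `contributor`, `n`, `y` holding
#'   each contributor's own counts against the descriptor.
#' @param null The [null_component()] for the descriptor.
#' @return A `beta_mixture` of kind `"prior"` or `"degenerate"`.
#' @export
build_prior <- function(weights, evidence, null) {
  if (length(weights) == 0) {
    return(beta_mixture("<background>", 1, null$a, null$b,
                        kind = "degenerate"))
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("contributor weights must sum to 1")
  }
  ids <- names(weights)
  if (is.null(ids)) stop("weights must be named by contributor id")
  miss <- setdiff(ids, evidence$contributor)
  if (length(miss)) {
    stop("missing evidence for contributor(s): ",
         paste(miss, collapse = ", "))
  }
  rows <- match(ids, evidence$contributor)
  comp <- mapply(function(n, y) shrink_component(n, y, null),
                 evidence$n[rows], evidence$y[rows], SIMPLIFY = FALSE)
  beta_mixture(ids, unname(weights),
               vapply(comp, `[[`, numeric(1), "a"),
               vapply(comp, `[[`, numeric(1), "b"),
               kind = "prior")
}

#' Posterior mixture after observing the target's own literature
#'
#' Updates every component with the target's counts,
#' `Beta(a_i + y_k, b_i + n_k - y_k)`, and reweights the mixture by each
#' contributor's Beta-binomial marginal likelihood of those counts,
#' \deqn{W_{i,k} \propto w_{i,k} \binom{n_k}{y_k}
#'   B(a_i + y_k, b_i + n_k - y_k) / B(a_i, b_i),}
#' computed in log space and normalized by log-sum-exp. Contributors whose
#' prior component explains the observations better gain weight. With
#' `n_k = 0` the posterior equals the prior. A degenerate prior yields the
#' single-component conjugate update.
#'
#' @param prior A [build_prior()] result.
#' @param n_k,y_k The target's article and co-mention counts.
#' @return A `beta_mixture` of kind `"posterior"`.
#' @export
posterior_mixture <- function(prior, n_k, y_k) {
  stopifnot(inherits(prior, "beta_mixture"), n_k >= 0, y_k >= 0)
  if (y_k > n_k) stop("y_k exceeds n_k")
  a2 <- prior$a + y_k
  b2 <- prior$b + (n_k - y_k)
  logC <- lchoose(n_k, y_k) + lbeta(a2, b2) - lbeta(prior$a, prior$b)
  logW <- log(prior$weights) + logC
  W <- exp(logW - logsumexp(logW))
  beta_mixture(prior$contributors, W / sum(W), a2, b2, kind = "posterior")
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Mixture mean, density and CDF
#'
#' `mixture_mean` is the closed-form expectation
#' \eqn{\sum_i W_i a_i/(a_i+b_i)}; `mixture_cdf` evaluates
#' \eqn{\Pr(p \le x) = \sum_i W_i I_x(a_i, b_i)} through the regularized
#' incomplete beta function; `mixture_density` the weighted Beta density.
#'
#' @param mix A `beta_mixture`.
#' @param x Evaluation point(s) in `[0, 1]`.
#' @return Numeric vector of the same length as `x` (scalar for
#'   `mixture_mean`).
#' @export
mixture_mean <- function(mix) {
  sum(mix$weights * mix$a / (mix$a + mix$b))
}

#' @rdname mixture_mean
#' @export
mixture_cdf <- function(mix, x) {
  if (any(x < 0 | x > 1)) stop("x must lie in [0, 1]")
  vapply(x, function(xi) sum(mix$weights * pbeta(xi, mix$a, mix$b)),
         numeric(1))
}

#' @rdname mixture_mean
#' @export
mixture_density <- function(mix, x) {
  vapply(x, function(xi) sum(mix$weights * dbeta(xi, mix$a, mix$b)),
         numeric(1))
}

# upper tail computed directly to keep precision when CDF ~ 1
mixture_sf <- function(mix, x) {
  sum(mix$weights * pbeta(x, mix$a, mix$b, lower.tail = FALSE))
}

#' Association predictors of a mixture
#'
#' From the mixture distribution of `p_k` and the background rate `P`:
#' `CDF = Pr(p_k <= P)` is the posterior error that the metabolite
#' mentions the disease more often than expected, `q = 1 - CDF`, and
#' \deqn{LogOdds = \log(q / (1 - q)), \quad
#'   Log2FC = \log_2(E[p_k] / P).}
#' `LogOdds` is a significance-like measure, `Log2FC` an effect size; they
#' are complementary. When the CDF underflows to 0 (or rounds to 1)
#' `LogOdds` is clamped to `±logodds_cap` and flagged, since the log-odds
#' would otherwise be infinite; `Log2FC` remains a usable ranking in those
#' cases.
#'
#' @param mix A `beta_mixture`.
#' @param P Background rate in (0, 1).
#' @param logodds_cap Clamp for `|LogOdds|` (default 709, about the log of
#'   the largest double).
#' @param log_base Base of the `LogOdds` logarithm (default natural;
#'   settable to 10 for comparisons).
#' @return List with `LogOdds`, `Log2FC`, `mean`, `CDF` and `clamped`.
#' @export
predictors <- function(mix, P, logodds_cap = 709, log_base = exp(1)) {
  if (P <= 0 || P >= 1) stop("P must lie strictly inside (0, 1)")
  cdf <- mixture_cdf(mix, P)
  q <- mixture_sf(mix, P)
  lo <- (log(q) - log(cdf)) / log(log_base)
  clamped <- FALSE
  if (!is.finite(lo) || abs(lo) > logodds_cap) {
    lo <- sign(if (is.finite(lo)) lo else (q - cdf)) * logodds_cap
    clamped <- TRUE
  }
  list(LogOdds = lo,
       Log2FC = log2(mixture_mean(mix) / P),
       mean = mixture_mean(mix),
       CDF = cdf,
       clamped = clamped)
}

#' Per-contributor predictors
#'
#' `LogOdds` and `Log2FC` evaluated independently on each contributor's
#' single component in the prior and in the posterior mixture; these color
#' the contribution profiles (is a contributor pushing the association up
#' or down?).
#'
#' @param prior,post Prior and posterior `beta_mixture` sharing the same
#'   contributor set.
#' @param P Background rate.
#' @inheritParams predictors
#' @return Data frame with one row per contributor: prior/posterior
#'   weights and per-component `LogOdds` and `Log2FC`.
#' @export
contributor_indicators <- function(prior, post, P, logodds_cap = 709,
                                   log_base = exp(1)) {
  if (!identical(prior$contributors, post$contributors)) {
    stop("prior and posterior mixtures have mismatched contributor sets")
  }
  one <- function(a, b) {
    predictors(beta_mixture("x", 1, a, b, kind = "prior"), P,
               logodds_cap = logodds_cap, log_base = log_base)
  }
  pr <- mapply(one, prior$a, prior$b, SIMPLIFY = FALSE)
  po <- mapply(one, post$a, post$b, SIMPLIFY = FALSE)
  data.frame(contributor = prior$contributors,
             weight_prior = prior$weights,
             weight_post = post$weights,
             prior_LogOdds = vapply(pr, `[[`, numeric(1), "LogOdds"),
             prior_Log2FC = vapply(pr, `[[`, numeric(1), "Log2FC"),
             post_LogOdds = vapply(po, `[[`, numeric(1), "LogOdds"),
             post_Log2FC = vapply(po, `[[`, numeric(1), "Log2FC"),
             stringsAsFactors = FALSE)
}

#' Serialize a mixture to JSON
#' @param mix A `beta_mixture`.
#' @param P Optional background rate recorded alongside.
#' @return A JSON string.
#' @export
mixture_to_json <- function(mix, P = NULL) {
  obj <- list(kind = mix$kind, P = P,
              components = data.frame(contributor = mix$contributors,
                                      weight = mix$weights,
                                      a = mix$a, b = mix$b))
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
}
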