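# Comparison baselines and the ROC validation harness. Both baselines
# deliberately use less information than the propagation method:
# Baseline-Freq ignores the metabolite entirely, Baseline-DN looks only at
# the direct neighborhood's pooled co-mention rate.

#' Baseline-Freq: background-frequency score
#'
#' Scores every metabolite identically by the descriptor's overall
#' probability of being mentioned, `P = m/N`. It ignores the network, so
#' it ranks descriptors, never metabolites, and serves as the floor any
#' neighborhood-aware method must beat.
#'
#' @param descriptor Descriptor id.
#' @param cooc A [cooccurrence_table()].
#' @return The score `P`.
#' @export
baseline_freq <- function(descriptor, cooc) {
  descriptor_rate(cooc, descriptor)
}

#' Baseline-DN: direct-neighborhood rate ratio
#'
#' The ratio between the average probability of mentioning the disease in
#' the direct neighborhood and its overall probability. By default the
#' neighborhood average is the pooled rate
#' \eqn{(\sum_j y_j) / (\sum_j n_j)} over the direct neighbors (robust to
#' neighbors with empty corpora); `pooled = FALSE` averages the
#' per-neighbor ratios `y_j/n_j` over neighbors with literature instead.
#'
#' @param metabolite Target metabolite id (excluded from its own
#'   neighborhood).
#' @param descriptor Descriptor id.
#' @param graph Compound graph.
#' @param corpus A [mention_corpus()].
#' @param cooc A [cooccurrence_table()].
#' @param pooled Use the pooled rate (default) or the mean of ratios.
#' @return The score, or `NA` (flagged via attribute `reason`) when no
#'   direct neighbor has literature.
#' @export
baseline_dn <- function(metabolite, descriptor, graph, corpus, cooc,
                        pooled = TRUE) {
  nb <- setdiff(igraph::neighbors(graph, metabolite)$name, metabolite)
  P <- descriptor_rate(cooc, descriptor)
  if (P <= 0 || P >= 1) stop("descriptor background rate outside (0, 1)")
  if (length(nb) == 0) {
    return(structure(NA_real_, reason = "no direct neighbors"))
  }
  n <- corpus$n[nb]
  yv <- descriptor_comentions(cooc, descriptor)
  y <- ifelse(nb %in% names(yv), yv[nb], 0)
  if (sum(n) == 0) {
    return(structure(NA_real_, reason = "no neighbor literature"))
  }
  rate <- if (pooled) {
    sum(y) / sum(n)
  } else {
    mean((y / n)[n > 0])
  }
  rate / P
}

#' ROC area under the curve with midrank ties
#'
#' AUC via the rank (Mann-Whitney) formulation with average ranks for
#' ties, equal to the trapezoidal area under the ROC curve. Optionally
#' also reports the (TPR, FPR) operating points at strict score
#' thresholds.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Logical (or 0/1) true labels; both classes must occur.
#' @param thresholds Optional numeric vector of strict thresholds
#'   (`score > threshold` predicts positive).
#' @return List with `auc` and, when thresholds are given,
#'   `operating_points` (data frame threshold/TPR/FPR).
#' @export
roc_auc <- function(scores, labels, thresholds = NULL) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !any(is.na(scores)),
            !any(is.na(labels)))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to compute an ROC")
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  out <- list(auc = auc)
  if (!is.null(thresholds)) {
    out$operating_points <- data.frame(
      threshold = thresholds,
      TPR = vapply(thresholds, function(th) mean(scores[labels] > th),
                   numeric(1)),
      FPR = vapply(thresholds, function(th) mean(scores[!labels] > th),
                   numeric(1)))
  }
  out
}

#' Build a validation set of positive and negative pairs
#'
#' Positives are (metabolite, descriptor) pairs whose own literature is
#' significantly associated by the right-tailed Fisher exact test with BH
#' correction (`q <= q_max`) over all pairs of metabolites with
#' literature; negatives are sampled uniformly from the non-significant
#' pairs. The evaluated methods then score each pair with the target's
#' corpus masked, so the association must be recovered from the
#' neighborhood alone.
#'
#' @param corpus A [mention_corpus()].
#' @param cooc A [cooccurrence_table()].
#' @param n_pos,n_neg Requested numbers of positives and negatives.
#' @param q_max BH threshold defining positives (default 0.05).
#' @param seed Sampling seed (mandatory; the set is a pure function of the
#'   inputs and the seed).
#' @return Data frame `metabolite`, `descriptor`, `label`
#'   (`"positive"`/`"negative"`).
#' @export
build_validation_set <- function(corpus, cooc, n_pos, n_neg,
                                 q_max = 0.05, seed) {
  stopifnot(!missing(seed))
  mets <- names(corpus$n)[corpus$n > 0]
  descs <- names(cooc$m)
  grid <- expand.grid(metabolite = mets, descriptor = descs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$y <- mapply(function(k, d) comentions(cooc, k, d),
                   grid$metabolite, grid$descriptor)
  grid$p <- mapply(function(k, d, y) {
    fisher_right_p(y, corpus$n[[k]], cooc$m[[d]], corpus$N)
  }, grid$metabolite, grid$descriptor, grid$y)
  grid$q <- p.adjust(grid$p, method = "BH")
  sig <- grid$q <= q_max
  if (sum(sig) < n_pos) {
    stop(sprintf("requested %d positives but only %d pairs are significant at q <= %g",
                 n_pos, sum(sig), q_max))
  }
  if (sum(!sig) < n_neg) {
    stop(sprintf("requested %d negatives but only %d non-significant pairs exist",
                 n_neg, sum(!sig)))
  }
  with_seed(seed, {
    pos <- grid[sample(which(sig), n_pos), c("metabolite", "descriptor")]
    neg <- grid[sample(which(!sig), n_neg), c("metabolite", "descriptor")]
  })
  out <- rbind(cbind(pos, label = "positive"),
               cbind(neg, label = "negative"))
  rownames(out) <- NULL
  out
}

#' Score a validation set with the method and both baselines
#'
#' Every pair is scored with the target's corpus masked: the propagation
#' method contributes its prior-only `Log2FC` and `LogOdds`, and the two
#' baselines their scores. Pairs the method cannot score (no contributors
#' and no literature once masked) get `NA` and are excluded from that
#' method's AUC.
#'
#' @param graph Compound graph.
#' @param corpus A [mention_corpus()].
#' @param cooc A [cooccurrence_table()].
#' @param vset A [build_validation_set()] data frame.
#' @param alpha Damping factor.
#' @param nu Prior pseudo-sample size.
#' @return List with `scores` (per-pair data frame) and `auc` (named list
#'   per method).
#' @export
evaluate_methods <- function(graph, corpus, cooc, vset, alpha = 0.4,
                             nu = 1000) {
  prop <- propagate(graph, corpus, alpha)
  sc <- vset
  method <- lapply(seq_len(nrow(vset)), function(r) {
    rec <- score_pair(prop, corpus, cooc, vset$metabolite[r],
                      vset$descriptor[r], nu = nu, mask = TRUE)
    if (rec$scenario == "no_information") {
      list(Log2FC = NA_real_, LogOdds = NA_real_)
    } else {
      list(Log2FC = rec$Log2FC, LogOdds = rec$LogOdds)
    }
  })
  sc$method_log2fc <- vapply(method, `[[`, numeric(1), "Log2FC")
  sc$method_logodds <- vapply(method, `[[`, numeric(1), "LogOdds")
  sc$baseline_dn <- mapply(function(k, d) {
    as.numeric(baseline_dn(k, d, graph, corpus, cooc))
  }, vset$metabolite, vset$descriptor)
  sc$baseline_freq <- vapply(vset$descriptor, baseline_freq,
                             numeric(1), cooc = cooc)
  lab <- sc$label == "positive"
  auc_of <- function(x) {
    ok <- !is.na(x)
    if (sum(lab[ok]) == 0 || sum(!lab[ok]) == 0) return(NA_real_)
    roc_auc(x[ok], lab[ok])$auc
  }
  list(scores = sc,
       auc = list(method_log2fc = auc_of(sc$method_log2fc),
                  method_logodds = auc_of(sc$method_logodds),
                  baseline_dn = auc_of(sc$baseline_dn),
                  baseline_freq = auc_of(sc$baseline_freq)))
}

# evaluate expr with a temporary RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
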