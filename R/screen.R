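# Orchestration of the screen: per-pair scenario dispatch, predictor and
# diagnostic computation, threshold filtering, the Fisher/BH
# over-representation re-evaluation, and serialization.

PREDICTION_COLUMNS <- c("metabolite", "descriptor", "scenario", "n", "y",
                        "P", "LogOdds", "Log2FC", "priorLogOdds",
                        "priorLog2FC", "Entropy", "CtbAvgDistance",
                        "CtbAvgCorporaSize", "fisher_p", "fisher_q",
                        "passes_filter")

#' Score one metabolite-descriptor pair
#'
#' Dispatches on the available information and returns a one-row
#' prediction record:
#'
#' * contributors and own literature (`few_articles`): predictors from the
#'   posterior mixture, plus `priorLogOdds`/`priorLog2FC` from the prior
#'   (the neighborhood's belief alone);
#' * contributors but no literature (`no_literature`): predictors from the
#'   prior mixture only;
#' * literature but no contributors (`no_neighbor_literature`): the prior
#'   degenerates to the null component and the posterior is its single
#'   conjugate update;
#' * neither (`no_information`): the bare null component; the record is
#'   automatically discarded (`passes_filter = FALSE`).
#'
#' Masking (`mask = TRUE`) scores the target as if its corpus were absent
#' (`n_k = y_k = 0`), the ground-truth protocol used for validation.
#' Because a metabolite never contributes to its own prior, the masked
#' record is identical to the one obtained by physically deleting the
#' target's corpus rows from the inputs.
#'
#' @param prop A [propagate()] model.
#' @param corpus A [mention_corpus()].
#' @param cooc A [cooccurrence_table()].
#' @param metabolite Target metabolite id.
#' @param descriptor Descriptor id; its background rate must lie strictly
#'   in (0, 1).
#' @param nu Prior pseudo-sample size (default 1000).
#' @param mask Hide the target's own literature.
#' @param logodds_cap,log_base Passed to [predictors()].
#' @param keep_mixtures Attach the prior/posterior mixtures as attributes
#'   (used by [build_profile()]).
#' @return A one-row data frame with the prediction-record columns (see
#'   [run_screen()]); `fisher_p`, `fisher_q` are `NA` until
#'   [fisher_reevaluate()].
#' @export
score_pair <- function(prop, corpus, cooc, metabolite, descriptor,
                       nu = 1000, mask = FALSE, logodds_cap = 709,
                       log_base = exp(1), keep_mixtures = FALSE) {
  if (!metabolite %in% prop$nodes) {
    stop("unknown metabolite: ", metabolite)
  }
  n_k <- corpus$n[[metabolite]]
  y_k <- comentions(cooc, metabolite, descriptor)
  if (mask) {
    # the masked corpus is invisible everywhere, including the global
    # bookkeeping: P is recomputed as if the target's rows were deleted
    m_d <- if (descriptor %in% names(cooc$m)) cooc$m[[descriptor]] else 0
    P <- (m_d - y_k) / (cooc$N - n_k)
    n_k <- 0
    y_k <- 0
  } else {
    P <- descriptor_rate(cooc, descriptor)
  }
  if (P <= 0 || P >= 1) {
    stop(sprintf("descriptor %s has background rate P = %g; scoring requires 0 < P < 1",
                 descriptor, P))
  }
  ctb <- prop$contributors[[metabolite]]
  null <- null_component(P, nu)

  ent <- avg_d <- avg_n <- NA_real_
  prior_lo <- prior_l2 <- NA_real_
  if (length(ctb) > 0) {
    w <- prop$w[ctb, metabolite]
    names(w) <- ctb
    yc <- descriptor_comentions(cooc, descriptor)
    if (mask) yc <- yc[names(yc) != metabolite]  # masked corpus is invisible everywhere
    ev <- data.frame(contributor = ctb,
                     n = unname(corpus$n[ctb]),
                     y = unname(ifelse(ctb %in% names(yc), yc[ctb], 0)),
                     stringsAsFactors = FALSE)
    if (mask) ev$n[ev$contributor == metabolite] <- 0  # defensive; self is never a contributor
    prior <- build_prior(w, ev, null)
    ent <- shannon_entropy(prior$weights)
    d <- igraph::distances(prop$graph, v = ctb, to = metabolite)[, 1]
    names(d) <- ctb
    cs <- contributor_stats(w, d, corpus$n)
    avg_d <- cs$CtbAvgDistance
    avg_n <- cs$CtbAvgCorporaSize
    if (n_k == 0) {
      scenario <- "no_literature"
      post <- prior
      pred <- predictors(prior, P, logodds_cap, log_base)
    } else {
      scenario <- "few_articles"
      post <- posterior_mixture(prior, n_k, y_k)
      pred <- predictors(post, P, logodds_cap, log_base)
      pp <- predictors(prior, P, logodds_cap, log_base)
      prior_lo <- pp$LogOdds
      prior_l2 <- pp$Log2FC
    }
  } else {
    prior <- build_prior(setNames(numeric(0), character(0)),
                         data.frame(contributor = character(0),
                                    n = numeric(0), y = numeric(0)),
                         null)
    if (n_k > 0) {
      scenario <- "no_neighbor_literature"
      post <- posterior_mixture(prior, n_k, y_k)
      pred <- predictors(post, P, logodds_cap, log_base)
    } else {
      scenario <- "no_information"
      post <- prior
      pred <- predictors(prior, P, logodds_cap, log_base)
    }
  }

  rec <- data.frame(metabolite = metabolite, descriptor = descriptor,
                    scenario = scenario, n = n_k, y = y_k, P = P,
                    LogOdds = pred$LogOdds, Log2FC = pred$Log2FC,
                    priorLogOdds = prior_lo, priorLog2FC = prior_l2,
                    Entropy = ent, CtbAvgDistance = avg_d,
                    CtbAvgCorporaSize = avg_n,
                    fisher_p = NA_real_, fisher_q = NA_real_,
                    passes_filter = NA,
                    stringsAsFactors = FALSE)
  if (keep_mixtures) {
    attr(rec, "prior") <- prior
    attr(rec, "post") <- post
  }
  rec
}

#' Mask a metabolite's literature out of the inputs
#'
#' Implements the masking semantics of the validation protocol: a masked
#' metabolite has no literature anywhere - it neither carries its own
#' evidence nor contributes to any neighbor's prior, exactly as if its
#' corpus and co-occurrence rows had been deleted from the input files.
#' For scoring the masked metabolite itself, `score_pair(mask = TRUE)` on
#' the unmasked propagation is an exact shortcut, because a metabolite
#' never enters its own prior; for scoring *other* metabolites under the
#' mask, propagation must be recomputed on the masked corpus returned
#' here.
#'
#' @param corpus A [mention_corpus()].
#' @param cooc A [cooccurrence_table()].
#' @param metabolite Metabolite id to mask.
#' @param graph The compound graph the corpus was built on.
#' @return List with masked `corpus` and `cooc`.
#' @export
mask_corpus <- function(corpus, cooc, metabolite, graph) {
  n <- corpus$n
  n[metabolite] <- 0
  masked_corpus <- mention_corpus(n, graph)
  pairs <- cooc$pairs[cooc$pairs$metabolite != metabolite, , drop = FALSE]
  list(corpus = masked_corpus,
       cooc = cooccurrence_table(pairs, masked_corpus))
}

#' Apply the screening thresholds
#'
#' A prediction passes when `LogOdds > logodds_min`, `Log2FC > log2fc_min`
#' and `Entropy > entropy_min`, all strict. The entropy threshold excludes
#' priors dominated by a single contributor. Records with `NA` in any
#' criterion (e.g. no contributors, hence no entropy) fail, and
#' `no_information` records are always discarded.
#'
#' @param records Data frame of prediction records.
#' @param logodds_min,log2fc_min,entropy_min Strict lower thresholds
#'   (defaults 2, 1, 1).
#' @return `records` with `passes_filter` set.
#' @export
apply_filters <- function(records, logodds_min = 2, log2fc_min = 1,
                          entropy_min = 1) {
  pass <- records$LogOdds > logodds_min &
    records$Log2FC > log2fc_min &
    records$Entropy > entropy_min
  pass[is.na(pass)] <- FALSE
  pass[records$scenario == "no_information"] <- FALSE
  records$passes_filter <- pass
  records
}

#' Fisher exact re-evaluation (over-representation analysis)
#'
#' For every record with own literature (`n > 0`), the right-tailed Fisher
#' exact test on the 2x2 mention table
#' `(y, n - y, m - y, N - n - m + y)` asks whether the pair's co-mentions
#' are over-represented given the marginals; p-values get a
#' Benjamini-Hochberg correction across the tested family (all `n > 0`
#' records of the run). `fisher_q <= 0.05` flags classically significant
#' pairs, mirroring a knowledge-base-wide over-representation screen.
#'
#' @param records Data frame of prediction records.
#' @param corpus A [mention_corpus()].
#' @param cooc A [cooccurrence_table()].
#' @return `records` with `fisher_p` and `fisher_q` filled for `n > 0`
#'   rows.
#' @export
fisher_reevaluate <- function(records, corpus, cooc) {
  idx <- which(records$n > 0)
  if (length(idx) == 0) return(records)
  N <- corpus$N
  p <- vapply(idx, function(r) {
    y <- records$y[r]
    n <- records$n[r]
    m <- if (records$descriptor[r] %in% names(cooc$m)) {
      cooc$m[[records$descriptor[r]]]
    } else 0
    if (n - y < 0 || m - y < 0 || N - n - m + y < 0) {
      stop(sprintf("negative cell in 2x2 table for pair %s / %s",
                   records$metabolite[r], records$descriptor[r]))
    }
    fisher_right_p(y, n, m, N)
  }, numeric(1))
  records$fisher_p[idx] <- p
  records$fisher_q[idx] <- p.adjust(p, method = "BH")
  records
}

#' Right-tailed Fisher exact p-value
#'
#' `Pr(X >= y)` for `X` hypergeometric with `n` draws from `N` mentions of
#' which `m` involve the descriptor. `y = 0` gives `p = 1` (the empty
#' tail).
#'
#' @param y Observed co-mentions.
#' @param n Target's mentions (draws).
#' @param m Descriptor's total mentions.
#' @param N Total mentions.
#' @return The one-sided p-value.
#' @export
fisher_right_p <- function(y, n, m, N) {
  phyper(y - 1, m, N - m, n, lower.tail = FALSE)
}

#' Run a full screen
#'
#' Scores every (target, descriptor) pair, applies the screening
#' thresholds, optionally re-evaluates with Fisher/BH, and returns (and
#' optionally writes) the prediction table sorted by
#' `(descriptor, -LogOdds, -Log2FC, metabolite)`. The run is fully
#' deterministic: identical inputs give byte-identical outputs.
#'
#' The default target set is the overlooked metabolites - strictly fewer
#' than `max_articles` mentioning articles. This is a prioritization
#' filter on what is reported, not a limit of the method: any target list
#' can be supplied.
#'
#' @param graph Compound graph.
#' @param corpus A [mention_corpus()].
#' @param cooc A [cooccurrence_table()].
#' @param descriptors Descriptor ids to screen (default: all in `cooc`).
#'   Each must have a background rate strictly in (0, 1).
#' @param targets Metabolite ids to score (default: all with
#'   `n < max_articles`).
#' @param alpha Damping factor.
#' @param nu Prior pseudo-sample size.
#' @param logodds_min,log2fc_min,entropy_min Screening thresholds.
#' @param max_articles Overlooked-metabolite cutoff (strict).
#' @param fisher Run the Fisher/BH re-evaluation (default TRUE).
#' @param out_dir If non-NULL, write `predictions.tsv` and
#'   `summary.json` there.
#' @param verbose Print the scenario summary.
#' @return Invisibly, a list with `predictions` (data frame) and
#'   `summary` (scenario counts and settings).
#' @export
run_screen <- function(graph, corpus, cooc, descriptors = NULL,
                       targets = NULL, alpha = 0.4, nu = 1000,
                       logodds_min = 2, log2fc_min = 1, entropy_min = 1,
                       max_articles = 100, fisher = TRUE, out_dir = NULL,
                       verbose = TRUE) {
  if (is.null(descriptors)) descriptors <- names(cooc$m)
  if (length(descriptors) == 0) stop("no descriptors to screen")
  for (d in descriptors) {
    P <- descriptor_rate(cooc, d)
    if (P <= 0 || P >= 1) {
      stop(sprintf("descriptor %s has P = %g, outside (0, 1)", d, P))
    }
  }
  if (is.null(targets)) {
    targets <- names(corpus$n)[corpus$n < max_articles]
  }
  prop <- propagate(graph, corpus, alpha)
  recs <- vector("list", length(targets) * length(descriptors))
  i <- 0L
  for (d in sort(descriptors)) {
    for (k in sort(targets)) {
      i <- i + 1L
      recs[[i]] <- score_pair(prop, corpus, cooc, k, d, nu = nu)
    }
  }
  predictions <- do.call(rbind, recs)
  predictions <- apply_filters(predictions, logodds_min, log2fc_min,
                               entropy_min)
  if (fisher) {
    predictions <- fisher_reevaluate(predictions, corpus, cooc)
  }
  ord <- order(predictions$descriptor, -predictions$LogOdds,
               -predictions$Log2FC, predictions$metabolite)
  predictions <- predictions[ord, PREDICTION_COLUMNS, drop = FALSE]
  rownames(predictions) <- NULL

  smry <- screen_summary(predictions,
                         settings = list(alpha = alpha, nu = nu,
                                         logodds_min = logodds_min,
                                         log2fc_min = log2fc_min,
                                         entropy_min = entropy_min,
                                         max_articles = max_articles))
  if (verbose) print_screen_summary(smry)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_predictions(predictions, file.path(out_dir, "predictions.tsv"))
    jsonlite::write_json(smry, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(predictions = predictions, summary = smry))
}

# scenario counts in the shape of the screen's summary table:
# no-literature targets vs few-article targets split by co-mention
screen_summary <- function(predictions, settings = list()) {
  sc <- predictions$scenario
  list(
    n_pairs = nrow(predictions),
    n_pass = sum(predictions$passes_filter),
    scenarios = list(
      no_literature = sum(sc == "no_literature"),
      few_articles_comention = sum(sc == "few_articles" &
                                     predictions$y > 0),
      few_articles_no_comention = sum(sc == "few_articles" &
                                        predictions$y == 0),
      no_neighbor_literature = sum(sc == "no_neighbor_literature"),
      no_information = sum(sc == "no_information")
    ),
    pass_by_scenario = as.list(tapply(predictions$passes_filter, sc, sum)),
    settings = settings
  )
}

print_screen_summary <- function(smry) {
  cat(sprintf("screen: %d pairs scored, %d pass the thresholds\n",
              smry$n_pairs, smry$n_pass))
  s <- smry$scenarios
  cat(sprintf("  no literature: %d | few articles (co-mention yes/no): %d/%d | no neighborhood literature: %d | no information (discarded): %d\n",
              s$no_literature, s$few_articles_comention,
              s$few_articles_no_comention, s$no_neighbor_literature,
              s$no_information))
  invisible(smry)
}

#' Write a prediction table as TSV
#'
#' Fixed column order, `NA` encoded literally; the serialization is
#' byte-stable across runs on identical inputs.
#'
#' @param predictions Data frame from [run_screen()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  out <- predictions[, PREDICTION_COLUMNS, drop = FALSE]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) {
    ifelse(is.na(x), NA, format(x, digits = 15, trim = TRUE,
                                scientific = FALSE))
  })
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}
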