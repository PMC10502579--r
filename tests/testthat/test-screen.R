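test_that("scenario dispatch produces the four contracted record shapes", {
  fx <- scenario_fixture()
  prop <- propagate(fx$graph, fx$corpus, alpha = 0.4)

  # no literature, contributors available: prior-only predictors
  rec_c <- score_pair(prop, fx$corpus, fx$cooc, "c", "D1")
  expect_equal(rec_c$scenario, "no_literature")
  expect_true(is.na(rec_c$priorLogOdds) && is.na(rec_c$priorLog2FC))
  expect_false(is.na(rec_c$LogOdds))
  expect_false(is.na(rec_c$Entropy))

  # literature and contributors: posterior predictors plus prior belief
  rec_b <- score_pair(prop, fx$corpus, fx$cooc, "b", "D1")
  expect_equal(rec_b$scenario, "few_articles")
  expect_false(any(is.na(c(rec_b$LogOdds, rec_b$priorLogOdds,
                           rec_b$Log2FC, rec_b$priorLog2FC))))

  # literature but no neighborhood literature: degenerate conjugate route
  rec_f <- score_pair(prop, fx$corpus, fx$cooc, "f", "D1",
                      keep_mixtures = TRUE)
  expect_equal(rec_f$scenario, "no_neighbor_literature")
  expect_true(is.na(rec_f$Entropy))
  null <- null_component(rec_f$P, 1000)
  post_f <- attr(rec_f, "post")
  expect_equal(post_f$a, null$a + rec_f$y)
  expect_equal(post_f$b, null$b + rec_f$n - rec_f$y)

  # neither literature nor neighborhood: discarded
  rec_e <- score_pair(prop, fx$corpus, fx$cooc, "e", "D1")
  expect_equal(rec_e$scenario, "no_information")
  filtered <- apply_filters(rbind(rec_c, rec_b, rec_f, rec_e))
  expect_false(filtered$passes_filter[filtered$scenario == "no_information"])
})

test_that("a single-contributor prior makes the record equal its contributor's component", {
  g <- igraph::make_graph(~ a - b)
  corpus <- mention_corpus(c(a = 50), g)
  cooc <- cooccurrence_table(
    data.frame(metabolite = "a", descriptor = "D1", n_comentions = 10),
    corpus)
  # give the descriptor background mass via a second, detached component
  g2 <- igraph::add_vertices(g, 1, name = "z")
  corpus2 <- mention_corpus(c(a = 50, z = 1000), g2)
  cooc2 <- cooccurrence_table(
    data.frame(metabolite = c("a", "z"), descriptor = "D1",
               n_comentions = c(10, 10)),
    corpus2)
  prop <- propagate(g2, corpus2, alpha = 0)
  rec <- score_pair(prop, corpus2, cooc2, "b", "D1", keep_mixtures = TRUE)
  expect_equal(rec$scenario, "no_literature")
  prior <- attr(rec, "prior")
  post <- attr(rec, "post")
  expect_equal(prior$weights, 1)
  ind <- contributor_indicators(prior, post, rec$P)
  expect_equal(rec$Log2FC, ind$prior_Log2FC)
  expect_equal(rec$LogOdds, ind$prior_LogOdds)
})

test_that("masking a metabolite equals deleting its corpus rows, for every pair", {
  fx <- scenario_fixture()
  prop <- propagate(fx$graph, fx$corpus, alpha = 0.4)
  for (masked in c("a", "b", "d")) {
    del <- mask_corpus(fx$corpus, fx$cooc, masked, fx$graph)
    prop_del <- propagate(fx$graph, del$corpus, alpha = 0.4)
    for (target in igraph::V(fx$graph)$name) {
      rec_del <- score_pair(prop_del, del$corpus, del$cooc, target, "D1")
      rec_msk <- if (target == masked) {
        # shortcut: the target never enters its own prior, so masking it
        # needs no re-propagation
        score_pair(prop, fx$corpus, fx$cooc, target, "D1", mask = TRUE)
      } else {
        score_pair(prop_del, del$corpus, del$cooc, target, "D1")
      }
      expect_equal(rec_msk, rec_del)
    }
  }
})

test_that("screening thresholds are strict and NA-safe", {
  rec <- data.frame(LogOdds = c(2.5, 2.5, 2.0, 5, NA),
                    Log2FC = c(1.2, 1.2, 3.0, 1.0, 2),
                    Entropy = c(1.3, 1.0, 2.0, 1.5, 1.5),
                    scenario = "few_articles")
  out <- apply_filters(rec)
  expect_identical(out$passes_filter, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  # configurable thresholds
  out2 <- apply_filters(rec, logodds_min = 1.9, log2fc_min = 0.5,
                        entropy_min = 0.9)
  expect_identical(out2$passes_filter, c(TRUE, TRUE, TRUE, TRUE, FALSE))
})

test_that("right-tailed Fisher p matches exhaustive enumeration", {
  expect_equal(fisher_right_p(0, 10, 15, 1000), 1)  # empty tail
  cases <- rbind(
    c(y = 5, n = 10, m = 15, N = 1000),   # the (5, 5, 10, 980) table
    c(y = 1, n = 4, m = 3, N = 40),
    c(y = 3, n = 3, m = 3, N = 30),
    c(y = 2, n = 30, m = 50, N = 2000),
    c(y = 0, n = 7, m = 9, N = 100))
  for (r in seq_len(nrow(cases))) {
    cs <- as.list(cases[r, ])
    expect_equal(fisher_right_p(cs$y, cs$n, cs$m, cs$N),
                 fisher_enum_oracle(cs$y, cs$n, cs$m, cs$N),
                 tolerance = 1e-12)
    # and the textbook implementation agrees
    tab <- matrix(c(cs$y, cs$n - cs$y, cs$m - cs$y,
                    cs$N - cs$n - cs$m + cs$y), 2)
    expect_equal(fisher_right_p(cs$y, cs$n, cs$m, cs$N),
                 stats::fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("BH adjustment reproduces the step-up arithmetic", {
  fx <- scenario_fixture()
  prop <- propagate(fx$graph, fx$corpus, alpha = 0.4)
  recs <- do.call(rbind, lapply(c("a", "b", "d", "f"), function(k) {
    score_pair(prop, fx$corpus, fx$cooc, k, "D1")
  }))
  recs <- fisher_reevaluate(recs, fx$corpus, fx$cooc)
  expect_false(any(is.na(recs$fisher_p)))
  expect_equal(recs$fisher_q, p.adjust(recs$fisher_p, "BH"))
  # toy vector: p = (.01,.02,.03,.04) with m = 4 gives q = .04 throughout
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
})

test_that("a full screen is deterministic, ordered and correctly summarized", {
  fx <- scenario_fixture()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- run_screen(fx$graph, fx$corpus, fx$cooc, max_articles = 100,
                   out_dir = d1, verbose = FALSE)
  r2 <- run_screen(fx$graph, fx$corpus, fx$cooc, max_articles = 100,
                   out_dir = d2, verbose = FALSE)
  expect_identical(readLines(file.path(d1, "predictions.tsv")),
                   readLines(file.path(d2, "predictions.tsv")))
  expect_identical(readLines(file.path(d1, "summary.json")),
                   readLines(file.path(d2, "summary.json")))

  preds <- r1$predictions
  # overlooked rule is strict: n = 100 is excluded from default targets
  corpus_100 <- fx$corpus
  corpus_100$n[["a"]] <- 100
  corpus_100$N <- sum(corpus_100$n)
  r100 <- run_screen(fx$graph, corpus_100, fx$cooc, max_articles = 100,
                     verbose = FALSE)
  expect_false("a" %in% r100$predictions$metabolite)
  expect_true("a" %in% preds$metabolite)

  # ordering contract
  expect_true(!is.unsorted(preds$descriptor))
  # scenario counts equal an independent recount from the inputs
  sc <- r1$summary$scenarios
  n_targets <- names(fx$corpus$n)
  has_ctb <- vapply(n_targets, function(k) {
    length(propagate(fx$graph, fx$corpus, 0.4)$contributors[[k]]) > 0
  }, logical(1))
  n_k <- fx$corpus$n
  expect_equal(sc$no_literature, sum(has_ctb & n_k == 0))
  expect_equal(sc$no_information, sum(!has_ctb & n_k == 0))
  expect_equal(sc$no_neighbor_literature, sum(!has_ctb & n_k > 0))
  expect_equal(sc$few_articles_comention + sc$few_articles_no_comention,
               sum(has_ctb & n_k > 0))
})

test_that("run_screen refuses descriptors with degenerate background rates", {
  g <- path3()
  corpus <- mention_corpus(c(a = 10, b = 5), g)
  cooc <- cooccurrence_table(
    data.frame(metabolite = c("a", "b"), descriptor = "Dall",
               n_comentions = c(10, 5)),
    corpus)
  expect_error(run_screen(g, corpus, cooc, verbose = FALSE),
               "outside \\(0, 1\\)")
})
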