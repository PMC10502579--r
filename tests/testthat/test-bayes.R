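test_that("null component has mean P and variance P(1-P)/(1+nu)", {
  comp <- null_component(0.01, 1000)
  expect_equal(comp$a, 10)
  expect_equal(comp$b, 990)
  for (P in c(0.001, 0.2, 0.7)) {
    for (nu in c(10, 1000)) {
      cc <- null_component(P, nu)
      expect_equal(cc$a / (cc$a + cc$b), P)
      v <- cc$a * cc$b / ((cc$a + cc$b)^2 * (cc$a + cc$b + 1))
      expect_equal(v, P * (1 - P) / (1 + nu))
    }
  }
  expect_error(null_component(0, 1000), "P")
  expect_error(null_component(1, 1000), "P")
  expect_error(null_component(0.5, 0), "nu")
})

test_that("shrinkage is the conjugate update and vanishes with evidence size", {
  null <- null_component(0.01, 1000)
  expect_equal(shrink_component(0, 0, null), null)
  up <- shrink_component(100, 10, null)
  expect_equal(up$a, 20)
  expect_equal(up$b, 1080)
  expect_equal(up$a / (up$a + up$b), 20 / 1100)
  # small-n contributors are pulled toward P...
  small <- shrink_component(2, 1, null)
  expect_lt(small$a / (small$a + small$b), 0.02)
  # ...while a huge corpus recovers its raw rate
  big <- shrink_component(1e6, 0.3 * 1e6, null)
  expect_equal(big$a / (big$a + big$b), 0.3, tolerance = 1e-3)
  expect_error(shrink_component(5, 6, null), "exceeds")
})

test_that("prior mixture assembles weighted shrunken components", {
  null <- null_component(0.05, 100)
  ev <- data.frame(contributor = c("x", "y"), n = c(50, 0), y = c(10, 0))
  single <- build_prior(c(x = 1), ev, null)
  expect_equal(single$kind, "prior")
  sx <- shrink_component(50, 10, null)
  expect_equal(single$a, sx$a)
  expect_equal(single$b, sx$b)

  degen <- build_prior(setNames(numeric(0), character(0)),
                       ev[0, ], null)
  expect_equal(degen$kind, "degenerate")
  expect_equal(degen$a, null$a)

  mix <- build_prior(c(x = 0.6, y = 0.4), ev, null)
  # closed-form mean against numeric integration of the density
  quad <- stats::integrate(function(p) p * mixture_density(mix, p), 0, 1,
                           rel.tol = 1e-12)$value
  expect_equal(mixture_mean(mix), quad, tolerance = 1e-10)
  expect_error(build_prior(c(x = 0.6, y = 0.6), ev, null), "sum to 1")
  expect_error(build_prior(c(z = 1), ev, null), "missing evidence")
})

test_that("posterior update follows Bayes' rule (quadrature oracle)", {
  null <- null_component(0.02, 500)
  ev <- data.frame(contributor = c("x", "y"), n = c(40, 400),
                   y = c(8, 10))
  prior <- build_prior(c(x = 0.5, y = 0.5), ev, null)
  post <- posterior_mixture(prior, 30, 6)
  grid <- seq(1e-4, 1 - 1e-4, length.out = 2001)
  oracle <- posterior_grid_oracle(prior, 30, 6, grid)
  expect_lt(max(abs(mixture_density(post, grid) - oracle)), 1e-6)

  # randomized configurations (up to 6 components, shapes in [0.5, 500])
  for (seed in 1:40) {
    cfg <- litprop:::with_seed(seed, {
      k <- sample(1:6, 1)
      n_k <- sample(0:200, 1)
      list(a = runif(k, 0.5, 500), b = runif(k, 0.5, 500),
           w = {
             w <- runif(k)
             w / sum(w)
           },
           n_k = n_k, y_k = sample(0:n_k, 1))
    })
    prior <- litprop:::beta_mixture(sprintf("c%d", seq_along(cfg$w)),
                                    cfg$w, cfg$a, cfg$b, kind = "prior")
    post <- posterior_mixture(prior, cfg$n_k, cfg$y_k)
    oracle <- posterior_grid_oracle(prior, cfg$n_k, cfg$y_k, grid)
    expect_lt(max(abs(mixture_density(post, grid) - oracle)), 1e-6)
  }
})

test_that("no data leaves the prior untouched; single contributor keeps weight 1", {
  null <- null_component(0.02, 500)
  ev <- data.frame(contributor = c("x", "y"), n = c(40, 400), y = c(8, 10))
  prior <- build_prior(c(x = 0.3, y = 0.7), ev, null)
  post0 <- posterior_mixture(prior, 0, 0)
  expect_equal(post0$weights, prior$weights)
  expect_equal(post0$a, prior$a)
  expect_equal(post0$b, prior$b)

  single <- build_prior(c(x = 1), ev, null)
  expect_equal(posterior_mixture(single, 50, 20)$weights, 1)
})

test_that("the target's data dominates the posterior as its corpus grows", {
  # prior pseudo-mass (nu plus contributor corpora) must be dwarfed by
  # the target's corpus for the mean to converge to the observed rate
  null <- null_component(0.01, 100)
  ev <- data.frame(contributor = c("x", "y"), n = c(10, 20),
                   y = c(1, 3))
  prior <- build_prior(c(x = 0.5, y = 0.5), ev, null)
  r <- 0.25
  means <- vapply(c(1e3, 1e4, 1e5), function(n_big) {
    mixture_mean(posterior_mixture(prior, n_big, r * n_big))
  }, numeric(1))
  expect_true(all(diff(abs(means - r)) < 0))   # monotone convergence
  expect_lt(abs(means[3] - r), 1e-3)
})

test_that("degenerate prior yields the single conjugate posterior update", {
  null <- null_component(0.05, 100)
  degen <- build_prior(setNames(numeric(0), character(0)),
                       data.frame(contributor = character(0),
                                  n = numeric(0), y = numeric(0)), null)
  post <- posterior_mixture(degen, 30, 6)
  expect_equal(post$a, null$a + 6)
  expect_equal(post$b, null$b + 24)
  expect_equal(post$weights, 1)
})

test_that("mixture CDF matches the incomplete beta and quadrature", {
  unif <- litprop:::beta_mixture("u", 1, 1, 1, kind = "prior")
  expect_equal(mixture_cdf(unif, 0.3), 0.3)
  mix <- litprop:::beta_mixture(c("a", "b", "c"), c(0.2, 0.3, 0.5),
                                c(2, 30, 5), c(50, 3, 5), kind = "prior")
  expect_equal(mixture_cdf(mix, 0), 0)
  expect_equal(mixture_cdf(mix, 1), 1)
  P <- 0.1
  quad <- stats::integrate(function(p) mixture_density(mix, p), 0, P,
                           rel.tol = 1e-13)$value
  expect_equal(mixture_cdf(mix, P), quad, tolerance = 1e-10)
  expect_error(mixture_cdf(mix, 1.5), "\\[0, 1\\]")
})

test_that("predictors are symmetric at CDF = 0.5, scale as defined, and clamp", {
  # symmetric Beta around P = 0.5: log-odds exactly 0
  sym <- litprop:::beta_mixture("s", 1, 7, 7, kind = "prior")
  pr <- predictors(sym, 0.5)
  expect_equal(pr$LogOdds, 0)
  expect_equal(pr$Log2FC, 0)

  # mixture mean at 2P gives Log2FC = 1
  P <- 0.05
  comp <- null_component(2 * P, 1000)
  mix <- litprop:::beta_mixture("x", 1, comp$a, comp$b, kind = "prior")
  expect_equal(predictors(mix, P)$Log2FC, 1)

  # closed-form mean against quadrature
  expect_equal(mixture_mean(mix),
               stats::integrate(function(p) p * mixture_density(mix, p),
                                0, 1, rel.tol = 1e-12)$value,
               tolerance = 1e-10)

  # an extreme mixture clamps instead of returning +/- Inf
  far <- litprop:::beta_mixture("f", 1, 5000, 5, kind = "prior")
  pf <- predictors(far, 1e-4)
  expect_true(is.finite(pf$LogOdds))
  expect_lte(abs(pf$LogOdds), 709)
  expect_true(pf$clamped)

  # base-10 option rescales the log-odds
  mid <- litprop:::beta_mixture("m", 1, 30, 70, kind = "prior")
  expect_equal(predictors(mid, 0.2, log_base = 10)$LogOdds,
               predictors(mid, 0.2)$LogOdds / log(10))
})

test_that("per-contributor indicators recover component-level effects", {
  P <- 0.02
  null <- null_component(P, 1000)
  ev <- data.frame(contributor = c("bg", "hot"),
                   n = c(0, 1e6), y = c(0, 4 * P * 1e6))
  prior <- build_prior(c(bg = 0.5, hot = 0.5), ev, null)
  post <- posterior_mixture(prior, 10, 1)
  ind <- contributor_indicators(prior, post, P)
  bg <- ind[ind$contributor == "bg", ]
  hot <- ind[ind$contributor == "hot", ]
  expect_equal(bg$prior_Log2FC, 0, tolerance = 1e-6)
  expect_equal(hot$prior_Log2FC, 2, tolerance = 1e-2)
  # sign of the log-odds matches the one-sided incomplete-beta tail
  for (r in seq_len(nrow(ind))) {
    comp_a <- prior$a[prior$contributors == ind$contributor[r]]
    comp_b <- prior$b[prior$contributors == ind$contributor[r]]
    tail <- pbeta(P, comp_a, comp_b, lower.tail = FALSE)
    expect_equal(sign(ind$prior_LogOdds[r]), sign(tail - 0.5))
  }
})

test_that("co-mention evidence shifts posterior weight toward the higher-mean contributor", {
  # two components at equal concentration a + b, different means
  a1 <- 30; b1 <- 70   # mean 0.3
  a2 <- 10; b2 <- 90   # mean 0.1
  prior <- litprop:::beta_mixture(c("hi", "lo"), c(0.5, 0.5),
                                  c(a1, a2), c(b1, b2), kind = "prior")
  for (n_k in c(5, 20, 60)) {
    W_hi <- vapply(0:n_k, function(y_k) {
      post <- posterior_mixture(prior, n_k, y_k)
      post$weights[post$contributors == "hi"]
    }, numeric(1))
    expect_true(all(diff(W_hi) >= -1e-12))
  }
})

test_that("mixtures serialize to stable JSON with components sorted by id", {
  null <- null_component(0.05, 100)
  ev <- data.frame(contributor = c("z", "a"), n = c(10, 20), y = c(1, 2))
  mix <- build_prior(c(z = 0.7, a = 0.3), ev, null)
  expect_identical(mix$contributors, c("a", "z"))
  parsed <- jsonlite::fromJSON(mixture_to_json(mix, P = 0.05))
  expect_equal(parsed$components$contributor, c("a", "z"))
  expect_equal(parsed$components$weight, c(0.3, 0.7))
})
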