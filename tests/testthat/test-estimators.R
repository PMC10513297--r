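test_that("f_tilde drops the proband and scores the remaining carriers", {
  expect_equal(f_tilde(make_family(c(TRUE, TRUE), c(TRUE, TRUE)))$estimate, 1)
  expect_equal(f_tilde(make_family(c(TRUE, TRUE), c(TRUE, FALSE)))$estimate, 0)
  # families whose only carrier was the proband cannot be scored
  d <- dplyr::bind_rows(
    make_family(c(TRUE, FALSE), c(TRUE, FALSE), family = 1),
    make_family(c(TRUE, FALSE), c(TRUE, TRUE), family = 2)
  )
  res <- f_tilde(d)
  expect_true(is.na(res$estimate))
  expect_equal(res$n_noncontributing, 2)
  # mixed dataset: only the scorable family counts
  d2 <- dplyr::bind_rows(d, make_family(c(TRUE, TRUE), c(TRUE, TRUE),
                                        family = 3))
  res2 <- f_tilde(d2)
  expect_equal(res2$estimate, 1)
  expect_equal(res2$n_contributing, 1)
})

test_that("f_tilde_star scores all carriers including the proband", {
  expect_equal(f_tilde_star(make_family(c(TRUE, TRUE),
                                        c(TRUE, FALSE)))$estimate, 0.5)
  expect_equal(f_tilde_star(make_family(c(TRUE, FALSE),
                                        c(TRUE, FALSE)))$estimate, 1)
  # ascertained s = 2 data: per-family proportions are >= 1/2
  set.seed(13)
  d <- simulate_dataset(trait_model(0.05, 0), ascertainment_model(1, s = 2),
                        200)
  expect_gte(f_tilde_star(d)$estimate, 0.5)
  expect_equal(f_tilde_star(d)$n_noncontributing, 0)
})

test_that("pooled and per-family averaging differ as documented", {
  d <- dplyr::bind_rows(
    make_family(c(TRUE, TRUE), c(TRUE, TRUE), family = 1),
    make_family(c(TRUE, FALSE), c(TRUE, FALSE), family = 2)
  )
  # per-family: mean(1, 1) = 1; pooled: 3 affected carriers / 3 carriers
  expect_equal(f_tilde_star(d)$estimate, 1)
  expect_equal(f_tilde_star(d, pooled = TRUE)$estimate, 1)
  d2 <- dplyr::bind_rows(
    make_family(c(TRUE, TRUE), c(TRUE, FALSE), family = 1),
    make_family(c(TRUE, FALSE), c(TRUE, FALSE), family = 2)
  )
  # per-family: mean(0.5, 1) = 0.75; pooled: 2/3
  expect_equal(f_tilde_star(d2)$estimate, 0.75)
  expect_equal(f_tilde_star(d2, pooled = TRUE)$estimate, 2 / 3)
})

test_that("enumeration reproduces the exact k-sweep expectations", {
  trait <- trait_model(0.5, 0)
  exp_at <- function(k) {
    expected_estimates_exact(trait, ascertainment_model(k, s = 2))
  }
  e1 <- exp_at(1)
  expect_equal(e1$expectation[e1$estimator == "f_tilde"], 0.5)
  expect_equal(e1$expectation[e1$estimator == "f_tilde_star"], 7 / 8)
  e0 <- exp_at(0)
  expect_equal(e0$expectation[e0$estimator == "f_tilde"], 3 / 7)
  expect_equal(e0$expectation[e0$estimator == "f_tilde_star"], 13 / 15)
  e2 <- exp_at(2)
  expect_equal(e2$expectation[e2$estimator == "f_tilde"], 0.6)
  expect_equal(e2$expectation[e2$estimator == "f_tilde_star"], 8 / 9)
  em1 <- exp_at(-1)
  expect_equal(em1$expectation[em1$estimator == "f_tilde"], 2.5 / 6.5)
  expect_equal(em1$expectation[em1$estimator == "f_tilde_star"], 12.5 / 14.5)
})

test_that("f_tilde is exactly unbiased under single ascertainment", {
  for (f in c(0.05, 0.2, 0.5, 0.8, 1)) {
    e <- expected_estimates_exact(trait_model(f, 0),
                                  ascertainment_model(1, s = 2))
    expect_equal(e$expectation[e$estimator == "f_tilde"], f,
                 tolerance = 1e-12)
  }
  # also at larger sibship sizes
  e5 <- expected_estimates_exact(trait_model(0.3, 0),
                                 ascertainment_model(1, s = 5))
  expect_equal(e5$expectation[e5$estimator == "f_tilde"], 0.3,
               tolerance = 1e-12)
})

test_that("expected f_tilde increases with the ascertainment exponent", {
  vals <- sapply(c(-1, 0, 1, 2), function(k) {
    e <- expected_estimates_exact(trait_model(0.5, 0),
                                  ascertainment_model(k, s = 2))
    e$expectation[e$estimator == "f_tilde"]
  })
  expect_true(all(diff(vals) > 0))
  expect_equal(round(vals, 2), c(0.38, 0.43, 0.50, 0.60))
})

test_that("simulation means agree with enumeration across a parameter grid", {
  set.seed(202)
  grid <- expand.grid(f = c(0.2, 0.5), gamma = c(0, 0.1), k = c(0, 1))
  n_rep <- 300
  for (i in seq_len(nrow(grid))) {
    trait <- trait_model(grid$f[i], grid$gamma[i])
    asc <- ascertainment_model(grid$k[i], s = 2)
    ex <- expected_estimates_exact(trait, asc)
    vals_t <- vals_s <- numeric(n_rep)
    for (r in seq_len(n_rep)) {
      d <- simulate_dataset(trait, asc, 30)
      vals_t[r] <- f_tilde(d)$estimate
      vals_s[r] <- f_tilde_star(d)$estimate
    }
    for (est in c("f_tilde", "f_tilde_star")) {
      v <- if (est == "f_tilde") vals_t else vals_s
      v <- v[!is.na(v)]
      mc_se <- sd(v) / sqrt(length(v))
      expect_lt(abs(mean(v) - ex$expectation[ex$estimator == est]),
                3 * mc_se + 1e-8)
    }
  }
})

test_that("enumeration guards its inputs", {
  expect_error(
    expected_estimates_exact(trait_model(0.5), ascertainment_model(1, s = 2),
                             s = 13),
    "s <= 12"
  )
})
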