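test_that("hand-derived family likelihoods are reproduced exactly", {
  m <- two_locus_model(penetrances = c(0.5, 0.5, 0))
  qq <- make_family(c(TRUE, TRUE), c(TRUE, TRUE))
  # complete coupling, theta = 0: each sib inherits the V-D haplotype with
  # probability 1/2 and is then affected with probability f
  expect_equal(family_likelihood(qq, m)$likelihood, (0.5 / 2)^2)
  # unlinked model: markers factorize, P(both sibs Vv | Vv x vv) = 1/4
  never_aff <- two_locus_model(penetrances = c(0, 0, 0))
  un <- make_family(c(TRUE, TRUE), c(FALSE, FALSE))
  expect_equal(family_likelihood(un, never_aff, linked = FALSE)$likelihood,
               1 / 4)
  expect_equal(family_likelihood(un, never_aff, linked = TRUE)$likelihood,
               1 / 4)
})

test_that("the joint likelihood sums to one over the outcome space", {
  set.seed(55)
  s <- 2
  outcomes <- expand.grid(c1 = c(TRUE, FALSE), c2 = c(TRUE, FALSE),
                          a1 = c(TRUE, FALSE), a2 = c(TRUE, FALSE))
  for (i in 1:20) {
    m <- random_two_locus_model()
    tot <- sum(sapply(seq_len(nrow(outcomes)), function(j) {
      fam <- make_family(c(outcomes$c1[j], outcomes$c2[j]),
                         c(outcomes$a1[j], outcomes$a2[j]), proband_idx = 1)
      family_likelihood(fam, m)$likelihood
    }))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("family likelihood agrees with the brute-force oracle", {
  set.seed(66)
  for (i in 1:12) {
    m <- random_two_locus_model()
    s <- sample(1:3, 1)
    carrier <- runif(s) < 0.5
    affected <- runif(s) < 0.5
    fam <- make_family(carrier, affected, proband_idx = 1)
    for (linked in c(TRUE, FALSE)) {
      mine <- family_likelihood(fam, m, linked = linked)$likelihood
      ref <- oracle_family_likelihood(
        carrier, affected, m$penetrances, m$p, m$q,
        if (linked) m$dprime else 0, if (linked) m$theta else 0.5
      )
      expect_equal(mine, ref, tolerance = 1e-12)
      mine_c <- family_likelihood(fam, m, linked = linked,
                                  conditional = TRUE)$likelihood
      ref_c <- oracle_family_likelihood(
        carrier, affected, m$penetrances, m$p, m$q,
        if (linked) m$dprime else 0, if (linked) m$theta else 0.5,
        conditional = TRUE
      )
      expect_equal(mine_c, ref_c, tolerance = 1e-12)
    }
  }
})

test_that("dataset log-likelihood collapses admixture limits correctly", {
  set.seed(77)
  d <- simulate_dataset(trait_model(0.6, 0.05), ascertainment_model(1, s = 2),
                        15)
  pen <- c(0.6, 0.6, 0.05)
  m_a0 <- two_locus_model(penetrances = pen, alpha = 0)
  m_a1 <- two_locus_model(penetrances = pen, alpha = 1)
  unlinked_ll <- sum(log10(family_likelihood(d, m_a1,
                                             linked = FALSE)$likelihood))
  linked_ll <- sum(log10(family_likelihood(d, m_a1,
                                           linked = TRUE)$likelihood))
  expect_equal(dataset_log_likelihood(d, m_a0), unlinked_ll)
  expect_equal(dataset_log_likelihood(d, m_a1), linked_ll)
})

test_that("dataset log-likelihood is additive over concatenated datasets", {
  set.seed(78)
  d1 <- simulate_dataset(trait_model(0.4, 0.1), ascertainment_model(1, s = 2),
                         10)
  d2 <- simulate_dataset(trait_model(0.4, 0.1), ascertainment_model(1, s = 2),
                         8)
  d2$family <- d2$family + 10L
  m <- two_locus_model(penetrances = c(0.4, 0.4, 0.1), alpha = 0.8)
  both <- dplyr::bind_rows(d1, d2)
  expect_equal(dataset_log_likelihood(both, m),
               dataset_log_likelihood(d1, m) + dataset_log_likelihood(d2, m))
  expect_equal(ld_lod(both, m), ld_lod(d1, m) + ld_lod(d2, m))
})

test_that("the LOD vanishes when the numerator equals the null", {
  set.seed(79)
  d <- simulate_dataset(trait_model(0.5, 0), ascertainment_model(1, s = 2), 12)
  null_model <- two_locus_model(dprime = 0, theta = 0.5,
                                penetrances = c(0.5, 0.5, 0))
  expect_equal(ld_lod(d, null_model), 0)
  a0 <- two_locus_model(penetrances = c(0.5, 0.5, 0), alpha = 0)
  expect_equal(ld_lod(d, a0), 0)
  le_half <- two_locus_model(theta = 0.5, penetrances = c(0.5, 0.5, 0))
  expect_equal(le_lod(d, le_half), 0)
})

test_that("LE-LOD of a doubly-affected carrier pair matches the rare-q value", {
  # sum over which parent carries D (each ~1/2 given a rare allele) and
  # phase (1/2 each): P(markers | both affected) -> 3/8 against a null of
  # 1/4, i.e. log10(1.5), exact as q -> 0
  qq <- make_family(c(TRUE, TRUE), c(TRUE, TRUE))
  m <- two_locus_model(penetrances = c(0.5, 0.5, 0))
  val <- le_lod(qq, m)
  expect_lt(abs(val - log10(1.5)), 2e-3)
  # and equals the independently coded oracle exactly
  num <- oracle_family_likelihood(c(TRUE, TRUE), c(TRUE, TRUE),
                                  m$penetrances, dprime = 0, theta = 0,
                                  conditional = TRUE)
  den <- oracle_family_likelihood(c(TRUE, TRUE), c(TRUE, TRUE),
                                  m$penetrances, dprime = 0, theta = 0.5,
                                  conditional = TRUE)
  expect_equal(val, log10(num / den), tolerance = 1e-12)
})

test_that("collapsed-configuration evaluation equals the naive per-family sum", {
  set.seed(88)
  d <- simulate_dataset(trait_model(0.5, 0.1), ascertainment_model(0, s = 2),
                        40)
  m <- two_locus_model(penetrances = c(0.7, 0.7, 0.1), alpha = 0.9)
  naive <- sum(log10(
    m$alpha * family_likelihood(d, m, conditional = TRUE)$likelihood +
      (1 - m$alpha) * family_likelihood(d, m, linked = FALSE,
                                        conditional = TRUE)$likelihood
  )) - sum(log10(family_likelihood(d, m, linked = FALSE,
                                   conditional = TRUE)$likelihood))
  expect_equal(ld_lod(d, m), naive, tolerance = 1e-10)
})

test_that("the MOD dominates the LOD at any fixed model", {
  set.seed(99)
  for (i in 1:4) {
    d <- simulate_dataset(trait_model(0.5, 0), ascertainment_model(1, s = 2),
                          20)
    fit <- maximize_ld_lod(d)
    gen <- two_locus_model(penetrances = c(0.5, 0.5, 0), alpha = 1)
    expect_gte(fit$ld_mod, ld_lod(d, gen) - 1e-9)
    expect_gte(fit$ld_mod, ld_lod(d, fit$model) - 1e-9)
    expect_true(fit$f_hat >= 0 && fit$f_hat <= 1)
    expect_equal(le_lod_max_from_fit <- fit$le_lod_max,
                 le_lod(d, fit$model), tolerance = 1e-9)
  }
})

test_that("f_hat concentrates around f as the number of families grows", {
  set.seed(111)
  mean_at <- function(n_fam, reps) {
    vals <- replicate(reps, {
      d <- simulate_dataset(trait_model(0.5, 0), ascertainment_model(1, s = 2),
                            n_fam)
      maximize_ld_lod(d)$f_hat
    })
    c(mean = mean(vals), se = sd(vals) / sqrt(reps))
  }
  small <- mean_at(20, 30)
  large <- mean_at(500, 15)
  expect_lt(abs(large[["mean"]] - 0.5), abs(small[["mean"]] - 0.5) + 0.05)
  expect_lt(abs(large[["mean"]] - 0.5), 3 * large[["se"]] + 0.01)
})

test_that("le_lod_max wrapper matches the fit field", {
  set.seed(121)
  d <- simulate_dataset(trait_model(0.5, 0), ascertainment_model(1, s = 2), 15)
  set.seed(1); v1 <- le_lod_max(d)
  set.seed(1); fit <- maximize_ld_lod(d)
  expect_equal(v1, fit$le_lod_max)
})
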