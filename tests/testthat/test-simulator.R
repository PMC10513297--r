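test_that("simulation is deterministic given a seed", {
  trait <- trait_model(0.5, 0.1)
  asc <- ascertainment_model(1, s = 3)
  set.seed(123)
  d1 <- simulate_dataset(trait, asc, 25)
  set.seed(123)
  d2 <- simulate_dataset(trait, asc, 25)
  expect_identical(d1, d2)
  set.seed(123)
  n1 <- simulate_null_dataset(trait, asc, 25)
  set.seed(123)
  n2 <- simulate_null_dataset(trait, asc, 25)
  expect_identical(n1, n2)
})

test_that("deterministic penetrance produces deterministic phenotypes", {
  set.seed(5)
  d <- simulate_dataset(trait_model(1, 0), ascertainment_model(1, s = 3), 40)
  expect_true(all(d$affected == d$carrier))
})

test_that("ascertained datasets satisfy their structural contract", {
  set.seed(9)
  d <- simulate_dataset(trait_model(0.3, 0.2), ascertainment_model(0, s = 2),
                        30)
  fc <- dplyr::count(d, family)
  expect_equal(nrow(fc), 30)
  expect_true(all(fc$n == 2)) # shared sibship size
  pro <- d[d$proband, ]
  expect_equal(nrow(pro), 30) # exactly one proband per family
  expect_true(all(pro$carrier & pro$affected)) # proband is a QI
  per_fam <- dplyr::summarise(dplyr::group_by(d, family),
                              r = sum(carrier & affected))
  expect_true(all(per_fam$r >= 1))
})

test_that("ascertainment is impossible without any cause of disease", {
  expect_error(
    simulate_dataset(trait_model(0, 0), ascertainment_model(1, s = 2), 5),
    "impossible"
  )
})

test_that("ascertain() matches the k-model weight on fixed sibships", {
  asc <- ascertainment_model(1, s = 2) # c = 1/4
  qi_qi <- tibble::tibble(carrier = c(TRUE, TRUE), affected = c(TRUE, TRUE))
  qi_cu <- tibble::tibble(carrier = c(TRUE, TRUE), affected = c(TRUE, FALSE))
  no_qi <- tibble::tibble(carrier = c(FALSE, TRUE), affected = c(TRUE, FALSE))
  set.seed(31)
  expect_true(all(replicate(50, ascertain(qi_qi, asc)))) # weight (2+2)/4 = 1
  n <- 4000
  acc <- mean(replicate(n, ascertain(qi_cu, asc))) # weight (1+1)/4 = 0.5
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / n))
  expect_false(any(replicate(50, ascertain(no_qi, asc)))) # r = 0: never
})

test_that("accepted family configurations match the enumeration oracle", {
  # s = 2, f = 0.5, gamma = 0: unascertained probabilities 1/16, 2/16, 4/16
  # for (QI,QI), (QI,carrier-unaffected), (QI,non-carrier), reweighted by
  # the k-model weight and renormalized.
  cases <- list(
    list(k = 1, expected = c(qq = 0.25, qc = 0.25, qn = 0.50)),
    list(k = 0, expected = c(qq = 0.20, qc = 4 / 15, qn = 8 / 15))
  )
  set.seed(77)
  n <- 4000
  for (cs in cases) {
    d <- simulate_dataset(trait_model(0.5, 0),
                          ascertainment_model(cs$k, s = 2), n)
    cfg <- dplyr::summarise(
      dplyr::group_by(d, family),
      type = dplyr::case_when(
        sum(carrier & affected) == 2 ~ "qq",
        sum(carrier) == 2 ~ "qc",
        TRUE ~ "qn"
      ),
      .groups = "drop"
    )
    freq <- table(factor(cfg$type, levels = c("qq", "qc", "qn"))) / n
    for (nm in names(cs$expected)) {
      p0 <- cs$expected[[nm]]
      expect_lt(abs(freq[[nm]] - p0), 3 * sqrt(p0 * (1 - p0) / n))
    }
  }
})

test_that("null generator matches its enumeration oracle", {
  # under the null, affection is driven by an unlinked causal allele, so a
  # sib is (marker-carrier, affected) with probability 1/2 * (beta+gamma)/2
  # independently; ascertainment then reweights configurations by r^k + t.
  set.seed(101)
  trait <- trait_model(0.5, 0)
  n <- 4000
  d <- simulate_null_dataset(trait, ascertainment_model(1, s = 2), n)
  # probands are still marker-QIs by construction
  expect_true(all(d$carrier[d$proband] & d$affected[d$proband]))
  expected <- oracle_config_dist_s2(state_probs_null(trait), k = 1)
  cfg <- dplyr::summarise(
    dplyr::group_by(d, family),
    key = paste(sort(paste0(ifelse(carrier, "M", "m"),
                            ifelse(affected, "A", "U"))), collapse = "|"),
    .groups = "drop"
  )
  freq <- table(factor(cfg$key, levels = names(expected))) / n
  for (nm in names(expected)) {
    tol <- 3 * sqrt(expected[[nm]] * (1 - expected[[nm]]) / n) + 1e-9
    expect_lt(abs(freq[[nm]] - expected[[nm]]), tol)
  }
  # the unaffected co-sib carries the marker with probability exactly 1/2
  co <- d[!d$proband, ]
  p_cu <- mean(co$carrier[!co$affected])
  expect_lt(abs(p_cu - 0.5), 3 * sqrt(0.25 / sum(!co$affected)))
})
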