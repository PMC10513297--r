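# Counting estimators of penetrance and their exact ascertainment-weighted
# expectations by enumeration.

#' Single-ascertainment-corrected counting estimator
#'
#' The classical "drop the proband" correction: within each family the
#' designated proband (a qualifying individual) is removed, and the
#' proportion of affected individuals among the remaining carrier sibs is
#' computed. Families whose only carrier was the proband cannot be scored
#' and are excluded, effectively reducing the sample size. The estimate is
#' the mean of per-family proportions over contributing families (or, with
#' `pooled = TRUE`, the pooled proportion across all remaining carriers).
#' This estimator is unbiased under true single ascertainment (`k = 1`)
#' with no phenocopies, and biased under other ascertainment models.
#'
#' @param data A sibship dataset (tibble with `family`, `carrier`,
#'   `affected`, `proband` columns), e.g. from [simulate_dataset()].
#' @param pooled Pool individuals across families instead of averaging
#'   per-family proportions? Default `FALSE` (per-family averaging).
#' @return A one-row tibble: `estimate` (`NA` if no family contributes),
#'   `n_families`, `n_contributing`, `n_noncontributing`.
#' @examples
#' set.seed(1)
#' d <- simulate_dataset(trait_model(0.5), ascertainment_model(1, s = 2), 100)
#' f_tilde(d)
#' @export
f_tilde <- function(data, pooled = FALSE) {
  if (!all(c("family", "carrier", "affected", "proband") %in% names(data))) {
    stop("`data` must have family, carrier, affected and proband columns.",
         call. = FALSE)
  }
  if (any(is.na(data$proband))) {
    stop("Every family needs a designated proband to compute f_tilde.",
         call. = FALSE)
  }
  per_fam <- data |>
    dplyr::filter(!.data$proband) |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(
      n_carrier = sum(.data$carrier),
      n_aff_carrier = sum(.data$carrier & .data$affected),
      .groups = "drop"
    )
  # families whose sibs are all probands (s = 1) drop out of per_fam too
  n_families <- dplyr::n_distinct(data$family)
  contributing <- per_fam[per_fam$n_carrier > 0, ]
  n_contributing <- nrow(contributing)
  est <- if (n_contributing == 0L) {
    NA_real_
  } else if (pooled) {
    sum(contributing$n_aff_carrier) / sum(contributing$n_carrier)
  } else {
    mean(contributing$n_aff_carrier / contributing$n_carrier)
  }
  tibble::tibble(estimate = est,
                 n_families = n_families,
                 n_contributing = n_contributing,
                 n_noncontributing = n_families - n_contributing)
}

#' Naive (uncorrected) counting estimator
#'
#' The proportion of affected individuals among all carrier sibs, proband
#' included — no ascertainment correction at all. Every ascertained family
#' contains at least one carrier (its qualifying individual), so all
#' families contribute; the per-family proportion is therefore at least
#' `1/s`, which is why this estimator is severely inflated under
#' ascertainment.
#'
#' @inheritParams f_tilde
#' @return A one-row tibble: `estimate`, `n_families`, `n_contributing`,
#'   `n_noncontributing` (always 0 on ascertained data).
#' @export
f_tilde_star <- function(data, pooled = FALSE) {
  if (!all(c("family", "carrier", "affected") %in% names(data))) {
    stop("`data` must have family, carrier and affected columns.",
         call. = FALSE)
  }
  per_fam <- data |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(
      n_carrier = sum(.data$carrier),
      n_aff_carrier = sum(.data$carrier & .data$affected),
      .groups = "drop"
    )
  n_families <- nrow(per_fam)
  contributing <- per_fam[per_fam$n_carrier > 0, ]
  est <- if (nrow(contributing) == 0L) {
    NA_real_
  } else if (pooled) {
    sum(contributing$n_aff_carrier) / sum(contributing$n_carrier)
  } else {
    mean(contributing$n_aff_carrier / contributing$n_carrier)
  }
  tibble::tibble(estimate = est,
                 n_families = n_families,
                 n_contributing = nrow(contributing),
                 n_noncontributing = n_families - nrow(contributing))
}

#' Exact expectations of the counting estimators by enumeration
#'
#' Enumerates every per-sib configuration of an `s`-sized sibship by its
#' counts of (QI, carrier-unaffected, non-carrier affected, non-carrier
#' unaffected) sibs, weights each by its generating probability under the
#' trait model times the ascertainment weight `(r^k + t)` (restricted to
#' `r >= 1`; the normalizing constant cancels), and returns the
#' ascertainment-weighted expectations of the per-family proportions
#' underlying [f_tilde()] and [f_tilde_star()]. For `f_tilde` the
#' expectation is renormalized over contributing configurations (those with
#' a carrier left after dropping the proband); dropping any uniformly
#' chosen QI removes exactly one affected carrier, so the proband draw does
#' not enter the value.
#'
#' @param trait A [trait_model()].
#' @param asc An [ascertainment_model()].
#' @param s Sibship size; enumeration is guarded at `s <= 12`.
#' @return A tibble with one row per estimator: `estimator`, `expectation`,
#'   and `prob_contributing` (ascertained-family probability of
#'   contributing to the estimator).
#' @examples
#' expected_estimates_exact(trait_model(0.5), ascertainment_model(1, s = 2))
#' @export
expected_estimates_exact <- function(trait, asc, s = asc$s) {
  stopifnot(inherits(trait, "trait_model"),
            inherits(asc, "ascertainment_model"))
  if (s < 1 || s > 12) {
    stop("Enumeration is supported for 1 <= s <= 12.", call. = FALSE)
  }
  state_prob <- c(qi = 0.5 * trait$beta,
                  carrier_unaff = 0.5 * (1 - trait$beta),
                  noncarrier_aff = 0.5 * trait$gamma,
                  noncarrier_unaff = 0.5 * (1 - trait$gamma))

  counts <- expand.grid(n_qi = 0:s, n_cu = 0:s, n_na = 0:s)
  counts <- counts[rowSums(counts) <= s, , drop = FALSE]
  counts$n_nu <- s - rowSums(counts)
  counts <- counts[counts$n_qi >= 1, , drop = FALSE] # r >= 1 to ascertain
  if (nrow(counts) == 0L) {
    stop("No configuration is ascertainable.", call. = FALSE)
  }

  log_multinom <- lgamma(s + 1) -
    (lgamma(counts$n_qi + 1) + lgamma(counts$n_cu + 1) +
       lgamma(counts$n_na + 1) + lgamma(counts$n_nu + 1))
  with_log <- function(n, p) ifelse(n == 0, 0, n * log(p))
  log_p <- log_multinom +
    with_log(counts$n_qi, state_prob["qi"]) +
    with_log(counts$n_cu, state_prob["carrier_unaff"]) +
    with_log(counts$n_na, state_prob["noncarrier_aff"]) +
    with_log(counts$n_nu, state_prob["noncarrier_unaff"])
  prob <- exp(log_p)

  r <- counts$n_qi
  t <- counts$n_qi + counts$n_na
  w <- prob * (r^asc$k + t)
  if (sum(w) <= 0) {
    stop("No configuration is ascertainable under this model.", call. = FALSE)
  }

  n_carrier <- counts$n_qi + counts$n_cu
  val_star <- counts$n_qi / n_carrier # n_carrier >= r >= 1
  e_star <- sum(w * val_star) / sum(w)

  contrib <- n_carrier >= 2
  e_tilde <- if (!any(contrib)) {
    NA_real_
  } else {
    val_tilde <- (counts$n_qi[contrib] - 1) / (n_carrier[contrib] - 1)
    sum(w[contrib] * val_tilde) / sum(w[contrib])
  }

  tibble::tibble(
    estimator = c("f_tilde", "f_tilde_star"),
    expectation = c(e_tilde, e_star),
    prob_contributing = c(sum(w[contrib]) / sum(w), 1)
  )
}
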