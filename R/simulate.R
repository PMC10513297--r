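# Sibship simulator: rejection sampling under the k-model of ascertainment.
#
# Every simulated family is a nuclear family with one marker-heterozygous
# parent (Vv, the father by convention) and one non-carrier parent (vv);
# two-carrier matings are negligible for a very rare variant. Parents'
# phenotypes are always unknown.

new_sibship_data <- function(df, provenance) {
  out <- tibble::as_tibble(df)
  attr(out, "provenance") <- provenance
  out
}

#' Provenance of a simulated dataset
#'
#' @param data A dataset produced by [simulate_dataset()].
#' @return The list of generating parameters attached to the dataset, or
#'   `NULL` for data not produced by the simulator.
#' @export
provenance <- function(data) {
  attr(data, "provenance")
}

# Simulate one batch of `b` unascertained sibships; returns carrier and
# affected as s x b logical matrices. Under the null generator the
# phenotype is driven by an unlinked biallelic causal locus, heterozygous
# in the marker-carrier parent, transmitted independently of the marker.
simulate_batch <- function(trait, s, b, null = FALSE) {
  carrier <- matrix(runif(s * b) < 0.5, nrow = s)
  risk_carrier <- if (null) {
    matrix(runif(s * b) < 0.5, nrow = s) # unlinked causal allele
  } else {
    carrier
  }
  prob <- ifelse(risk_carrier, trait$beta, trait$gamma)
  affected <- matrix(runif(s * b) < prob, nrow = s)
  list(carrier = carrier, affected = affected)
}

#' Simulate one unascertained sibship
#'
#' Each sib independently inherits the variant from the single heterozygous
#' parent with probability 1/2; carriers are affected with probability
#' `beta = gamma + f - gamma * f` and non-carriers with probability `gamma`.
#'
#' @param trait A [trait_model()].
#' @param s Sibship size.
#' @return A tibble with one row per sib and logical columns `carrier` and
#'   `affected`.
#' @examples
#' set.seed(1)
#' simulate_sibship(trait_model(0.5), s = 4)
#' @export
simulate_sibship <- function(trait, s = 2) {
  stopifnot(inherits(trait, "trait_model"))
  b <- simulate_batch(trait, s, 1L)
  tibble::tibble(sib = seq_len(s),
                 carrier = as.vector(b$carrier),
                 affected = as.vector(b$affected))
}

#' Ascertainment decision for one sibship
#'
#' Bernoulli draw with probability `c * (r^k + t)` when the sibship contains
#' at least one qualifying individual (carrier and affected), and certain
#' rejection otherwise.
#'
#' @param sibship A one-sibship tibble as from [simulate_sibship()] (logical
#'   columns `carrier`, `affected`).
#' @param asc An [ascertainment_model()].
#' @return `TRUE` if the sibship is ascertained.
#' @export
ascertain <- function(sibship, asc) {
  r <- sum(sibship$carrier & sibship$affected)
  t <- sum(sibship$affected)
  runif(1) < ascertainment_prob(asc, r, t)
}

#' Simulate an ascertained sibship dataset
#'
#' Repeats simulate-then-accept rejection sampling until `n_families`
#' sibships have been ascertained under the k-model weight `c * (r^k + t)`,
#' then designates in each family a proband drawn uniformly at random from
#' its qualifying individuals (carrier and affected sibs). With
#' `null = TRUE` the phenotype is generated by an unlinked causal locus
#' (heterozygous in the marker-carrier parent, transmitted independently of
#' the marker) with the same `f` and `gamma`, while ascertainment still
#' requires a marker-carrier affected sib — the no-linkage / no-LD null.
#'
#' @param trait A [trait_model()].
#' @param asc An [ascertainment_model()].
#' @param n_families Number of ascertained families to produce.
#' @param s Sibship size (all families share it).
#' @param null Generate under the unlinked-causal-locus null hypothesis?
#' @return A tibble with one row per sib: `family`, `sib`, `carrier`
#'   (marker heterozygote), `affected`, `proband`, and parental marker
#'   genotypes `father_gt` (`"Vv"`), `mother_gt` (`"vv"`). Generating
#'   parameters are attached as a `provenance` attribute.
#' @examples
#' set.seed(7)
#' d <- simulate_dataset(trait_model(0.5), ascertainment_model(1, s = 2),
#'                       n_families = 5)
#' d
#' @export
simulate_dataset <- function(trait, asc, n_families, s = asc$s, null = FALSE) {
  stopifnot(inherits(trait, "trait_model"),
            inherits(asc, "ascertainment_model"))
  if (n_families < 1) stop("`n_families` must be >= 1.", call. = FALSE)
  if (trait$beta == 0) {
    stop("Ascertainment is impossible: f = 0 and gamma = 0 produce no ",
         "qualifying individuals.", call. = FALSE)
  }
  carrier_acc <- list()
  affected_acc <- list()
  got <- 0L
  batch_size <- max(2000L, 20L * n_families)
  while (got < n_families) {
    b <- simulate_batch(trait, s, batch_size, null = null)
    r <- colSums(b$carrier & b$affected)
    t <- colSums(b$affected)
    keep <- runif(batch_size) < ascertainment_prob(asc, r, t)
    if (any(keep)) {
      carrier_acc[[length(carrier_acc) + 1L]] <- b$carrier[, keep, drop = FALSE]
      affected_acc[[length(affected_acc) + 1L]] <- b$affected[, keep, drop = FALSE]
      got <- got + sum(keep)
    }
  }
  carrier <- do.call(cbind, carrier_acc)[, seq_len(n_families), drop = FALSE]
  affected <- do.call(cbind, affected_acc)[, seq_len(n_families), drop = FALSE]

  qi <- carrier & affected
  proband <- matrix(FALSE, nrow = s, ncol = n_families)
  for (j in seq_len(n_families)) {
    idx <- which(qi[, j])
    pick <- if (length(idx) == 1L) idx else idx[sample.int(length(idx), 1L)]
    proband[pick, j] <- TRUE
  }

  new_sibship_data(
    tibble::tibble(
      family = rep(seq_len(n_families), each = s),
      sib = rep(seq_len(s), times = n_families),
      carrier = as.vector(carrier),
      affected = as.vector(affected),
      proband = as.vector(proband),
      father_gt = "Vv",
      mother_gt = "vv"
    ),
    provenance = list(trait = trait, asc = asc, s = s,
                      n_families = n_families, null = null)
  )
}

#' Simulate a dataset under the no-linkage / no-LD null
#'
#' Convenience wrapper for `simulate_dataset(..., null = TRUE)`: the marker
#' is neutral and an unlinked familial cause with the same `f` and `gamma`
#' drives the phenotype, but families are still ascertained through a
#' marker-carrier affected sib.
#'
#' @inheritParams simulate_dataset
#' @return As [simulate_dataset()].
#' @export
simulate_null_dataset <- function(trait, asc, n_families, s = asc$s) {
  simulate_dataset(trait, asc, n_families, s = s, null = TRUE)
}

# family counts r (QI) and t (affected) as a per-family tibble
family_counts <- function(data) {
  dplyr::summarise(
    dplyr::group_by(data, .data$family),
    s = dplyr::n(),
    r = sum(.data$carrier & .data$affected),
    t = sum(.data$affected),
    .groups = "drop"
  )
}
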