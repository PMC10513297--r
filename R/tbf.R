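# Proband-conditioned Bayes factor for co-segregation (log10 scale).
#
# Operationalization: the correction for single ascertainment through a
# qualifying proband divides each family's likelihood ratio by the same
# ratio computed on the proband alone (treated as a one-sib family, still
# conditional on the parental marker genotypes). The statistic is then
# exactly the LD-LOD of the full data minus the LD-LOD of the probands,
# and collapses to 0 on one-child sibships.

check_probands <- function(data) {
  if (is.null(data$proband) || any(is.na(data$proband))) {
    stop("Every family needs a designated proband to compute the TBF.",
         call. = FALSE)
  }
  pro <- data[data$proband, , drop = FALSE]
  if (nrow(pro) != dplyr::n_distinct(data$family) ||
      any(!(pro$carrier & pro$affected))) {
    stop("Each family must have exactly one proband, and the proband must ",
         "be a qualifying individual (carrier and affected).", call. = FALSE)
  }
  invisible(data)
}

# summed log10 proband corrections at one parameter vector
proband_correction <- function(prep, pen, alpha) {
  pm <- pen_to_mat(pen)
  total <- 0
  for (g in prep$groups) {
    for (st in g$proband_states) {
      p_link <- cond_likelihoods(g$tab_link, list(st), pm)
      p_null <- cond_likelihoods(g$tab_null, list(st), pm)
      contrib <- slog10(alpha * p_link + (1 - alpha) * p_null) -
        slog10(p_null)
      if (is.nan(contrib)) contrib <- -Inf
      total <- total + st$n * contrib
    }
  }
  total
}

#' Thompson-style Bayes factor (log10 scale)
#'
#' A co-segregation statistic closely related to the LD-LOD but with an
#' additional adjustment for single ascertainment through the qualifying
#' proband: each family's likelihood ratio (admixed LD model over the
#' no-linkage / no-LD null) is divided by the same ratio evaluated on the
#' proband's own marker genotype and phenotype, conditional on the
#' parental marker genotypes. Equivalently,
#' `tbf = ld_lod(full data) - ld_lod(probands only)`.
#'
#' @inheritParams family_likelihood
#' @param data A sibship dataset with a designated qualifying proband in
#'   every family.
#' @return The log10 Bayes factor (scalar).
#' @export
tbf <- function(data, model) {
  stopifnot(inherits(model, "two_locus_model"))
  data <- check_sibship_data(data)
  check_probands(data)
  prep <- mod_prep(data, model$p, model$q, model$dprime, model$theta)
  pen <- model$penetrances
  prep_lod(prep, pen, model$alpha, numerator = "link") -
    proband_correction(prep, pen, model$alpha)
}

#' TBF at the generating trait model
#'
#' Evaluates [tbf()] at the generating penetrances — carrier penetrance
#' `beta = gamma + f - gamma * f` for both carrier genotypes and `gamma`
#' for non-carriers — with `alpha = 1`.
#'
#' @inheritParams tbf
#' @param trait The generating [trait_model()].
#' @param p,q,dprime,theta Structural parameters of the analysis model.
#' @return The log10 Bayes factor at the generating model (scalar).
#' @export
tbf_gen <- function(data, trait, p = 0.001, q = 0.001, dprime = 1,
                    theta = 0) {
  stopifnot(inherits(trait, "trait_model"))
  model <- two_locus_model(
    p = p, q = q, dprime = dprime, theta = theta,
    penetrances = c(trait$beta, trait$beta, trait$gamma), alpha = 1
  )
  tbf(data, model)
}

#' Maximize the TBF over penetrances and admixture
#'
#' Maximizes [tbf()] over `(f_DD, f_Dd, f_dd, alpha)` with the structural
#' model fixed, by the same grid-then-refine search as
#' [maximize_ld_lod()]. The maximizing `f_Dd` (`f_tbf`) is reported as a
#' diagnostic: unlike the LD-MOD, the proband-conditioned TBF does not
#' yield ascertainment-corrected penetrance estimates, and `f_tbf` is
#' badly biased in the presence of phenocopies — which is what this
#' function exists to demonstrate.
#'
#' @inheritParams maximize_ld_lod
#' @return An object of class `ascpen_tbf`: fields `tbf_max`, `f_tbf`,
#'   `alpha_hat`, `model`, `n_families`, `convergence`.
#' @export
maximize_tbf <- function(data, p = 0.001, q = 0.001, dprime = 1, theta = 0,
                         grid_step = 0.05, refine = TRUE) {
  data <- check_sibship_data(data)
  check_probands(data)
  prep <- mod_prep(data, p, q, dprime, theta)
  gs <- prep_lod_grid(prep, grid_step)

  # proband corrections over the same grid (few distinct proband states)
  g1 <- seq(0, 1, by = grid_step)
  pg <- expand.grid(f_Dd = g1, f_dd = g1)
  pen_mat <- rbind(dd = pg$f_dd, Dd = pg$f_Dd, DD = pg$f_Dd)
  tbf_vals <- gs$lod
  G <- nrow(pg)
  for (ai in seq_along(g1)) {
    a <- g1[ai]
    corr <- numeric(G)
    for (g in prep$groups) {
      for (st in g$proband_states) {
        p_link <- cond_likelihoods(g$tab_link, list(st), pen_mat)
        p_null <- cond_likelihoods(g$tab_null, list(st), pen_mat)
        contrib <- slog10(a * p_link + (1 - a) * p_null) - slog10(p_null)
        contrib[is.nan(contrib)] <- -Inf
        corr <- corr + st$n * contrib
      }
    }
    idx <- (ai - 1L) * G + seq_len(G)
    tbf_vals[idx] <- tbf_vals[idx] - corr
  }

  res <- grid_refine(gs, tbf_vals, function(par) {
    prep_lod(prep, par[1:3], par[4], numerator = "link") -
      proband_correction(prep, par[1:3], par[4])
  }, refine)
  best_par <- res$par
  argmax <- two_locus_model(p = p, q = q, dprime = dprime, theta = theta,
                            penetrances = best_par[1:3], alpha = best_par[4])
  structure(
    list(tbf_max = res$value,
         f_tbf = best_par[2],
         alpha_hat = best_par[4],
         model = argmax,
         n_families = prep$n_families,
         convergence = res$converged,
         grid_step = grid_step),
    class = "ascpen_tbf"
  )
}

#' @export
print.ascpen_tbf <- function(x, ...) {
  cat("<ascpen_tbf> TBF maximization over", x$n_families, "families\n")
  cat("  max TBF =", signif(x$tbf_max, 5),
      " f_tbf =", signif(x$f_tbf, 4),
      " alpha_hat =", signif(x$alpha_hat, 4), "\n")
  invisible(x)
}
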