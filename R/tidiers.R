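# broom-style tidiers for fitted objects.

#' Tidy an LD-MOD fit
#'
#' @param x An `ascpen_mod` object from [maximize_ld_lod()].
#' @param ... Unused.
#' @return A tibble with one row per maximized parameter (`f_DD`, `f_Dd`,
#'   `f_dd`, `alpha`) and its estimate.
#' @exportS3Method generics::tidy
tidy.ascpen_mod <- function(x, ...) {
  tibble::tibble(
    term = c("f_DD", "f_Dd", "f_dd", "alpha"),
    estimate = c(unname(x$model$penetrances), x$alpha_hat)
  )
}

#' One-row summary of an LD-MOD fit
#'
#' @inheritParams tidy.ascpen_mod
#' @return A one-row tibble: `ld_mod`, `f_hat`, `alpha_hat`, `le_lod_max`,
#'   `n_families`, `convergence`.
#' @exportS3Method generics::glance
glance.ascpen_mod <- function(x, ...) {
  tibble::tibble(
    ld_mod = x$ld_mod, f_hat = x$f_hat, alpha_hat = x$alpha_hat,
    le_lod_max = x$le_lod_max, n_families = x$n_families,
    convergence = x$convergence
  )
}

#' Tidy a TBF maximization
#'
#' @param x An `ascpen_tbf` object from [maximize_tbf()].
#' @param ... Unused.
#' @return A tibble with one row per maximized parameter.
#' @exportS3Method generics::tidy
tidy.ascpen_tbf <- function(x, ...) {
  tibble::tibble(
    term = c("f_DD", "f_Dd", "f_dd", "alpha"),
    estimate = c(unname(x$model$penetrances), x$alpha_hat)
  )
}

#' One-row summary of a TBF maximization
#'
#' @inheritParams tidy.ascpen_tbf
#' @return A one-row tibble: `tbf_max`, `f_tbf`, `alpha_hat`,
#'   `n_families`, `convergence`.
#' @exportS3Method generics::glance
glance.ascpen_tbf <- function(x, ...) {
  tibble::tibble(
    tbf_max = x$tbf_max, f_tbf = x$f_tbf, alpha_hat = x$alpha_hat,
    n_families = x$n_families, convergence = x$convergence
  )
}
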