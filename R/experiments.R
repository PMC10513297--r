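# Replicate-level experiment runner: simulates many datasets per
# generating condition and collects the requested estimators and
# co-segregation statistics as a tidy table.

all_statistics <- c("f_tilde", "f_tilde_star", "f_hat", "ld_mod",
                    "le_lod_max", "alpha_hat", "f_tbf", "tbf_max", "tbf_gen")

replicate_statistics <- function(data, trait, statistics, grid_step = 0.05) {
  out <- list()
  if ("f_tilde" %in% statistics) {
    ft <- f_tilde(data)
    out$f_tilde <- ft$estimate
    out$n_noncontributing <- ft$n_noncontributing
  }
  if ("f_tilde_star" %in% statistics) {
    out$f_tilde_star <- f_tilde_star(data)$estimate
  }
  if (any(c("f_hat", "ld_mod", "le_lod_max", "alpha_hat") %in% statistics)) {
    fit <- maximize_ld_lod(data, grid_step = grid_step)
    for (nm in intersect(c("f_hat", "ld_mod", "le_lod_max", "alpha_hat"),
                         statistics)) {
      out[[nm]] <- fit[[nm]]
    }
  }
  if (any(c("f_tbf", "tbf_max") %in% statistics)) {
    tfit <- maximize_tbf(data, grid_step = grid_step)
    for (nm in intersect(c("f_tbf", "tbf_max"), statistics)) {
      out[[nm]] <- tfit[[nm]]
    }
  }
  if ("tbf_gen" %in% statistics) {
    out$tbf_gen <- tbf_gen(data, trait)
  }
  tibble::as_tibble(out)
}

#' Run replicate simulations over a grid of generating conditions
#'
#' For each row of `grid` (a generating condition), simulates
#' `n_replicates` ascertained datasets and computes the requested
#' statistics on each, returning one tidy row per replicate per condition.
#' Per-replicate seeds are derived from the master `seed` by counter, so
#' every cell is reproducible independently of the others.
#'
#' @param grid A data frame of generating conditions with columns among
#'   `f`, `gamma`, `k`, `s`, `n_families`, `null` (missing columns take
#'   defaults `gamma = 0`, `s = 2`, `null = FALSE`; `f`, `k` and
#'   `n_families` are required). Build it with [tidyr::crossing()].
#' @param n_replicates Number of replicate datasets per condition.
#' @param statistics Character vector of statistics to compute per
#'   replicate, from `r paste0('"', all_statistics, '"', collapse = ", ")`.
#' @param seed Master seed.
#' @param grid_step Grid resolution passed to the likelihood maximizers.
#' @return A tibble: the condition columns, `replicate`, and one column
#'   per requested statistic (plus `n_noncontributing` when `f_tilde` is
#'   requested; `f_tilde` is `NA` for replicates where no family
#'   contributes).
#' @examples
#' res <- run_replicates(tidyr::crossing(f = 0.5, k = c(0, 1),
#'                                       n_families = 10),
#'                       n_replicates = 20, seed = 1)
#' summarize_replicates(res)
#' @export
run_replicates <- function(grid, n_replicates = 1000,
                           statistics = c("f_tilde", "f_tilde_star"),
                           seed = 1, grid_step = 0.05) {
  grid <- tibble::as_tibble(grid)
  if (!all(c("f", "k", "n_families") %in% names(grid))) {
    stop("`grid` needs columns f, k and n_families.", call. = FALSE)
  }
  statistics <- match.arg(statistics, all_statistics, several.ok = TRUE)
  if (!"gamma" %in% names(grid)) grid$gamma <- 0
  if (!"s" %in% names(grid)) grid$s <- 2L
  if (!"null" %in% names(grid)) grid$null <- FALSE
  if (n_replicates < 1) {
    return(dplyr::bind_cols(grid[0, ], tibble::tibble(replicate = integer())))
  }
  set.seed(seed)
  seeds <- matrix(sample.int(2147483646L, nrow(grid) * n_replicates),
                  nrow = nrow(grid))
  cells <- lapply(seq_len(nrow(grid)), function(ci) {
    cell <- grid[ci, ]
    trait <- trait_model(cell$f, cell$gamma)
    asc <- ascertainment_model(cell$k, s = cell$s)
    reps <- lapply(seq_len(n_replicates), function(ri) {
      set.seed(seeds[ci, ri])
      d <- simulate_dataset(trait, asc, n_families = cell$n_families,
                            s = cell$s, null = cell$null)
      stats <- tryCatch(
        replicate_statistics(d, trait, statistics, grid_step = grid_step),
        error = function(e) tibble::tibble(failed = conditionMessage(e))
      )
      dplyr::bind_cols(tibble::tibble(replicate = ri), stats)
    })
    dplyr::bind_cols(cell[rep(1, n_replicates), ], dplyr::bind_rows(reps))
  })
  dplyr::bind_rows(cells)
}

#' Summarize replicate results into per-condition means and SDs
#'
#' Cross-replicate mean, standard deviation and count for every statistic
#' column, by generating condition. Non-contributing replicates (`NA`
#' values, e.g. `f_tilde` when no family retains a scorable carrier) are
#' excluded from the mean and SD and tallied.
#'
#' @param results Output of [run_replicates()].
#' @return A long tibble: condition columns, `statistic`, `mean`, `sd`,
#'   `n` (contributing replicates), `n_excluded`.
#' @export
summarize_replicates <- function(results) {
  cond_cols <- intersect(c("f", "gamma", "k", "s", "n_families", "null"),
                         names(results))
  stat_cols <- intersect(all_statistics, names(results))
  results |>
    tidyr::pivot_longer(dplyr::all_of(stat_cols), names_to = "statistic",
                        values_to = "value") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(cond_cols, "statistic")))) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = sd(.data$value, na.rm = TRUE),
      n = sum(!is.na(.data$value)),
      n_excluded = sum(is.na(.data$value)),
      .groups = "drop"
    )
}

#' Count values reaching a threshold
#'
#' @param values Numeric vector (e.g. per-replicate LE-LOD(max) values).
#' @param threshold Threshold.
#' @return Number of non-missing values `>= threshold`.
#' @examples
#' threshold_exceedance(c(1, 2, 3, 4), 3) # 2
#' @export
threshold_exceedance <- function(values, threshold) {
  sum(values >= threshold, na.rm = TRUE)
}
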