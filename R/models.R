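# Domain model constructors and the small pieces of trait/ascertainment
# arithmetic shared by the simulator, the estimators and the likelihoods.

check_prob <- function(x, name, upper_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop("`", name, "` must be a single number.", call. = FALSE)
  }
  if (x < 0 || x > 1 || (upper_open && x == 1)) {
    stop("`", name, "` must be a probability in [0, 1",
         if (upper_open) ")" else "]", ".", call. = FALSE)
  }
  invisible(x)
}

#' Trait model for a rare dominant variant
#'
#' Describes the generating phenotype model: a very rare autosomal dominant
#' variant of interest (VOI) with attributable penetrance `f`, on top of a
#' background of all other causes of disease with combined penetrance
#' `gamma`. Because the VOI is rare, `gamma` is effectively the population
#' prevalence (the phenocopy rate). Carriers are affected with probability
#' `beta = gamma + f - gamma * f` (independent causes); non-carriers with
#' probability `gamma`.
#'
#' @param f Attributable penetrance of the variant, in `[0, 1]`.
#' @param gamma Combined penetrance of all other causes (phenocopy rate /
#'   population prevalence), in `[0, 1)`.
#' @return An object of class `trait_model` with fields `f`, `gamma` and the
#'   derived carrier penetrance `beta`.
#' @examples
#' trait_model(f = 0.5, gamma = 0.1)
#' @seealso [combined_penetrance()]
#' @export
trait_model <- function(f, gamma = 0) {
  check_prob(f, "f")
  check_prob(gamma, "gamma", upper_open = TRUE)
  structure(
    list(f = f, gamma = gamma, beta = combined_penetrance(f, gamma)),
    class = "trait_model"
  )
}

#' @export
print.trait_model <- function(x, ...) {
  cat("<trait_model> f =", x$f, " gamma =", x$gamma,
      " beta = P(AFF | carrier) =", signif(x$beta, 4), "\n")
  invisible(x)
}

#' Carrier penetrance under independent causes
#'
#' The total probability that a variant carrier is affected when the variant
#' (penetrance `f`) and all other causes (combined penetrance `gamma`) act
#' independently: `beta = gamma + f - gamma * f`.
#'
#' @param f Attributable penetrance, or a [trait_model()] (in which case
#'   `gamma` is taken from it).
#' @param gamma Phenocopy rate.
#' @return The carrier penetrance `beta`, a probability.
#' @examples
#' combined_penetrance(0.5, 0.5) # 0.75
#' @export
combined_penetrance <- function(f, gamma = 0) {
  if (inherits(f, "trait_model")) {
    gamma <- f$gamma
    f <- f$f
  }
  gamma + f - gamma * f
}

#' Normalizing constant of the k-model ascertainment weight
#'
#' The ascertainment weight is `c * (r^k + t)` over the number of qualifying
#' sibs `r` (carrier and affected) and affected sibs `t`. This returns the
#' largest `c` for which the weight is a valid probability for every
#' attainable pair `1 <= r <= t <= s`. The attainable set is scanned by
#' brute force: for negative `k` the maximizing cell is not `(s, s)`.
#'
#' @param k Ascertainment exponent (any real; `k = 1` is single
#'   ascertainment, `k = 0` complete/truncate ascertainment).
#' @param s Sibship size, integer `>= 1`.
#' @return The normalizing constant `c` in `(0, 1]`.
#' @examples
#' normalizing_constant(1, 2)  # 1/4
#' normalizing_constant(-1, 2) # 1/2.5
#' @export
normalizing_constant <- function(k, s) {
  if (!is.numeric(s) || length(s) != 1L || is.na(s) || s < 1 || s != round(s)) {
    stop("`s` must be an integer >= 1.", call. = FALSE)
  }
  w_max <- 0
  for (r in seq_len(s)) {
    for (t in r:s) {
      w_max <- max(w_max, r^k + t)
    }
  }
  1 / w_max
}

#' k-model of family ascertainment
#'
#' A sibship with `r >= 1` qualifying individuals (QIs: carrier and
#' affected) and `t` affected sibs is ascertained with probability
#' `c * (r^k + t)`; sibships with no QI are never ascertained. `k = 1`
#' recovers classical single ascertainment (probability proportional to the
#' number of QIs); `k = 0` complete/truncate ascertainment; the `+ t` term
#' allows additional preferential recruitment of multiplex families.
#'
#' @param k Ascertainment exponent.
#' @param s Sibship size the model will be applied to (used to compute the
#'   default normalizing constant).
#' @param c Normalizing constant; defaults to the largest valid value for
#'   sibships of size `s` (see [normalizing_constant()]).
#' @return An object of class `ascertainment_model` with fields `k`, `s`, `c`.
#' @examples
#' ascertainment_model(k = 1, s = 2)
#' @export
ascertainment_model <- function(k, s, c = NULL) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k)) {
    stop("`k` must be a single number.", call. = FALSE)
  }
  c_max <- normalizing_constant(k, s)
  if (is.null(c)) {
    c <- c_max
  }
  if (!is.numeric(c) || length(c) != 1L || c <= 0 || c > c_max + 1e-12) {
    stop("`c` must lie in (0, ", signif(c_max, 6),
         "] so that every weight is a probability.", call. = FALSE)
  }
  structure(list(k = k, s = as.integer(s), c = c),
            class = "ascertainment_model")
}

#' @export
print.ascertainment_model <- function(x, ...) {
  cat("<ascertainment_model> P(ascertained | r, t) =",
      signif(x$c, 4), "* (r^", x$k, " + t) for r >= 1; s =", x$s, "\n")
  invisible(x)
}

#' Ascertainment probability for given family counts
#'
#' @param asc An [ascertainment_model()].
#' @param r Number of qualifying (carrier and affected) sibs; vectorized.
#' @param t Number of affected sibs; vectorized.
#' @return Probability of ascertainment, `c * (r^k + t)` for `r >= 1`,
#'   0 otherwise.
#' @examples
#' asc <- ascertainment_model(k = 1, s = 2)
#' ascertainment_prob(asc, r = c(0, 1, 2), t = c(1, 1, 2))
#' @export
ascertainment_prob <- function(asc, r, t) {
  stopifnot(inherits(asc, "ascertainment_model"))
  p <- rep(0, length(r))
  pos <- r >= 1
  p[pos] <- asc$c * (r[pos]^asc$k + t[pos])
  p
}

#' Two-locus marker--disease haplotype frequencies
#'
#' Haplotype frequencies for a biallelic marker (alleles `V`/`v`, the
#' variant of interest) and a biallelic disease locus (`D`/`d`), given the
#' allele frequencies and the standardized disequilibrium coefficient
#' `D' in [0, 1]` (scaled by its maximum attainable value).
#'
#' @param p Frequency of the marker allele `V`.
#' @param q Frequency of the disease allele `D`.
#' @param dprime Standardized linkage-disequilibrium coefficient in `[0, 1]`.
#' @return Named numeric vector `c(VD, Vd, vD, vd)` summing to 1.
#' @examples
#' haplotype_frequencies(0.001, 0.001, 1) # complete coupling: Vd = vD = 0
#' @export
haplotype_frequencies <- function(p, q, dprime) {
  check_prob(p, "p")
  check_prob(q, "q")
  check_prob(dprime, "dprime")
  d <- dprime * min(p * (1 - q), (1 - p) * q)
  h <- c(VD = p * q + d,
         Vd = p * (1 - q) - d,
         vD = (1 - p) * q - d,
         vd = (1 - p) * (1 - q) + d)
  if (any(h < -1e-12)) {
    stop("Haplotype frequencies implied by (p, q, dprime) are negative.",
         call. = FALSE)
  }
  pmax(h, 0)
}

#' Two-locus analysis model
#'
#' The marker--disease model under which LOD-type statistics are computed:
#' marker allele frequency `p`, disease allele frequency `q`, standardized
#' disequilibrium `dprime`, recombination fraction `theta`, the penetrance
#' vector over disease genotypes, and Smith's admixture parameter `alpha`
#' (probability that a family is of the linked type). The defaults are the
#' analysis model used throughout: a very rare marker in complete coupling
#' with an equally rare disease allele and zero recombination.
#'
#' @param p Marker (variant of interest) allele frequency.
#' @param q Disease allele frequency.
#' @param dprime Standardized LD coefficient in `[0, 1]`.
#' @param theta Recombination fraction in `[0, 0.5]`.
#' @param penetrances Named or positional numeric vector
#'   `c(f_DD, f_Dd, f_dd)` of penetrances for each disease-locus genotype.
#' @param alpha Admixture parameter in `[0, 1]`.
#' @return An object of class `two_locus_model`.
#' @examples
#' two_locus_model(penetrances = c(0.5, 0.5, 0))
#' @export
two_locus_model <- function(p = 0.001, q = 0.001, dprime = 1, theta = 0,
                            penetrances = c(f_DD = 1, f_Dd = 1, f_dd = 0),
                            alpha = 1) {
  check_prob(p, "p")
  check_prob(q, "q")
  check_prob(dprime, "dprime")
  check_prob(alpha, "alpha")
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0 || theta > 0.5) {
    stop("`theta` must lie in [0, 0.5].", call. = FALSE)
  }
  if (length(penetrances) != 3L || !is.numeric(penetrances) ||
      any(penetrances < 0) || any(penetrances > 1)) {
    stop("`penetrances` must be three probabilities (f_DD, f_Dd, f_dd).",
         call. = FALSE)
  }
  penetrances <- setNames(as.numeric(penetrances), c("f_DD", "f_Dd", "f_dd"))
  haplotype_frequencies(p, q, dprime) # validates
  structure(
    list(p = p, q = q, dprime = dprime, theta = theta,
         penetrances = penetrances, alpha = alpha),
    class = "two_locus_model"
  )
}

#' @export
print.two_locus_model <- function(x, ...) {
  cat("<two_locus_model> p =", x$p, " q =", x$q, " D' =", x$dprime,
      " theta =", x$theta, " alpha =", x$alpha, "\n  penetrances:",
      paste(names(x$penetrances), signif(x$penetrances, 4),
            sep = " = ", collapse = ", "), "\n")
  invisible(x)
}
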