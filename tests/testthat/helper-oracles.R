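# Independent brute-force oracles, coded directly from the model
# definitions (no shared machinery with the package internals): explicit
# enumeration over parental haplotype pairs and per-sib meiosis outcomes.

oracle_haps <- data.frame(
  marker = c("V", "V", "v", "v"),
  disease = c("D", "d", "D", "d"),
  stringsAsFactors = FALSE
)

oracle_hap_freq <- function(p, q, dprime) {
  dmax <- min(p * (1 - q), (1 - p) * q)
  dval <- dprime * dmax
  sapply(seq_len(4), function(i) {
    m <- oracle_haps$marker[i]
    dis <- oracle_haps$disease[i]
    base <- (if (m == "V") p else 1 - p) * (if (dis == "D") q else 1 - q)
    sgn <- if ((m == "V") == (dis == "D")) 1 else -1
    base + sgn * dval
  })
}

oracle_geno_label <- function(m1, m2) paste(sort(c(m1, m2)), collapse = "")

# ordered parental haplotype pairs consistent with a marker genotype
oracle_parent_pairs <- function(geno, hf) {
  pairs <- list()
  ws <- c()
  for (i in 1:4) for (j in 1:4) {
    if (oracle_geno_label(oracle_haps$marker[i], oracle_haps$marker[j]) ==
        paste(sort(strsplit(geno, "")[[1]]), collapse = "")) {
      pairs[[length(pairs) + 1]] <- c(i, j)
      ws <- c(ws, hf[i] * hf[j])
    }
  }
  list(pairs = pairs, w = ws / sum(ws))
}

# meiosis outcomes for one gamete from an ordered pair (i, j): choose a
# strand, then recombine or not
oracle_gametes <- function(i, j, theta) {
  out <- list()
  for (strand in 1:2) for (rc in 0:1) {
    own <- if (strand == 1) i else j
    oth <- if (strand == 1) j else i
    gm <- oracle_haps$marker[own]
    gd <- if (rc == 1) oracle_haps$disease[oth] else oracle_haps$disease[own]
    out[[length(out) + 1]] <- list(
      m = gm, nd = as.integer(gd == "D"),
      pr = 0.5 * (if (rc == 1) theta else 1 - theta)
    )
  }
  out
}

# P(sib markers, sib phenotypes | parental marker genotypes), or the
# phenotype-conditional version. pen = c(f_DD, f_Dd, f_dd).
oracle_family_likelihood <- function(carrier, affected, pen,
                                     p = 0.001, q = 0.001, dprime = 1,
                                     theta = 0, father_gt = "Vv",
                                     mother_gt = "vv",
                                     conditional = FALSE) {
  hf <- oracle_hap_freq(p, q, dprime)
  fa <- oracle_parent_pairs(father_gt, hf)
  mo <- oracle_parent_pairs(mother_gt, hf)
  pen_by_nd <- unname(c(pen[3], pen[2], pen[1])) # nD = 0, 1, 2
  total_joint <- 0
  total_marg <- 0
  for (ai in seq_along(fa$pairs)) for (bi in seq_along(mo$pairs)) {
    gf <- oracle_gametes(fa$pairs[[ai]][1], fa$pairs[[ai]][2], theta)
    gm <- oracle_gametes(mo$pairs[[bi]][1], mo$pairs[[bi]][2], theta)
    prod_joint <- 1
    prod_marg <- 1
    for (si in seq_along(carrier)) {
      sib_joint <- 0
      sib_marg <- 0
      want <- if (carrier[si]) "Vv" else "vv"
      for (u in gf) for (v in gm) {
        nd <- u$nd + v$nd
        phi <- if (affected[si]) pen_by_nd[nd + 1] else 1 - pen_by_nd[nd + 1]
        sib_marg <- sib_marg + u$pr * v$pr * phi
        if (oracle_geno_label(u$m, v$m) == want) {
          sib_joint <- sib_joint + u$pr * v$pr * phi
        }
      }
      prod_joint <- prod_joint * sib_joint
      prod_marg <- prod_marg * sib_marg
    }
    total_joint <- total_joint + fa$w[ai] * mo$w[bi] * prod_joint
    total_marg <- total_marg + fa$w[ai] * mo$w[bi] * prod_marg
  }
  if (conditional) {
    if (total_marg == 0) 0 else total_joint / total_marg
  } else {
    total_joint
  }
}

# admixed phenotype-conditional family likelihood ratio pieces
oracle_cond_mix <- function(carrier, affected, pen, alpha,
                            p = 0.001, q = 0.001, dprime = 1, theta = 0) {
  l_link <- oracle_family_likelihood(carrier, affected, pen, p, q,
                                     dprime, theta, conditional = TRUE)
  l_null <- oracle_family_likelihood(carrier, affected, pen, p, q,
                                     0, 0.5, conditional = TRUE)
  list(mix = alpha * l_link + (1 - alpha) * l_null, null = l_null)
}

# per-family proband-conditioned Bayes factor, log10
oracle_tbf_family <- function(carrier, affected, proband_idx, pen, alpha,
                              p = 0.001, q = 0.001, dprime = 1, theta = 0) {
  full <- oracle_cond_mix(carrier, affected, pen, alpha, p, q, dprime, theta)
  pro <- oracle_cond_mix(carrier[proband_idx], affected[proband_idx],
                         pen, alpha, p, q, dprime, theta)
  log10((full$mix / pro$mix) / (full$null / pro$null))
}

# small helper to build a one-family dataset tibble
make_family <- function(carrier, affected, proband_idx = which(carrier & affected)[1],
                        family = 1L, father_gt = "Vv", mother_gt = "vv") {
  s <- length(carrier)
  tibble::tibble(
    family = as.integer(family), sib = seq_len(s),
    carrier = carrier, affected = affected,
    proband = seq_len(s) == proband_idx,
    father_gt = father_gt, mother_gt = mother_gt
  )
}

random_two_locus_model <- function() {
  two_locus_model(
    p = runif(1, 0.001, 0.3), q = runif(1, 0.001, 0.3),
    dprime = runif(1), theta = runif(1, 0, 0.5),
    penetrances = runif(3), alpha = runif(1)
  )
}

# per-sib (marker, affected) state probabilities, in the order
# MA, MU, mA, mU (M = marker carrier, A = affected)
state_probs_alt <- function(trait) {
  c(MA = 0.5 * trait$beta, MU = 0.5 * (1 - trait$beta),
    mA = 0.5 * trait$gamma, mU = 0.5 * (1 - trait$gamma))
}

state_probs_null <- function(trait) {
  pa <- (trait$beta + trait$gamma) / 2 # affection independent of marker
  c(MA = 0.5 * pa, MU = 0.5 * (1 - pa), mA = 0.5 * pa, mU = 0.5 * (1 - pa))
}

# ascertained distribution over unordered sib-pair configurations (s = 2)
# under weight r^k + t, r >= 1; keys like "MA|MU" (sorted states)
oracle_config_dist_s2 <- function(sp, k) {
  states <- names(sp)
  out <- list()
  for (i in seq_along(states)) for (j in seq_along(states)) {
    st <- sort(c(states[i], states[j]))
    r <- sum(st == "MA")
    t <- sum(substr(st, 2, 2) == "A")
    if (r < 1) next
    key <- paste(st, collapse = "|")
    w <- sp[[i]] * sp[[j]] * (r^k + t)
    out[[key]] <- (if (is.null(out[[key]])) 0 else out[[key]]) + w
  }
  probs <- unlist(out)
  probs / sum(probs)
}
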