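# LINKAGE pre-makeped pedigree file reader/writer.
#
# One whitespace-delimited row per individual: famID indID fatherID
# motherID sex affection allele1 allele2. Marker alleles are coded
# 1 = variant of interest (V), 2 = other (v); affection 2 = affected,
# 1 = unaffected, 0 = unknown (parents are always phenotype-unknown).
# Proband designation and generating parameters live in a companion YAML
# sidecar so the .ped file stays consumable by classical linkage tools.

gt_to_alleles <- function(gt) {
  switch(gt,
         VV = c(1L, 1L), Vv = c(1L, 2L), vv = c(2L, 2L),
         stop("Unknown genotype '", gt, "'.", call. = FALSE))
}

#' Write a sibship dataset as a LINKAGE pre-makeped pedigree file
#'
#' Each family is written as two phenotype-unknown parents followed by its
#' sibs. Sib sexes are assigned alternately (the models here are
#' autosomal; sex is carried only to satisfy the format). The proband of
#' each family and, for simulated data, the generating parameters are
#' written to a YAML sidecar next to the pedigree file.
#'
#' @param data A sibship dataset (see [simulate_dataset()]).
#' @param path Output path for the pedigree file.
#' @param sidecar_path Path for the companion YAML; default
#'   `paste0(path, ".yaml")`.
#' @return `path`, invisibly.
#' @examples
#' set.seed(1)
#' d <- simulate_dataset(trait_model(0.5), ascertainment_model(1, s = 2), 3)
#' ped <- file.path(tempdir(), "sim.ped")
#' write_ped(d, ped)
#' read_ped(ped)
#' @export
write_ped <- function(data, path, sidecar_path = paste0(path, ".yaml")) {
  data <- check_sibship_data(data)
  fams <- split(data, data$family)
  rows <- lapply(fams, function(fd) {
    fid <- fd$family[1]
    fa <- gt_to_alleles(fd$father_gt[1])
    mo <- gt_to_alleles(fd$mother_gt[1])
    s <- nrow(fd)
    sib_al <- t(vapply(fd$carrier,
                       function(cr) if (cr) c(1L, 2L) else c(2L, 2L),
                       integer(2)))
    data.frame(
      fam = fid,
      id = c(1L, 2L, 2L + seq_len(s)),
      father = c(0L, 0L, rep(1L, s)),
      mother = c(0L, 0L, rep(2L, s)),
      sex = c(1L, 2L, 1L + (seq_len(s) %% 2L)),
      aff = c(0L, 0L, ifelse(fd$affected, 2L, 1L)),
      a1 = c(fa[1], mo[1], sib_al[, 1]),
      a2 = c(fa[2], mo[2], sib_al[, 2])
    )
  })
  tab <- do.call(rbind, rows)
  tryCatch(
    utils::write.table(tab, path, quote = FALSE, row.names = FALSE,
                       col.names = FALSE),
    error = function(e) stop("Failed to write pedigree file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  probands <- data[!is.na(data$proband) & data$proband, c("family", "sib")]
  side <- list(
    probands = lapply(seq_len(nrow(probands)), function(i) {
      list(family = as.integer(probands$family[i]),
           individual = as.integer(probands$sib[i]) + 2L)
    })
  )
  prov <- provenance(data)
  if (!is.null(prov)) {
    side$provenance <- list(
      f = prov$trait$f, gamma = prov$trait$gamma,
      k = prov$asc$k, c = prov$asc$c, s = prov$s,
      n_families = prov$n_families, null = prov$null
    )
  }
  yaml::write_yaml(side, sidecar_path, precision = 12L)
  invisible(path)
}

#' Read a LINKAGE pre-makeped pedigree file
#'
#' Reconstructs a sibship dataset from a pedigree file written by
#' [write_ped()] or by compatible tools. Families are expected to be
#' nuclear: two founders and their children. Files whose parental mating
#' type deviates from the simulator's one-heterozygous-carrier assumption
#' (e.g. both parents carriers) are accepted with a warning; the
#' likelihood functions condition on whatever parental genotypes are
#' recorded. Marker-homozygous (`1 1`) children are rejected: sibs are
#' represented as carrier/non-carrier flags under the rare-variant model.
#'
#' @param path Pedigree file path.
#' @param sidecar_path Companion YAML path; if the file does not exist
#'   probands are left unset (`NA`).
#' @return A sibship dataset tibble as produced by [simulate_dataset()].
#' @export
read_ped <- function(path, sidecar_path = paste0(path, ".yaml")) {
  tab <- tryCatch(
    utils::read.table(path, header = FALSE,
                      col.names = c("fam", "id", "father", "mother",
                                    "sex", "aff", "a1", "a2")),
    error = function(e) stop("Failed to read pedigree file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!all(unlist(tab[, c("a1", "a2")]) %in% c(1L, 2L))) {
    bad <- which(!(tab$a1 %in% c(1, 2) & tab$a2 %in% c(1, 2)))[1]
    stop("Unknown marker allele code at line ", bad, " of '", path, "'.",
         call. = FALSE)
  }
  gt_of <- function(a1, a2) c("vv", "Vv", "VV")[(a1 == 1) + (a2 == 1) + 1L]

  fams <- split(tab, tab$fam)
  out <- lapply(fams, function(fd) {
    founders <- fd[fd$father == 0 & fd$mother == 0, , drop = FALSE]
    kids <- fd[fd$father != 0 | fd$mother != 0, , drop = FALSE]
    if (nrow(founders) != 2L || nrow(kids) < 1L) {
      stop("Family ", fd$fam[1], " is not a nuclear family with two ",
           "founders and at least one child.", call. = FALSE)
    }
    if (!all(kids$father %in% founders$id) ||
        !all(kids$mother %in% founders$id)) {
      stop("Family ", fd$fam[1], " has a child whose parents are absent.",
           call. = FALSE)
    }
    fa <- founders[match(kids$father[1], founders$id), ]
    mo <- founders[match(kids$mother[1], founders$id), ]
    father_gt <- gt_of(fa$a1, fa$a2)
    mother_gt <- gt_of(mo$a1, mo$a2)
    kid_gt <- gt_of(kids$a1, kids$a2)
    if (any(kid_gt == "VV")) {
      stop("Family ", fd$fam[1], " has a marker-homozygous child; ",
           "carrier/non-carrier coding cannot represent it.", call. = FALSE)
    }
    if (any(!kids$aff %in% c(1L, 2L))) {
      stop("Family ", fd$fam[1], " has a child with unknown affection ",
           "status; phenotypes of sibs must be observed.", call. = FALSE)
    }
    if (!setequal(c(father_gt, mother_gt), c("Vv", "vv"))) {
      warning("Family ", fd$fam[1], " deviates from the one-carrier-parent ",
              "mating type (", father_gt, " x ", mother_gt, "); moment ",
              "estimators assume simulator-style families.", call. = FALSE)
    }
    tibble::tibble(
      family = as.integer(fd$fam[1]),
      sib = seq_len(nrow(kids)),
      individual = kids$id,
      carrier = kid_gt == "Vv",
      affected = kids$aff == 2L,
      proband = NA,
      father_gt = father_gt,
      mother_gt = mother_gt
    )
  })
  res <- dplyr::bind_rows(out)

  if (file.exists(sidecar_path)) {
    side <- yaml::read_yaml(sidecar_path)
    res$proband <- FALSE
    for (pr in side$probands) {
      hit <- res$family == pr$family & res$individual == pr$individual
      res$proband[hit] <- TRUE
    }
    if (!is.null(side$provenance)) {
      pv <- side$provenance
      # clamp against the YAML round-trip precision of c
      c_in <- min(pv$c, normalizing_constant(pv$k, pv$s))
      attr(res, "provenance") <- list(
        trait = trait_model(pv$f, pv$gamma),
        asc = ascertainment_model(pv$k, s = pv$s, c = c_in),
        s = pv$s, n_families = pv$n_families, null = pv$null
      )
    }
  }
  res$individual <- NULL
  res
}
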