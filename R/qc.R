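#' Genotype quality control
#'
#' Applies the standard SNP-chip QC used for the vulva-size analyses, in a
#' fixed order:
#' 1. calls with a quality (GenCall) score below `gencall_min` are replaced
#'    by the mean dosage of that marker within the animal's breed group,
#'    computed from the remaining good calls (mean imputation, real-valued);
#' 2. animals with a call rate below `call_rate_min` are dropped;
#' 3. markers with a call rate below `call_rate_min` are dropped;
#' 4. markers with minor allele frequency below `maf_min` — computed as
#'    `min(p, 1 - p)` with `p = mean(dosage) / 2` on the retained animals —
#'    are dropped;
#' 5. any calls still missing are mean-imputed within group, so downstream
#'    methods never see missing dosages.
#'
#' A marker whose calls are all missing (or all low-quality) within a group
#' cannot be imputed and is dropped and logged.
#'
#' @param g A [genotype_data()] object.
#' @param gencall_min Quality threshold below which a call is treated as
#'   no-call and imputed (ignored when `g` has no quality matrix).
#' @param maf_min Minimum minor allele frequency.
#' @param call_rate_min Minimum per-animal and per-marker call rate.
#' @param group Optional character vector of breed labels, either named by
#'   animal ID or parallel to the rows of `g$calls`; imputation is done
#'   within group. `NULL` treats all animals as one group.
#'
#' @return A list with elements `genotypes` (the filtered, fully imputed
#'   `vs_geno`; its quality matrix is dropped) and `report` (a `vs_qc_report`
#'   tibble tallying each step).
#' @export
apply_genotype_qc <- function(g, gencall_min = 0.20, maf_min = 0.01,
                              call_rate_min = 0.8, group = NULL) {
  stopifnot(inherits(g, "vs_geno"))
  calls <- g$calls
  n0 <- nrow(calls); m0 <- ncol(calls)
  if (is.null(group)) {
    grp <- rep("all", n0)
  } else {
    grp <- if (!is.null(names(group))) {
      unname(group[rownames(calls)])
    } else {
      if (length(group) != n0) abort("`group` must cover all samples.")
      as.character(group)
    }
    if (anyNA(grp)) abort("`group` must cover all samples.")
  }

  n_lowq <- 0L
  dropped_unimputable <- character(0)

  # step 1: low-quality calls -> within-group marker mean
  if (!is.null(g$quality) && !is.null(gencall_min)) {
    lowq <- !is.na(calls) & !is.na(g$quality) & g$quality < gencall_min
    n_lowq <- sum(lowq)
    if (n_lowq > 0) {
      for (gr in unique(grp)) {
        rows <- which(grp == gr)
        sub <- calls[rows, , drop = FALSE]
        bad <- lowq[rows, , drop = FALSE]
        good <- sub
        good[bad] <- NA
        mu <- colMeans(good, na.rm = TRUE)
        for (j in which(colSums(bad) > 0)) {
          if (is.nan(mu[j])) {
            dropped_unimputable <- c(dropped_unimputable, colnames(calls)[j])
          } else {
            sub[bad[, j], j] <- mu[j]
          }
        }
        calls[rows, ] <- sub
      }
    }
  }
  dropped_unimputable <- unique(dropped_unimputable)
  if (length(dropped_unimputable)) {
    warn(paste0(length(dropped_unimputable),
                " marker(s) had no usable calls in a group and were dropped: ",
                paste(head(dropped_unimputable, 5), collapse = ", ")))
    keep <- !colnames(calls) %in% dropped_unimputable
    calls <- calls[, keep, drop = FALSE]
  }
  m_unimp <- length(dropped_unimputable)

  # step 2: animal call rate
  cr_animal <- rowMeans(!is.na(calls))
  drop_a <- cr_animal < call_rate_min
  n_cr <- sum(drop_a)
  calls <- calls[!drop_a, , drop = FALSE]
  grp <- grp[!drop_a]

  # step 3: marker call rate
  cr_marker <- colMeans(!is.na(calls))
  drop_cr <- cr_marker < call_rate_min
  m_cr <- sum(drop_cr)
  calls <- calls[, !drop_cr, drop = FALSE]

  # step 4: MAF on retained animals
  p <- colMeans(calls, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  drop_maf <- maf < maf_min | is.nan(maf)
  m_maf <- sum(drop_maf)
  calls <- calls[, !drop_maf, drop = FALSE]

  # step 5: residual missing calls -> within-group mean
  n_imp_missing <- 0L
  if (anyNA(calls)) {
    for (gr in unique(grp)) {
      rows <- which(grp == gr)
      sub <- calls[rows, , drop = FALSE]
      miss <- is.na(sub)
      if (any(miss)) {
        mu <- colMeans(sub, na.rm = TRUE)
        for (j in which(colSums(miss) > 0)) {
          sub[miss[, j], j] <- mu[j]
        }
        n_imp_missing <- n_imp_missing + sum(miss)
        calls[rows, ] <- sub
      }
    }
    if (anyNA(calls)) {
      # a marker all-missing within one group but not overall: fall back to
      # the overall mean so the no-missing guarantee holds
      miss <- is.na(calls)
      mu <- colMeans(calls, na.rm = TRUE)
      for (j in which(colSums(miss) > 0)) calls[miss[, j], j] <- mu[j]
      n_imp_missing <- n_imp_missing + sum(miss)
    }
  }

  keep_markers <- colnames(calls)
  map <- g$map[g$map$marker %in% keep_markers, , drop = FALSE]
  out <- genotype_data(calls, map, NULL)
  report <- tibble::tibble(
    step = c("input_markers", "markers_unimputable", "markers_call_rate",
             "markers_maf", "retained_markers",
             "input_samples", "samples_call_rate", "retained_samples",
             "calls_imputed_low_quality", "calls_imputed_missing"),
    count = c(m0, m_unimp, m_cr, m_maf, ncol(calls),
              n0, n_cr, nrow(calls),
              n_lowq, n_imp_missing)
  )
  class(report) <- c("vs_qc_report", class(report))
  list(genotypes = out, report = report)
}

#' @export
print.vs_qc_report <- function(x, ...) {
  cat("<genotype QC report>\n")
  NextMethod()
}

#' Derive vulva area from height and width
#'
#' Vulva area (mm^2) is defined as the product of vulva height and width
#' (both mm); any existing `va` column is recomputed.
#'
#' @param pheno Phenotype tibble with numeric `vh` and `vw` columns.
#' @return The tibble with a `va` column.
#' @export
derive_va <- function(pheno) {
  if (!all(c("vh", "vw") %in% names(pheno))) {
    abort("`pheno` needs `vh` and `vw` columns.")
  }
  if (any(pheno$vh < 0, na.rm = TRUE) || any(pheno$vw < 0, na.rm = TRUE)) {
    abort("Negative vulva measurements are invalid.")
  }
  dplyr::mutate(tibble::as_tibble(pheno), va = .data$vh * .data$vw)
}
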