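#' Assign markers to 1-Mb windows
#'
#' Windows are half-open megabase bins `[k Mb, (k+1) Mb)` within a
#' chromosome, so every marker belongs to exactly one window and windows
#' never span chromosomes.
#'
#' @param map Marker map tibble (`marker`, `chrom`, `pos` in bp) or a
#'   [genotype_data()] object.
#' @param size_mb Window size in Mb.
#' @return The map with added `window` (Mb bin start within chromosome) and
#'   `window_id` (`"chrom:window"`) columns.
#' @export
assign_windows <- function(map, size_mb = 1) {
  if (inherits(map, "vs_geno")) map <- map$map
  map <- tibble::as_tibble(map)
  dplyr::mutate(
    map,
    window = floor(.data$pos / (size_mb * 1e6)) * size_mb,
    window_id = paste0(.data$chrom, ":", .data$window)
  )
}

#' Per-window share of marker-explained genetic variance (%TGVM)
#'
#' For each retained MCMC draw, the window's genomic values
#' `u_w = X_w alpha_w` (centered dosages, the draw's effects restricted to
#' the window) are computed and their empirical variance across animals
#' taken; the draw-level share is `var(u_w) / sum_w var(u_w)` and %TGVM is
#' 100 times the posterior mean share (`average = "draw_ratio"`, which
#' propagates joint uncertainty across windows). Alternatively the ratio of
#' posterior-mean variances can be requested (`average =
#' "variance_ratio"`). Draws in which no marker is included have undefined
#' shares and are skipped; their count is reported in the
#' `skipped_draws` attribute. %TGVM sums to 100 over windows.
#'
#' @param fit A `vs_bayes_fit`.
#' @param g The [genotype_data()] the chain was fitted to (defines dosages
#'   and the marker map).
#' @param size_mb Window size in Mb.
#' @param average `"draw_ratio"` (default) or `"variance_ratio"`.
#' @return A tibble with one row per non-empty window: `chrom`, `start_mb`,
#'   `end_mb`, `window_id`, `n_snp`, `tgvm_pct`.
#' @export
window_variance <- function(fit, g, size_mb = 1,
                            average = c("draw_ratio", "variance_ratio")) {
  average <- match.arg(average)
  stopifnot(inherits(fit, "vs_bayes_fit"), inherits(g, "vs_geno"))
  if (fit$n_draws < 1) abort("No retained draws.")
  wmap <- assign_windows(g$map, size_mb = size_mb)
  wmap <- wmap[wmap$marker %in% fit$markers, ]
  groups <- split(wmap$marker, wmap$window_id)
  Xc <- sweep(g$calls[fit$animals, wmap$marker, drop = FALSE], 2,
              fit$centers[wmap$marker])
  # draws x windows matrix of window-GEBV variances
  vw <- matrix(0, fit$n_draws, length(groups),
               dimnames = list(NULL, names(groups)))
  for (w in seq_along(groups)) {
    U <- Xc[, groups[[w]], drop = FALSE] %*%
      t(fit$effects[, groups[[w]], drop = FALSE])
    vw[, w] <- matrixStats_colVars(U)
  }
  tot <- rowSums(vw)
  ok <- tot > 0
  skipped <- sum(!ok)
  if (!any(ok)) abort("Every retained draw has zero genetic variance.")
  if (average == "draw_ratio") {
    shares <- colMeans(vw[ok, , drop = FALSE] / tot[ok])
  } else {
    mv <- colMeans(vw[ok, , drop = FALSE])
    shares <- mv / sum(mv)
  }
  info <- dplyr::summarise(
    dplyr::group_by(wmap, .data$window_id, .data$chrom, .data$window),
    n_snp = dplyr::n(), .groups = "drop"
  )
  out <- tibble::tibble(
    window_id = names(groups),
    tgvm_pct = 100 * unname(shares)
  )
  out <- dplyr::left_join(info, out, by = "window_id")
  out <- dplyr::transmute(
    dplyr::arrange(out, .data$chrom, .data$window),
    chrom = .data$chrom,
    start_mb = .data$window,
    end_mb = .data$window + size_mb,
    window_id = .data$window_id,
    n_snp = .data$n_snp,
    tgvm_pct = .data$tgvm_pct
  )
  attr(out, "skipped_draws") <- skipped
  out
}

# column variances of a matrix (n x k), denominator n - 1
matrixStats_colVars <- function(M) {
  n <- nrow(M)
  if (n < 2) return(rep(0, ncol(M)))
  mu <- colMeans(M)
  (colSums(M^2) - n * mu^2) / (n - 1)
}

#' Posterior probability of inclusion per window
#'
#' `PPI_w` is the fraction of retained draws in which at least one marker
#' of window `w` has a nonzero effect.
#'
#' @inheritParams window_variance
#' @param map Marker map or [genotype_data()] (defaults to the fit's
#'   markers; required to place markers into windows).
#' @return A tibble `window_id`, `ppi`.
#' @export
window_ppi <- function(fit, map, size_mb = 1) {
  stopifnot(inherits(fit, "vs_bayes_fit"))
  wmap <- assign_windows(map, size_mb = size_mb)
  wmap <- wmap[wmap$marker %in% fit$markers, ]
  groups <- split(wmap$marker, wmap$window_id)
  ppi <- vapply(groups, function(mk) {
    mean(rowSums(fit$indicators[, mk, drop = FALSE]) > 0)
  }, numeric(1))
  ord <- unique(wmap$window_id)
  tibble::tibble(window_id = ord, ppi = unname(ppi[ord]))
}

#' Combined per-window GWAS results
#'
#' Convenience wrapper joining [window_variance()] and [window_ppi()] into
#' the Table-style layout `chrom, start_mb, end_mb, n_snp, tgvm_pct, ppi`.
#'
#' @inheritParams window_variance
#' @return A `vs_window_result` tibble.
#' @export
window_results <- function(fit, g, size_mb = 1,
                           average = c("draw_ratio", "variance_ratio")) {
  tv <- window_variance(fit, g, size_mb = size_mb, average = average)
  pp <- window_ppi(fit, g$map, size_mb = size_mb)
  out <- dplyr::left_join(tv, pp, by = "window_id")
  class(out) <- c("vs_window_result", class(out))
  attr(out, "skipped_draws") <- attr(tv, "skipped_draws")
  out
}

#' Call QTL regions from window results
#'
#' Windows reaching `tgvm_min` %TGVM seed regions; runs of seed windows on
#' the same chromosome whose gap is at most `merge_gap_mb` are merged. A
#' region's %TGVM is the sum over its windows and its PPI the maximum.
#'
#' @param results Window results from [window_results()] (or
#'   [window_variance()]; PPI then reported as `NA`).
#' @param tgvm_min Minimum %TGVM for a window to seed a region. The default
#'   4 is the conventional discussion threshold; regions down to ~3.4 can
#'   be kept by lowering it.
#' @param merge_gap_mb Maximum gap (Mb) between the end of one seed window
#'   and the start of the next for them to merge.
#' @return A tibble of regions: `chrom`, `start_mb`, `end_mb`, `n_windows`,
#'   `n_snp`, `tgvm_pct` (sum), `ppi` (max), `windows` (list column of
#'   constituent window IDs).
#' @export
call_qtl <- function(results, tgvm_min = 4, merge_gap_mb = 1) {
  res <- tibble::as_tibble(results)
  if (!"ppi" %in% names(res)) res$ppi <- NA_real_
  seeds <- dplyr::arrange(
    dplyr::filter(res, .data$tgvm_pct >= tgvm_min),
    .data$chrom, .data$start_mb
  )
  if (nrow(seeds) == 0) {
    return(tibble::tibble(
      chrom = integer(), start_mb = numeric(), end_mb = numeric(),
      n_windows = integer(), n_snp = integer(), tgvm_pct = numeric(),
      ppi = numeric(), windows = list()
    ))
  }
  new_region <- c(TRUE, seeds$chrom[-1] != seeds$chrom[-nrow(seeds)] |
                    seeds$start_mb[-1] - seeds$end_mb[-nrow(seeds)] > merge_gap_mb)
  seeds$region <- cumsum(new_region)
  dplyr::summarise(
    dplyr::group_by(seeds, .data$region),
    chrom = .data$chrom[1],
    start_mb = min(.data$start_mb),
    end_mb = max(.data$end_mb),
    n_windows = dplyr::n(),
    n_snp = sum(.data$n_snp),
    tgvm_pct = sum(.data$tgvm_pct),
    ppi = if (all(is.na(.data$ppi))) NA_real_ else max(.data$ppi, na.rm = TRUE),
    windows = list(.data$window_id),
    .groups = "drop"
  )[, -1]
}

#' Cross-trait QTL overlap report
#'
#' Given per-trait region calls, lists regions that share any interval
#' across traits on the same chromosome — the pattern used to flag common
#' (putatively pleiotropic) QTL.
#'
#' @param regions Named list of region tibbles from [call_qtl()], one per
#'   trait.
#' @return A tibble of pairwise overlaps: `trait_a`, `trait_b`, `chrom` and
#'   the two intervals.
#' @export
qtl_overlap <- function(regions) {
  stopifnot(is.list(regions), !is.null(names(regions)))
  traits <- names(regions)
  out <- list()
  for (a in seq_along(traits)) {
    for (b in seq_along(traits)) {
      if (b <= a) next
      ra <- regions[[a]]; rb <- regions[[b]]
      if (!nrow(ra) || !nrow(rb)) next
      for (i in seq_len(nrow(ra))) {
        hit <- rb$chrom == ra$chrom[i] &
          rb$start_mb < ra$end_mb[i] & rb$end_mb > ra$start_mb[i]
        if (any(hit)) {
          out[[length(out) + 1]] <- tibble::tibble(
            trait_a = traits[a], trait_b = traits[b],
            chrom = ra$chrom[i],
            start_mb_a = ra$start_mb[i], end_mb_a = ra$end_mb[i],
            start_mb_b = rb$start_mb[hit], end_mb_b = rb$end_mb[hit]
          )
        }
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(
      trait_a = character(), trait_b = character(), chrom = integer(),
      start_mb_a = numeric(), end_mb_a = numeric(),
      start_mb_b = numeric(), end_mb_b = numeric()
    ))
  }
  dplyr::bind_rows(out)
}

#' Manhattan-style plot of window %TGVM
#'
#' @param object A `vs_window_result`.
#' @param tgvm_min Reference line for the region-calling threshold.
#' @param ... Unused.
#' @return A ggplot: %TGVM per 1-Mb window along the genome, chromosomes
#'   alternating in shade.
#' @export
autoplot.vs_window_result <- function(object, tgvm_min = 4, ...) {
  dat <- dplyr::arrange(tibble::as_tibble(object), .data$chrom, .data$start_mb)
  dat$index <- seq_len(nrow(dat))
  dat$chrom_f <- factor(dat$chrom)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$index, y = .data$tgvm_pct,
                                    colour = .data$chrom_f)) +
    ggplot2::geom_point(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = tgvm_min, linetype = 2) +
    ggplot2::labs(x = "1-Mb window (genome order)",
                  y = "% of total genetic variance (TGVM)") +
    ggplot2::theme_minimal()
}
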