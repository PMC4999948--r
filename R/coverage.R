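#' Filter CpGs by read-depth coverage
#'
#' Removes CpG sites with insufficient raw coverage before any testing, the
#' standard guard against stochastic sampling drift at shallow MeDIP depth.
#' The default retains a CpG when its *mean* raw depth across all samples is
#' at least `min_depth`; `mode = "all"` requires every sample to reach the
#' threshold, `mode = "any"` at least one.
#'
#' @param depth tibble with `chrom`, `pos` and one raw-depth column per
#'   sample.
#' @param min_depth minimum read depth (default 10).
#' @param mode how the per-sample depths are aggregated against the
#'   threshold: `"mean"` (default), `"all"` or `"any"`.
#' @return The filtered tibble (possibly 0-row; an empty input is returned
#'   unchanged, not an error), with attribute `retained_fraction`.
#' @examples
#' d <- tibble::tibble(chrom = "chr1", pos = c(0, 100),
#'                     A1 = c(12, 3), B1 = c(9, 2))
#' filter_low_coverage(d, min_depth = 10)
#' @export
filter_low_coverage <- function(depth, min_depth = 10,
                                mode = c("mean", "all", "any")) {
  mode <- match.arg(mode)
  if (min_depth < 0) abort("min_depth must be >= 0")
  check_depth_table(depth)
  smp <- depth_sample_cols(depth)
  if (nrow(depth) == 0L) {
    return(structure(depth, retained_fraction = NA_real_))
  }
  m <- as.matrix(depth[, smp, drop = FALSE])
  keep <- switch(mode,
    mean = rowMeans(m) >= min_depth,
    all  = apply(m >= min_depth, 1L, all),
    any  = apply(m >= min_depth, 1L, any)
  )
  out <- depth[keep, , drop = FALSE]
  attr(out, "retained_fraction") <- mean(keep)
  out
}

#' Normalize depths to the overall group average
#'
#' Each sample's depths are divided by the grand mean raw depth over all
#' CpGs and all samples of that sample's group, so that the group-wise
#' grand mean of normalized depths is exactly 1 and the two groups are
#' comparable despite different sequencing yields.
#'
#' @inheritParams filter_low_coverage
#' @param groups tibble `sample`, `group` (exactly two groups).
#' @return Tibble of the same shape with sample columns normalized;
#'   attribute `group_means` records the divisors.
#' @examples
#' d <- tibble::tibble(chrom = "chr1", pos = c(0, 100), A1 = c(10, 30))
#' g <- tibble::tibble(sample = "A1", group = "A")
#' normalize_depths(d, g)$A1  # 0.5, 1.5
#' @export
normalize_depths <- function(depth, groups) {
  check_depth_table(depth)
  groups <- check_groups(depth, groups)
  lv <- group_levels(groups)
  out <- depth
  gm <- setNames(numeric(length(lv)), lv)
  for (g in lv) {
    gsmp <- groups$sample[groups$group == g]
    gmean <- mean(as.matrix(depth[, gsmp, drop = FALSE]))
    if (!is.finite(gmean) || gmean <= 0) {
      abort(sprintf("group '%s' has zero total depth; cannot normalize", g))
    }
    gm[g] <- gmean
    for (s in gsmp) out[[s]] <- depth[[s]] / gmean
  }
  attr(out, "group_means") <- gm
  out
}
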