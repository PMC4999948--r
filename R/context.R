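#' Subtelomeric mask for one chromosome
#'
#' Splits a chromosome into subtelomeric intervals (`span` bp from each
#' end, default 7 Mb) and the non-subtelomeric remainder. When the
#' chromosome is no longer than twice the span the whole chromosome is
#' subtelomeric and the non-subtelomeric set is empty. Intervals are
#' 0-based half-open and partition the chromosome exactly.
#'
#' @param chrom_length chromosome length in bp.
#' @param span bp from each chromosome end treated as subtelomeric.
#' @return list with tibbles `subtelomeric` and `non_subtelomeric`
#'   (`start`, `end`).
#' @examples
#' subtelomere_mask(30e6)  # [0,7M) + [23M,30M) vs [7M,23M)
#' @export
subtelomere_mask <- function(chrom_length, span = 7e6) {
  if (chrom_length <= 0) abort("chrom_length must be positive")
  if (span <= 0) abort("span must be positive")
  if (chrom_length <= 2 * span) {
    return(list(
      subtelomeric = tibble(start = 0, end = chrom_length),
      non_subtelomeric = tibble(start = numeric(), end = numeric())
    ))
  }
  list(
    subtelomeric = tibble(start = c(0, chrom_length - span),
                          end = c(span, chrom_length)),
    non_subtelomeric = tibble(start = span, end = chrom_length - span)
  )
}

#' Per-chromosome methylation by subtelomeric zone
#'
#' Mean normalized depth per chromosome, group and zone (subtelomeric vs
#' non-subtelomeric), with the per-chromosome sign of the group contrast in
#' each zone. Chromosomes present in the depth table but absent from the
#' sizes table are an error; a zone with no retained CpG gets NA.
#'
#' @param depth normalized depth table.
#' @param groups sample-to-group map.
#' @param chrom_sizes tibble `chrom`, `length` (or a `genome_annotation`).
#' @param span subtelomeric span in bp from each end.
#' @return tibble `chrom`, `length`, `zone`, `mean_<groupA>`,
#'   `mean_<groupB>` ... one row per chromosome x zone, columns `mean_a`,
#'   `mean_b`, `n_cpgs`, `higher_group` (NA on ties/missing).
#' @export
zone_methylation <- function(depth, groups, chrom_sizes, span = 7e6) {
  if (inherits(chrom_sizes, "genome_annotation")) {
    chrom_sizes <- chrom_sizes$chrom_sizes
  }
  check_depth_table(depth)
  groups <- check_groups(depth, groups)
  lv <- group_levels(groups)
  bad <- setdiff(unique(depth$chrom), chrom_sizes$chrom)
  if (length(bad)) {
    abort(paste0("chromosome(s) missing from sizes: ", paste(bad, collapse = ", ")))
  }
  smpA <- groups$sample[groups$group == lv[1]]
  smpB <- groups$sample[groups$group == lv[2]]
  d <- depth |>
    left_join(chrom_sizes, by = "chrom") |>
    mutate(zone = ifelse(.data$pos < span | .data$pos >= .data$length - span |
                           .data$length <= 2 * span,
                         "subtelomeric", "non_subtelomeric"),
           a = rowMeans(as.matrix(depth[, smpA, drop = FALSE])),
           b = rowMeans(as.matrix(depth[, smpB, drop = FALSE])))
  zones <- tidyr::expand_grid(chrom = chrom_sizes$chrom,
                              zone = c("subtelomeric", "non_subtelomeric"))
  d |>
    group_by(.data$chrom, .data$zone) |>
    summarise(mean_a = mean(.data$a), mean_b = mean(.data$b),
              n_cpgs = n(), .groups = "drop") |>
    dplyr::right_join(zones, by = c("chrom", "zone")) |>
    left_join(chrom_sizes, by = "chrom") |>
    mutate(n_cpgs = ifelse(is.na(.data$n_cpgs), 0L, .data$n_cpgs),
           higher_group = dplyr::case_when(
             is.na(.data$mean_a) | is.na(.data$mean_b) ~ NA_character_,
             .data$mean_b > .data$mean_a ~ lv[2],
             .data$mean_b < .data$mean_a ~ lv[1],
             TRUE ~ NA_character_),
           diff_b_minus_a = .data$mean_b - .data$mean_a) |>
    select("chrom", "length", "zone", "mean_a", "mean_b",
           "diff_b_minus_a", "higher_group", "n_cpgs") |>
    arrange(.data$chrom, dplyr::desc(.data$zone))
}

#' Tally which group is higher per zone
#'
#' Summarises a [zone_methylation()] table into, per zone, how many
#' chromosomes have each group higher — the "17 out of 19" style count.
#'
#' @param zones output of [zone_methylation()].
#' @return tibble `zone`, `higher_group`, `n_chromosomes`.
#' @export
zone_comparison_summary <- function(zones) {
  zones |>
    filter(!is.na(.data$higher_group)) |>
    count(.data$zone, .data$higher_group, name = "n_chromosomes")
}

#' Build per-chromosome summaries
#'
#' Mean normalized depth per chromosome plus correlate covariates: length,
#' gene/CGI/miRNA/repeat/SNP densities per Mb, and GC / CpG observed-over-
#' expected ratio when sequences are available.
#'
#' @param depth normalized depth table.
#' @param groups sample-to-group map.
#' @param annotation a `genome_annotation`.
#' @param sequences optional named chromosome sequences for GC / CpGo/e.
#' @return tibble, one row per chromosome.
#' @export
chromosome_summaries <- function(depth, groups, annotation,
                                 sequences = NULL) {
  groups <- check_groups(depth, groups)
  sizes <- annotation$chrom_sizes
  mdepth <- rowMeans(as.matrix(depth[, groups$sample, drop = FALSE]))
  base <- tibble(chrom = depth$chrom, d = mdepth) |>
    group_by(.data$chrom) |>
    summarise(mean_norm_depth = mean(.data$d), n_cpgs = n(),
              .groups = "drop") |>
    dplyr::right_join(sizes, by = "chrom")

  dens <- function(tbl) {
    if (is.null(tbl) || !nrow(tbl)) return(rep(0, nrow(base)))
    cnt <- table(factor(tbl$chrom, levels = base$chrom))
    as.numeric(cnt) / (base$length / 1e6)
  }
  base$gene_density <- dens(annotation$genes)
  base$cgi_density <- dens(annotation$cgis)
  base$mirna_density <- dens(annotation$mirnas)
  base$repeat_density <- dens(annotation$repeats)
  base$snp_density <- dens(annotation$snps)
  if (!is.null(sequences)) {
    comp <- purrr::map_dfr(base$chrom, function(ch) {
      s <- sequences[[ch]]
      len <- nchar(s)
      nC <- len - nchar(gsub("C", "", s, fixed = TRUE))
      nG <- len - nchar(gsub("G", "", s, fixed = TRUE))
      nCG <- if (grepl("CG", s, fixed = TRUE))
        length(gregexpr("CG", s, fixed = TRUE)[[1]]) else 0L
      tibble(gc = (nC + nG) / len,
             cpg_oe = if (nC == 0 || nG == 0) 0 else nCG * len / (nC * nG))
    })
    base <- bind_cols(base, comp)
  } else {
    base$gc <- NA_real_
    base$cpg_oe <- NA_real_
  }
  base
}

#' Correlate chromosome methylation with genomic covariates
#'
#' Pearson correlation (with two-sided t-approximation p) between the
#' per-chromosome mean methylation and each available covariate. A
#' zero-variance vector yields an NA marker rather than an error.
#'
#' @param summaries tibble from [chromosome_summaries()] (needs
#'   `mean_norm_depth` plus covariate columns).
#' @param covariates covariate column names to correlate against.
#' @return tibble `covariate`, `r`, `p`, `n`.
#' @export
chromosome_correlates <- function(summaries,
                                  covariates = c("length", "gc", "cpg_oe",
                                                 "gene_density", "cgi_density",
                                                 "repeat_density",
                                                 "snp_density")) {
  covariates <- intersect(covariates, names(summaries))
  purrr::map_dfr(covariates, function(cv) {
    d <- summaries[stats::complete.cases(summaries[, c("mean_norm_depth", cv)]), ]
    x <- d$mean_norm_depth; y <- d[[cv]]
    if (length(x) < 3) abort("need >= 3 chromosomes for correlation")
    if (sd(x) == 0 || sd(y) == 0) {
      return(tibble(covariate = cv, r = NA_real_, p = NA_real_,
                    n = length(x)))
    }
    ct <- cor.test(x, y)
    tibble(covariate = cv, r = unname(ct$estimate), p = ct$p.value,
           n = length(x))
  })
}
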