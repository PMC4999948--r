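#' Simulate expression coupled to promoter methylation
#'
#' Per-feature expression follows a linear-Gaussian model on the
#' standardised promoter mean normalized depth \eqn{z}: the latent
#' group-level expression is \eqn{r z + \sqrt{1 - r^2}\,\epsilon} with
#' \eqn{\epsilon \sim N(0,1)}, so the population Pearson correlation
#' between promoter methylation and expression equals `cfg$coupling_r`.
#' The coupling acts on the per-group promoter methylation, so features
#' whose promoters fall in planted regions acquire expression shifts of
#' opposite (for negative `coupling_r`) sign. Each sample's value adds
#' replicate noise `N(0, expr_rep_sd)`. Features without promoter CpGs get
#' pure noise and are flagged in the truth ledger.
#'
#' @param annotation a `genome_annotation`.
#' @param depth raw depth table from [simulate_depths()] (normalized
#'   internally with [normalize_depths()]).
#' @param groups sample-to-group map.
#' @param cfg a [sim_config()].
#' @param feature_type `"gene"` (promoter = 2 kb upstream of TSS) or
#'   `"mirna"` (promoter = 2 kb upstream of the locus start on its strand).
#' @param promoter_up promoter span in bp upstream of the start site.
#' @return list with `expression` (tibble `feature_id` + one column per
#'   sample) and `truth` (tibble `feature_id`, `meth_level`, `slope`,
#'   `noise_sd`, `coupled`).
#' @examples
#' cfg <- sim_config(chrom_length = 5e5, genes_per_chrom = 20, seed = 5)
#' ann <- simulate_genome(cfg)
#' sim <- simulate_depths(ann, cfg)
#' ex <- simulate_expression(ann, sim$depth, sim$groups, cfg)
#' head(ex$expression)
#' @export
simulate_expression <- function(annotation, depth, groups, cfg,
                                feature_type = c("gene", "mirna"),
                                promoter_up = 2000) {
  validate_sim_config(cfg)
  feature_type <- match.arg(feature_type)
  if (abs(cfg$coupling_r) > 1) abort("coupling_r must lie in [-1, 1]")
  groups <- check_groups(depth, groups)
  set.seed(cfg$seed + ifelse(feature_type == "gene", 2L, 3L))

  feats <- if (feature_type == "gene") {
    annotation$genes |>
      mutate(feature_id = .data$gene_id,
             anchor = .data$tss)
  } else {
    annotation$mirnas |>
      mutate(feature_id = .data$mirna_id,
             anchor = ifelse(.data$strand == "+", .data$start, .data$end))
  }
  if (!nrow(feats)) abort("annotation has no features of the requested type")

  norm <- normalize_depths(depth, groups)
  prom <- feats |>
    mutate(start = ifelse(.data$strand == "+",
                          pmax(0, .data$anchor - promoter_up), .data$anchor),
           end = ifelse(.data$strand == "+",
                        .data$anchor, .data$anchor + promoter_up)) |>
    select("feature_id", "chrom", "start", "end")

  smp <- groups$sample
  lv <- group_levels(groups)
  # per-feature per-group promoter mean normalized depth
  hits <- GenomicRanges::findOverlaps(
    pos_to_gr(norm$chrom, norm$pos), tbl_to_gr(prom))
  per_group <- matrix(NA_real_, nrow(prom), 2,
                      dimnames = list(prom$feature_id, lv))
  if (length(hits)) {
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    for (g in lv) {
      gsmp <- groups$sample[groups$group == g]
      v <- rowMeans(as.matrix(norm[, gsmp, drop = FALSE]))
      per_group[, g] <- as.numeric(tapply(v[qi], factor(si, seq_len(nrow(prom))), mean))
    }
  }
  coupled <- stats::complete.cases(per_group)
  meth_overall <- rowMeans(per_group)

  mu_m <- mean(meth_overall[coupled])
  sd_m <- sd(meth_overall[coupled])
  if (!is.finite(sd_m) || sd_m == 0) sd_m <- 1
  r <- cfg$coupling_r
  eps <- rnorm(nrow(prom))
  noise_sd <- sqrt(1 - r^2)
  z <- (per_group - mu_m) / sd_m
  latent <- r * z + noise_sd * eps  # feature x group, shared gene noise
  latent[!coupled, ] <- eps[!coupled]

  expr <- tibble(feature_id = prom$feature_id)
  for (s in smp) {
    g <- groups$group[match(s, groups$sample)]
    expr[[s]] <- latent[, g] + rnorm(nrow(prom), sd = cfg$expr_rep_sd)
  }

  truth <- tibble(
    feature_id = prom$feature_id,
    meth_level = meth_overall,
    slope = ifelse(coupled, r / sd_m, 0),
    noise_sd = ifelse(coupled, noise_sd, 1),
    coupled = coupled
  )
  list(expression = expr, truth = truth)
}
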