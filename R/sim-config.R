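#' Simulation configuration
#'
#' Parameters of the synthetic MeDIP-seq experiment: a toy annotated genome,
#' negative-binomial per-CpG read depths for two groups of replicates with
#' depth-shifted regions planted as ground truth, and expression values
#' coupled to promoter methylation with a tunable Pearson correlation.
#'
#' The depth model is \eqn{NB(\mu, \phi)} with variance
#' \eqn{\mu + \phi \mu^2}: MeDIP read depth is overdispersed count data, and
#' `nb_dispersion = 0` degrades gracefully to Poisson. The group effect is a
#' multiplicative fold on the group-B mean confined to planted regions;
#' hyper- and hypo-methylated regions are planted in equal numbers. Planted
#' regions are placed on runs of `dmr_n_cpgs` consecutive CpGs whose internal
#' gaps do not exceed `dmr_max_gap`, emulating the CpG-dense (island-like)
#' context in which real differentially methylated regions occur.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length length of each chromosome in bp.
#' @param cpg_spacing_mean mean CpG spacing in bp (exponential spacing).
#' @param n_samples_per_group replicates per group (two groups, `A` and `B`).
#' @param nb_mean expected read depth per CpG per sample.
#' @param nb_dispersion NB dispersion; variance = mean + dispersion * mean^2.
#' @param n_planted_dmrs number of depth-shifted regions to plant.
#' @param dmr_n_cpgs CpGs per planted region.
#' @param dmr_fold depth fold applied to group B inside planted regions
#'   (hyper regions use `dmr_fold`, hypo regions `1/dmr_fold`).
#' @param dmr_max_gap maximum spacing (bp) between consecutive CpGs of a
#'   planted region.
#' @param coupling_r target Pearson correlation between promoter methylation
#'   and expression (negative for repression).
#' @param expr_rep_sd replicate (technical) noise sd added to per-sample
#'   expression values.
#' @param genes_per_chrom,mirnas_per_chrom gene and miRNA loci per chromosome.
#' @param cgi_fraction fraction of promoters overlapped by a CpG island.
#' @param seed integer RNG seed; every simulation is deterministic given it.
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_chromosomes = 1, chrom_length = 1e6, seed = 7)
#' @export
sim_config <- function(n_chromosomes = 1L,
                       chrom_length = 1e7,
                       cpg_spacing_mean = 200,
                       n_samples_per_group = 3L,
                       nb_mean = 20,
                       nb_dispersion = 0.1,
                       n_planted_dmrs = 0L,
                       dmr_n_cpgs = 8L,
                       dmr_fold = 2.5,
                       dmr_max_gap = 200,
                       coupling_r = -0.5,
                       expr_rep_sd = 0.05,
                       genes_per_chrom = 200L,
                       mirnas_per_chrom = 30L,
                       cgi_fraction = 0.4,
                       seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.numeric(chrom_length),
    cpg_spacing_mean = as.numeric(cpg_spacing_mean),
    n_samples_per_group = as.integer(n_samples_per_group),
    nb_mean = as.numeric(nb_mean),
    nb_dispersion = as.numeric(nb_dispersion),
    n_planted_dmrs = as.integer(n_planted_dmrs),
    dmr_n_cpgs = as.integer(dmr_n_cpgs),
    dmr_fold = as.numeric(dmr_fold),
    dmr_max_gap = as.numeric(dmr_max_gap),
    coupling_r = as.numeric(coupling_r),
    expr_rep_sd = as.numeric(expr_rep_sd),
    genes_per_chrom = as.integer(genes_per_chrom),
    mirnas_per_chrom = as.integer(mirnas_per_chrom),
    cgi_fraction = as.numeric(cgi_fraction),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot_msg <- function(ok, msg) if (!ok) abort(msg)
  stopifnot_msg(cfg$n_chromosomes >= 1, "n_chromosomes must be >= 1")
  stopifnot_msg(cfg$chrom_length > 0, "chrom_length must be positive")
  stopifnot_msg(cfg$cpg_spacing_mean > 0, "cpg_spacing_mean must be positive")
  stopifnot_msg(cfg$n_samples_per_group >= 1, "n_samples_per_group must be >= 1")
  stopifnot_msg(cfg$nb_mean > 0, "nb_mean must be positive")
  stopifnot_msg(cfg$nb_dispersion >= 0, "nb_dispersion must be >= 0")
  stopifnot_msg(cfg$n_planted_dmrs >= 0, "n_planted_dmrs must be >= 0")
  stopifnot_msg(cfg$dmr_n_cpgs >= 1, "dmr_n_cpgs must be >= 1")
  stopifnot_msg(cfg$dmr_fold > 0, "dmr_fold must be positive")
  stopifnot_msg(cfg$coupling_r >= -1 && cfg$coupling_r <= 1,
                "coupling_r must lie in [-1, 1]")
  stopifnot_msg(cfg$expr_rep_sd >= 0, "expr_rep_sd must be >= 0")
  stopifnot_msg(cfg$cgi_fraction >= 0 && cfg$cgi_fraction <= 1,
                "cgi_fraction must lie in [0, 1]")
  invisible(cfg)
}
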