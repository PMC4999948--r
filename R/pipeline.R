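#' Pipeline configuration
#'
#' Bundles the stage configurations and a single master seed from which
#' each stage derives its own seed (stable offsets per stage), so stages
#' can be rerun in isolation and the whole run is reproducible end to end.
#'
#' @param sim a [sim_config()]; its `seed` is overridden by the derived
#'   stage seed.
#' @param dmr a [dmr_config()]; its `perm_seed` is likewise derived.
#' @param integration an [integration_config()].
#' @param min_depth,min_depth_mode coverage filter settings.
#' @param subtel_span subtelomeric span (bp).
#' @param window profile window width (bp).
#' @param master_seed master RNG seed, recorded in every output header.
#' @param simulate generate the inputs with the synthetic-data module
#'   (default). With `simulate = FALSE` the depth table, group map and
#'   chromosome sizes are read from the `*_path` arguments and the
#'   annotation-dependent stages (element annotation, integration) are
#'   skipped.
#' @param depth_path,groups_path,chrom_sizes_path input files used when
#'   `simulate = FALSE`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            dmr = dmr_config(),
                            integration = integration_config(),
                            min_depth = 10, min_depth_mode = "mean",
                            subtel_span = 7e6, window = 1e6,
                            master_seed = 1L, simulate = TRUE,
                            depth_path = NULL, groups_path = NULL,
                            chrom_sizes_path = NULL) {
  structure(list(sim = sim, dmr = dmr, integration = integration,
                 min_depth = min_depth, min_depth_mode = min_depth_mode,
                 subtel_span = subtel_span, window = window,
                 master_seed = as.integer(master_seed),
                 simulate = isTRUE(simulate),
                 depth_path = depth_path, groups_path = groups_path,
                 chrom_sizes_path = chrom_sizes_path),
            class = "pipeline_config")
}

# derived per-stage seeds: stable small offsets from the master seed
stage_seed <- function(master_seed, stage) {
  offsets <- c(simulate = 0L, dmr = 101L, expression = 211L)
  as.integer(master_seed) + offsets[[stage]]
}

#' Run the full synthetic-to-integration pipeline
#'
#' Executes simulate -> filter -> normalize -> call DMRs -> annotate ->
#' chromosome context -> integrate, writes each stage output as
#' '#'-headered plain text under `outdir`, and returns a manifest of file
#' digests. Identical configuration and master seed produce byte-identical
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @return list with `results` (the in-memory stage outputs) and
#'   `manifest` (tibble `stage`, `file`, `md5`).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  if (missing(outdir)) abort("`outdir` is required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hd <- function(stage, ...) {
    c(sprintf("medipdmr stage=%s", stage),
      sprintf("master_seed=%d", config$master_seed), ...)
  }
  paths <- list()

  if (config$simulate) {
    cfg <- config$sim
    cfg$seed <- stage_seed(config$master_seed, "simulate")
    ann <- simulate_genome(cfg)
    sim <- simulate_depths(ann, cfg)
    expr <- simulate_expression(ann, sim$depth, sim$groups, cfg,
                                feature_type = "gene")
    mirna_expr <- simulate_expression(ann, sim$depth, sim$groups, cfg,
                                      feature_type = "mirna")

    paths$chrom_sizes <- write_chrom_sizes(
      ann$chrom_sizes, file.path(outdir, "genome.chrom.sizes"))
    paths$gtf <- write_gtf(ann, file.path(outdir, "annotation.gtf"))
    paths$cgis <- write_bed6(ann$cgis |> mutate(name = .data$cgi_id),
                             file.path(outdir, "cgi.bed"),
                             header = hd("simulate"))
    paths$truth <- write_bed6(
      sim$truth |> mutate(name = sprintf("planted_%04d", dplyr::row_number()),
                          strand = "."),
      file.path(outdir, "planted_truth.bed"),
      header = hd("simulate", sprintf("n_planted=%d", nrow(sim$truth))),
      extra_cols = c("fold", "direction"))
    paths$depth <- write_header_tsv(
      sim$depth, file.path(outdir, "depth_raw.tsv"),
      hd("simulate", sprintf("nb_mean=%g nb_dispersion=%g", cfg$nb_mean,
                             cfg$nb_dispersion)))
    paths$groups <- write_header_tsv(sim$groups,
                                     file.path(outdir, "sample_groups.tsv"),
                                     hd("simulate"))
  } else {
    for (nm in c("depth_path", "groups_path", "chrom_sizes_path")) {
      p <- config[[nm]]
      if (is.null(p) || !file.exists(p)) {
        abort(sprintf("simulate disabled and required input `%s` missing: %s",
                      nm, p %||% "<unset>"))
      }
    }
    ann <- structure(
      list(chrom_sizes = read_chrom_sizes(config$chrom_sizes_path),
           genes = tibble(), exons = tibble(), cgis = tibble(),
           mirnas = tibble(), repeats = NULL, snps = NULL),
      class = "genome_annotation")
    sim <- list(depth = read_pkg_tsv(config$depth_path),
                groups = read_pkg_tsv(config$groups_path),
                truth = tibble())
    expr <- NULL
    mirna_expr <- NULL
  }

  filt <- filter_low_coverage(sim$depth, config$min_depth,
                              config$min_depth_mode)
  norm <- normalize_depths(filt, sim$groups)
  paths$norm <- write_header_tsv(
    norm, file.path(outdir, "depth_filtered_normalized.tsv"),
    hd("normalize",
       sprintf("min_depth=%g mode=%s retained=%.6f", config$min_depth,
               config$min_depth_mode, attr(filt, "retained_fraction"))))

  dcfg <- config$dmr
  dcfg$perm_seed <- stage_seed(config$master_seed, "dmr")
  dmrs <- call_dmrs(norm, sim$groups, dcfg)
  dmr_tbl <- tidy(dmrs, all = FALSE)
  paths$dmrs <- write_bed6(
    dmr_tbl |> mutate(name = sprintf("dmr_%05d", dplyr::row_number()),
                      score = pmin(1000, round(-10 * log10(.data$q))),
                      strand = "."),
    file.path(outdir, "dmrs.bed"),
    header = hd("call-dmrs",
                sprintf("site_alpha=%g max_gap=%g max_span=%g min_sig_cpgs=%d fdr=%g n_perm=%d perm_seed=%d",
                        dcfg$site_alpha, dcfg$max_gap, dcfg$max_span,
                        dcfg$min_sig_cpgs, dcfg$fdr_threshold,
                        dcfg$n_permutations, dcfg$perm_seed)),
    extra_cols = c("n_cpgs", "n_sig", "mean_a", "mean_b", "log2_ratio",
                   "p_region", "q"))
  paths$sites <- write_header_tsv(attr(dmrs, "sites"),
                                  file.path(outdir, "site_tests.tsv"),
                                  hd("call-dmrs"))

  if (nrow(ann$genes)) {
    catalogue <- element_catalogue(ann,
                                   promoter_up = config$integration$promoter_up,
                                   downstream = config$integration$downstream)
    cpg_ann <- tibble(chrom = norm$chrom, pos = norm$pos,
                      element = annotate_position(norm$chrom, norm$pos,
                                                  catalogue,
                                                  ann$chrom_sizes$chrom))
    paths$annotation <- write_header_tsv(cpg_ann,
                                         file.path(outdir, "cpg_elements.tsv"),
                                         hd("annotate"))
  }
  profile <- windowed_profile(norm, sim$groups, ann, config$window)
  paths$profile <- write_header_tsv(
    profile, file.path(outdir, "windowed_profile.tsv"),
    hd("profile", sprintf("window=%g", config$window)))

  zones <- zone_methylation(norm, sim$groups, ann, config$subtel_span)
  paths$zones <- write_header_tsv(
    zones, file.path(outdir, "zone_methylation.tsv"),
    hd("context", sprintf("subtel_span=%g", config$subtel_span)))

  de <- fm <- cors <- asg <- NULL
  if (nrow(ann$genes) && !is.null(expr)) {
    de <- differential_expression(expr$expression, sim$groups,
                                  config$integration)
    fm <- feature_methylation(norm, sim$groups, ann, config$integration)
    asg <- assign_dmrs(dmr_tbl, ann, config$integration)
    cors <- bind_rows(
      methylation_expression_correlation(fm, expr$expression, sim$groups,
                                         "promoter", "levels"),
      methylation_expression_correlation(fm, expr$expression, sim$groups,
                                         "gene_body", "levels"))
    pairs <- classify_pairs(fm, de, asg$assignments)
    paths$integration <- write_header_tsv(
      cors, file.path(outdir, "methylation_expression_correlation.tsv"),
      hd("integrate"))
    paths$pairs <- write_header_tsv(as_tibble(pairs),
                                    file.path(outdir, "pairs.tsv"),
                                    hd("integrate"))
    paths$dmr_counts <- write_header_tsv(asg$counts,
                                         file.path(outdir,
                                                   "dmr_compartment_counts.tsv"),
                                         hd("integrate"))
  }

  files <- unlist(paths, use.names = FALSE)
  manifest <- tibble(
    stage = names(paths),
    file = basename(files),
    md5 = unname(tools::md5sum(files))
  )
  write_header_tsv(manifest, file.path(outdir, "manifest.tsv"),
                   hd("manifest"))
  list(results = list(annotation = ann, sim = sim, expression = expr,
                      mirna_expression = mirna_expr, normalized = norm,
                      dmrs = dmrs, profile = profile, zones = zones,
                      de = de, feature_methylation = fm,
                      correlations = cors, assignments = asg),
       manifest = manifest)
}
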