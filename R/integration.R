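#' Integration configuration
#'
#' Spans and differential-expression thresholds used when joining
#' methylation with expression: the promoter is the 2-kb region upstream of
#' the TSS, the downstream compartment the 2-kb region after the TTS, and
#' the miRNA promoter the 2-kb region upstream of the annotated locus start
#' (all strand-aware).
#'
#' @param promoter_up bp upstream of the TSS.
#' @param downstream bp after the TTS.
#' @param mirna_promoter_up bp upstream of the miRNA locus.
#' @param de_alpha BH q-value threshold for differential expression.
#' @param de_min_fold minimum fold change (linear scale) for DE.
#' @return list of class `integration_config`.
#' @export
integration_config <- function(promoter_up = 2000, downstream = 2000,
                               mirna_promoter_up = 2000,
                               de_alpha = 0.05, de_min_fold = 1.5) {
  if (promoter_up <= 0 || downstream <= 0 || mirna_promoter_up <= 0) {
    abort("all spans must be positive")
  }
  structure(list(promoter_up = promoter_up, downstream = downstream,
                 mirna_promoter_up = mirna_promoter_up,
                 de_alpha = de_alpha, de_min_fold = de_min_fold),
            class = "integration_config")
}

# strand-aware compartment intervals for each gene: promoter upstream of
# the TSS, gene body = the annotated span, downstream after the TTS;
# disjoint by construction
gene_compartments <- function(genes, config) {
  bind_rows(
    genes |>
      mutate(start = ifelse(.data$strand == "+",
                            pmax(0, .data$tss - config$promoter_up),
                            .data$tss),
             end = ifelse(.data$strand == "+",
                          .data$tss, .data$tss + config$promoter_up),
             compartment = "promoter"),
    genes |> mutate(compartment = "gene_body"),
    genes |>
      mutate(start = ifelse(.data$strand == "+",
                            .data$tts, pmax(0, .data$tts - config$downstream)),
             end = ifelse(.data$strand == "+",
                          .data$tts + config$downstream, .data$tts),
             compartment = "downstream")
  ) |>
    select(feature_id = "gene_id", "chrom", "start", "end", "compartment")
}

#' Assign DMRs to gene compartments
#'
#' A DMR is assigned to every compartment it overlaps by at least 1 bp
#' (half-open intersection); with `unique_assignment = TRUE` each DMR
#' counts once, resolved by the priority promoter > gene body > downstream.
#' DMRs overlapping nothing are tallied as intergenic.
#'
#' @param dmrs tibble of regions (`chrom`, `start`, `end`), e.g. a
#'   `dmr_result`.
#' @param annotation a `genome_annotation`.
#' @param config an [integration_config()].
#' @param unique_assignment assign each DMR to a single compartment.
#' @return list with `assignments` (tibble `dmr_id`, `feature_id`,
#'   `compartment`) and `counts` (tibble `compartment`, `n_dmrs`).
#' @export
assign_dmrs <- function(dmrs, annotation, config = integration_config(),
                        unique_assignment = FALSE) {
  dmrs <- as_tibble(dmrs)
  comp <- gene_compartments(annotation$genes, config)
  comp_rank <- c(promoter = 1, gene_body = 2, downstream = 3)
  if (!nrow(dmrs)) {
    return(list(assignments = tibble(dmr_id = integer(),
                                     feature_id = character(),
                                     compartment = character()),
                counts = tibble(compartment = names(comp_rank),
                                n_dmrs = 0L)))
  }
  hits <- GenomicRanges::findOverlaps(tbl_to_gr(dmrs), tbl_to_gr(comp))
  asg <- tibble(dmr_id = S4Vectors::queryHits(hits),
                feature_id = comp$feature_id[S4Vectors::subjectHits(hits)],
                compartment = comp$compartment[S4Vectors::subjectHits(hits)]) |>
    dplyr::distinct()
  if (unique_assignment) {
    asg <- asg |>
      mutate(rank = comp_rank[.data$compartment]) |>
      arrange(.data$dmr_id, .data$rank) |>
      dplyr::distinct(.data$dmr_id, .keep_all = TRUE) |>
      select(-"rank")
  }
  counts <- tibble(compartment = names(comp_rank)) |>
    left_join(asg |> dplyr::distinct(.data$dmr_id, .data$compartment) |>
                count(.data$compartment, name = "n_dmrs"),
              by = "compartment") |>
    mutate(n_dmrs = ifelse(is.na(.data$n_dmrs), 0L, .data$n_dmrs))
  counts <- bind_rows(counts,
                      tibble(compartment = "intergenic",
                             n_dmrs = sum(!seq_len(nrow(dmrs)) %in% asg$dmr_id)))
  list(assignments = asg, counts = counts)
}

#' Per-feature compartment methylation
#'
#' Mean normalized depth over the retained CpGs of each gene compartment
#' (promoter / gene body / downstream), overall and per group. Features
#' with no CpGs in a compartment carry NA means and `n_cpgs = 0`.
#'
#' @param depth normalized depth table.
#' @param groups sample-to-group map.
#' @param annotation a `genome_annotation`.
#' @param config an [integration_config()].
#' @param features `"gene"` or `"mirna"` (miRNAs have a promoter
#'   compartment only).
#' @return tibble `feature_id`, `compartment`, `n_cpgs`, `mean_norm`,
#'   `mean_a`, `mean_b`, `meth_diff` (B - A).
#' @export
feature_methylation <- function(depth, groups, annotation,
                                config = integration_config(),
                                features = c("gene", "mirna")) {
  features <- match.arg(features)
  check_depth_table(depth)
  groups <- check_groups(depth, groups)
  lv <- group_levels(groups)
  comp <- if (features == "gene") {
    gene_compartments(annotation$genes, config)
  } else {
    annotation$mirnas |>
      mutate(anchor = ifelse(.data$strand == "+", .data$start, .data$end),
             start = ifelse(.data$strand == "+",
                            pmax(0, .data$anchor - config$mirna_promoter_up),
                            .data$anchor),
             end = ifelse(.data$strand == "+",
                          .data$anchor,
                          .data$anchor + config$mirna_promoter_up),
             compartment = "promoter") |>
      select(feature_id = "mirna_id", "chrom", "start", "end", "compartment")
  }
  a <- rowMeans(as.matrix(depth[, groups$sample[groups$group == lv[1]],
                                drop = FALSE]))
  b <- rowMeans(as.matrix(depth[, groups$sample[groups$group == lv[2]],
                                drop = FALSE]))
  hits <- GenomicRanges::findOverlaps(pos_to_gr(depth$chrom, depth$pos),
                                      tbl_to_gr(comp))
  agg <- tibble(s = S4Vectors::subjectHits(hits),
                a = a[S4Vectors::queryHits(hits)],
                b = b[S4Vectors::queryHits(hits)]) |>
    group_by(.data$s) |>
    summarise(n_cpgs = n(), mean_a = mean(.data$a), mean_b = mean(.data$b),
              .groups = "drop")
  comp |>
    mutate(s = row_number()) |>
    left_join(agg, by = "s") |>
    mutate(n_cpgs = ifelse(is.na(.data$n_cpgs), 0L, .data$n_cpgs),
           mean_norm = (.data$mean_a + .data$mean_b) / 2,
           meth_diff = .data$mean_b - .data$mean_a) |>
    select("feature_id", "compartment", "n_cpgs", "mean_norm",
           "mean_a", "mean_b", "meth_diff")
}

#' Differential expression between two groups
#'
#' Per-feature two-sample pooled t-test on (log-scale) expression with BH
#' adjustment; a feature is differentially expressed when q < `de_alpha`
#' and |log2 fold change| >= log2(`de_min_fold`). Constant features get
#' p = 1.
#'
#' @param expr expression tibble: `feature_id` + one column per sample.
#' @param groups sample-to-group map.
#' @param config an [integration_config()].
#' @param log2_transform set `TRUE` when `expr` holds linear-scale values
#'   (they are log2(x + 1) transformed first); the default assumes values
#'   already on a log-like scale.
#' @return tibble `feature_id`, `lfc` (B - A), `p`, `q`, `de`,
#'   `direction` (`up_in_B` / `down_in_B` / `ns`).
#' @export
differential_expression <- function(expr, groups,
                                    config = integration_config(),
                                    log2_transform = FALSE) {
  groups <- check_groups(expr, groups, key = "feature_id")
  lv <- group_levels(groups)
  if (any(table(groups$group) < 2)) abort("each group needs >= 2 samples")
  A <- as.matrix(expr[, groups$sample[groups$group == lv[1]], drop = FALSE])
  B <- as.matrix(expr[, groups$sample[groups$group == lv[2]], drop = FALSE])
  if (log2_transform) { A <- log2(A + 1); B <- log2(B + 1) }
  na <- ncol(A); nb <- ncol(B); N <- na + nb
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- (rowSums(A * A) - na * mA^2) / (na - 1)
  vB <- (rowSums(B * B) - nb * mB^2) / (nb - 1)
  sp2 <- ((na - 1) * pmax(vA, 0) + (nb - 1) * pmax(vB, 0)) / (N - 2)
  tt <- (mB - mA) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * pt(-abs(tt), df = N - 2)
  p[!is.finite(tt)] <- 1  # constant features
  q <- bh_adjust(p)
  lfc <- mB - mA
  de <- q < config$de_alpha & abs(lfc) >= log2(config$de_min_fold)
  tibble(feature_id = expr$feature_id, lfc = lfc, p = p, q = q, de = de,
         direction = dplyr::case_when(
           de & lfc > 0 ~ "up_in_B",
           de & lfc < 0 ~ "down_in_B",
           TRUE ~ "ns"))
}

#' Correlate feature methylation with expression
#'
#' Pearson correlation across features between methylation and expression,
#' either on group differences (`mode = "difference"`: B - A methylation
#' difference vs log2 fold change) or on levels (`mode = "levels"`:
#' per-feature mean methylation vs mean expression).
#'
#' @param fm [feature_methylation()] output for one compartment (filter
#'   first, or pass `compartment`).
#' @param expr expression tibble (`feature_id` + sample columns).
#' @param groups sample-to-group map.
#' @param compartment compartment to keep from `fm`.
#' @param mode `"difference"` or `"levels"`.
#' @return tibble `compartment`, `mode`, `r`, `p`, `n`.
#' @export
methylation_expression_correlation <- function(fm, expr, groups,
                                               compartment = "promoter",
                                               mode = c("difference",
                                                        "levels")) {
  mode <- match.arg(mode)
  groups <- check_groups(expr, groups, key = "feature_id")
  lv <- group_levels(groups)
  fm <- fm[fm$compartment == compartment & fm$n_cpgs > 0, , drop = FALSE]
  A <- rowMeans(as.matrix(expr[, groups$sample[groups$group == lv[1]],
                               drop = FALSE]))
  B <- rowMeans(as.matrix(expr[, groups$sample[groups$group == lv[2]],
                               drop = FALSE]))
  ex <- tibble(feature_id = expr$feature_id,
               expr_diff = B - A, expr_level = (A + B) / 2)
  d <- inner_join(fm, ex, by = "feature_id")
  x <- if (mode == "difference") d$meth_diff else d$mean_norm
  y <- if (mode == "difference") d$expr_diff else d$expr_level
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("need >= 3 complete feature pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(compartment = compartment, mode = mode, r = NA_real_,
                  p = NA_real_, n = length(x)))
  }
  ct <- cor.test(x, y)
  tibble(compartment = compartment, mode = mode, r = unname(ct$estimate),
         p = ct$p.value, n = length(x))
}

#' Classify methylation-expression pairs by sign
#'
#' For features that both carry a DMR and are differentially expressed,
#' classifies the relation as `negative` when the methylation difference
#' and the expression difference have opposite signs, `positive` when they
#' agree. Counts of each relation are attached as attribute `counts`.
#'
#' @param fm [feature_methylation()] output (one compartment).
#' @param de [differential_expression()] output.
#' @param assignments optional `assignments` tibble from [assign_dmrs()];
#'   when supplied, "DMR-bearing" means the feature appears there (any
#'   compartment), otherwise every feature with `meth_diff != 0` in `fm` is
#'   eligible.
#' @param compartment compartment of `fm` to use.
#' @return tibble `feature_id`, `meth_diff`, `expr_diff`, `relation`.
#' @export
classify_pairs <- function(fm, de, assignments = NULL,
                           compartment = "promoter") {
  fm <- fm[fm$compartment == compartment & fm$n_cpgs > 0, , drop = FALSE]
  d <- inner_join(fm, de, by = "feature_id") |>
    filter(.data$de)
  if (!is.null(assignments)) {
    d <- d[d$feature_id %in% unique(assignments$feature_id), , drop = FALSE]
  }
  d <- d |>
    filter(.data$meth_diff != 0, .data$lfc != 0) |>
    mutate(relation = ifelse(sign(.data$meth_diff) != sign(.data$lfc),
                             "negative", "positive")) |>
    select("feature_id", "meth_diff", expr_diff = "lfc", "relation")
  structure(d, counts = c(negative = sum(d$relation == "negative"),
                          positive = sum(d$relation == "positive")))
}

#' miRNA promoter methylation vs miRNA expression
#'
#' Computes per-miRNA promoter methylation (2 kb upstream of the locus on
#' its strand) per group and correlates it with miRNA expression across
#' miRNAs ([methylation_expression_correlation()], levels mode by
#' default). miRNAs without promoter CpGs are flagged and excluded from
#' the correlation.
#'
#' @param depth normalized depth table.
#' @param groups sample-to-group map.
#' @param annotation a `genome_annotation` with `mirnas`.
#' @param mirna_expr miRNA expression tibble (`feature_id` + samples).
#' @param config an [integration_config()].
#' @param mode correlation mode, see
#'   [methylation_expression_correlation()].
#' @return list with `per_mirna` (tibble) and `correlation` (tibble
#'   `r`, `p`, `n`).
#' @export
mirna_promoter_analysis <- function(depth, groups, annotation, mirna_expr,
                                    config = integration_config(),
                                    mode = c("levels", "difference")) {
  mode <- match.arg(mode)
  fm <- feature_methylation(depth, groups, annotation, config,
                            features = "mirna")
  cor_tbl <- methylation_expression_correlation(
    fm, mirna_expr, groups, compartment = "promoter", mode = mode)
  list(per_mirna = fm |> mutate(flagged_no_cpg = .data$n_cpgs == 0),
       correlation = cor_tbl)
}

#' Down-regulated targets of up-regulated miRNAs
#'
#' For each direction, enumerates genes that are targets of at least one
#' up-regulated miRNA and are themselves down-regulated (miRNA repression
#' signature). A gene targeted by several qualifying miRNAs appears once in
#' the gene tally but once per miRNA in the pair list.
#'
#' @param de_mirnas [differential_expression()] output for miRNAs.
#' @param de_genes [differential_expression()] output for genes.
#' @param targets tibble `mirna_id`, `gene_id` (externally supplied pairs).
#' @return list with `pairs` (tibble `mirna_id`, `gene_id`,
#'   `mirna_direction`) and `gene_counts` (tibble `mirna_direction`,
#'   `n_genes` of unique down-regulated targets).
#' @export
reverse_target_pairs <- function(de_mirnas, de_genes, targets) {
  dirs <- tibble(mirna_direction = c("up_in_B", "up_in_A"),
                 mir_dir = c("up_in_B", "down_in_B"),
                 gene_dir = c("down_in_B", "up_in_B"))
  pairs <- purrr::map_dfr(seq_len(nrow(dirs)), function(i) {
    mir_up <- de_mirnas$feature_id[de_mirnas$direction == dirs$mir_dir[i]]
    gene_dn <- de_genes$feature_id[de_genes$direction == dirs$gene_dir[i]]
    targets |>
      filter(.data$mirna_id %in% mir_up, .data$gene_id %in% gene_dn) |>
      dplyr::distinct(.data$mirna_id, .data$gene_id) |>
      mutate(mirna_direction = dirs$mirna_direction[i])
  })
  gene_counts <- dirs |>
    select("mirna_direction") |>
    left_join(pairs |> group_by(.data$mirna_direction) |>
                summarise(n_genes = dplyr::n_distinct(.data$gene_id),
                          .groups = "drop"),
              by = "mirna_direction") |>
    mutate(n_genes = ifelse(is.na(.data$n_genes), 0L, .data$n_genes))
  list(pairs = pairs, gene_counts = gene_counts)
}
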