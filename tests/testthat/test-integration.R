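toy_annotation <- function() {
  genes <- tibble::tibble(
    gene_id = c("gplus", "gminus"),
    chrom = "chr1",
    start = c(10000, 40000),
    end = c(20000, 50000),
    strand = c("+", "-"),
    tss = c(10000, 50000),
    tts = c(20000, 40000)
  )
  structure(list(
    chrom_sizes = tibble::tibble(chrom = "chr1", length = 1e5),
    genes = genes, exons = tibble::tibble(), cgis = tibble::tibble(),
    mirnas = tibble::tibble(
      mirna_id = c("mir1", "mir2"), chrom = "chr1",
      start = c(70000, 80000), end = c(70100, 80100),
      strand = c("+", "-")),
    repeats = NULL, snps = NULL), class = "genome_annotation")
}

toy_depth <- function(pos, a, b) {
  tibble::tibble(chrom = "chr1", pos = pos,
                 A1 = a, A2 = a, B1 = b, B2 = b)
}

toy_groups <- tibble::tibble(sample = c("A1", "A2", "B1", "B2"),
                             group = c("A", "A", "B", "B"))

test_that("DMRs are assigned to every overlapped compartment", {
  ann <- toy_annotation()
  dmrs <- tibble::tibble(
    chrom = "chr1",
    start = c(8500, 9800, 60000),
    end = c(9500, 10500, 61000)
  )
  asg <- assign_dmrs(dmrs, ann)
  # wholly inside the + promoter [8000, 10000)
  expect_equal(asg$assignments$compartment[asg$assignments$dmr_id == 1],
               "promoter")
  # straddles the TSS: both promoter and gene body
  expect_setequal(asg$assignments$compartment[asg$assignments$dmr_id == 2],
                  c("promoter", "gene_body"))
  # far from every feature: intergenic only
  expect_false(3 %in% asg$assignments$dmr_id)
  expect_equal(asg$counts$n_dmrs[asg$counts$compartment == "intergenic"], 1)
  expect_equal(asg$counts$n_dmrs[asg$counts$compartment == "promoter"], 2)

  # unique assignment resolves by priority promoter > gene body
  asg_u <- assign_dmrs(dmrs, ann, unique_assignment = TRUE)
  expect_equal(asg_u$assignments$compartment[asg_u$assignments$dmr_id == 2],
               "promoter")

  # brute-force overlap scan agreement
  comp <- medipdmr:::gene_compartments(ann$genes, integration_config())
  brute <- do.call(rbind, lapply(seq_len(nrow(dmrs)), function(i) {
    hit <- comp[comp$start < dmrs$end[i] & comp$end > dmrs$start[i], ]
    if (!nrow(hit)) return(NULL)
    data.frame(dmr_id = i, feature_id = hit$feature_id,
               compartment = hit$compartment)
  }))
  got <- as.data.frame(asg$assignments[order(asg$assignments$dmr_id,
                                             asg$assignments$compartment), ])
  brute <- brute[order(brute$dmr_id, brute$compartment), ]
  rownames(got) <- rownames(brute) <- NULL
  expect_equal(got, brute)
})

test_that("feature methylation is strand-aware and flags CpG-free features", {
  ann <- toy_annotation()
  # CpGs: two in + promoter, one in + body, two in the - promoter
  # (- promoter is [50000, 52000) in genome coordinates)
  d <- toy_depth(pos = c(8100, 9900, 15000, 50500, 51900),
                 a = c(0.5, 1.5, 1.0, 2.0, 2.0),
                 b = c(1.0, 3.0, 1.0, 1.0, 1.0))
  fm <- feature_methylation(d, toy_groups, ann)
  pp <- fm[fm$feature_id == "gplus" & fm$compartment == "promoter", ]
  expect_equal(pp$n_cpgs, 2)
  expect_equal(pp$mean_a, 1.0)       # mean of (0.5, 1.5)
  expect_equal(pp$mean_b, 2.0)
  expect_equal(pp$meth_diff, 1.0)
  pm <- fm[fm$feature_id == "gminus" & fm$compartment == "promoter", ]
  expect_equal(pm$n_cpgs, 2)         # both CpGs upstream of the - TSS
  expect_equal(pm$mean_a, 2.0)
  dn <- fm[fm$feature_id == "gminus" & fm$compartment == "downstream", ]
  expect_equal(dn$n_cpgs, 0)         # no CpGs -> flagged missing
  expect_true(is.na(dn$mean_norm))

  # miRNA promoters: 2 kb upstream on the locus strand
  dm <- toy_depth(pos = c(68500, 81500), a = c(1, 2), b = c(3, 4))
  fmm <- feature_methylation(dm, toy_groups, ann, features = "mirna")
  expect_equal(fmm$n_cpgs[fmm$feature_id == "mir1"], 1)  # [68000, 70000)
  expect_equal(fmm$n_cpgs[fmm$feature_id == "mir2"], 1)  # [80100, 82100)
})

test_that("differential expression applies the t-test, BH and fold gates", {
  g <- toy_groups
  # identical groups: nothing differentially expressed
  e0 <- tibble::tibble(feature_id = paste0("f", 1:5),
                       A1 = 1:5, A2 = 1:5, B1 = 1:5, B2 = 1:5)
  de0 <- differential_expression(e0, g)
  expect_true(all(!de0$de))
  expect_true(all(de0$p == 1))

  # planted 4-fold (2 units on log2 scale) shift with tiny noise
  set.seed(2)
  n <- 200
  e <- tibble::tibble(feature_id = paste0("f", 1:n))
  for (s in g$sample) e[[s]] <- rnorm(n, 5, 0.01)
  e$B1[1] <- e$B1[1] + 2; e$B2[1] <- e$B2[1] + 2
  de <- differential_expression(e, g)
  expect_true(de$de[1])
  expect_equal(de$direction[1], "up_in_B")
  # hand-computed t for the planted feature
  ref <- stats::t.test(as.numeric(e[1, c("B1", "B2")]),
                       as.numeric(e[1, c("A1", "A2")]), var.equal = TRUE)
  expect_equal(de$p[1], ref$p.value, tolerance = 1e-9)
  expect_equal(de$lfc[1], unname(diff(rev(ref$estimate))), tolerance = 1e-9)

  # null features: raw p ~ alpha rate, BH wipes them out
  expect_lt(mean(de$p[-1] < 0.05), 0.12)
  expect_equal(sum(de$de[-1]), 0)
})

test_that("methylation-expression correlation supports both pairing modes", {
  ann <- toy_annotation()
  fm <- tibble::tibble(
    feature_id = paste0("f", 1:50),
    compartment = "promoter",
    n_cpgs = 5,
    mean_a = seq(1, 2, length.out = 50),
    mean_b = seq(2, 1, length.out = 50)
  ) |>
    dplyr::mutate(mean_norm = (mean_a + mean_b) / 2,
                  meth_diff = mean_b - mean_a)
  # expression difference exactly opposite the methylation difference
  expr <- tibble::tibble(feature_id = fm$feature_id,
                         A1 = 0, A2 = 0,
                         B1 = -fm$meth_diff, B2 = -fm$meth_diff)
  out <- methylation_expression_correlation(fm, expr, toy_groups,
                                            mode = "difference")
  expect_equal(out$r, -1)
  expect_equal(out$n, 50)

  # independence: |r| small over 2000 simulated pairs
  set.seed(9)
  fm2 <- tibble::tibble(feature_id = paste0("g", 1:2000),
                        compartment = "promoter", n_cpgs = 1,
                        mean_a = rnorm(2000), mean_b = rnorm(2000)) |>
    dplyr::mutate(mean_norm = (mean_a + mean_b) / 2,
                  meth_diff = mean_b - mean_a)
  expr2 <- tibble::tibble(feature_id = fm2$feature_id,
                          A1 = rnorm(2000), A2 = rnorm(2000),
                          B1 = rnorm(2000), B2 = rnorm(2000))
  out2 <- methylation_expression_correlation(fm2, expr2, toy_groups,
                                             mode = "levels")
  expect_lt(abs(out2$r), 0.05)

  expect_error(methylation_expression_correlation(fm[1:2, ], expr[1:2, ],
                                                  toy_groups),
               ">= 3")
})

test_that("pair classification follows the sign-opposition rule", {
  fm <- tibble::tibble(
    feature_id = paste0("f", 1:5),
    compartment = "promoter", n_cpgs = 3,
    mean_a = 1, mean_b = 1 + c(1, 1, -1, -1, 1),
    mean_norm = 1, meth_diff = c(1, 1, -1, -1, 1)
  )
  de <- tibble::tibble(feature_id = paste0("f", 1:5),
                       lfc = c(-2, -1, 1, -1, 2),
                       p = 0.001, q = 0.001, de = TRUE,
                       direction = "up_in_B")
  pairs <- classify_pairs(fm, de)
  # hyper+down, hyper+down, hypo+up -> negative; hypo+down, hyper+up -> positive
  expect_equal(unname(attr(pairs, "counts")),
               c(3, 2))
  expect_equal(pairs$relation,
               c("negative", "negative", "negative", "positive", "positive"))
  # negative + positive = number of DMR-bearing DE features
  expect_equal(sum(attr(pairs, "counts")), nrow(pairs))
})

test_that("miRNA promoter analysis couples methylation and expression", {
  cfg <- sim_config(chrom_length = 4e6, cpg_spacing_mean = 150,
                    genes_per_chrom = 50, mirnas_per_chrom = 300,
                    coupling_r = -0.6, expr_rep_sd = 0.05, seed = 27)
  ann <- simulate_genome(cfg)
  sim <- simulate_depths(ann, cfg)
  ex <- simulate_expression(ann, sim$depth, sim$groups, cfg,
                            feature_type = "mirna")
  norm <- normalize_depths(sim$depth, sim$groups)
  out <- mirna_promoter_analysis(norm, sim$groups, ann, ex$expression)
  expect_lt(abs(out$correlation$r - (-0.6)), 0.1)
  expect_gte(out$correlation$n, 250)

  # constant promoter methylation -> undefined-correlation marker
  dz <- norm
  for (s in sim$groups$sample) dz[[s]] <- 1
  outz <- mirna_promoter_analysis(dz, sim$groups, ann, ex$expression)
  expect_true(is.na(outz$correlation$r))

  # a single miRNA cannot be correlated
  ann1 <- ann
  ann1$mirnas <- ann$mirnas[1, ]
  expect_error(mirna_promoter_analysis(norm, sim$groups, ann1,
                                       ex$expression),
               ">= 3")
})

test_that("reverse miRNA-target enumeration counts unique repressed genes", {
  de_mir <- tibble::tibble(feature_id = c("m1", "m2", "m3"),
                           lfc = c(2, 1.5, -2), p = 0, q = 0, de = TRUE,
                           direction = c("up_in_B", "up_in_B", "down_in_B"))
  de_gene <- tibble::tibble(feature_id = c("g1", "g2", "g3", "g4"),
                            lfc = c(-2, -2, 2, -2), p = 0, q = 0, de = TRUE,
                            direction = c("down_in_B", "down_in_B",
                                          "up_in_B", "down_in_B"))
  targets <- tibble::tibble(
    mirna_id = c("m1", "m1", "m2", "m3", "m3"),
    gene_id = c("g2", "g3", "g2", "g3", "g1"))
  out <- reverse_target_pairs(de_mir, de_gene, targets)
  up_b <- out$pairs[out$pairs$mirna_direction == "up_in_B", ]
  # g2 targeted by both up miRNAs: 2 pairs, 1 unique gene
  expect_equal(nrow(up_b), 2)
  expect_equal(out$gene_counts$n_genes[
    out$gene_counts$mirna_direction == "up_in_B"], 1)
  # m3 up in A targets g3 (up in B = down in A): 1 pair
  up_a <- out$pairs[out$pairs$mirna_direction == "up_in_A", ]
  expect_equal(up_a$gene_id, "g3")

  # empty target table
  out0 <- reverse_target_pairs(de_mir, de_gene, targets[0, ])
  expect_equal(nrow(out0$pairs), 0)
  expect_true(all(out0$gene_counts$n_genes == 0))
})
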