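sites_tbl <- function(pos, p, chrom = "chr1") {
  tibble::tibble(chrom = chrom, pos = pos, p = p)
}

test_that("seed-and-extend follows the adjacency, span and significance rules", {
  cfg <- dmr_config()
  # five adjacent significant CpGs -> one region spanning them
  s <- sites_tbl(c(100, 250, 380, 500, 650), rep(0.001, 5))
  out <- seed_extend(s, cfg)
  expect_equal(nrow(out), 1)
  expect_equal(out$start, 100)
  expect_equal(out$end, 651)
  expect_equal(out$n_sig, 5)

  # four significant CpGs then a 250 bp gap: below the member minimum
  s2 <- sites_tbl(c(0, 100, 200, 300, 550), rep(0.001, 5))
  expect_equal(nrow(seed_extend(s2, cfg)), 0)

  # span cap: members past 2 kb from the seed start a new region
  pos <- seq(0, by = 190, length.out = 16)   # 0 .. 2850
  s3 <- sites_tbl(pos, rep(0.001, 16))
  out3 <- seed_extend(s3, cfg)
  expect_equal(nrow(out3), 2)
  expect_equal(out3$start[1], 0)
  expect_lte(out3$end[1] - 1 - out3$start[1], cfg$max_span)
  expect_equal(out3$start[2], pos[which(pos > 2000)[1]])

  # a non-significant CpG terminates the region even within range
  s4 <- sites_tbl(seq(0, by = 100, length.out = 12),
                  c(rep(0.001, 5), 0.5, rep(0.001, 6)))
  out4 <- seed_extend(s4, cfg)
  expect_equal(out4$n_sig, c(5, 6))

  expect_error(seed_extend(sites_tbl(c(200, 100), c(0.1, 0.1)), cfg),
               "sorted")
})

test_that("seed-and-extend matches the brute-force enumeration oracle", {
  set.seed(99)
  cfg <- dmr_config(min_sig_cpgs = 3)
  for (i in 1:300) {
    n <- sample(1:20, 1)
    pos <- sort(sample.int(3000, n))
    p <- ifelse(runif(n) < 0.5, 0.001, 0.5)
    got <- seed_extend(sites_tbl(pos, p), cfg)
    want <- oracle_seed_extend(pos, p < cfg$site_alpha,
                               cfg$max_gap, cfg$max_span, cfg$min_sig_cpgs)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      expect_equal(got$start, pos[vapply(want, `[[`, 1, "first")])
      expect_equal(got$end, pos[vapply(want, `[[`, 1, "last")] + 1)
    }
  }
})

test_that("BH adjustment equals the naive step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.001, 0.008, 0.039, 0.041)),
               c(0.004, 0.016, 0.041, 0.041))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  set.seed(17)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    # monotone in p-rank
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("permutation p-values behave at the extremes and under the null", {
  sim <- strong_signal_sim(seed = 31, n_planted = 4)
  norm <- normalize_depths(sim$sim$depth, sim$sim$groups)
  cfg <- dmr_config(n_permutations = 1000, perm_seed = 5)

  # a strongly shifted planted region beats every null draw
  tr <- sim$sim$truth[sim$sim$truth$direction == "hyper_in_B", ][1, ]
  rows <- which(norm$pos >= tr$start & norm$pos < tr$end)
  rp <- region_pvalue(norm, sim$sim$groups, rows, cfg)
  expect_equal(rp$p_region, 1 / 1001)

  # observed statistic of zero can never beat the null
  dz <- norm
  for (s in sim$sim$groups$sample) dz[[s]] <- 1
  rp0 <- region_pvalue(dz, sim$sim$groups, 1:8, cfg)
  expect_equal(rp0$observed, 0)
  expect_equal(rp0$p_region, 1)

  # under exchangeability the p-values are ~ uniform (KS distance < 0.1)
  cfg0 <- sim_config(chrom_length = 1e6, cpg_spacing_mean = 100,
                     nb_mean = 20, nb_dispersion = 0.1, seed = 41)
  s0 <- simulate_depths(simulate_genome(cfg0), cfg0)
  n0 <- normalize_depths(s0$depth, s0$groups)
  set.seed(8)
  starts <- sample.int(nrow(n0) - 8, 150)
  cfg_p <- dmr_config(n_permutations = 400)
  ps <- vapply(starts, function(st)
    region_pvalue(n0, s0$groups, st:(st + 7), cfg_p, seed = NULL)$p_region,
    numeric(1))
  ks <- max(abs(sort(ps) - seq_along(ps) / length(ps)))
  expect_lt(ks, 0.1)
})

test_that("the full caller recovers strong planted regions and honours its invariants", {
  sim <- strong_signal_sim(seed = 23, n_planted = 20)
  norm <- normalize_depths(filter_low_coverage(sim$sim$depth), sim$sim$groups)
  cfg <- dmr_config(perm_seed = 77)
  res <- call_dmrs(norm, sim$sim$groups, cfg)

  expect_s3_class(res, "dmr_result")
  expect_gte(overlap_fraction(sim$sim$truth, res), 0.9)
  # directions recovered correctly for overlapping calls
  for (i in seq_len(nrow(res))) {
    tr <- sim$sim$truth[sim$sim$truth$start < res$end[i] &
                          sim$sim$truth$end > res$start[i], ]
    if (nrow(tr) == 1) expect_equal(res$direction[i], tr$direction)
  }
  # output invariants
  expect_true(all(res$n_sig >= cfg$min_sig_cpgs))
  expect_true(all(res$end - 1 - res$start <= cfg$max_span))
  expect_true(all(res$q < cfg$fdr_threshold))
  expect_true(all(res$p_region >= 1 / (cfg$n_permutations + 1)))

  # determinism under a fixed permutation seed
  res2 <- call_dmrs(norm, sim$sim$groups, cfg)
  expect_identical(as.data.frame(res), as.data.frame(res2))

  # tidiers
  g <- glance(res)
  expect_equal(g$n_dmrs, nrow(res))
  expect_gte(g$n_candidates, g$n_dmrs)
  expect_equal(nrow(tidy(res, all = TRUE)), g$n_candidates)

  # empty input
  empty <- call_dmrs(norm[0, ], sim$sim$groups)
  expect_equal(nrow(empty), 0)
})

test_that("plot methods return ggplot objects", {
  sim <- strong_signal_sim(seed = 23, n_planted = 10)
  norm <- normalize_depths(sim$sim$depth, sim$sim$groups)
  res <- call_dmrs(norm, sim$sim$groups, dmr_config(perm_seed = 1))
  expect_s3_class(autoplot(res), "ggplot")
  prof <- windowed_profile(norm, sim$sim$groups, sim$ann, window = 2e5)
  expect_s3_class(plot_windowed_profile(prof), "ggplot")
})
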