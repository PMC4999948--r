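make_depth <- function(rows) {
  # rows: list of per-sample depth vectors, one list element per CpG
  m <- do.call(rbind, rows)
  d <- tibble::tibble(chrom = "chr1", pos = seq(0, by = 100,
                                                length.out = nrow(m)))
  for (j in seq_len(ncol(m))) d[[paste0("s", j)]] <- m[, j]
  d
}

test_that("coverage filter applies the mean-depth rule and its variants", {
  d <- make_depth(list(c(12, 15, 11, 10, 13, 14),   # all >= 10
                       c(0, 0, 0, 0, 0, 0),         # all zero
                       c(9, 9, 9, 11, 11, 11)))     # mean exactly 10
  out <- filter_low_coverage(d, min_depth = 10)
  expect_equal(out$pos, c(0, 200))
  expect_equal(attr(out, "retained_fraction"), 2 / 3)

  # per-sample modes
  expect_equal(nrow(filter_low_coverage(d, 10, mode = "all")), 1)
  expect_equal(nrow(filter_low_coverage(d, 10, mode = "any")), 2)

  # idempotent (row content unchanged by a second pass)
  once <- filter_low_coverage(d, 10)
  twice <- filter_low_coverage(once, 10)
  attr(once, "retained_fraction") <- attr(twice, "retained_fraction") <- NULL
  expect_equal(twice, once)

  # empty input is an explicit empty result, not an error
  empty <- filter_low_coverage(d[0, ], 10)
  expect_equal(nrow(empty), 0)
})

test_that("normalization divides by the group grand mean", {
  d <- tibble::tibble(chrom = "chr1", pos = c(0, 100), A1 = c(10, 30))
  g <- tibble::tibble(sample = "A1", group = "A")
  expect_error(normalize_depths(d, g), "two group")

  d2 <- tibble::tibble(chrom = "chr1", pos = c(0, 100),
                       A1 = c(10, 30), B1 = c(20, 20))
  g2 <- tibble::tibble(sample = c("A1", "B1"), group = c("A", "B"))
  out <- normalize_depths(d2, g2)
  expect_equal(out$A1, c(0.5, 1.5))   # group mean 20
  expect_equal(out$B1, c(1, 1))

  # grand mean per group is exactly 1 on random data
  set.seed(1)
  dr <- make_depth(lapply(1:50, function(i) rpois(6, 30)))
  gr <- tibble::tibble(sample = paste0("s", 1:6),
                       group = rep(c("A", "B"), each = 3))
  nr <- normalize_depths(dr, gr)
  expect_equal(mean(as.matrix(nr[, paste0("s", 1:3)])), 1, tolerance = 1e-12)
  expect_equal(mean(as.matrix(nr[, paste0("s", 4:6)])), 1, tolerance = 1e-12)

  # all-zero group is a normalization error
  dz <- tibble::tibble(chrom = "chr1", pos = 0, A1 = 5, B1 = 0)
  expect_error(normalize_depths(dz, g2), "zero total depth")
})

test_that("promoter CpG classes follow the observed/expected thresholds", {
  expect_equal(classify_promoter(strrep("AT", 500)), "LCP")  # no CpG, GC 0
  expect_equal(classify_promoter(strrep("CG", 500)), "HCP")  # oe 2, GC 1

  # engineered intermediate case: 36 CG pairs, 250 C, 250 G in 1000 bp
  s <- paste0(strrep("CGA", 36), strrep("CA", 214), strrep("GA", 214),
              strrep("T", 36))
  expect_equal(nchar(s), 1000)
  # direct-count oracle
  nC <- lengths(regmatches(s, gregexpr("C", s)))
  nG <- lengths(regmatches(s, gregexpr("G", s)))
  nCG <- lengths(regmatches(s, gregexpr("CG", s)))
  oe <- nCG * 1000 / (nC * nG)
  expect_equal(oe, 0.576)
  expect_equal((nC + nG) / 1000, 0.5)
  expect_equal(classify_promoter(s), "ICP")

  expect_error(classify_promoter(strrep("N", 1000)), "all-N")
  expect_error(classify_promoter("ACGT"), ">= 200")
})

test_that("position annotation resolves overlaps by priority", {
  cat <- tibble::tibble(
    chrom = "chr1",
    start = c(1000, 1500, 5000),
    end = c(2000, 1800, 6000),
    element = c("exon", "CGI", "promoter"),
    priority = c(10, 1, 6)
  )
  expect_equal(annotate_position("chr1", 1600, cat), "CGI")     # CGI > exon
  expect_equal(annotate_position("chr1", 1100, cat), "exon")
  expect_equal(annotate_position("chr1", 9000, cat), "intergenic")
  expect_equal(annotate_position("chr1", 5500, cat), "promoter")
  expect_error(annotate_position("chrX", 10, cat), "unknown chromosome")

  # agreement with a brute-force scan over all intervals
  set.seed(42)
  cat2 <- tibble::tibble(
    chrom = "chr1",
    start = sample.int(1e5, 50),
    element = paste0("el", 1:50),
    priority = sample.int(50)
  )
  cat2$end <- cat2$start + sample.int(5000, 50)
  pos <- sample.int(1.1e5, 1e4) - 1
  got <- annotate_position(rep("chr1", length(pos)), pos, cat2)
  brute <- vapply(pos, function(p) {
    hit <- which(cat2$start <= p & p < cat2$end)
    if (!length(hit)) "intergenic"
    else cat2$element[hit[which.min(cat2$priority[hit])]]
  }, character(1))
  expect_identical(got, brute)
})

test_that("element catalogue derives strand-aware promoters and shores", {
  ann <- simulate_genome(sim_config(chrom_length = 1e6, genes_per_chrom = 20,
                                    seed = 9))
  cat <- element_catalogue(ann)
  expect_s3_class(cat, "element_catalogue")
  expect_true(all(c("CGI", "CGI_shore", "promoter", "first_exon") %in%
                    cat$element))
  # one promoter interval per gene, 2 kb, ending at the TSS on + strand
  prom <- cat[cat$element == "promoter", ]
  expect_equal(nrow(prom), 20)
  gplus <- ann$genes[ann$genes$strand == "+", ][1, ]
  expect_true(any(prom$start == gplus$tss - 2000 & prom$end == gplus$tss))
  gminus <- ann$genes[ann$genes$strand == "-", ][1, ]
  expect_true(any(prom$start == gminus$tss & prom$end == gminus$tss + 2000))
})

test_that("windowed profiles tile, average and reconcile", {
  ann <- structure(list(
    chrom_sizes = tibble::tibble(chrom = "chr1", length = 1e7),
    genes = tibble::tibble(gene_id = paste0("g", 1:3), chrom = "chr1",
                           start = c(100, 2e5, 9e5), end = c(5e3, 3e5, 1e6),
                           strand = "+", tss = c(100, 2e5, 9e5),
                           tts = c(5e3, 3e5, 1e6)),
    exons = tibble::tibble(), cgis = tibble::tibble(),
    mirnas = tibble::tibble(), repeats = NULL, snps = NULL),
    class = "genome_annotation")
  d <- tibble::tibble(chrom = "chr1", pos = c(5e5, 6e5, 25e5),
                      A1 = c(1, 3, 2), B1 = c(1, 3, 2))
  g <- tibble::tibble(sample = c("A1", "B1"), group = c("A", "B"))
  prof <- windowed_profile(d, g, ann, window = 1e6)
  expect_equal(nrow(prof), 10)                       # 10 Mb / 1 Mb
  expect_equal(prof$mean_norm_depth[1], 2)           # mean of (1, 3)
  expect_equal(prof$gene_density[1], 3)              # 3 TSS in window 1
  expect_true(is.na(prof$mean_norm_depth[5]))        # empty window

  # depth-weighted window means reconcile with the genome-wide mean
  w <- prof$n_cpgs > 0
  expect_equal(sum(prof$mean_norm_depth[w] * prof$n_cpgs[w]) /
                 sum(prof$n_cpgs[w]),
               mean(rowMeans(cbind(d$A1, d$B1))))
  expect_error(windowed_profile(d, g, ann, window = 0), "positive")
})
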