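#' DMR-caller configuration
#'
#' Thresholds of the seed-and-extend differential-methylation caller:
#' per-CpG two-sided significance `site_alpha` selects seeds and members;
#' `bartlett_alpha` gates the parametric vs non-parametric branch; a member
#' CpG must lie within `max_gap` bp of the previous member and within
#' `max_span` bp of the seed; regions need at least `min_sig_cpgs`
#' significant CpGs; region p-values come from `n_permutations` random-window
#' label-shuffled null draws and are BH-adjusted against `fdr_threshold`.
#'
#' @param site_alpha per-CpG significance threshold.
#' @param bartlett_alpha variance-homogeneity gate threshold.
#' @param max_gap maximum bp between consecutive member CpGs.
#' @param max_span maximum bp from the seed CpG to any member.
#' @param min_sig_cpgs minimum significant CpGs per region.
#' @param fdr_threshold BH q-value cutoff for reported regions.
#' @param n_permutations null draws per candidate region.
#' @param perm_seed RNG seed for the permutation null.
#' @return list of class `dmr_config`.
#' @export
dmr_config <- function(site_alpha = 0.01, bartlett_alpha = 0.05,
                       max_gap = 200, max_span = 2000, min_sig_cpgs = 5L,
                       fdr_threshold = 0.01, n_permutations = 1000L,
                       perm_seed = 1L) {
  if (site_alpha <= 0 || site_alpha >= 1) abort("site_alpha must be in (0, 1)")
  if (max_gap > max_span) abort("max_gap must be <= max_span")
  if (min_sig_cpgs < 2) abort("min_sig_cpgs must be >= 2")
  if (n_permutations < 1) abort("n_permutations must be >= 1")
  structure(list(site_alpha = site_alpha, bartlett_alpha = bartlett_alpha,
                 max_gap = max_gap, max_span = max_span,
                 min_sig_cpgs = as.integer(min_sig_cpgs),
                 fdr_threshold = fdr_threshold,
                 n_permutations = as.integer(n_permutations),
                 perm_seed = as.integer(perm_seed)),
            class = "dmr_config")
}

#' Bartlett's test of equal variances (two groups)
#'
#' Closed-form two-group Bartlett statistic
#' \deqn{T = \frac{(N-k)\ln s_p^2 - \sum_i (n_i-1)\ln s_i^2}{C}, \quad
#'       C = 1 + \frac{1}{3(k-1)}\Big(\sum_i \frac{1}{n_i-1} -
#'       \frac{1}{N-k}\Big)}
#' with p from \eqn{\chi^2_{k-1}}. Zero variance in either group makes the
#' statistic undefined; callers treat that as failing the gate (routed to
#' the non-parametric branch) rather than an error.
#'
#' @param a,b numeric depth vectors, each of length >= 2.
#' @return list with `statistic` and `p.value` (both NA when a group
#'   variance is zero).
#' @examples
#' bartlett_test(c(10, 12, 14), c(11, 12, 13))  # T ~ 0.714, p ~ 0.40
#' @export
bartlett_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) abort("each group needs >= 2 values")
  na <- length(a); nb <- length(b); N <- na + nb; k <- 2
  va <- var(a); vb <- var(b)
  if (va == 0 || vb == 0) {
    return(list(statistic = NA_real_, p.value = NA_real_))
  }
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (N - k)
  C <- 1 + (1 / (3 * (k - 1))) *
    (1 / (na - 1) + 1 / (nb - 1) - 1 / (N - k))
  T <- ((N - k) * log(sp2) - (na - 1) * log(va) - (nb - 1) * log(vb)) / C
  list(statistic = T, p.value = pchisq(T, df = k - 1, lower.tail = FALSE))
}

#' Per-CpG two-group test with Bartlett gate
#'
#' When Bartlett's p exceeds `bartlett_alpha` the variances are taken as
#' homogeneous and a pooled-variance two-sample t-test is used; otherwise a
#' Mann-Whitney rank-sum test with normal approximation and midrank tie
#' correction. Sites where both groups are constant get p = 1. The
#' direction is the sign of (mean B - mean A).
#'
#' @param a,b normalized depth vectors at one CpG (group A, group B).
#' @param config a [dmr_config()].
#' @return list `bartlett_p`, `branch` (`"parametric"`/`"nonparametric"`),
#'   `p`, `direction`.
#' @examples
#' test_site(c(10, 12, 14), c(11, 12, 13))$p  # 1: identical means
#' @export
test_site <- function(a, b, config = dmr_config()) {
  if (length(a) < 2 || length(b) < 2) abort("each group needs >= 2 values")
  st <- site_tests_matrix(matrix(a, nrow = 1), matrix(b, nrow = 1), config)
  list(bartlett_p = st$bartlett_p, branch = st$branch, p = st$p,
       direction = st$direction)
}

# vectorised site tests over matrices (sites x samples); the workhorse
# behind test_site() and call_dmrs(); cross-checked in the tests against
# stats::bartlett.test / t.test / wilcox.test
site_tests_matrix <- function(A, B, config = dmr_config()) {
  na <- ncol(A); nb <- ncol(B); N <- na + nb
  m <- nrow(A)
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- (rowSums(A * A) - na * mA^2) / (na - 1)
  vB <- (rowSums(B * B) - nb * mB^2) / (nb - 1)
  vA <- pmax(vA, 0); vB <- pmax(vB, 0)  # guard rounding

  bart_p <- rep(NA_real_, m)
  ok <- vA > 0 & vB > 0
  if (any(ok)) {
    sp2 <- ((na - 1) * vA[ok] + (nb - 1) * vB[ok]) / (N - 2)
    C <- 1 + (1 / 3) * (1 / (na - 1) + 1 / (nb - 1) - 1 / (N - 2))
    T <- ((N - 2) * log(sp2) - (na - 1) * log(vA[ok]) -
            (nb - 1) * log(vB[ok])) / C
    bart_p[ok] <- pchisq(T, df = 1, lower.tail = FALSE)
  }
  parametric <- !is.na(bart_p) & bart_p > config$bartlett_alpha

  p <- rep(NA_real_, m)
  if (any(parametric)) {
    sp2 <- ((na - 1) * vA[parametric] + (nb - 1) * vB[parametric]) / (N - 2)
    tt <- (mB[parametric] - mA[parametric]) / sqrt(sp2 * (1 / na + 1 / nb))
    p[parametric] <- 2 * pt(-abs(tt), df = N - 2)
  }
  np <- which(!parametric)
  if (length(np)) {
    M <- cbind(A[np, , drop = FALSE], B[np, , drop = FALSE])
    p[np] <- apply(M, 1L, function(x) mw_normal_p(x[1:na], x[(na + 1):N]))
  }
  tibble(bartlett_p = bart_p,
         branch = ifelse(parametric, "parametric", "nonparametric"),
         p = p,
         direction = sign(mB - mA),
         mean_a = mA, mean_b = mB)
}

# Mann-Whitney two-sided p, normal approximation with midrank tie
# correction, no continuity correction; complete ties -> p = 1
mw_normal_p <- function(a, b) {
  na <- length(a); nb <- length(b); N <- na + nb
  r <- rank(c(a, b))
  U <- sum(r[(na + 1):N]) - nb * (nb + 1) / 2
  tie <- table(r)
  v <- na * nb / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
  if (v <= 0) return(1)
  z <- (U - na * nb / 2) / sqrt(v)
  min(1, 2 * pnorm(-abs(z)))
}

#' Test every CpG of a depth table
#'
#' Applies the Bartlett-gated per-CpG test to each row of a normalized
#' depth table.
#'
#' @param depth normalized depth table (`chrom`, `pos`, sample columns).
#' @param groups sample-to-group map (first-appearing group is "A").
#' @param config a [dmr_config()].
#' @return tibble `chrom`, `pos`, `bartlett_p`, `branch`, `p`,
#'   `direction`, `mean_a`, `mean_b`.
#' @export
site_tests <- function(depth, groups, config = dmr_config()) {
  check_depth_table(depth)
  check_sorted(depth)
  groups <- check_groups(depth, groups)
  lv <- group_levels(groups)
  if (any(table(groups$group) < 2)) abort("each group needs >= 2 samples")
  A <- as.matrix(depth[, groups$sample[groups$group == lv[1]], drop = FALSE])
  B <- as.matrix(depth[, groups$sample[groups$group == lv[2]], drop = FALSE])
  bind_cols(depth[, c("chrom", "pos")], site_tests_matrix(A, B, config))
}
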