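#' Seed-and-extend candidate region building
#'
#' Scanning each chromosome in coordinate order, every significant CpG
#' (p < `site_alpha`) not already absorbed into a region starts a seed. The
#' region extends 3' over consecutive CpGs while the next CpG (i) lies
#' within `max_gap` of the current last member, (ii) lies within `max_span`
#' of the seed, and (iii) is itself significant; the first CpG violating
#' any rule terminates the region. Regions with at least `min_sig_cpgs`
#' members are emitted. A CpG consumed by a region cannot seed again, so
#' calls never overlap; a CpG rejected for range alone may start the next
#' seed.
#'
#' @param sites tibble from [site_tests()], sorted by (`chrom`, `pos`).
#' @param config a [dmr_config()].
#' @return tibble of candidates: `chrom`, `start`, `end` (0-based
#'   half-open, spanning first to last member CpG), `n_cpgs`, `n_sig`,
#'   `members` (list column of member positions), `row_first`, `row_last`
#'   (row indices into `sites`).
#' @export
seed_extend <- function(sites, config = dmr_config()) {
  if (!all(c("chrom", "pos", "p") %in% names(sites))) {
    abort("`sites` must have columns chrom, pos, p")
  }
  o <- order(sites$chrom, sites$pos)
  if (!identical(o, seq_len(nrow(sites)))) {
    abort("`sites` must be sorted by (chrom, pos)")
  }
  n <- nrow(sites)
  sig <- !is.na(sites$p) & sites$p < config$site_alpha
  pos <- sites$pos
  chrom <- sites$chrom

  out <- list()
  sig_idx <- which(sig)
  consumed_until <- 0L
  for (i in sig_idx) {
    if (i <= consumed_until) next
    j <- i
    while (j + 1L <= n &&
           chrom[j + 1L] == chrom[i] &&
           sig[j + 1L] &&
           pos[j + 1L] - pos[j] <= config$max_gap &&
           pos[j + 1L] - pos[i] <= config$max_span) {
      j <- j + 1L
    }
    if (j - i + 1L >= config$min_sig_cpgs) {
      out[[length(out) + 1L]] <- tibble(
        chrom = chrom[i], start = pos[i], end = pos[j] + 1,
        n_cpgs = j - i + 1L, n_sig = j - i + 1L,
        members = list(pos[i:j]), row_first = i, row_last = j
      )
    }
    consumed_until <- j
  }
  if (!length(out)) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  n_cpgs = integer(), n_sig = integer(), members = list(),
                  row_first = integer(), row_last = integer()))
  }
  bind_rows(out)
}

#' Permutation p-value for a candidate region
#'
#' The observed statistic is the absolute difference of group means of the
#' per-sample mean normalized depth over the member CpGs. The null
#' distribution is built from `n_permutations` draws, each taking an
#' equal-length run of retained CpGs at a uniformly random genomic start
#' (within one chromosome) and randomly reassigning the group labels; the
#' pseudocount estimate \eqn{p = (1 + \#\{null \ge obs\}) / (1 + n)} never
#' returns zero.
#'
#' @param depth normalized depth table.
#' @param groups sample-to-group map.
#' @param member_rows integer row indices of the member CpGs in `depth`.
#' @param config a [dmr_config()].
#' @param seed RNG seed; `NULL` uses the current RNG state (as inside
#'   [call_dmrs()], which seeds once with `config$perm_seed`).
#' @return list `observed`, `p_region`.
#' @export
region_pvalue <- function(depth, groups, member_rows,
                          config = dmr_config(), seed = config$perm_seed) {
  groups <- check_groups(depth, groups)
  if (!is.null(seed)) set.seed(seed)
  pc <- perm_context(depth, groups, config)
  res <- region_pvalue_ctx(pc, member_rows, config)
  list(observed = res$observed, p_region = res$p_region)
}

# precompute cumulative per-sample depth sums and label-subset masks once
# per call_dmrs() run
perm_context <- function(depth, groups, config) {
  smp <- groups$sample
  lv <- group_levels(groups)
  isB <- groups$group == lv[2]
  M <- as.matrix(depth[, smp, drop = FALSE])
  cs <- rbind(0, apply(M, 2L, cumsum))
  nb <- sum(isB); ns <- length(smp)
  subsets <- utils::combn(ns, nb)  # all B-label assignments, equally likely
  maskB <- matrix(0, ns, ncol(subsets))
  for (k in seq_len(ncol(subsets))) maskB[subsets[, k], k] <- 1
  list(M = M, cs = cs, chrom = depth$chrom, isB = isB, nb = nb,
       na = ns - nb, ns = ns, maskB = maskB)
}

region_pvalue_ctx <- function(pc, member_rows, config) {
  L <- length(member_rows)
  w_obs <- colMeans(pc$M[member_rows, , drop = FALSE])
  observed <- abs(mean(w_obs[pc$isB]) - mean(w_obs[!pc$isB]))

  n <- nrow(pc$M)
  if (L > n) abort("region longer than the retained CpG table")
  # valid starts: runs of L consecutive retained CpGs within one chromosome
  valid <- which(pc$chrom[seq_len(n - L + 1)] ==
                   pc$chrom[seq_len(n - L + 1) + L - 1])
  if (!length(valid)) abort("genome too small to draw null windows")
  nperm <- config$n_permutations
  starts <- valid[sample.int(length(valid), nperm, replace = TRUE)]
  W <- (pc$cs[starts + L, , drop = FALSE] -
          pc$cs[starts, , drop = FALSE]) / L          # nperm x ns window means
  sub <- sample.int(ncol(pc$maskB), nperm, replace = TRUE)
  sumB <- rowSums(W * t(pc$maskB[, sub, drop = FALSE]))
  tot <- rowSums(W)
  null <- abs(sumB / pc$nb - (tot - sumB) / pc$na)
  p <- (1 + sum(null >= observed)) / (1 + nperm)
  list(observed = observed, p_region = p, null = null)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j},
#' capped at 1 and order-preserving with the input.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values in input order.
#' @examples
#' bh_adjust(c(0.001, 0.008, 0.039, 0.041))
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Call differentially methylated regions
#'
#' The full caller: Bartlett-gated per-CpG tests, seed-and-extend candidate
#' building, a random-window label-shuffled permutation p-value per
#' candidate, and BH adjustment over the candidate set. Regions with
#' q < `fdr_threshold` are returned. Fully deterministic given
#' `config$perm_seed`.
#'
#' @param depth filtered, normalized depth table.
#' @param groups sample-to-group map (first-appearing group is "A").
#' @param config a [dmr_config()].
#' @return A tibble of class `dmr_result`: `chrom`, `start`, `end`,
#'   `n_cpgs`, `n_sig`, `mean_a`, `mean_b`, `log2_ratio`, `direction`
#'   (`hyper_in_B`/`hypo_in_B`), `p_region`, `q`. Attributes: `sites`
#'   (per-CpG tests), `candidates` (all candidates incl. non-significant),
#'   `config`, `groups`.
#' @export
call_dmrs <- function(depth, groups, config = dmr_config()) {
  check_depth_table(depth)
  groups <- check_groups(depth, groups)
  empty <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  n_cpgs = integer(), n_sig = integer(),
                  mean_a = numeric(), mean_b = numeric(),
                  log2_ratio = numeric(), direction = character(),
                  p_region = numeric(), q = numeric())
  if (nrow(depth) == 0L) {
    return(new_dmr_result(empty, empty, tibble(), config, groups))
  }
  sites <- site_tests(depth, groups, config)
  cand <- seed_extend(sites, config)
  if (!nrow(cand)) {
    return(new_dmr_result(empty, empty, sites, config, groups))
  }

  set.seed(config$perm_seed)
  pc <- perm_context(depth, groups, config)
  pv <- purrr::map_dbl(seq_len(nrow(cand)), function(i) {
    region_pvalue_ctx(pc, cand$row_first[i]:cand$row_last[i], config)$p_region
  })
  smpA <- groups$sample[groups$group == group_levels(groups)[1]]
  smpB <- groups$sample[groups$group == group_levels(groups)[2]]
  cand <- cand |>
    mutate(
      mean_a = purrr::map_dbl(seq_len(n()), function(i)
        mean(as.matrix(depth[.data$row_first[i]:.data$row_last[i], smpA]))),
      mean_b = purrr::map_dbl(seq_len(n()), function(i)
        mean(as.matrix(depth[.data$row_first[i]:.data$row_last[i], smpB]))),
      log2_ratio = log2(.data$mean_b / .data$mean_a),
      direction = ifelse(.data$mean_b >= .data$mean_a,
                         "hyper_in_B", "hypo_in_B"),
      p_region = pv,
      q = bh_adjust(pv)
    ) |>
    select(-"members", -"row_first", -"row_last")
  new_dmr_result(cand[cand$q < config$fdr_threshold, , drop = FALSE],
                 cand, sites, config, groups)
}

new_dmr_result <- function(dmrs, candidates, sites, config, groups) {
  structure(as_tibble(dmrs),
            candidates = as_tibble(candidates),
            sites = sites, config = config, groups = groups,
            class = c("dmr_result", class(tibble())))
}

#' @export
print.dmr_result <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<dmr_result> %d DMRs (q < %g) from %d candidate regions, %d CpGs tested\n",
              nrow(x), cfg$fdr_threshold, nrow(attr(x, "candidates")),
              nrow(attr(x, "sites"))))
  NextMethod()
}

#' Tidy a DMR result
#'
#' @param x a `dmr_result`.
#' @param all return every candidate region (default) or only reported DMRs.
#' @param ... unused.
#' @return plain tibble of regions.
#' @method tidy dmr_result
#' @export
tidy.dmr_result <- function(x, all = TRUE, ...) {
  if (all) {
    attr(x, "candidates")
  } else {
    attributes(x)[c("candidates", "sites", "config", "groups")] <- NULL
    class(x) <- class(tibble())
    x
  }
}

#' One-row summary of a DMR analysis
#'
#' @param x a `dmr_result`.
#' @param ... unused.
#' @method glance dmr_result
#' @export
glance.dmr_result <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble(
    n_sites = nrow(attr(x, "sites")),
    n_sig_sites = sum(attr(x, "sites")$p < cfg$site_alpha, na.rm = TRUE),
    n_candidates = nrow(attr(x, "candidates")),
    n_dmrs = nrow(x),
    n_hyper_in_b = sum(x$direction == "hyper_in_B"),
    n_hypo_in_b = sum(x$direction == "hypo_in_B"),
    fdr_threshold = cfg$fdr_threshold
  )
}
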