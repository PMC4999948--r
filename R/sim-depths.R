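#' Simulate per-CpG read depths with planted differential regions
#'
#' CpG positions are placed with exponential spacing (mean
#' `cfg$cpg_spacing_mean`). Each sample's depth at each CpG is drawn from a
#' negative binomial with mean `cfg$nb_mean` (variance
#' `mean + dispersion * mean^2`; Poisson when `nb_dispersion = 0`). Inside
#' planted regions the group-B mean is multiplied by `dmr_fold` (hyper
#' regions) or `1/dmr_fold` (hypo regions), alternating so both directions
#' are planted in equal numbers. Planted regions are disjoint runs of
#' `dmr_n_cpgs` consecutive CpGs with internal gaps at most `dmr_max_gap`.
#'
#' @param annotation a `genome_annotation` from [simulate_genome()].
#' @param cfg a [sim_config()].
#' @return A list with
#'   * `depth`: tibble `chrom`, `pos` plus one raw-depth column per sample
#'     (`A1..An`, `B1..Bn`),
#'   * `groups`: tibble `sample`, `group`,
#'   * `truth`: tibble of planted regions (`chrom`, `start`, `end`, `fold`,
#'     `direction`, `n_cpgs`), the simulator's ground-truth ledger.
#' @examples
#' cfg <- sim_config(chrom_length = 2e5, n_planted_dmrs = 2, seed = 3)
#' sim <- simulate_depths(simulate_genome(cfg), cfg)
#' head(sim$depth)
#' @export
simulate_depths <- function(annotation, cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed + 1L)
  ns <- cfg$n_samples_per_group
  samples <- c(paste0("A", seq_len(ns)), paste0("B", seq_len(ns)))
  groups <- tibble(sample = samples,
                   group = rep(c("A", "B"), each = ns))

  sites <- purrr::map_dfr(seq_len(nrow(annotation$chrom_sizes)), function(i) {
    ch <- annotation$chrom_sizes$chrom[i]
    len <- annotation$chrom_sizes$length[i]
    n_exp <- ceiling(len / cfg$cpg_spacing_mean * 1.3) + 50
    pos <- cumsum(ceiling(rexp(n_exp, rate = 1 / cfg$cpg_spacing_mean)))
    while (pos[length(pos)] < len - 1) {
      pos <- c(pos, pos[length(pos)] +
                 cumsum(ceiling(rexp(1000, rate = 1 / cfg$cpg_spacing_mean))))
    }
    tibble(chrom = ch, pos = pos[pos < len])
  })
  m <- nrow(sites)

  # plant disjoint dense runs of dmr_n_cpgs consecutive CpGs
  truth <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  fold = numeric(), direction = character(),
                  n_cpgs = integer())
  fold_site <- rep(1, m)
  if (cfg$n_planted_dmrs > 0) {
    L <- cfg$dmr_n_cpgs
    if (L > m) abort("dmr_n_cpgs exceeds the number of simulated CpGs")
    starts_all <- seq_len(m - L + 1)
    if (L == 1L) {
      candidates <- starts_all
    } else {
      gaps_ok <- c(diff(sites$pos) <= cfg$dmr_max_gap &
                     sites$chrom[-1] == sites$chrom[-m], FALSE)
      # run of L sites starting at i is dense iff gaps i..(i+L-2) all ok
      ok_cum <- cumsum(gaps_ok)
      dense <- (ok_cum[starts_all + L - 2] -
                  c(0, ok_cum)[starts_all]) == (L - 1)
      candidates <- starts_all[dense]
    }
    if (length(candidates) < cfg$n_planted_dmrs) {
      abort(sprintf(
        "genome too small/sparse: only %d dense CpG runs available for %d planted regions",
        length(candidates), cfg$n_planted_dmrs))
    }
    chosen <- integer(0)
    taken <- rep(FALSE, m)
    pool <- sample(candidates)
    for (s in pool) {
      if (length(chosen) == cfg$n_planted_dmrs) break
      idx <- s:(s + L - 1)
      if (!any(taken[idx])) {
        chosen <- c(chosen, s)
        taken[idx] <- TRUE
      }
    }
    if (length(chosen) < cfg$n_planted_dmrs) {
      abort("could not place the requested number of disjoint planted regions")
    }
    chosen <- sort(chosen)
    direction <- rep(c("hyper_in_B", "hypo_in_B"),
                     length.out = length(chosen))
    fold <- ifelse(direction == "hyper_in_B", cfg$dmr_fold, 1 / cfg$dmr_fold)
    for (k in seq_along(chosen)) {
      idx <- chosen[k]:(chosen[k] + L - 1)
      fold_site[idx] <- fold[k]
    }
    truth <- tibble(
      chrom = sites$chrom[chosen],
      start = sites$pos[chosen],
      end = sites$pos[chosen + L - 1] + 1,
      fold = fold,
      direction = direction,
      n_cpgs = L
    )
  }

  draw <- function(mu) {
    if (cfg$nb_dispersion == 0) rpois(length(mu), lambda = mu)
    else rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion)
  }
  depth <- sites
  for (s in samples) {
    mu <- if (startsWith(s, "B")) cfg$nb_mean * fold_site else rep(cfg$nb_mean, m)
    depth[[s]] <- draw(mu)
  }

  list(depth = depth, groups = groups, truth = truth)
}
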