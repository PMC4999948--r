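# independent brute-force oracles used to check the implementation paths

# region building by explicit enumeration: walk positions left to right,
# from each unconsumed significant site grow the run by checking every
# rule on the candidate member directly; deliberately different code shape
# from the package's scanner
oracle_seed_extend <- function(pos, sig, max_gap, max_span, min_sig) {
  n <- length(pos)
  consumed <- rep(FALSE, n)
  regions <- list()
  for (i in seq_len(n)) {
    if (!sig[i] || consumed[i]) next
    members <- i
    repeat {
      nxt <- members[length(members)] + 1L
      ok <- nxt <= n &&
        sig[nxt] &&
        (pos[nxt] - pos[members[length(members)]]) <= max_gap &&
        (pos[nxt] - pos[i]) <= max_span
      if (!ok) break
      members <- c(members, nxt)
    }
    consumed[members] <- TRUE
    if (length(members) >= min_sig) {
      regions[[length(regions) + 1L]] <-
        c(first = members[1], last = members[length(members)])
    }
  }
  regions
}

# naive O(m^2) BH step-up straight from the definition
oracle_bh <- function(p) {
  m <- length(p)
  vapply(seq_len(m), function(i) {
    js <- which(p >= p[i])
    min(1, min(vapply(js, function(j) p[j] * m / sum(p <= p[j]), numeric(1))))
  }, numeric(1))
}

# Pearson r from first principles
oracle_pearson <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

# exact two-sided rank-sum p by enumerating every group assignment
oracle_exact_ranksum_p <- function(a, b) {
  na <- length(a); vals <- c(a, b); N <- length(vals)
  r <- rank(vals)
  combs <- utils::combn(N, na)
  stats <- apply(combs, 2, function(idx) sum(r[idx]))
  obs <- sum(r[seq_len(na)])
  mu <- mean(stats)
  mean(abs(stats - mu) >= abs(obs - mu))
}

# fraction of truth regions overlapped by >= 1 call (and vice versa)
overlap_fraction <- function(x, y) {
  if (!nrow(x)) return(NA_real_)
  if (!nrow(y)) return(0)
  hit <- vapply(seq_len(nrow(x)), function(i) {
    any(y$chrom == x$chrom[i] & y$start < x$end[i] & y$end > x$start[i])
  }, logical(1))
  mean(hit)
}

# small shared fixture: dense simulated experiment with strong planted
# signal the caller can actually recover (high depth, Poisson noise, 5v5
# replicates so both test branches can reach the per-site threshold)
strong_signal_sim <- function(seed = 11, n_planted = 20) {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 2e6,
                    cpg_spacing_mean = 100, nb_mean = 100,
                    nb_dispersion = 0, n_planted_dmrs = n_planted,
                    dmr_n_cpgs = 8, dmr_fold = 4,
                    n_samples_per_group = 5,
                    genes_per_chrom = 50, mirnas_per_chrom = 10,
                    seed = seed)
  ann <- simulate_genome(cfg)
  sim <- simulate_depths(ann, cfg)
  list(cfg = cfg, ann = ann, sim = sim)
}
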