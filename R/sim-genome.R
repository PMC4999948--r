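#' Simulate a toy annotated genome
#'
#' Generates chromosome sizes, non-overlapping gene models (TSS/TTS/strand,
#' exon structure), CpG islands and miRNA loci. Genes are laid out on an
#' even grid of slots so models never overlap; a configurable fraction of
#' promoters carries a CpG island, and additional islands fall intergenic.
#' Deterministic for a fixed `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return A list of class `genome_annotation` with tibbles
#'   `chrom_sizes` (chrom, length), `genes` (gene_id, chrom, start, end,
#'   strand, tss, tts), `exons`, `cgis`, `mirnas`. All coordinates 0-based
#'   half-open.
#' @examples
#' ann <- simulate_genome(sim_config(chrom_length = 1e6, seed = 7))
#' ann$chrom_sizes
#' @export
simulate_genome <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  chrom_sizes <- tibble(chrom = chroms, length = cfg$chrom_length)

  slot <- cfg$chrom_length / max(cfg$genes_per_chrom, 1L)
  if (cfg$genes_per_chrom > 0 && slot < 4000) {
    abort("chrom_length too small to place the requested genes (need >= 4 kb per gene slot)")
  }

  genes <- purrr::map_dfr(chroms, function(ch) {
    if (cfg$genes_per_chrom == 0L) return(tibble())
    i <- seq_len(cfg$genes_per_chrom)
    slot_start <- (i - 1) * slot
    # keep a >= 2.2 kb margin at both slot ends so promoters/downstream
    # windows stay inside the slot and gene models never collide
    margin <- min(2200, slot * 0.25)
    glen <- round(runif(length(i), min = 0.2, max = 0.5) * (slot - 2 * margin))
    glen <- pmax(glen, 1000)
    gstart <- round(slot_start + margin +
                      runif(length(i)) * (slot - 2 * margin - glen))
    strand <- sample(c("+", "-"), length(i), replace = TRUE)
    tibble(
      gene_id = sprintf("%s_g%04d", ch, i),
      chrom = ch,
      start = gstart,
      end = gstart + glen,
      strand = strand,
      tss = ifelse(strand == "+", gstart, gstart + glen),
      tts = ifelse(strand == "+", gstart + glen, gstart)
    )
  })

  exons <- if (nrow(genes)) {
    purrr::pmap_dfr(genes, function(gene_id, chrom, start, end, strand, ...) {
      n_ex <- sample(1:4, 1L)
      cuts <- sort(runif(2 * n_ex - 2, start, end))
      bounds <- round(c(start, cuts, end))
      idx <- seq(1, length(bounds) - 1, by = 2)
      tibble(
        gene_id = gene_id, chrom = chrom,
        start = bounds[idx], end = pmax(bounds[idx + 1], bounds[idx] + 1),
        exon_rank = seq_along(idx), strand = strand
      )
    })
  } else tibble()

  cgis <- if (nrow(genes)) {
    with_cgi <- genes[runif(nrow(genes)) < cfg$cgi_fraction, , drop = FALSE]
    promoter_cgi <- if (nrow(with_cgi)) tibble(
      chrom = with_cgi$chrom,
      start = pmax(0, with_cgi$tss - 500),
      end = pmin(cfg$chrom_length, with_cgi$tss + 500)
    ) else tibble()
    n_inter <- max(1L, round(0.2 * cfg$genes_per_chrom)) * cfg$n_chromosomes
    inter <- tibble(
      chrom = sample(chroms, n_inter, replace = TRUE),
      start = round(runif(n_inter, 0, cfg$chrom_length - 1000))
    ) |> mutate(end = .data$start + round(runif(n_inter, 300, 1000)))
    bind_rows(promoter_cgi, inter) |>
      arrange(.data$chrom, .data$start) |>
      mutate(cgi_id = sprintf("cgi%05d", row_number()))
  } else tibble()

  mirnas <- purrr::map_dfr(chroms, function(ch) {
    if (cfg$mirnas_per_chrom == 0L) return(tibble())
    i <- seq_len(cfg$mirnas_per_chrom)
    pos <- round(runif(length(i), 2500, cfg$chrom_length - 2500))
    len <- round(runif(length(i), 80, 120))
    tibble(
      mirna_id = sprintf("%s_mir%03d", ch, i),
      chrom = ch, start = pos, end = pos + len,
      strand = sample(c("+", "-"), length(i), replace = TRUE)
    )
  })

  structure(
    list(chrom_sizes = chrom_sizes, genes = genes, exons = exons,
         cgis = cgis, mirnas = mirnas, repeats = NULL, snps = NULL),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("<genome_annotation>\n")
  cat("  chromosomes:", nrow(x$chrom_sizes),
      " genes:", nrow(x$genes),
      " CGIs:", nrow(x$cgis),
      " miRNAs:", nrow(x$mirnas), "\n")
  invisible(x)
}
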