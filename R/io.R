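# plain-text IO: every writer prepends '#'-prefixed header lines carrying
# the parameters and master seed, so outputs are self-describing and
# byte-stable for a fixed configuration

write_header_tsv <- function(x, path, header = character()) {
  if (length(header)) {
    writeLines(paste0("# ", header), path)
    readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(x, path)
  }
  invisible(path)
}

#' Read a TSV written by this package
#'
#' Skips `#` header lines.
#' @param path file path.
#' @return tibble.
#' @export
read_pkg_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' Write / read a chromosome-sizes file
#'
#' Two-column headerless text (`chrom`, `length`), the conventional
#' `chrom.sizes` format.
#' @param chrom_sizes tibble `chrom`, `length`.
#' @param path file path.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  readr::write_tsv(chrom_sizes[, c("chrom", "length")], path,
                   col_names = FALSE)
  invisible(path)
}

#' @rdname write_chrom_sizes
#' @export
read_chrom_sizes <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "length"),
                  show_col_types = FALSE, progress = FALSE)
}

#' Write intervals as BED6
#'
#' 0-based half-open intervals with name/score/strand columns; used for
#' planted-truth regions and called DMRs (score = -10 log10 q, capped at
#' 1000).
#'
#' @param x tibble with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand`.
#' @param path file path.
#' @param header character vector of header comment lines.
#' @param extra_cols extra column names of `x` to append after the BED6
#'   fields.
#' @export
write_bed6 <- function(x, path, header = character(), extra_cols = NULL) {
  bed <- tibble(
    chrom = x$chrom,
    start = format(x$start, scientific = FALSE, trim = TRUE),
    end = format(x$end, scientific = FALSE, trim = TRUE),
    name = x[["name"]] %||% sprintf("region_%05d", seq_len(nrow(x))),
    score = x[["score"]] %||% 0,
    strand = x[["strand"]] %||% "."
  )
  if (!is.null(extra_cols)) bed <- bind_cols(bed, x[, extra_cols, drop = FALSE])
  if (length(header)) {
    writeLines(paste0("# ", header), path)
    readr::write_tsv(bed, path, append = TRUE, col_names = FALSE)
  } else {
    readr::write_tsv(bed, path, col_names = FALSE)
  }
  invisible(path)
}

#' Write gene and miRNA models as GTF
#'
#' Emits `gene` (and `exon`) features for genes and `miRNA` features for
#' miRNA loci; GTF is 1-based closed, converted from the package's 0-based
#' half-open coordinates at this boundary.
#'
#' @param annotation a `genome_annotation`.
#' @param path file path.
#' @export
write_gtf <- function(annotation, path) {
  fmt <- function(tbl, type, idcol) {
    if (is.null(tbl) || !nrow(tbl)) return(character())
    sprintf("%s\tmedipdmr\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
            tbl$chrom, type, as.integer(tbl$start) + 1L,
            as.integer(tbl$end), tbl$strand %||% "+", tbl[[idcol]])
  }
  lines <- c(fmt(annotation$genes, "gene", "gene_id"),
             fmt(annotation$exons, "exon", "gene_id"),
             fmt(annotation$mirnas, "miRNA", "mirna_id"))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GTF/GFF
#'
#' Thin wrapper over `rtracklayer::import()` returning the package's gene
#' tibble (0-based half-open, with TSS/TTS).
#'
#' @param path GTF/GFF file.
#' @param feature_type feature type to keep (default `"gene"`).
#' @return tibble `gene_id`, `chrom`, `start`, `end`, `strand`, `tss`,
#'   `tts`.
#' @export
read_gtf_genes <- function(path, feature_type = "gene") {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("reading GTF requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path)
  gr <- gr[as.character(gr$type) == feature_type]
  tibble(
    gene_id = as.character(gr$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  ) |>
    mutate(tss = ifelse(.data$strand == "+", .data$start, .data$end),
           tts = ifelse(.data$strand == "+", .data$end, .data$start))
}
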