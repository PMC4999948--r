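#' Promoter CpG-class parameters
#'
#' Thresholds for the high/intermediate/low CpG-density promoter classes
#' (HCP/ICP/LCP). A promoter is HCP when its CpG observed/expected ratio is
#' at least `hcp_cpg_ratio_min` and its GC fraction at least `hcp_gc_min`;
#' LCP when CpGo/e is below `lcp_cpg_ratio_max`; ICP otherwise. The window
#' is the span around the TSS used when extracting promoter sequence.
#'
#' @param window c(upstream, downstream) of the TSS in bp.
#' @param hcp_cpg_ratio_min,hcp_gc_min,lcp_cpg_ratio_max class thresholds.
#' @return list of class `promoter_class_params`.
#' @export
promoter_class_params <- function(window = c(800, 200),
                                  hcp_cpg_ratio_min = 0.75,
                                  hcp_gc_min = 0.55,
                                  lcp_cpg_ratio_max = 0.48) {
  if (lcp_cpg_ratio_max >= hcp_cpg_ratio_min) {
    abort("lcp_cpg_ratio_max must be < hcp_cpg_ratio_min")
  }
  if (hcp_gc_min <= 0 || hcp_gc_min >= 1) abort("hcp_gc_min must be in (0, 1)")
  structure(list(window = window,
                 hcp_cpg_ratio_min = hcp_cpg_ratio_min,
                 hcp_gc_min = hcp_gc_min,
                 lcp_cpg_ratio_max = lcp_cpg_ratio_max),
            class = "promoter_class_params")
}

#' Classify a promoter by CpG density
#'
#' Computes the CpG observed/expected ratio
#' \eqn{(\#CG \times L) / (\#C \times \#G)} and the GC fraction of a
#' promoter sequence and assigns the HCP/ICP/LCP class.
#'
#' @param sequence promoter DNA string(s), A/C/G/T/N alphabet, length >= 200.
#' @param params a [promoter_class_params()].
#' @return character vector of classes (`"HCP"`, `"ICP"`, `"LCP"`).
#' @examples
#' classify_promoter(strrep("CG", 500))  # "HCP"
#' classify_promoter(strrep("AT", 500))  # "LCP"
#' @export
classify_promoter <- function(sequence, params = promoter_class_params()) {
  sequence <- toupper(sequence)
  vapply(sequence, function(s) {
    len <- nchar(s)
    if (len < 200) abort("promoter sequence must be >= 200 bp")
    if (grepl("^N+$", s)) abort("all-N promoter sequence cannot be classified")
    nC <- len - nchar(gsub("C", "", s, fixed = TRUE))
    nG <- len - nchar(gsub("G", "", s, fixed = TRUE))
    nCG <- if (grepl("CG", s, fixed = TRUE))
      length(gregexpr("CG", s, fixed = TRUE)[[1]]) else 0L
    oe <- if (nC == 0 || nG == 0) 0 else nCG * len / (nC * nG)
    gc <- (nC + nG) / len
    if (oe >= params$hcp_cpg_ratio_min && gc >= params$hcp_gc_min) "HCP"
    else if (oe < params$lcp_cpg_ratio_max) "LCP"
    else "ICP"
  }, character(1), USE.NAMES = FALSE)
}

# default priority order for overlap resolution, most specific first
default_element_priority <- c(
  "CGI", "CGI_shore",
  "promoter_HCP", "promoter_ICP", "promoter_LCP", "promoter",
  "five_prime_UTR", "first_exon", "first_intron", "exon", "intron",
  "three_prime_UTR", "downstream2kb", "mirna",
  "repeat", "SNP", "intergenic"
)

#' Build a genomic-element catalogue
#'
#' Derives named interval sets (promoters, first/other exons and introns,
#' 2-kb downstream windows, CGIs and their 2-kb shores, miRNA loci,
#' repeats, ...) from an annotation, with a total priority order used to
#' resolve overlaps. The catalogue is data-driven: categories exist only
#' where the inputs define them. When promoter sequences are supplied the
#' promoter set is split into HCP/ICP/LCP classes.
#'
#' @param annotation a `genome_annotation`.
#' @param promoter_up promoter span upstream of the TSS (bp, strand-aware).
#' @param downstream span after the TTS (bp).
#' @param shore_width CGI shore width (bp, each flank).
#' @param promoter_seqs optional named character vector of promoter
#'   sequences (names = gene ids) used to split promoter classes.
#' @param params promoter-class thresholds.
#' @return tibble `chrom`, `start`, `end`, `element`, `priority`
#'   (class `element_catalogue`).
#' @export
element_catalogue <- function(annotation, promoter_up = 2000,
                              downstream = 2000, shore_width = 2000,
                              promoter_seqs = NULL,
                              params = promoter_class_params()) {
  genes <- annotation$genes
  out <- list()

  if (!is.null(genes) && nrow(genes)) {
    prom <- genes |>
      mutate(start = ifelse(.data$strand == "+",
                            pmax(0, .data$tss - promoter_up), .data$tss),
             end = ifelse(.data$strand == "+",
                          .data$tss, .data$tss + promoter_up),
             element = "promoter") |>
      select("chrom", "start", "end", "element")
    if (!is.null(promoter_seqs)) {
      cls <- rep("promoter", nrow(genes))
      has <- genes$gene_id %in% names(promoter_seqs)
      cls[has] <- paste0("promoter_",
                         classify_promoter(promoter_seqs[genes$gene_id[has]],
                                           params))
      prom$element <- cls
    }
    out$prom <- prom

    down <- genes |>
      mutate(start = ifelse(.data$strand == "+",
                            .data$tts, pmax(0, .data$tts - downstream)),
             end = ifelse(.data$strand == "+",
                          .data$tts + downstream, .data$tts),
             element = "downstream2kb") |>
      select("chrom", "start", "end", "element")
    out$down <- down
  }

  ex <- annotation$exons
  if (!is.null(ex) && nrow(ex)) {
    out$exons <- ex |>
      mutate(element = ifelse(.data$exon_rank == 1L, "first_exon", "exon")) |>
      select("chrom", "start", "end", "element")
    introns <- ex |>
      arrange(.data$gene_id, .data$exon_rank) |>
      group_by(.data$gene_id, .data$chrom) |>
      summarise(istart = list(head(.data$end, -1)),
                iend = list(tail(.data$start, -1)), .groups = "drop") |>
      tidyr::unnest(c("istart", "iend")) |>
      dplyr::rename(start = "istart", end = "iend") |>
      group_by(.data$gene_id) |>
      mutate(element = ifelse(row_number() == 1L, "first_intron", "intron")) |>
      ungroup() |>
      filter(.data$end > .data$start) |>
      select("chrom", "start", "end", "element")
    out$introns <- introns
  }

  cg <- annotation$cgis
  if (!is.null(cg) && nrow(cg)) {
    out$cgi <- cg |> mutate(element = "CGI") |>
      select("chrom", "start", "end", "element")
    out$shore <- bind_rows(
      cg |> mutate(start = pmax(0, .data$start - shore_width),
                   end = .data$start + shore_width),
      cg |> mutate(start = .data$end,
                   end = .data$end + shore_width)
    ) |>
      mutate(element = "CGI_shore") |>
      filter(.data$end > .data$start) |>
      select("chrom", "start", "end", "element")
  }

  mi <- annotation$mirnas
  if (!is.null(mi) && nrow(mi)) {
    out$mirna <- mi |> mutate(element = "mirna") |>
      select("chrom", "start", "end", "element")
  }
  rp <- annotation$repeats
  if (!is.null(rp) && nrow(rp)) {
    out$rep <- rp |> mutate(element = "repeat") |>
      select("chrom", "start", "end", "element")
  }

  cat_tbl <- bind_rows(out)
  prio <- tibble(element = default_element_priority,
                 priority = seq_along(default_element_priority))
  cat_tbl <- cat_tbl |>
    left_join(prio, by = "element") |>
    mutate(priority = ifelse(is.na(.data$priority),
                             max(prio$priority) + 1L, .data$priority)) |>
    arrange(.data$chrom, .data$start)
  class(cat_tbl) <- c("element_catalogue", class(cat_tbl))
  cat_tbl
}

#' Annotate positions against an element catalogue
#'
#' Returns, for each position, the highest-priority (lowest rank) catalogue
#' element whose interval contains it, or `"intergenic"` when none does.
#' Shore flanks are clipped at the start of the chromosome only; a position
#' on an unknown chromosome is an error.
#'
#' @param chrom,pos chromosome names and 0-based positions (vectorised).
#' @param catalogue an [element_catalogue()].
#' @param known_chroms optional character vector of valid chromosome names
#'   (defaults to those in the catalogue).
#' @return character vector of element labels.
#' @export
annotate_position <- function(chrom, pos, catalogue, known_chroms = NULL) {
  known_chroms <- known_chroms %||% unique(catalogue$chrom)
  bad <- setdiff(unique(chrom), known_chroms)
  if (length(bad)) {
    abort(paste0("unknown chromosome(s): ", paste(bad, collapse = ", ")))
  }
  lab <- rep("intergenic", length(pos))
  if (!nrow(catalogue)) return(lab)
  hits <- GenomicRanges::findOverlaps(pos_to_gr(chrom, pos),
                                      tbl_to_gr(catalogue))
  if (length(hits)) {
    h <- tibble(q = S4Vectors::queryHits(hits),
                pr = catalogue$priority[S4Vectors::subjectHits(hits)],
                el = catalogue$element[S4Vectors::subjectHits(hits)]) |>
      arrange(.data$q, .data$pr) |>
      dplyr::distinct(.data$q, .keep_all = TRUE)
    lab[h$q] <- h$el
  }
  lab
}

#' Windowed chromosome profile
#'
#' Tiles each chromosome into non-overlapping windows (the final partial
#' window is kept) and reports, per window, the mean normalized depth over
#' retained CpGs (NA where a window holds none), the number of CpGs, and
#' feature densities (gene TSS, CGI, miRNA, repeat, SNP counts per window).
#' GC fraction and CpG observed/expected ratio are added when chromosome
#' sequences are supplied.
#'
#' @param depth normalized depth table.
#' @param groups sample-to-group map.
#' @param annotation a `genome_annotation` (chromosome sizes and features).
#' @param window window width in bp (default 1 Mb).
#' @param sequences optional named character vector of chromosome sequences.
#' @return tibble with one row per window.
#' @export
windowed_profile <- function(depth, groups, annotation, window = 1e6,
                             sequences = NULL) {
  if (window <= 0) abort("window must be positive")
  check_depth_table(depth)
  groups <- check_groups(depth, groups)
  sizes <- annotation$chrom_sizes

  wins <- purrr::map_dfr(seq_len(nrow(sizes)), function(i) {
    len <- sizes$length[i]
    starts <- seq(0, len - 1, by = window)
    tibble(chrom = sizes$chrom[i], start = starts,
           end = pmin(starts + window, len))
  }) |>
    mutate(window_id = row_number())

  mdepth <- rowMeans(as.matrix(depth[, groups$sample, drop = FALSE]))
  di <- tibble(chrom = depth$chrom, pos = depth$pos, d = mdepth)
  hits <- GenomicRanges::findOverlaps(pos_to_gr(di$chrom, di$pos),
                                      tbl_to_gr(wins))
  agg <- tibble(w = S4Vectors::subjectHits(hits),
                d = di$d[S4Vectors::queryHits(hits)]) |>
    group_by(.data$w) |>
    summarise(mean_norm_depth = mean(.data$d), n_cpgs = n(), .groups = "drop")
  wins <- wins |>
    left_join(agg, by = c(window_id = "w")) |>
    mutate(n_cpgs = ifelse(is.na(.data$n_cpgs), 0L, .data$n_cpgs))

  count_in <- function(tbl, posfun) {
    if (is.null(tbl) || !nrow(tbl)) return(integer(nrow(wins)))
    p <- posfun(tbl)
    h <- GenomicRanges::findOverlaps(pos_to_gr(tbl$chrom, p), tbl_to_gr(wins))
    tabulate(S4Vectors::subjectHits(h), nbins = nrow(wins))
  }
  wins$gene_density <- count_in(annotation$genes, function(t) t$tss)
  wins$cgi_density <- count_in(annotation$cgis,
                               function(t) floor((t$start + t$end) / 2))
  wins$mirna_density <- count_in(annotation$mirnas, function(t) t$start)
  wins$repeat_density <- count_in(annotation$repeats, function(t) t$start)
  wins$snp_density <- count_in(annotation$snps, function(t) t$pos)

  if (!is.null(sequences)) {
    gcoe <- purrr::pmap_dfr(wins, function(chrom, start, end, ...) {
      s <- substr(sequences[[chrom]], start + 1, end)
      len <- nchar(s)
      nC <- len - nchar(gsub("C", "", s, fixed = TRUE))
      nG <- len - nchar(gsub("G", "", s, fixed = TRUE))
      nCG <- if (grepl("CG", s, fixed = TRUE))
        length(gregexpr("CG", s, fixed = TRUE)[[1]]) else 0L
      tibble(gc = (nC + nG) / len,
             cpg_oe = if (nC == 0 || nG == 0) 0 else nCG * len / (nC * nG))
    })
    wins <- bind_cols(wins, gcoe)
  } else {
    wins$gc <- NA_real_
    wins$cpg_oe <- NA_real_
  }
  select(wins, -"window_id")
}
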