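# internal helpers shared across modules

# sample columns of a depth/expression table = everything except the key cols
depth_sample_cols <- function(depth, key = c("chrom", "pos")) {
  setdiff(names(depth), key)
}

# validate a sample -> group map against a depth table; returns the map with
# group as character and exactly two levels
check_groups <- function(depth, groups, key = c("chrom", "pos")) {
  if (!is.data.frame(groups) || !all(c("sample", "group") %in% names(groups))) {
    abort("`groups` must be a data frame with columns `sample` and `group`.")
  }
  groups <- tibble(sample = as.character(groups$sample),
                   group  = as.character(groups$group))
  smp <- depth_sample_cols(depth, key)
  missing <- setdiff(smp, groups$sample)
  if (length(missing)) {
    abort(paste0("samples in table but not in `groups`: ",
                 paste(missing, collapse = ", ")))
  }
  groups <- groups[groups$sample %in% smp, , drop = FALSE]
  lv <- unique(groups$group)
  if (length(lv) != 2L) {
    abort(sprintf("exactly two group labels required, got %d", length(lv)))
  }
  groups
}

# the two group labels in stable (first-appearance) order: A then B
group_levels <- function(groups) unique(groups$group)

check_depth_table <- function(depth, key = c("chrom", "pos")) {
  if (!is.data.frame(depth) || !all(key %in% names(depth))) {
    abort(paste0("depth table must contain columns ",
                 paste(key, collapse = ", ")))
  }
  smp <- depth_sample_cols(depth, key)
  if (!length(smp)) abort("depth table has no sample columns")
  invisible(depth)
}

# positions strictly increasing within chromosome
check_sorted <- function(depth) {
  ok <- depth |>
    group_by(.data$chrom) |>
    summarise(ok = all(diff(.data$pos) > 0) || n() < 2L, .groups = "drop")
  if (!all(ok$ok)) abort("positions must be strictly increasing within each chromosome")
  invisible(depth)
}

# 0-based half-open tibble(chrom,start,end[,strand]) -> GRanges (1-based closed)
tbl_to_gr <- function(x, seqlengths = NULL) {
  strand <- if ("strand" %in% names(x)) x$strand else "*"
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

# point positions (0-based) -> width-1 GRanges
pos_to_gr <- function(chrom, pos) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, width = 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
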