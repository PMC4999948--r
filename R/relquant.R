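#' Average technical replicates of a Ct table
#'
#' qPCR reactions are run in replicate; all downstream arithmetic uses the
#' arithmetic mean Ct per (sample, target).
#'
#' @param ct tibble with columns `sample`, `target`, `ct` (and optionally
#'   `replicate`).
#' @return tibble `sample`, `target`, `ct` (one row per pair).
#' @export
average_ct <- function(ct) {
  if (!all(c("sample", "target", "ct") %in% names(ct))) {
    abort("`ct` needs columns sample, target, ct")
  }
  if (any(ct$ct <= 0)) abort("Ct values must be positive")
  ct |>
    group_by(.data$sample, .data$target) |>
    summarise(ct = mean(.data$ct), .groups = "drop")
}

#' Relative expression by the 2^-ddCt method
#'
#' The reference Ct of a sample is the arithmetic mean of the control-gene
#' Cts (equivalent to a geometric mean on the linear scale; e.g. ACTB, TBP
#' and TOP2B for mRNA, 5S rRNA for miRNA). Then
#' \eqn{\Delta Ct = Ct_{target} - Ct_{ref}},
#' \eqn{\Delta\Delta Ct = \Delta Ct_{sample} - \Delta Ct_{calibrator}} and
#' relative abundance \eqn{= 2^{-\Delta\Delta Ct}}; amplification
#' efficiency is the ideal 2.
#'
#' @param ct Ct tibble (`sample`, `target`, `ct`, optional `replicate`;
#'   replicates are averaged first).
#' @param target assay target gene name.
#' @param references character vector of control-gene target names.
#' @param calibrator sample id used as calibrator.
#' @return tibble `sample`, `delta_ct`, `ddct`, `rel_expr` (calibrator
#'   row included, `rel_expr` = 1 by construction).
#' @examples
#' ct <- tibble::tibble(sample = rep(c("s1", "cal"), each = 2),
#'                      target = rep(c("GENE", "ACTB"), 2),
#'                      ct = c(25, 20, 24, 20))
#' delta_delta_ct(ct, "GENE", "ACTB", "cal")$rel_expr  # 0.5, 1
#' @export
delta_delta_ct <- function(ct, target, references, calibrator) {
  ctm <- average_ct(ct)
  get_ct <- function(s, tg) {
    v <- ctm$ct[ctm$sample == s & ctm$target == tg]
    if (length(v) != 1L) {
      abort(sprintf("missing Ct for sample '%s', target '%s'", s, tg))
    }
    v
  }
  samples <- unique(ctm$sample)
  if (!calibrator %in% samples) abort("calibrator sample not found")
  dct <- vapply(samples, function(s) {
    refs <- vapply(references, function(r) get_ct(s, r), numeric(1))
    get_ct(s, target) - mean(refs)
  }, numeric(1))
  ddct <- dct - dct[[calibrator]]
  tibble(sample = samples, delta_ct = unname(dct), ddct = unname(ddct),
         rel_expr = 2^-unname(ddct))
}

#' Telomere-to-single-copy (T/S) ratio
#'
#' Relative telomere length from two qPCR assays: the telomere-repeat
#' signal (T) and a single-copy nuclear gene (S, here GCG), each as a Ct.
#' \eqn{T/S = 2^{-[(Ct_T - Ct_S)_{sample} - (Ct_T - Ct_S)_{calibrator}]}}.
#'
#' @param ct Ct tibble (`sample`, `target`, `ct`).
#' @param telomere_target target name of the telomere assay.
#' @param single_copy_target target name of the single-copy gene.
#' @param calibrator calibrator sample id.
#' @return tibble `sample`, `delta_ct`, `ts_ratio`.
#' @examples
#' ct <- tibble::tibble(sample = rep(c("s1", "cal"), each = 2),
#'                      target = rep(c("TEL", "GCG"), 2),
#'                      ct = c(14, 20, 15, 20))
#' ts_ratio(ct, calibrator = "cal")$ts_ratio  # 2, 1
#' @export
ts_ratio <- function(ct, telomere_target = "TEL",
                     single_copy_target = "GCG", calibrator) {
  ctm <- average_ct(ct)
  get_ct <- function(s, tg) {
    v <- ctm$ct[ctm$sample == s & ctm$target == tg]
    if (length(v) != 1L) {
      abort(sprintf("missing Ct for sample '%s', target '%s'", s, tg))
    }
    v
  }
  samples <- unique(ctm$sample)
  if (!calibrator %in% samples) abort("calibrator sample not found")
  dct <- vapply(samples, function(s)
    get_ct(s, telomere_target) - get_ct(s, single_copy_target), numeric(1))
  tibble(sample = samples, delta_ct = unname(dct),
         ts_ratio = 2^-(unname(dct) - dct[[calibrator]]))
}

#' Mitochondrial DNA content
#'
#' Copies of mtDNA per diploid cell as the doubled ratio of the
#' mitochondrial COX1 signal to the nuclear single-copy GCG signal within a
#' sample: \eqn{2 \times 2^{Ct_{GCG} - Ct_{COX1}}} (the nuclear reference is
#' present in two copies per cell).
#'
#' @param ct_cox1,ct_gcg Ct values (vectorised).
#' @return numeric vector of mtDNA copies per diploid cell.
#' @examples
#' mtdna_content(15, 22)  # 2 * 2^7 = 256
#' @export
mtdna_content <- function(ct_cox1, ct_gcg) {
  if (any(!is.finite(ct_cox1)) || any(!is.finite(ct_gcg))) {
    abort("both Ct values are required")
  }
  2 * 2^(ct_gcg - ct_cox1)
}
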