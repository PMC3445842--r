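#' Analysis parameters
#'
#' Bundles every tunable threshold used across the pipeline. Defaults follow
#' the published analysis of the wheat 3DS/3B homoeologous loci: an E-value
#' cutoff of 1e-10 for all homology searches, a nucleotide match reward of 2,
#' EST hits retained only at 100% identity over at least 100 bp, scaffold-end
#' merging at 99% identity over 100 bp, repeat screening of scaffold ends at
#' 95% identity over 100 bp, a pseudogene deletion allowance of 30% of the
#' intact homolog, 1 kb upstream regions for promoter scans, a TATA-box
#' window of 14-38 bp upstream of the predicted transcription start site,
#' and divergence times of 35 My (wheat/Brachypodium), 10 My (barley),
#' 2.5-4.5 My (wheat B/D progenitors) and 0.5 My (tetraploidization).
#'
#' Mismatch and gap penalties are not fixed by the published analysis (it
#' relied on an external search tool's defaults); the defaults here are
#' standard nucleotide-search values consistent with the match reward of 2.
#'
#' @param evalue_max maximum Karlin-Altschul E-value for a retained hit.
#' @param match_reward,mismatch_penalty nucleotide match/mismatch scores
#'   (mismatch given as a positive penalty).
#' @param gap_open,gap_extend affine gap penalties (positive).
#' @param karlin_k Karlin-Altschul K constant used in `E = K m n exp(-lambda S)`.
#'   `lambda` is solved numerically for the configured scoring.
#' @param est_min_len minimum exact-match length (bp) for an EST hit.
#' @param est_min_identity required EST identity in percent; only 100 is
#'   supported (the matching rule is exact).
#' @param merge_min_identity,merge_min_len scaffold-end merge thresholds.
#' @param repeat_screen_min_identity,repeat_screen_min_len scaffold-end
#'   repeat-risk thresholds.
#' @param pseudo_deletion_frac fraction of the intact homolog that may be
#'   missing before a deletion defect is called (coverage below
#'   `1 - pseudo_deletion_frac` flags a deletion).
#' @param fragment_coverage_max coverage below which a defect-free model is
#'   called a gene fragment.
#' @param upstream_len promoter region length (bp upstream of the start codon).
#' @param tata_tss_range allowed TATA-box offset window (bp upstream of TSS).
#' @param tss_min_score,tata_less_score promoter-scan score thresholds (see
#'   [scan_promoter()]).
#' @param t_brachy_split,t_barley_split,t_bd_split_range,t_tetraploid
#'   divergence times in million years.
#' @param t_old duration (My) of the shared-wheat insertion epoch used by
#'   [insertion_rate_ratio()].
#' @param tandem_max_intervening maximum number of genes allowed between the
#'   two members of a tandem pair.
#'
#' @return A list of class `homeo_params`.
#' @export
analysis_params <- function(evalue_max = 1e-10,
                            match_reward = 2L,
                            mismatch_penalty = 3L,
                            gap_open = 5L,
                            gap_extend = 2L,
                            karlin_k = 0.1,
                            est_min_len = 100L,
                            est_min_identity = 100,
                            merge_min_identity = 99,
                            merge_min_len = 100L,
                            repeat_screen_min_identity = 95,
                            repeat_screen_min_len = 100L,
                            pseudo_deletion_frac = 0.30,
                            fragment_coverage_max = 0.50,
                            upstream_len = 1000L,
                            tata_tss_range = c(14L, 38L),
                            tss_min_score = 9,
                            tata_less_score = 14,
                            t_brachy_split = 35,
                            t_barley_split = 10,
                            t_bd_split_range = c(2.5, 4.5),
                            t_tetraploid = 0.5,
                            t_old = 30,
                            tandem_max_intervening = 1L) {
  p <- as.list(environment())
  stopifnot(
    p$evalue_max > 0, p$match_reward > 0, p$mismatch_penalty > 0,
    p$gap_open >= 0, p$gap_extend > 0, p$karlin_k > 0,
    p$est_min_len > 0, p$merge_min_len > 0, p$repeat_screen_min_len > 0,
    p$upstream_len > 0, p$t_old > 0
  )
  for (nm in c("est_min_identity", "merge_min_identity",
               "repeat_screen_min_identity")) {
    v <- p[[nm]]
    if (!(v > 0 && v <= 100)) abort(sprintf("`%s` must be in (0, 100]", nm))
  }
  if (!(p$pseudo_deletion_frac > 0 && p$pseudo_deletion_frac < 1)) {
    abort("`pseudo_deletion_frac` must be in (0, 1)")
  }
  if (length(p$tata_tss_range) != 2L || diff(p$tata_tss_range) < 0) {
    abort("`tata_tss_range` must be an ordered pair")
  }
  if (length(p$t_bd_split_range) != 2L || diff(p$t_bd_split_range) < 0) {
    abort("`t_bd_split_range` must be an ordered pair")
  }
  if (!(p$t_brachy_split > max(p$t_bd_split_range))) {
    abort("`t_brachy_split` must exceed the wheat B/D split")
  }
  structure(p, class = "homeo_params")
}

#' @export
print.homeo_params <- function(x, ...) {
  cat("<homeo_params>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-28s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

as_params <- function(params) {
  if (is.null(params)) return(analysis_params())
  if (!inherits(params, "homeo_params")) {
    abort("`params` must be created by analysis_params()")
  }
  params
}
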