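#' Simplified core-promoter scan of an upstream region
#'
#' A documented stand-in for black-box promoter predictors, preserving the
#' structure of the analysis (promoter present/absent and TATA-box offset):
#' the transcription start site (TSS) is the highest-scoring
#' pyrimidine-purine initiator context in the final 200 bp of the region
#' (score = number of pyrimidines in the 12 bases preceding the YR
#' dinucleotide, plus 2 for the canonical `CA`; ties go to the position
#' closest to the start codon), and a TATA box is the closest upstream match
#' to the consensus `TATAWAW`. The promoter is called present when a TSS
#' scoring at least `params$tss_min_score` has a TATA box 14-38 bp upstream,
#' or when the initiator alone reaches `params$tata_less_score`.
#'
#' @param upstream upstream region on the coding strand (see
#'   [upstream_region()]), ideally `params$upstream_len` long.
#' @param params [analysis_params()].
#' @param gene_id id copied into the result.
#' @return one-row tibble: `gene_id`, `tss_offset` (bp upstream of the start
#'   codon), `tss_score`, `tata_offset` (bp between TATA box and TSS, `NA`
#'   if none in range), `has_promoter`, `no_call` (region under 50 bp).
#' @export
scan_promoter <- function(upstream, params = analysis_params(),
                          gene_id = "gene") {
  n <- nchar(upstream)
  empty <- tibble(gene_id = gene_id, tss_offset = NA_integer_,
                  tss_score = NA_real_, tata_offset = NA_integer_,
                  has_promoter = FALSE, no_call = FALSE)
  if (n < 50L) return(mutate(empty, no_call = TRUE))
  s <- strsplit(upstream, "")[[1]]
  win_lo <- max(n - 200L + 1L, 13L)  # need 12 context bases upstream
  cand <- win_lo:(n - 1L)
  is_y <- s %in% c("C", "T")
  is_r <- s %in% c("A", "G")
  cand <- cand[is_y[cand] & is_r[cand + 1L]]
  if (!length(cand)) return(empty)
  score <- vapply(cand, function(i) {
    sum(is_y[(i - 12L):(i - 1L)]) + 2 * (s[i] == "C" && s[i + 1L] == "A")
  }, numeric(1))
  best <- max(score)
  if (best < params$tss_min_score) return(empty)
  i <- max(cand[score == best])       # tie -> closest to the start codon
  tss_pos <- i + 1L                   # the purine: first transcribed base
  tss_offset <- n - tss_pos + 1L
  # closest TATAWAW upstream of the TSS
  tata_offset <- NA_integer_
  up <- substring(upstream, 1L, i - 1L)
  m <- gregexpr("TATA[AT]A[AT]", up)[[1]]
  if (m[1] != -1L) {
    ends <- as.integer(m) + 6L          # last base of the TATA box
    offs <- tss_pos - ends              # bp between box and TSS
    ok <- offs >= params$tata_tss_range[1] & offs <= params$tata_tss_range[2]
    if (any(ok)) tata_offset <- min(offs[ok]) else tata_offset <- NA_integer_
  }
  has <- (!is.na(tata_offset)) || best >= params$tata_less_score
  tibble(gene_id = gene_id, tss_offset = as.integer(tss_offset),
         tss_score = best, tata_offset = tata_offset,
         has_promoter = has, no_call = FALSE)
}

#' Promoter calls for all genes of a set of loci
#'
#' @param loci a `locus_annotation` or list of them.
#' @param params [analysis_params()].
#' @return tibble of [scan_promoter()] calls with `locus_id`, `genome_tag`.
#' @export
scan_promoters <- function(loci, params = analysis_params()) {
  up <- upstream_table(loci, params$upstream_len)
  calls <- list_rbind(map(seq_len(nrow(up)), function(i) {
    scan_promoter(up$seq[i], params, gene_id = up$gene_id[i])
  }))
  mutate(calls, locus_id = up$locus_id, genome_tag = up$genome_tag)
}

#' Promoter fractions per locus and collinearity group
#'
#' @param calls output of [scan_promoters()].
#' @param profiles classified profiles.
#' @inheritParams expression_summary
#' @return tibble `genome_tag`, `group`, `n_genes`, `n_promoter`, `pct`.
#' @export
promoter_summary <- function(calls, profiles, wheat_tags = NULL) {
  wheat_tags <- wheat_tags %||%
    unique(profiles$genome_tag[!is.na(profiles$pair_id)])
  pr <- filter(profiles, .data$category != "EXCLUDED",
               .data$genome_tag %in% wheat_tags)
  joined <- left_join(pr, select(calls, "gene_id", "has_promoter"),
                      by = "gene_id")
  joined |>
    mutate(group = ifelse(.data$category %in% COLLINEAR_CATEGORIES,
                          "collinear", "non_collinear")) |>
    group_by(.data$genome_tag, .data$group) |>
    summarise(n_genes = dplyr::n(),
              n_promoter = sum(.data$has_promoter, na.rm = TRUE),
              pct = round_half_up(100 * .data$n_promoter / .data$n_genes, 1),
              .groups = "drop")
}
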