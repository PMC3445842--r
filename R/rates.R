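#' Assign insertion epochs from collinearity categories
#'
#' Genes at collinear positions predate the wheat/Brachypodium split
#' (`ANCESTRAL`); genes shared by the two wheat loci but absent from the
#' model genomes were inserted between that split and the divergence of the
#' wheat B/D progenitors (`INTERMEDIATE`); locus-specific genes and
#' post-split tandem copies are `RECENT`. Annotation-excluded genes are not
#' assigned.
#'
#' @param profiles classified profiles ([classify_genes()]); only wheat
#'   genes (rows with a wheat category) are assigned.
#' @param wheat_tags genome tags of the wheat loci; defaults to the tags
#'   carrying homoeologous pairs.
#' @return tibble `gene_id`, `genome_tag`, `category`, `epoch`.
#' @export
assign_epochs <- function(profiles, wheat_tags = NULL) {
  wheat_tags <- wheat_tags %||%
    unique(profiles$genome_tag[!is.na(profiles$pair_id)])
  pr <- filter(profiles, .data$category != "EXCLUDED",
               .data$genome_tag %in% wheat_tags)
  if (any(is.na(pr$category))) abort("unclassified gene in profiles")
  mutate(
    select(pr, "gene_id", "genome_tag", "category"),
    epoch = dplyr::case_when(
      .data$category %in% COLLINEAR_CATEGORIES ~ "ANCESTRAL",
      .data$category == "SHARED_WHEAT_NC" ~ "INTERMEDIATE",
      .data$category %in% c("LOCUS_SPECIFIC_NC", "TANDEM_DUP_NC") ~ "RECENT"
    )
  ) |> filter(!is.na(.data$epoch))
}

#' Ratio of recent to intermediate gene-insertion rates
#'
#' Computes `(n_recent / T) / (n_intermediate / t_old)` at both endpoints of
#' the recent-epoch duration range (default 2.5-4.5 My for the divergence of
#' the wheat B and D progenitors, against 30 My of shared evolution since
#' the wheat/Brachypodium split). Returned ordered with the low ratio first
#' (obtained at the larger `T`).
#'
#' @param n_intermediate,n_recent insertion counts per epoch.
#' @param t_old duration of the intermediate epoch (My).
#' @param t_recent_range duration range of the recent epoch (My pair).
#' @return tibble with `t_recent`, `ratio` and an `infinite` flag (set when
#'   `n_intermediate` is zero but `n_recent` is not).
#' @export
insertion_rate_ratio <- function(n_intermediate, n_recent,
                                 t_old = 30, t_recent_range = c(2.5, 4.5)) {
  stopifnot(n_intermediate >= 0, n_recent >= 0, t_old > 0,
            all(t_recent_range > 0))
  ts <- sort(t_recent_range, decreasing = TRUE)  # larger T -> lower ratio
  if (n_intermediate == 0 && n_recent > 0) {
    return(tibble(t_recent = ts, ratio = Inf, infinite = TRUE))
  }
  old_rate <- n_intermediate / t_old
  ratio <- if (n_recent == 0 && n_intermediate == 0) {
    rep(NA_real_, 2)
  } else {
    (n_recent / ts) / old_rate
  }
  tibble(t_recent = ts, ratio = ratio, infinite = FALSE)
}

#' Per-epoch insertion counts and rate ratios
#'
#' Tabulates epoch counts per wheat locus and pooled across both (shared
#' insertions counted once in the pooled framing), then applies
#' [insertion_rate_ratio()]. For pooled counts the recent-epoch rate is per
#' lineage (two independent branches since the B/D split).
#'
#' @param profiles classified profiles.
#' @param params [analysis_params()] (supplies `t_old`, `t_bd_split_range`).
#' @param wheat_tags genome tags of the wheat loci; defaults to the tags
#'   carrying homoeologous pairs.
#' @return list with `counts` and `ratios` tibbles.
#' @export
insertion_rate_table <- function(profiles, params = analysis_params(),
                                 wheat_tags = NULL) {
  wheat_tags <- wheat_tags %||%
    unique(profiles$genome_tag[!is.na(profiles$pair_id)])
  ep <- assign_epochs(profiles, wheat_tags)
  counts <- ep |>
    count(.data$genome_tag, .data$epoch, name = "n") |>
    tidyr::complete(genome_tag = wheat_tags,
                    epoch = c("ANCESTRAL", "INTERMEDIATE", "RECENT"),
                    fill = list(n = 0L))
  pooled_int <- counts |>
    filter(.data$epoch == "INTERMEDIATE") |>
    pull(.data$n) |> max()  # shared insertions counted once
  pooled_rec <- counts |>
    filter(.data$epoch == "RECENT") |>
    pull(.data$n) |> sum()
  per_locus <- counts |>
    tidyr::pivot_wider(names_from = "epoch", values_from = "n") |>
    mutate(ratios = map2(.data$INTERMEDIATE, .data$RECENT,
                         ~ insertion_rate_ratio(.x, .y, params$t_old,
                                                params$t_bd_split_range)))
  pooled <- insertion_rate_ratio(pooled_int, pooled_rec, params$t_old,
                                 sort(params$t_bd_split_range * 2,
                                      decreasing = FALSE))
  list(counts = counts, per_locus = per_locus,
       pooled = mutate(pooled, n_intermediate = pooled_int,
                       n_recent = pooled_rec))
}
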