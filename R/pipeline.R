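#' Compare two wheat loci against two model-genome regions
#'
#' The full comparative pipeline: spliced CDS extraction, reciprocal-best
#' homoeolog pairing between the wheat loci at the configured E-value
#' cutoff, reciprocal-best ortholog anchors against each model genome,
#' maximum-weight anchor chaining, tandem resolution and per-gene
#' classification, plus the per-genome summary. Genes flagged `excluded` in
#' the annotation are withheld from pairing but kept in denominators.
#'
#' @param loci named list of four [locus_annotation()] objects.
#' @param wheat_tags genome tags of the wheat loci (D-genome locus first).
#' @param model_tags model-genome tags: Brachypodium first, rice second.
#' @param params [analysis_params()].
#' @return object of class `homeo_comparison`: list with `profiles`,
#'   `summary`, `pairs`, `model_pairs`, `best_model`, `cds`, `distances`.
#' @export
compare_loci <- function(loci, wheat_tags = c("3DS", "3B"),
                         model_tags = c("Bd2", "Os1"),
                         params = analysis_params()) {
  tags <- map_chr(loci, "genome_tag")
  names(loci) <- tags
  missing <- setdiff(c(wheat_tags, model_tags), tags)
  if (length(missing)) {
    abort(sprintf("loci missing for genome tag(s): %s",
                  paste(missing, collapse = ", ")))
  }
  cds <- cds_table(loci)
  cds_of <- function(tag, drop_excluded = TRUE) {
    out <- filter(cds, .data$genome_tag == tag)
    if (drop_excluded) out <- filter(out, .data$status != "excluded")
    out
  }
  wd <- wheat_tags[1]; wb <- wheat_tags[2]

  pairs <- reciprocal_best_pairs(cds_of(wd), cds_of(wb), params)
  model_pairs <- map(setNames(wheat_tags, wheat_tags), function(wt) {
    map(setNames(model_tags, model_tags), function(mt) {
      reciprocal_best_pairs(cds_of(wt), cds_of(mt), params)
    })
  })
  model_cds <- bind_rows(cds_of(model_tags[1]), cds_of(model_tags[2]))
  best_model <- map(setNames(wheat_tags, wheat_tags), function(wt) {
    homology_search(cds_of(wt), model_cds, params)
  })

  profiles <- classify_genes(loci, wheat_tags, model_tags, pairs,
                             model_pairs, params, best_model = best_model)
  distances <- map(loci, function(lc) {
    if (nrow(lc$genes) < 2L) return(NULL)
    d <- gene_distances(lc)
    tibble(genome_tag = lc$genome_tag, mean_bp = d$mean, median_bp = d$median)
  }) |> list_rbind()

  structure(
    list(profiles = profiles, summary = summarize_collinearity(profiles),
         pairs = pairs, model_pairs = model_pairs, best_model = best_model,
         cds = cds, distances = distances,
         wheat_tags = wheat_tags, model_tags = model_tags, params = params),
    class = "homeo_comparison"
  )
}

#' @export
print.homeo_comparison <- function(x, ...) {
  cat(sprintf("<homeo_comparison> %s vs %s (models: %s)\n",
              x$wheat_tags[1], x$wheat_tags[2],
              paste(x$model_tags, collapse = ", ")))
  cat(sprintf("  %d homoeologous pairs\n", nrow(x$pairs)))
  print(x$summary)
  invisible(x)
}

#' @describeIn compare_loci per-gene profiles as a tibble.
#' @param x a `homeo_comparison`.
#' @param ... unused.
#' @export
tidy.homeo_comparison <- function(x, ...) {
  as_tibble(x$profiles)
}

#' @describeIn compare_loci one row of headline numbers (pair count, wheat
#'   homoeolog percentage, per-genome collinear percentages).
#' @export
glance.homeo_comparison <- function(x, ...) {
  s <- x$summary
  get <- function(tag, col) s[[col]][match(tag, s$genome_tag)]
  tibble(
    n_pairs = nrow(x$pairs),
    pct_homoeolog_b = get(x$wheat_tags[2], "pct_homoeolog"),
    pct_collinear_d = get(x$wheat_tags[1], "pct_collinear"),
    pct_collinear_b = get(x$wheat_tags[2], "pct_collinear"),
    pct_collinear_bd = get(x$model_tags[1], "pct_collinear"),
    pct_collinear_os = get(x$model_tags[2], "pct_collinear")
  )
}

#' Call pseudogenes across the compared wheat loci
#'
#' Assesses every wheat gene (except annotation-excluded ones) against an
#' intact reference, preferring the homoeologous partner when it has an open
#' reading frame and falling back to the gene's best model-genome homolog;
#' genes with no usable reference get the intrinsic premature-stop check
#' only. For defective genes with an intact homoeologous partner the
#' pseudogenization mechanism is attributed from the surrounding regions and
#' repeat annotation ([attribute_mechanism()]).
#'
#' @param comparison a [compare_loci()] result.
#' @param loci the same loci list.
#' @param params [analysis_params()].
#' @param flank flank length (bp) for mechanism attribution.
#' @return tibble of integrity calls with `genome_tag`, `category` and
#'   `mechanism`.
#' @export
call_pseudogenes <- function(comparison, loci,
                             params = analysis_params(), flank = 1000L) {
  tags <- map_chr(loci, "genome_tag")
  names(loci) <- tags
  cds <- comparison$cds
  seq_of <- setNames(cds$seq, cds$gene_id)
  tag_of <- setNames(cds$genome_tag, cds$gene_id)
  pr <- filter(comparison$profiles,
               .data$genome_tag %in% comparison$wheat_tags,
               .data$category != "EXCLUDED")
  valid_orf <- function(s) {
    st <- first_stop_codon(s)
    is.na(st) || st >= nchar(s) %/% 3L
  }
  calls <- list()
  for (i in seq_len(nrow(pr))) {
    g <- pr[i, ]
    ref <- NULL
    if (!is.na(g$pair_id) && valid_orf(seq_of[[g$pair_id]])) {
      ref <- seq_of[[g$pair_id]]
    } else if (!is.na(g$best_model_id) &&
               valid_orf(seq_of[[g$best_model_id]])) {
      ref <- seq_of[[g$best_model_id]]
    }
    call <- assess_integrity(seq_of[[g$gene_id]], ref, params,
                             gene_id = g$gene_id)
    call$genome_tag <- g$genome_tag
    call$category <- g$category
    call$mechanism <- NA_character_
    if (call$status != "intact" && !is.na(g$pair_id) &&
        valid_orf(seq_of[[g$pair_id]])) {
      partner_tag <- tag_of[[g$pair_id]]
      gene_locus <- loci[[partner_tag]]
      pseudo_locus <- loci[[g$genome_tag]]
      pg <- locus_gene(gene_locus, g$pair_id)
      qg <- locus_gene(pseudo_locus, g$gene_id)
      g_lo <- max(0L, pg$start - flank)
      g_hi <- min(nchar(gene_locus$seq), pg$end + flank)
      p_lo <- max(0L, qg$start - flank)
      p_hi <- min(nchar(pseudo_locus$seq), qg$end + flank)
      gene_region <- substring(gene_locus$seq, g_lo + 1L, g_hi)
      pseudo_region <- substring(pseudo_locus$seq, p_lo + 1L, p_hi)
      if (pg$strand == "-") gene_region <- revcomp(gene_region)
      if (qg$strand == "-") pseudo_region <- revcomp(pseudo_region)
      reps <- filter(pseudo_locus$repeats,
                     .data$start < p_hi, .data$end > p_lo) |>
        mutate(start = .data$start - p_lo, end = .data$end - p_lo)
      span <- if (pg$strand == "-") {
        c(g_hi - pg$end, g_hi - pg$start)
      } else {
        c(pg$start - g_lo, pg$end - g_lo)
      }
      call$mechanism <- attribute_mechanism(
        gene_region, span, pseudo_region, reps, params)
    }
    calls[[length(calls) + 1L]] <- call
  }
  list_rbind(calls)
}

#' Score expression of the compared wheat loci from an EST collection
#'
#' Runs the exact-match EST rule, removes ESTs hitting both members of any
#' homoeologous pair, and summarises expressed fractions per locus and
#' collinearity group.
#'
#' @param comparison a [compare_loci()] result.
#' @param ests tibble with `id`, `seq`.
#' @param params [analysis_params()].
#' @return list with `hits`, `removed` (EST ids) and `summary`.
#' @export
score_expression <- function(comparison, ests, params = analysis_params()) {
  wheat_cds <- filter(comparison$cds,
                      .data$genome_tag %in% comparison$wheat_tags,
                      .data$status != "excluded")
  hits <- match_ests(wheat_cds, ests, params)
  filtered <- drop_shared_ests(hits, comparison$pairs)
  summary <- expression_summary(filtered$hits, comparison$profiles,
                                wheat_tags = comparison$wheat_tags)
  list(hits = filtered$hits, removed = filtered$removed, summary = summary)
}

#' Gene-map plot of a comparison
#'
#' Draws each locus as a horizontal track with genes as segments coloured by
#' collinearity category, mirroring the usual figure style for such
#' comparisons (collinear green, wheat-shared blue, locus-specific red).
#'
#' @param object a `homeo_comparison`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.homeo_comparison <- function(object, ...) {
  pr <- object$profiles
  lv <- c(object$model_tags[2], object$model_tags[1],
          object$wheat_tags[1], object$wheat_tags[2])
  pr$genome_tag <- factor(pr$genome_tag, levels = lv)
  cols <- c(COLLINEAR_ALL = "#2e7d32", COLLINEAR_RICE_WHEAT = "#66bb6a",
            SHARED_WHEAT_NC = "#1565c0", LOCUS_SPECIFIC_NC = "#c62828",
            TANDEM_DUP_NC = "#ef6c00", EXCLUDED = "grey60")
  ggplot2::ggplot(pr) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start / 1e3, xend = .data$end / 1e3,
                   y = .data$genome_tag, yend = .data$genome_tag),
      linewidth = 6, colour = "grey85") +
    ggplot2::geom_point(
      ggplot2::aes(x = (.data$start + .data$end) / 2e3,
                   y = .data$genome_tag, colour = .data$category),
      shape = 15, size = 3) +
    ggplot2::scale_colour_manual(values = cols, name = "category") +
    ggplot2::labs(x = "position (kb)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Expression-summary bar plot
#'
#' @param summary output of [expression_summary()] (or
#'   `score_expression()$summary`).
#' @return a ggplot object.
#' @export
plot_expression_summary <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$genome_tag,
                               y = .data$pct_expressed,
                               fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% genes with EST support", fill = NULL) +
    ggplot2::theme_minimal()
}
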