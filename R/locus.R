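#' Construct a locus annotation
#'
#' A locus annotation couples one contiguous DNA sequence with its ordered
#' gene models and repeat features. All coordinates are 0-based, half-open
#' (`start < end`, `end` exclusive); GFF3 import/export is the only 1-based
#' surface. Genes are sorted by start and ids must be unique.
#'
#' @param locus_id locus identifier (also the GFF3/FASTA seqid).
#' @param genome_tag genome label, e.g. `"3DS"`, `"3B"`, `"Bd2"`, `"Os1"`.
#' @param seq the locus DNA sequence (single string over `A,C,G,T,N`).
#' @param genes tibble with columns `gene_id`, `strand` (`"+"`/`"-"`),
#'   `start`, `end`, `status` (`intact`, `pseudogene`, `fragment`,
#'   `excluded`) and a list-column `exons` of tibbles with `start`, `end`.
#' @param repeats tibble with columns `start`, `end`, `class`, `order`,
#'   `superfamily`, `complete`.
#' @return An object of class `locus_annotation`.
#' @export
locus_annotation <- function(locus_id, genome_tag, seq,
                             genes = empty_genes(), repeats = empty_repeats()) {
  genes <- as_tibble(genes)
  repeats <- as_tibble(repeats)
  if (!"status" %in% names(genes)) genes$status <- rep("intact", nrow(genes))
  if (!"notes" %in% names(genes)) genes$notes <- rep("", nrow(genes))
  if (nrow(genes)) genes <- arrange(genes, .data$start, .data$end)
  x <- structure(
    list(locus_id = locus_id, genome_tag = genome_tag, seq = seq,
         genes = genes, repeats = repeats),
    class = "locus_annotation"
  )
  validate_locus(x)
  x
}

empty_genes <- function() {
  tibble(gene_id = character(), strand = character(),
         start = integer(), end = integer(), status = character(),
         exons = list(), notes = character())
}

empty_repeats <- function() {
  tibble(start = integer(), end = integer(), class = character(),
         order = character(), superfamily = character(), complete = logical())
}

REPEAT_SUPERFAMILIES <- c("Gypsy", "Copia", "CACTA", "LINE", "Harbinger",
                          "Mutator", "Mariner", "unclassified")

validate_locus <- function(x) {
  len <- nchar(x$seq)
  g <- x$genes
  if (nrow(g)) {
    if (anyDuplicated(g$gene_id)) {
      abort(sprintf("duplicated gene ids in locus %s", x$locus_id))
    }
    if (!all(g$strand %in% c("+", "-"))) abort("gene strand must be + or -")
    if (!all(g$status %in% c("intact", "pseudogene", "fragment", "excluded"))) {
      abort("unknown gene status")
    }
    if (any(g$start < 0L | g$start >= g$end | g$end > len)) {
      abort(sprintf("gene span outside locus %s", x$locus_id))
    }
    for (i in seq_len(nrow(g))) {
      ex <- g$exons[[i]]
      if (is.null(ex) || nrow(ex) == 0L) {
        abort(sprintf("gene %s has no exons", g$gene_id[i]))
      }
      if (is.unsorted(ex$start, strictly = TRUE) && nrow(ex) > 1L) {
        abort(sprintf("exons of %s are not sorted", g$gene_id[i]))
      }
      if (any(ex$start >= ex$end)) abort("empty exon span")
      if (nrow(ex) > 1L && any(ex$start[-1] < ex$end[-nrow(ex)])) {
        abort(sprintf("overlapping exons in %s", g$gene_id[i]))
      }
      if (ex$start[1] < g$start[i] || ex$end[nrow(ex)] > g$end[i]) {
        abort(sprintf("exon outside gene span in %s", g$gene_id[i]))
      }
    }
  }
  r <- x$repeats
  if (nrow(r)) {
    if (any(r$start < 0L | r$start >= r$end | r$end > len)) {
      abort(sprintf("repeat span outside locus %s", x$locus_id))
    }
    if (!all(r$superfamily %in% REPEAT_SUPERFAMILIES)) {
      abort("repeat superfamily outside controlled vocabulary")
    }
  }
  invisible(x)
}

#' @export
print.locus_annotation <- function(x, ...) {
  cat(sprintf("<locus_annotation> %s (%s): %s bp, %d genes, %d repeats\n",
              x$locus_id, x$genome_tag,
              format(nchar(x$seq), big.mark = ","),
              nrow(x$genes), nrow(x$repeats)))
  invisible(x)
}

locus_gene <- function(locus, gene_id) {
  i <- match(gene_id, locus$genes$gene_id)
  if (is.na(i)) {
    abort(sprintf("gene %s not found in locus %s", gene_id, locus$locus_id))
  }
  locus$genes[i, ]
}

#' Gene tables of one or more loci as a single tibble
#'
#' @param loci a `locus_annotation` or list of them.
#' @return tibble with one row per gene plus `locus_id`, `genome_tag` and the
#'   spliced CDS length.
#' @export
gene_table <- function(loci) {
  if (inherits(loci, "locus_annotation")) loci <- list(loci)
  list_rbind(map(loci, function(lc) {
    g <- lc$genes
    if (!nrow(g)) return(NULL)
    mutate(g,
           locus_id = lc$locus_id, genome_tag = lc$genome_tag,
           cds_len = map_int(.data$exons, ~ sum(.x$end - .x$start)),
           .before = 1)
  }))
}
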