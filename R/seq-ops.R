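#' Extract the spliced coding sequence of a gene
#'
#' Exon substrings are concatenated 5' to 3' on the coding strand: minus-strand
#' genes are reverse complemented after concatenation of their (locus-forward)
#' exon spans. `N` residues inside exons are rejected unless `allow_n = TRUE`,
#' since gene models are expected to come from gap-free regions.
#'
#' @param locus a [locus_annotation()].
#' @param gene_id gene identifier within `locus`.
#' @param allow_n permit assembly-gap `N` residues inside the CDS.
#' @return A single character string (the spliced CDS).
#' @export
extract_cds <- function(locus, gene_id, allow_n = FALSE) {
  g <- locus_gene(locus, gene_id)
  ex <- g$exons[[1]]
  parts <- substring(locus$seq, ex$start + 1L, ex$end)
  cds <- paste(parts, collapse = "")
  if (!allow_n && grepl("N", cds, fixed = TRUE)) {
    abort(sprintf("gene %s contains N residues in its CDS", gene_id))
  }
  if (g$strand == "-") cds <- revcomp(cds)
  cds
}

#' Spliced CDS of every gene in a set of loci
#'
#' @inheritParams extract_cds
#' @param loci a `locus_annotation` or list of them.
#' @return tibble with `gene_id`, `locus_id`, `genome_tag`, `status`, `seq`.
#' @export
cds_table <- function(loci, allow_n = FALSE) {
  if (inherits(loci, "locus_annotation")) loci <- list(loci)
  list_rbind(map(loci, function(lc) {
    if (!nrow(lc$genes)) return(NULL)
    tibble(
      gene_id = lc$genes$gene_id,
      locus_id = lc$locus_id,
      genome_tag = lc$genome_tag,
      status = lc$genes$status,
      seq = map_chr(lc$genes$gene_id, ~ extract_cds(lc, .x, allow_n = allow_n))
    )
  }))
}

#' Upstream (promoter) region of a gene
#'
#' Returns the `length` bases 5' of the start codon, reported on the coding
#' strand (minus-strand regions are reverse complemented). Regions are
#' clipped at the locus boundary; clipped regions carry `short = TRUE`.
#'
#' @inheritParams extract_cds
#' @param length region length in bp (default from [analysis_params()]).
#' @return A list with elements `seq`, `short` and `length`.
#' @export
upstream_region <- function(locus, gene_id, length = 1000L) {
  g <- locus_gene(locus, gene_id)
  n <- nchar(locus$seq)
  if (g$strand == "+") {
    from <- max(0L, g$start - length)
    seq <- substring(locus$seq, from + 1L, g$start)
  } else {
    to <- min(n, g$end + length)
    seq <- revcomp(substring(locus$seq, g$end + 1L, to))
  }
  list(seq = seq, short = nchar(seq) < length, length = nchar(seq))
}

#' Upstream regions for all genes of one or more loci
#'
#' @inheritParams upstream_region
#' @param loci a `locus_annotation` or list of them.
#' @return tibble with `gene_id`, `locus_id`, `genome_tag`, `seq`, `short`.
#' @export
upstream_table <- function(loci, length = 1000L) {
  if (inherits(loci, "locus_annotation")) loci <- list(loci)
  list_rbind(map(loci, function(lc) {
    if (!nrow(lc$genes)) return(NULL)
    regs <- map(lc$genes$gene_id, ~ upstream_region(lc, .x, length))
    tibble(
      gene_id = lc$genes$gene_id,
      locus_id = lc$locus_id,
      genome_tag = lc$genome_tag,
      seq = map_chr(regs, "seq"),
      short = map_lgl(regs, "short")
    )
  }))
}

translate_codons <- function(cds) {
  n <- nchar(cds) %/% 3L
  if (n == 0L) return(character())
  substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# index of the first in-frame stop codon, NA if none
first_stop_codon <- function(cds) {
  codons <- translate_codons(cds)
  hit <- which(codons %in% STOP_CODONS)
  if (length(hit)) hit[1] else NA_integer_
}
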