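#' Read locus annotations from GFF3
#'
#' Accepts GFF3 with `gene` + `exon` features (exons linked by `Parent`) and
#' `repeat_region` features carrying `repeat_class`, `repeat_order`,
#' `superfamily` and `complete` attributes. 1-based closed GFF3 coordinates
#' are converted to the internal 0-based half-open convention. A `region`
#' feature per seqid may carry a `genome_tag` attribute.
#'
#' @param path path to a GFF3 file.
#' @param sequences tibble from [read_fasta()] (or named character vector)
#'   resolving every seqid used in the file.
#' @return A named list of [locus_annotation()] objects.
#' @export
read_gff3 <- function(path, sequences) {
  if (is.character(sequences)) {
    sequences <- tibble(id = names(sequences), seq = unname(sequences))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)
  parent <- if ("Parent" %in% names(df)) {
    vapply(df$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
           character(1))
  } else rep(NA_character_, nrow(df))
  df$parent <- parent

  seqids <- unique(df$seqnames)
  missing <- setdiff(seqids, sequences$id)
  if (length(missing)) {
    abort(sprintf("unknown seqid(s) in %s: %s", path,
                  paste(missing, collapse = ", ")))
  }

  get_chr <- function(d, col, default = NA_character_) {
    if (col %in% names(d)) as.character(d[[col]]) else rep(default, nrow(d))
  }

  loci <- map(seqids, function(sid) {
    d <- df[df$seqnames == sid, , drop = FALSE]
    reg <- d[d$type == "region", , drop = FALSE]
    tag <- if (nrow(reg) && "genome_tag" %in% names(reg) &&
               !is.na(reg$genome_tag[1])) as.character(reg$genome_tag[1]) else sid
    gd <- d[d$type == "gene", , drop = FALSE]
    ed <- d[d$type == "exon", , drop = FALSE]
    genes <- if (nrow(gd)) {
      ids <- get_chr(gd, "ID")
      if (any(is.na(ids))) abort(sprintf("gene without ID in %s", path))
      exons <- map(ids, function(gid) {
        ee <- ed[!is.na(ed$parent) & ed$parent == gid, , drop = FALSE]
        if (!nrow(ee)) {
          # single-exon gene written without explicit exon rows
          gg <- gd[ids == gid, , drop = FALSE]
          return(tibble(start = gg$start - 1L, end = gg$end))
        }
        arrange(tibble(start = ee$start - 1L, end = ee$end), .data$start)
      })
      tibble(
        gene_id = ids, strand = gd$strand,
        start = gd$start - 1L, end = gd$end,
        status = dplyr::coalesce(get_chr(gd, "status"), "intact"),
        exons = exons,
        notes = dplyr::coalesce(get_chr(gd, "notes"), "")
      )
    } else empty_genes()
    rd <- d[d$type == "repeat_region", , drop = FALSE]
    repeats <- if (nrow(rd)) {
      tibble(
        start = rd$start - 1L, end = rd$end,
        class = dplyr::coalesce(get_chr(rd, "repeat_class"), "unclassified"),
        order = dplyr::coalesce(get_chr(rd, "repeat_order"), "unclassified"),
        superfamily = dplyr::coalesce(get_chr(rd, "superfamily"),
                                      "unclassified"),
        complete = dplyr::coalesce(
          as.logical(get_chr(rd, "complete")), FALSE)
      )
    } else empty_repeats()
    seq <- sequences$seq[match(sid, sequences$id)]
    locus_annotation(sid, tag, seq, genes, repeats)
  })
  setNames(loci, seqids)
}

#' Write locus annotations to GFF3
#'
#' The inverse of [read_gff3()]: internal 0-based half-open spans are emitted
#' as 1-based closed GFF3 coordinates, so a read/write/read round trip is the
#' identity on the data model.
#'
#' @param loci a `locus_annotation` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(loci, path) {
  if (inherits(loci, "locus_annotation")) loci <- list(loci)
  rows <- list()
  add <- function(seqid, source, type, start0, end0, strand, attrs) {
    kv <- paste(names(attrs)[!is.na(attrs)],
                vapply(attrs[!is.na(attrs)], as.character, character(1)),
                sep = "=", collapse = ";")
    rows[[length(rows) + 1L]] <<- sprintf(
      "%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
      seqid, source, type, start0 + 1L, end0, strand, kv
    )
  }
  for (lc in loci) {
    add(lc$locus_id, "homeolocus", "region", 0L, nchar(lc$seq), "+",
        c(ID = lc$locus_id, genome_tag = lc$genome_tag))
    g <- lc$genes
    for (i in seq_len(nrow(g))) {
      add(lc$locus_id, "homeolocus", "gene", g$start[i], g$end[i], g$strand[i],
          c(ID = g$gene_id[i], status = g$status[i],
            notes = if (nzchar(g$notes[i])) g$notes[i] else NA))
      ex <- g$exons[[i]]
      for (j in seq_len(nrow(ex))) {
        add(lc$locus_id, "homeolocus", "exon", ex$start[j], ex$end[j],
            g$strand[i],
            c(ID = sprintf("%s.exon%d", g$gene_id[i], j),
              Parent = g$gene_id[i]))
      }
    }
    r <- lc$repeats
    for (i in seq_len(nrow(r))) {
      add(lc$locus_id, "homeolocus", "repeat_region", r$start[i], r$end[i], "+",
          c(ID = sprintf("%s.rep%d", lc$locus_id, i),
            repeat_class = r$class[i], repeat_order = r$order[i],
            superfamily = r$superfamily[i],
            complete = tolower(as.character(r$complete[i]))))
    }
  }
  writeLines(c("##gff-version 3", unlist(rows)), path)
  invisible(path)
}
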