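#' Simulation parameters for locus evolution
#'
#' Describes one ancestral gene layout evolving into four present-day loci:
#' rice (Os), Brachypodium (Bd) and the wheat B and D lineages. The wheat
#' lineages share a stem branch from the wheat/Brachypodium split
#' (`t_brachy_split`, 35 My ago) to the divergence of the B and D diploid
#' progenitors (`t_bd_split`, drawn from `t_bd_split_range`, 2.5-4.5 My ago);
#' afterwards they evolve independently, with gene insertion optionally
#' accelerated by `acceleration` (the hypothesis under study is a three- to
#' five-fold increase after the progenitor split). The rice lineage is
#' treated as splitting at the ancestral layout; only presence/absence
#' patterns matter downstream, not the Bd/Os joint branch history.
#'
#' @param n_ancestral_genes genes in the ancestral layout.
#' @param insertion_rate gene insertions per My per lineage.
#' @param acceleration fold-change of the insertion rate on the wheat B and
#'   D branches after `t_bd_split`.
#' @param deletion_rate,tandem_dup_rate,pseudogenization_rate events per My
#'   per lineage.
#' @param substitution_rate substitutions per site per My.
#' @param t_brachy_split,t_bd_split_range,t_tetraploid times in My.
#' @param t_barley_split optional barley split time (My); the barley lineage
#'   is off by default and not simulated.
#' @param te_expansion_factor_B fractional intergenic expansion of the B
#'   lineage locus (the B genome is about 27% larger).
#' @param gene_length_range CDS length range (bp; rounded to codons).
#' @param intergenic_mean mean intergenic distance (bp).
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_ancestral_genes = 10L,
                       insertion_rate = 0.2,
                       acceleration = 4,
                       deletion_rate = 0,
                       tandem_dup_rate = 0,
                       pseudogenization_rate = 0,
                       substitution_rate = 0.0015,
                       t_brachy_split = 35,
                       t_bd_split_range = c(2.5, 4.5),
                       t_tetraploid = 0.5,
                       t_barley_split = 10,
                       te_expansion_factor_B = 0.27,
                       gene_length_range = c(300L, 600L),
                       intergenic_mean = 400) {
  p <- as.list(environment())
  stopifnot(p$insertion_rate >= 0, p$deletion_rate >= 0,
            p$tandem_dup_rate >= 0, p$pseudogenization_rate >= 0,
            p$acceleration > 0, p$substitution_rate >= 0,
            p$t_brachy_split > max(p$t_bd_split_range),
            min(p$t_bd_split_range) > p$t_tetraploid)
  structure(p, class = "sim_params")
}

# random CDS: ATG + non-stop codons + stop
make_cds <- function(len) {
  n_codons <- max(4L, round(len / 3))
  codons <- character(n_codons)
  codons[1] <- "ATG"
  body <- replicate(n_codons - 2L, {
    repeat {
      c3 <- paste(sample(DNA_BASES, 3L, replace = TRUE), collapse = "")
      if (!c3 %in% STOP_CODONS) return(c3)
    }
  })
  codons[2:(n_codons - 1L)] <- body
  codons[n_codons] <- sample(STOP_CODONS, 1L)
  paste(codons, collapse = "")
}

# substitution-only divergence; optionally codon-safe (never creates an
# in-frame stop, never touches protected positions, 1-based)
mutate_cds <- function(cds, n_subs, protect = integer(), codon_safe = TRUE) {
  n <- nchar(cds)
  if (n_subs <= 0L || n < 10L) return(cds)
  s <- strsplit(cds, "")[[1]]
  avail <- setdiff(4:(n - 3L), protect)
  pos <- sample(avail, min(n_subs, length(avail)))
  for (p in pos) {
    repeat {
      nb <- sample(setdiff(DNA_BASES, s[p]), 1L)
      if (!codon_safe) { s[p] <- nb; break }
      old <- s[p]
      s[p] <- nb
      ci <- (p - 1L) %/% 3L
      codon <- paste(s[(3L * ci + 1L):(3L * ci + 3L)], collapse = "")
      if (!codon %in% STOP_CODONS) break
      s[p] <- old
    }
  }
  paste(s, collapse = "")
}

# stratified divergence: >=1 substitution per `window` bp, so no exact
# common run of ~2*window or longer survives between the two versions;
# positions inside `keep_block` (1-based [lo, hi]) are never touched
mutate_spaced <- function(cds, rate, window = 45L, keep_block = NULL,
                          protect = integer(), codon_safe = TRUE) {
  n <- nchar(cds)
  s <- strsplit(cds, "")[[1]]
  protect_all <- unique(c(1:3, (n - 2L):n, protect,
                          if (!is.null(keep_block))
                            keep_block[1]:keep_block[2]))
  starts <- seq(1L, n, by = window)
  for (w in starts) {
    hi <- min(w + window - 1L, n)
    avail <- setdiff(w:hi, protect_all)
    if (!length(avail)) next
    k <- max(1L, rbinom(1L, length(avail), rate))
    pos <- sample(avail, min(k, length(avail)))
    for (p in pos) {
      repeat {
        nb <- sample(setdiff(DNA_BASES, s[p]), 1L)
        if (!codon_safe) { s[p] <- nb; break }
        old <- s[p]
        s[p] <- nb
        ci <- (p - 1L) %/% 3L
        codon <- paste(s[(3L * ci + 1L):(3L * ci + 3L)], collapse = "")
        if (!codon %in% STOP_CODONS) break
        s[p] <- old
      }
    }
  }
  paste(s, collapse = "")
}

SIM_MECHANISMS <- c("TE_INSERTION", "POINT_FRAMESHIFT", "INTERNAL_DELETION",
                    "TERMINAL_TRUNCATION")

# apply one pseudogenization mechanism; returns list(cds, repeat_span or NULL)
apply_mechanism <- function(cds, mechanism, te_len = 2000L) {
  n <- nchar(cds)
  switch(
    mechanism,
    TE_INSERTION = {
      at <- round(n * runif(1, 0.55, 0.8))
      te <- random_dna(te_len)
      list(cds = paste0(substring(cds, 1L, at), te, substring(cds, at + 1L)),
           repeat_span = c(at, at + te_len))  # 0-based within the new CDS
    },
    POINT_FRAMESHIFT = {
      at <- round(n * runif(1, 0.3, 0.7))
      list(cds = paste0(substring(cds, 1L, at), sample(DNA_BASES, 1L),
                        substring(cds, at + 1L)),
           repeat_span = NULL)
    },
    INTERNAL_DELETION = {
      del <- 3L * round(n * runif(1, 0.31, 0.45) / 3)
      from <- round(n * runif(1, 0.15, 0.25))
      list(cds = paste0(substring(cds, 1L, from),
                        substring(cds, from + del + 1L)),
           repeat_span = NULL)
    },
    TERMINAL_TRUNCATION = {
      cut <- 3L * round(n * runif(1, 0.35, 0.55) / 3)
      cds2 <- if (runif(1) < 0.5) substring(cds, cut + 1L) else
        substring(cds, 1L, n - cut)
      list(cds = cds2, repeat_span = NULL)
    }
  )
}

#' Simulate the evolution of four orthologous loci
#'
#' Starting from one ancestral gene layout, evolves rice, Brachypodium and
#' the wheat B and D lineages with per-branch Poisson events (gene
#' insertion, deletion, tandem duplication, pseudogenization by one of the
#' four defect mechanisms) and substitution-only sequence divergence. All
#' events are logged with their time, lineage and mechanism: the log is the
#' ground truth for parameter-recovery tests.
#'
#' @param sp [sim_params()].
#' @param seed RNG seed (the simulator is a pure function of `(sp, seed)`).
#' @return list with `loci` (named list of [locus_annotation()]: `3DS`,
#'   `3B`, `Bd2`, `Os1`), `events` tibble (`time`, `lineage`, `kind`,
#'   `mechanism`, `gene_id` — base gene id) and `truth` tibble mapping base
#'   gene ids to per-locus gene ids with origin lineage/time.
#' @export
simulate_locus_evolution <- function(sp = sim_params(), seed = 1L) {
  stopifnot(inherits(sp, "sim_params"))
  withr::with_seed(seed, {
    t_bd <- runif(1, sp$t_bd_split_range[1], sp$t_bd_split_range[2])
    counter <- 0L
    new_id <- function() {
      counter <<- counter + 1L
      sprintf("g%04d", counter)
    }
    new_gene <- function(time, lineage) {
      len <- sample(seq(sp$gene_length_range[1], sp$gene_length_range[2]), 1L)
      tibble(base_id = new_id(), cds = make_cds(len), status = "intact",
             mechanism = NA_character_, repeat_off = NA_integer_,
             repeat_len = NA_integer_,
             origin_time = time, origin_lineage = lineage)
    }
    events <- list()
    log_event <- function(time, lineage, kind, mechanism, base_id) {
      events[[length(events) + 1L]] <<- tibble(
        time = time, lineage = lineage, kind = kind,
        mechanism = mechanism, gene_id = base_id)
    }

    ancestor <- list_rbind(map(seq_len(sp$n_ancestral_genes),
                               ~ new_gene(sp$t_brachy_split, "ancestral")))

    evolve <- function(genes, lineage, t_from, t_to, insertion_mult = 1) {
      dur <- t_from - t_to
      draw_times <- function(rate) {
        k <- rpois(1L, rate * dur)
        sort(runif(k, t_to, t_from), decreasing = TRUE)
      }
      sched <- bind_rows(
        tibble(time = draw_times(sp$insertion_rate * insertion_mult),
               kind = "insert"),
        tibble(time = draw_times(sp$deletion_rate), kind = "delete"),
        tibble(time = draw_times(sp$tandem_dup_rate), kind = "tandem_dup"),
        tibble(time = draw_times(sp$pseudogenization_rate),
               kind = "pseudogenize")
      ) |> arrange(desc(.data$time))
      if (nrow(genes) + sum(sched$kind %in% c("insert", "tandem_dup")) > 1e4L) {
        abort("simulated gene count would exceed 10000; lower the rates")
      }
      for (i in seq_len(nrow(sched))) {
        tm <- sched$time[i]
        kind <- sched$kind[i]
        if (kind == "insert") {
          g <- new_gene(tm, lineage)
          at <- sample(nrow(genes) + 1L, 1L)
          genes <- bind_rows(head(genes, at - 1L), g,
                             tail(genes, nrow(genes) - at + 1L))
          log_event(tm, lineage, "insert", NA_character_, g$base_id)
        } else if (kind == "delete") {
          if (!nrow(genes)) next
          at <- sample(nrow(genes), 1L)
          log_event(tm, lineage, "delete", NA_character_,
                    genes$base_id[at])
          genes <- genes[-at, ]
        } else if (kind == "tandem_dup") {
          if (!nrow(genes)) next
          at <- sample(nrow(genes), 1L)
          copy <- genes[at, ]
          copy$base_id <- new_id()
          copy$cds <- mutate_spaced(copy$cds, 0.02,
                                    codon_safe = copy$status == "intact")
          copy$origin_time <- tm
          copy$origin_lineage <- lineage
          genes <- bind_rows(head(genes, at), copy,
                             tail(genes, nrow(genes) - at))
          log_event(tm, lineage, "tandem_dup", NA_character_, copy$base_id)
        } else {
          intact <- which(genes$status == "intact")
          if (!length(intact)) next
          at <- if (length(intact) == 1L) intact else sample(intact, 1L)
          mech <- sample(SIM_MECHANISMS, 1L)
          res <- apply_mechanism(genes$cds[at], mech)
          genes$cds[at] <- res$cds
          genes$status[at] <- "pseudogene"
          genes$mechanism[at] <- mech
          if (!is.null(res$repeat_span)) {
            genes$repeat_off[at] <- res$repeat_span[1]
            genes$repeat_len[at] <- res$repeat_span[2] - res$repeat_span[1]
          }
          log_event(tm, lineage, paste0("pseudogenize:", mech), mech,
                    genes$base_id[at])
        }
      }
      # substitution divergence over the residence time of each gene
      genes$cds <- map_chr(seq_len(nrow(genes)), function(i) {
        dt <- min(genes$origin_time[i], t_from) - t_to
        n_subs <- rpois(1L, sp$substitution_rate * dt * nchar(genes$cds[i]))
        mutate_cds(genes$cds[i], n_subs,
                   codon_safe = genes$status[i] == "intact")
      })
      genes
    }

    os <- evolve(ancestor, "Os", sp$t_brachy_split, 0)
    bd <- evolve(ancestor, "Bd", sp$t_brachy_split, 0)
    stem <- evolve(ancestor, "wheat_stem", sp$t_brachy_split, t_bd)
    wd <- evolve(stem, "D", t_bd, 0, insertion_mult = sp$acceleration)
    wb <- evolve(stem, "B", t_bd, 0, insertion_mult = sp$acceleration)

    assemble <- function(genes, tag, locus_id, expand = 0) {
      pieces <- character(0)
      rows <- list()
      reps <- list()
      pos <- 0L
      mean_gap <- sp$intergenic_mean * (1 + expand)
      for (i in seq_len(nrow(genes))) {
        gap <- 200L + rpois(1L, mean_gap)
        pieces <- c(pieces, random_dna(gap))
        pos <- pos + gap
        cds <- genes$cds[i]
        gid <- paste0(genes$base_id[i], "_", tag)
        rows[[i]] <- tibble(
          gene_id = gid, strand = "+", start = pos,
          end = pos + nchar(cds), status = "intact",
          exons = list(tibble(start = pos, end = pos + nchar(cds))),
          notes = ""
        )
        if (!is.na(genes$repeat_off[i])) {
          reps[[length(reps) + 1L]] <- tibble(
            start = pos + genes$repeat_off[i],
            end = pos + genes$repeat_off[i] + genes$repeat_len[i],
            class = "Retrotransposons", order = "LTR_retrotransposons",
            superfamily = "Gypsy", complete = FALSE)
        }
        pieces <- c(pieces, cds)
        pos <- pos + nchar(cds)
      }
      pieces <- c(pieces, random_dna(200L + rpois(1L, mean_gap)))
      locus_annotation(locus_id, tag, paste(pieces, collapse = ""),
                       rbind_or(rows, empty_genes()),
                       rbind_or(reps, empty_repeats()))
    }

    loci <- list(
      `3DS` = assemble(wd, "3DS", "sim_3DS"),
      `3B` = assemble(wb, "3B", "sim_3B", expand = sp$te_expansion_factor_B),
      Bd2 = assemble(bd, "Bd2", "sim_Bd2"),
      Os1 = assemble(os, "Os1", "sim_Os1")
    )
    truth <- list_rbind(imap(
      list(`3DS` = wd, `3B` = wb, Bd2 = bd, Os1 = os),
      function(genes, tag) {
        mutate(select(genes, "base_id", "status", "mechanism",
                      "origin_time", "origin_lineage"),
               genome_tag = tag,
               gene_id = paste0(.data$base_id, "_", tag))
      }))
    list(
      loci = loci,
      events = rbind_or(events, tibble(
        time = numeric(), lineage = character(), kind = character(),
        mechanism = character(), gene_id = character())),
      truth = truth,
      t_bd_split = t_bd
    )
  })
}
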