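test_that("the null model leaves four identical gene complements", {
  sp <- sim_params(insertion_rate = 0, deletion_rate = 0,
                   tandem_dup_rate = 0, pseudogenization_rate = 0,
                   substitution_rate = 0, n_ancestral_genes = 6)
  sim <- simulate_locus_evolution(sp, seed = 70)
  expect_equal(nrow(sim$events), 0L)
  fams <- purrr::map(sim$loci, ~ sub("_[^_]+$", "", .x$genes$gene_id))
  expect_true(all(purrr::map_lgl(fams, ~ identical(.x, fams[[1]]))))
  # with zero substitution rate the CDS are identical across lineages
  cds <- purrr::map(sim$loci, ~ cds_table(.x)$seq)
  expect_identical(cds[["3DS"]], cds[["Os1"]])
})

test_that("a fixed seed reproduces the simulation byte for byte", {
  sp <- sim_params(n_ancestral_genes = 5, insertion_rate = 0.2,
                   pseudogenization_rate = 0.05)
  a <- simulate_locus_evolution(sp, seed = 71)
  b <- simulate_locus_evolution(sp, seed = 71)
  expect_identical(purrr::map_chr(a$loci, "seq"), purrr::map_chr(b$loci, "seq"))
  expect_identical(a$events, b$events)
})

test_that("logged insertion counts follow the Poisson expectation", {
  # Brachypodium branch: duration 35 My at rate 0.3 -> mean 10.5
  sp <- sim_params(n_ancestral_genes = 2, insertion_rate = 0.3,
                   acceleration = 1, substitution_rate = 0,
                   gene_length_range = c(300L, 306L), intergenic_mean = 50)
  counts <- purrr::map_int(1:120, function(s) {
    sim <- simulate_locus_evolution(sp, seed = 1000L + s)
    sum(sim$events$kind == "insert" & sim$events$lineage == "Bd")
  })
  lambda <- 0.3 * 35
  se <- sqrt(lambda / length(counts))
  expect_lt(abs(mean(counts) - lambda), 3 * se)
})

test_that("runaway rates are refused before the locus is built", {
  sp <- sim_params(insertion_rate = 400)
  expect_error(simulate_locus_evolution(sp, seed = 72), "10000")
})

test_that("event times stay within the tree depth and ids resolve", {
  sp <- sim_params(n_ancestral_genes = 5, insertion_rate = 0.3,
                   tandem_dup_rate = 0.02, pseudogenization_rate = 0.05)
  sim <- simulate_locus_evolution(sp, seed = 73)
  expect_true(all(sim$events$time >= 0 & sim$events$time <= 35))
  surviving <- setdiff(sim$events$gene_id,
                       sim$events$gene_id[sim$events$kind == "delete"])
  expect_true(all(surviving %in% sim$truth$base_id))
})

test_that("mechanism attribution recovers logged mechanisms on simulations", {
  # a short stem keeps most gene-pseudogene pairs one-sided, so the intact
  # partner is available as the comparison reference
  sp <- sim_params(n_ancestral_genes = 8, insertion_rate = 0,
                   pseudogenization_rate = 0.4, substitution_rate = 5e-4,
                   t_brachy_split = 6, intergenic_mean = 300)
  total <- 0L
  correct <- 0L
  for (s in 1:10) {
    sim <- simulate_locus_evolution(sp, seed = 200L + s)
    # wheat-lineage pseudogenes whose partner stayed intact
    tr <- sim$truth
    ps <- dplyr::filter(tr, genome_tag %in% c("3DS", "3B"),
                        status == "pseudogene")
    for (i in seq_len(nrow(ps))) {
      other_tag <- setdiff(c("3DS", "3B"), ps$genome_tag[i])
      partner <- dplyr::filter(tr, base_id == ps$base_id[i],
                               genome_tag == other_tag)
      if (!nrow(partner) || partner$status != "intact") next
      p_locus <- sim$loci[[ps$genome_tag[i]]]
      g_locus <- sim$loci[[other_tag]]
      pg <- p_locus$genes[match(ps$gene_id[i], p_locus$genes$gene_id), ]
      gg <- g_locus$genes[match(partner$gene_id, g_locus$genes$gene_id), ]
      flank <- 300L
      g_lo <- max(0L, gg$start - flank)
      g_hi <- min(nchar(g_locus$seq), gg$end + flank)
      p_lo <- max(0L, pg$start - flank)
      p_hi <- min(nchar(p_locus$seq), pg$end + flank)
      reps <- dplyr::filter(p_locus$repeats, start < p_hi, end > p_lo) |>
        dplyr::mutate(start = start - p_lo, end = end - p_lo)
      mech <- attribute_mechanism(
        substring(g_locus$seq, g_lo + 1, g_hi),
        c(gg$start - g_lo, gg$end - g_lo),
        substring(p_locus$seq, p_lo + 1, p_hi),
        reps)
      total <- total + 1L
      if (mech == ps$mechanism[i]) correct <- correct + 1L
    }
  }
  expect_gte(total, 10L)
  expect_gte(correct / total, 0.95)
})
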