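test_that("the fixture spec is internally consistent and validated", {
  fs <- fixture_spec()
  expect_equal(fs$n_collinear_all + fs$n_collinear_rice_wheat +
                 fs$n_shared_nc + fs$n_3DS_specific, fs$n_3DS)
  expect_equal(fs$n_collinear_all + fs$n_collinear_rice_wheat +
                 fs$n_shared_nc + fs$n_3B_specific + fs$n_3B_excluded,
               fs$n_3B)
  bad <- fs
  bad$n_3DS <- 40L
  expect_error(build_paper_fixture(bad), "violated.*n_3DS")
})

test_that("fixture gene counts match the declared count structure", {
  counts <- purrr::map_int(paper_fx$loci, ~ nrow(.x$genes))
  expect_equal(unname(counts[c("3DS", "3B", "Bd2", "Os1")]),
               c(39L, 38L, 22L, 21L))
  # exactly one annotation-excluded gene, on the 3B locus
  expect_equal(sum(paper_fx$loci[["3B"]]$genes$status == "excluded"), 1L)
  expect_equal(sum(paper_fx$loci[["3DS"]]$genes$status == "excluded"), 0L)
  # everything else is annotated intact: defects are discovered downstream
  expect_true(all(paper_fx$loci[["3B"]]$genes$status %in%
                    c("intact", "excluded")))
})

test_that("the generator is a pure function of (spec, seed)", {
  a <- build_paper_fixture(seed = 7)
  b <- build_paper_fixture(seed = 7)
  expect_identical(purrr::map_chr(a$loci, "seq"), purrr::map_chr(b$loci, "seq"))
  expect_identical(a$truth, b$truth)
  c2 <- build_paper_fixture(seed = 8)
  expect_false(identical(a$loci[["3DS"]]$seq, c2$loci[["3DS"]]$seq))
  expect_identical(dplyr::count(a$truth, genome_tag, category_truth),
                   dplyr::count(c2$truth, genome_tag, category_truth))
})

test_that("a degenerate spec with no pairs yields unrelated loci", {
  fs <- fixture_spec()
  fs$n_pairs <- 0L
  fs$n_collinear_all <- 0L
  fs$n_collinear_rice_wheat <- 0L
  fs$n_shared_nc <- 0L
  fs$n_3DS_specific <- 39L
  fs$n_3B_specific <- 37L
  fs$tandem_3DS <- 0L
  fs$tandem_3B <- 0L
  fx0 <- build_paper_fixture(fs, seed = 5)
  expect_equal(nrow(fx0$loci[["3DS"]]$genes), 39L)
  cds <- cds_table(fx0$loci)
  p <- analysis_params()
  pairs <- reciprocal_best_pairs(
    dplyr::filter(cds, genome_tag == "3DS"),
    dplyr::filter(cds, genome_tag == "3B", status != "excluded"), p)
  expect_equal(nrow(pairs), 0L)
})

test_that("every expressed gene has an EST with a >=100 bp exact core", {
  hits <- paper_expr$hits
  truth <- dplyr::filter(paper_fx$truth, genome_tag %in% c("3DS", "3B"))
  expressed <- truth$gene_id[truth$expressed]
  expect_setequal(intersect(unique(hits$gene_id), truth$gene_id), expressed)
  expect_true(all(hits$match_len >= 100))
  # decoys are present in the collection but never matched
  expect_true(all(c("est_decoy_mismatch", "est_decoy_short") %in%
                    paper_ests$id))
  expect_false(any(c("est_decoy_mismatch", "est_decoy_short") %in%
                     hits$est_id))
})

test_that("EST errors are confined to tails, never the exact core", {
  noisy <- generate_ests(paper_fx, seed = 9, error_rate = 0.2)
  cmp_hits <- score_expression(paper_cmp, noisy)
  expect_equal(cmp_hits$summary, paper_expr$summary)
})
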