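test_that("pool design fills plate-major with 384-well addressing", {
  d <- design_pools(sprintf("c%04d", 1:3827))
  expect_equal(nrow(d$wells), 3827L)
  expect_equal(10L * 16L * 24L - nrow(d$wells), 13L)

  one <- design_pools("c1")
  expect_equal(one$wells$plate, 1L)
  expect_equal(one$wells$row, "A")
  expect_equal(one$wells$col, 1L)

  expect_error(design_pools(sprintf("c%04d", 1:3841)), "capacity")
  expect_error(design_pools(c("a", "a")), "duplicated")
})

test_that("positive pool counts reflect the clone layout", {
  d <- design_pools(sprintf("c%04d", 1:3827))
  # single clone: exactly one positive pool per dimension
  pp <- positive_pools(d, "c0001")
  expect_equal(lengths(pp), c(plates = 1L, rows = 1L, cols = 1L))

  # two clones sharing a row: 2 plate + 1 row + 2 column positives
  w <- d$wells
  same_row <- w[w$row == "E" & w$col %in% c(3L, 7L) &
                  w$plate %in% c(2L, 4L), ]
  same_row <- same_row[same_row$plate != same_row$plate[1] |
                         same_row$col != same_row$col[1], ]
  pick <- c(w$clone[w$plate == 2 & w$row == "E" & w$col == 3],
            w$clone[w$plate == 4 & w$row == "E" & w$col == 7])
  pp2 <- positive_pools(d, pick)
  expect_equal(lengths(pp2), c(plates = 2L, rows = 1L, cols = 2L))
})

test_that("deconvolution is exact for single-clone markers and bounded for pairs", {
  d <- design_pools(sprintf("c%04d", 1:200), n_plates = 2L)
  for (cl in d$wells$clone) {
    res <- deconvolve(d, positive_pools(d, cl))
    expect_equal(res$clone, cl)
    expect_equal(res$ambiguity[1], 1L)
  }
  # two clones at (1,A,1) and (2,B,2): candidates equal exhaustive search
  d2 <- design_pools(sprintf("c%04d", 1:3827))
  w <- d2$wells
  pick <- c(w$clone[w$plate == 1 & w$row == "A" & w$col == 1],
            w$clone[w$plate == 2 & w$row == "B" & w$col == 2])
  pp <- positive_pools(d2, pick)
  res <- deconvolve(d2, pp)
  manual <- w[w$plate %in% pp$plates & w$row %in% pp$rows &
                w$col %in% pp$cols, ]
  expect_setequal(res$clone, manual$clone)
  expect_true(all(pick %in% res$clone))
  expect_equal(unique(res$ambiguity), nrow(manual))

  # an empty dimension is a no-call
  nc <- deconvolve(d2, list(plates = 1L, rows = character(), cols = 1L))
  expect_equal(nrow(nc), 0L)
  expect_true(attr(nc, "no_call"))
})

test_that("true clones are always among deconvolution candidates", {
  d <- design_pools(sprintf("c%04d", 1:3827))
  set.seed(80)
  for (i in 1:150) {
    k <- sample(1:4, 1)
    picked <- sample(d$wells$clone, k)
    res <- deconvolve(d, positive_pools(d, picked))
    expect_true(all(picked %in% res$clone))
    expect_lte(nrow(res), k^3)
  }
})

test_that("contig overlaps are inferred from cross-contig markers", {
  pf <- build_pool_fixture(seed = 81)
  ov <- infer_contig_overlaps(pf$truth, pf$clone_contigs)
  expect_equal(nrow(ov), 3L)
  expect_equal(max(ov$support), 3L)
  # screening + deconvolution recovers the truth for every marker
  for (mk in names(pf$screen)) {
    res <- deconvolve(pf$design, pf$screen[[mk]], mk)
    expect_true(all(pf$truth$clone[pf$truth$marker_id == mk] %in% res$clone))
  }

  within <- tibble::tibble(marker_id = "m", clone = c("a", "b"))
  cc <- tibble::tibble(clone = c("a", "b"), contig = "ctg1")
  expect_equal(nrow(infer_contig_overlaps(within, cc)), 0L)

  tri <- tibble::tibble(marker_id = "m", clone = c("a", "b", "c"))
  cc3 <- tibble::tibble(clone = c("a", "b", "c"),
                        contig = c("c1", "c2", "c3"))
  ov3 <- infer_contig_overlaps(tri, cc3)
  expect_equal(nrow(ov3), 3L)
  expect_true(all(ov3$unusual))
})
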