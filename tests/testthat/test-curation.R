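# a locus fragmented into scaffolds with bridging contigs spanning the gaps
make_fragmented <- function(seed, n = 12000) {
  set.seed(seed)
  orig <- rand_seq(n)
  list(
    orig = orig,
    scaffolds = tibble::tibble(
      id = c("s2", "s1", "s3"),
      seq = c(substring(orig, 4501, 8000), substring(orig, 1, 4000),
              substring(orig, 8601, n))),
    contigs = tibble::tibble(
      id = c("c1", "c2"),
      seq = c(substring(orig, 3801, 4700), substring(orig, 7801, 8800)))
  )
}

test_that("end matches honour the 99% / 100 bp thresholds", {
  p <- analysis_params()
  set.seed(90)
  ctg <- rand_seq(800)
  scf_exact <- paste0(rand_seq(1500), substring(ctg, 1, 150))
  em <- find_end_matches(tibble::tibble(id = "s", seq = scf_exact),
                         tibble::tibble(id = "c", seq = ctg), p)
  expect_true(any(em$end == "right" & em$contig_end == "left"))

  # 98.5% identity over 200 bp: rejected
  tail200 <- substring(ctg, 1, 200)
  for (i in c(30, 90, 170)) {
    substr(tail200, i, i) <- setdiff(c("A", "C", "G", "T"),
                                     substr(tail200, i, i))[1]
  }
  em2 <- find_end_matches(tibble::tibble(id = "s",
                                         seq = paste0(rand_seq(1500), tail200)),
                          tibble::tibble(id = "c", seq = ctg), p)
  expect_equal(nrow(em2), 0L)

  # exact but only 90 bp: rejected
  em3 <- find_end_matches(
    tibble::tibble(id = "s", seq = paste0(rand_seq(1500),
                                          substring(ctg, 1, 90))),
    tibble::tibble(id = "c", seq = ctg), p)
  expect_equal(nrow(em3), 0L)
})

test_that("iterated merging reconstructs the original locus byte-exactly", {
  fr <- make_fragmented(91)
  res <- curate_assembly(fr$scaffolds, fr$contigs, end_window = 800)
  expect_equal(nrow(res$scaffolds), 1L)
  expect_identical(res$scaffolds$seq[1], fr$orig)
  # conservation: merged length = sum of scaffolds + inserted interiors
  interiors <- sum(nchar(fr$contigs$seq)) - 4 * 200  # two 200 bp overlaps each
  expect_equal(nchar(res$scaffolds$seq[1]),
               sum(nchar(fr$scaffolds$seq)) + interiors)
})

test_that("merging is idempotent and independent of scaffold order", {
  fr <- make_fragmented(92)
  res1 <- curate_assembly(fr$scaffolds, fr$contigs, end_window = 800)
  res_again <- curate_assembly(res1$scaffolds, fr$contigs, end_window = 800)
  expect_identical(res_again$scaffolds$seq, res1$scaffolds$seq)
  perm <- fr$scaffolds[c(3, 1, 2), ]
  res2 <- curate_assembly(perm, fr$contigs, end_window = 800)
  expect_identical(sort(res2$scaffolds$seq), sort(res1$scaffolds$seq))
})

test_that("no matches means no change; three ends on one contig conflict", {
  p <- analysis_params()
  set.seed(93)
  scf <- tibble::tibble(id = c("a", "b"),
                        seq = c(rand_seq(1500), rand_seq(1500)))
  ctg <- tibble::tibble(id = "c", seq = rand_seq(600))
  res <- curate_assembly(scf, ctg, end_window = 600)
  expect_identical(res$scaffolds$seq, scf$seq)

  # three scaffold ends matching one contig: refuse and log
  core <- rand_seq(900)
  scf3 <- tibble::tibble(
    id = c("x", "y", "z"),
    seq = c(paste0(rand_seq(1200), substring(core, 1, 150)),
            paste0(substring(core, 751, 900), rand_seq(1200)),
            paste0(rand_seq(1200), substring(core, 1, 150))))
  em <- find_end_matches(scf3, tibble::tibble(id = "c", seq = core), p,
                         end_window = 600)
  res3 <- merge_scaffolds(scf3, tibble::tibble(id = "c", seq = core), em)
  expect_false(res3$merged)
  expect_true(any(res3$log$action == "conflict"))
})

test_that("repeat-flagged ends are screened and block unsupported merges", {
  p <- analysis_params()
  set.seed(94)
  te <- rand_seq(120)
  te_div <- te
  for (i in seq(5, 115, by = 33)) {  # ~97% identity copy
    substr(te_div, i, i) <- setdiff(c("A", "C", "G", "T"),
                                    substr(te_div, i, i))[1]
  }
  scaffolds <- tibble::tibble(
    id = c("risky", "clean"),
    seq = c(paste0(rand_seq(1000), te_div), rand_seq(1100)))
  flags <- screen_end_repeats(scaffolds, tibble::tibble(id = "te", seq = te), p)
  expect_equal(nrow(flags), 4L)  # two ends per scaffold
  expect_true(flags$flagged[flags$scaffold_id == "risky" &
                              flags$end == "right"])
  expect_false(any(flags$flagged[flags$scaffold_id == "clean"]))

  # 33 scaffolds -> 66 screened ends
  set.seed(95)
  many <- tibble::tibble(id = sprintf("s%02d", 1:33),
                         seq = replicate(33, rand_seq(400)))
  expect_equal(nrow(screen_end_repeats(many,
                                       tibble::tibble(id = "te", seq = te),
                                       p, end_window = 400)), 66L)
})
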