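test_that("window arithmetic matches the hand-derived oracles", {
  plus <- gene_annotation("gp", "chr1", 1000L, 9000L, "+")
  w <- build_windows(plus, "tss")
  expect_equal(c(w$start, w$end), c(970L, 1300L))
  expect_equal(c(build_windows(plus, "body")$start,
                 build_windows(plus, "body")$end), c(1300L, 9000L))
  expect_equal(c(build_windows(plus, "pre_term")$start,
                 build_windows(plus, "pre_term")$end), c(7000L, 9000L))
  expect_equal(c(build_windows(plus, "term")$start,
                 build_windows(plus, "term")$end), c(9000L, 11000L))

  # mirror arithmetic: - strand gene with internal end = 5000 (TSS = 4999)
  minus <- gene_annotation("gm", "chr1", 3000L, 5000L, "-")
  wm <- build_windows(minus, "tss")
  expect_equal(c(wm$start, wm$end), c(4700L, 5030L))
  expect_equal(c(build_windows(minus, "term")$start,
                 build_windows(minus, "term")$end), c(1000L, 3000L))

  short <- gene_annotation("gs", "chr1", 100L, 300L, "+")
  ws <- build_windows(short, "body")
  expect_false(ws$valid)
  expect_equal(ws$reason, "short_gene")
})

test_that("windows are clipped to chromosome bounds and flagged", {
  edge <- gene_annotation("ge", "chr1", 500L, 3000L, "-",
                          seqlengths = c(chr1 = 4000L))
  term <- build_windows(edge, "term")  # wants [-1500, 500)
  expect_true(term$clipped)
  expect_equal(term$start, 0L)
  plus_edge <- gene_annotation("gf", "chr1", 1000L, 3500L, "+",
                               seqlengths = c(chr1 = 4000L))
  t2 <- build_windows(plus_edge, "term")  # wants [3500, 5500), chrom ends 4000
  expect_true(t2$clipped)
  expect_equal(t2$end, 4000L)
})

test_that("pausing index equals TSS mean over body mean with NA reasons", {
  ann <- gene_annotation("g", "chr1", 5000L, 10000L, "+")
  trk <- constructed_gene_track(ann, tss_level = 10, body_level = 2,
                                tail_level = 0)
  pi_tab <- pausing_index(trk, ann)
  expect_equal(pi_tab$pausing_index, 5)

  unif <- uniform_track("chr1", 0L, 15000L, 3)
  expect_equal(pausing_index(unif, ann)$pausing_index, 1)

  tss_only <- coverage_track(data.frame(chrom = "chr1", start = 4970L,
                                        end = 5300L, value = 7))
  z <- pausing_index(tss_only, ann)
  expect_true(is.na(z$pausing_index))
  expect_equal(z$reason, "zero_denominator")
})

test_that("readthrough index captures post-TES continuation on either strand", {
  ann <- gene_annotation("g", "chr1", 5000L, 10000L, "+")
  unif <- uniform_track("chr1", 0L, 15000L, 2)
  expect_equal(readthrough_index(unif, ann)$readthrough_index, 1)

  stops <- uniform_track("chr1", 4970L, 10000L, 2)  # signal ends at the TES
  expect_equal(readthrough_index(stops, ann)$readthrough_index, 0)

  tail_only <- coverage_track(data.frame(chrom = "chr1", start = 10000L,
                                         end = 12000L, value = 1))
  expect_true(is.na(readthrough_index(tail_only, ann)$readthrough_index))

  half <- constructed_gene_track(ann, tss_level = 0, body_level = 4,
                                 tail_level = 1)
  expect_equal(readthrough_index(half, ann)$readthrough_index, 0.25)

  # sense mode picks each gene's own strand from a stranded pair
  minus <- gene_annotation("gm", "chr1", 20000L, 26000L, "-")
  both <- rbind(ann, minus)
  class(both) <- class(ann)
  tr_plus <- constructed_gene_track(ann, 0, 4, 2)
  tr_minus <- constructed_gene_track(minus, 0, 4, 1)
  ri <- readthrough_index(list(plus = tr_plus, minus = tr_minus), both,
                          mode = "sense")
  expect_equal(ri$readthrough_index, c(0.5, 0.25))
  fwd <- readthrough_index(list(plus = tr_plus, minus = tr_minus), both,
                           mode = "forward")
  expect_equal(fwd$readthrough_index[1], 0.5)
  expect_true(is.na(fwd$readthrough_index[2]))  # no + strand signal there
})

test_that("elongation index divides TT by pSer2 body means", {
  ann <- gene_annotation("g", "chr1", 5000L, 10000L, "+")
  tt <- uniform_track("chr1", 0L, 12000L, 6)
  ps <- uniform_track("chr1", 0L, 12000L, 3)
  expect_equal(elongation_index(tt, ps, ann)$elongation_index, 2)
  expect_equal(elongation_index(tt, tt, ann)$elongation_index, 1)
  empty <- uniform_track("chr1", 0L, 100L, 1)  # zero over the body
  expect_true(is.na(elongation_index(tt, empty, ann)$elongation_index))
})

test_that("indices are invariant to track rescaling and strand mirroring", {
  ann <- gene_annotation("g", "chr1", 5000L, 10000L, "+")
  trk <- constructed_gene_track(ann, 8, 2, 1)
  a <- pausing_index(trk, ann)$pausing_index
  b <- pausing_index(scale_track(trk, 13.7), ann)$pausing_index
  expect_equal(a, b, tolerance = 1e-12)

  # mirror the gene and its track through coordinate M
  M <- 20000L
  mirrored_ann <- gene_annotation("g", "chr1", M - 10000L, M - 5000L, "-")
  mirrored <- constructed_gene_track(mirrored_ann, 8, 2, 1)
  expect_equal(pausing_index(mirrored, mirrored_ann)$pausing_index, a)
  expect_equal(readthrough_index(mirrored, mirrored_ann)$readthrough_index,
               readthrough_index(trk, ann)$readthrough_index)
})

test_that("metagene profiles are flat on uniform tracks and reverse - strand rows", {
  ann <- toy_annotation()[1:2, ]
  class(ann) <- c("gene_annotation", "data.frame")
  unif <- coverage_track(list(chr1 = S4Vectors::Rle(4, 60000L)))
  mp <- metagene_profile(unif, ann, upstream = 1000L, downstream = 1000L,
                         bin = 100L)
  expect_true(all(mp$matrix == 4))
  expect_equal(unname(mp$profile), rep(4, 20))

  # bump just downstream of the minus gene TSS must land in the first
  # downstream bin after orientation flipping
  minus <- ann[2, ]
  class(minus) <- class(ann)
  bump_start <- tss(minus) - 99L
  bump <- coverage_track(data.frame(chrom = "chr1", start = bump_start,
                                    end = bump_start + 100L, value = 9))
  mp2 <- metagene_profile(bump, minus, upstream = 1000L, downstream = 1000L,
                          bin = 100L)
  expect_equal(which(mp2$matrix[1, ] > 0), 11L)
  expect_equal(mp2$offset[11], 0L)

  expect_error(metagene_profile(unif, ann[0, ], 1000L, 1000L, 100L), "empty")
  expect_error(metagene_profile(unif, ann, 1000L, 1000L, 300L), "divide")
})
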