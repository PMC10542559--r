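test_that("IBD files round-trip, gzipped or plain, and malformed rows error", {
  seg <- dplyr::bind_rows(
    make_segment("s1", 1, "s2", 2, start_bp = 1e6, end_bp = 4e6, length_cm = 3),
    make_segment("s3", 2, "s4", 1, start_bp = 2e6, end_bp = 9e6, length_cm = 7)
  )
  plain <- withr::local_tempfile(fileext = ".ibd")
  gz <- withr::local_tempfile(fileext = ".ibd.gz")
  write_ibd(seg, plain)
  write_ibd(seg, gz)
  expect_equal(read_ibd(plain), seg)
  expect_equal(read_ibd(gz), seg)

  bad <- make_segment(hap1 = 3)
  f <- withr::local_tempfile(); write_ibd(bad, f)
  expect_error(read_ibd(f), "haplotype indices")
  bad <- make_segment(start_bp = 5e6, end_bp = 5e6)
  write_ibd(bad, f)
  expect_error(read_ibd(f), "start_bp < end_bp")
  bad <- make_segment(length_cm = 0)
  write_ibd(bad, f)
  expect_error(read_ibd(f), "positive")
  bad <- make_segment(id1 = "s1", id2 = "s1")
  write_ibd(bad, f)
  expect_error(read_ibd(f), "within-individual")
})

test_that("diploid-male deduplication keeps only male haplotype 1", {
  sexes <- tibble::tibble(id = c("m1", "m2", "f1", "f2"),
                          sex = c("M", "M", "F", "F"))
  # a male-male pair reported 4 ways by diploid coding
  mm <- dplyr::bind_rows(lapply(1:2, function(h1)
    lapply(1:2, function(h2) make_segment("m1", h1, "m2", h2))))
  out <- dedup_diploid_males(mm, sexes)
  expect_equal(nrow(out), 1L)
  expect_equal(c(out$hap1, out$hap2), c(1L, 1L))
  # female-female pairs untouched on every haplotype combination
  ff <- dplyr::bind_rows(lapply(1:2, function(h1)
    lapply(1:2, function(h2) make_segment("f1", h1, "f2", h2))))
  expect_equal(nrow(dedup_diploid_males(ff, sexes)), 4L)
  # male hap 1 with female hap 2 is kept
  mf <- make_segment("m1", 1, "f1", 2)
  expect_equal(nrow(dedup_diploid_males(mf, sexes)), 1L)
  # idempotent
  once <- dedup_diploid_males(mm, sexes)
  expect_equal(dedup_diploid_males(once, sexes), once)
  expect_error(dedup_diploid_males(make_segment("zz", 1, "m1", 1), sexes),
               "missing from sex table")
})

test_that("sex balancing removes the right number, reproducibly", {
  # the White-British-sized case: 91,532 females vs 75,298 males
  sexes <- tibble::tibble(
    id = sprintf("s%06d", seq_len(91532 + 75298)),
    sex = rep(c("F", "M"), c(91532, 75298))
  )
  bal <- balance_sexes(sexes, seed = 9)
  expect_length(attr(bal, "removed"), 16234L)
  expect_equal(sum(bal$sex == "F"), sum(bal$sex == "M"))
  # balanced haplotype pool is 2/3 female-borne
  nf <- sum(bal$sex == "F"); nm <- sum(bal$sex == "M")
  expect_equal(2 * nf / (2 * nf + nm), 2 / 3)
  # determinism and dependence on seed
  expect_identical(attr(balance_sexes(sexes, seed = 9), "removed"),
                   attr(bal, "removed"))
  expect_false(identical(attr(balance_sexes(sexes, seed = 10), "removed"),
                         attr(bal, "removed")))
  # already balanced: nothing removed
  even <- tibble::tibble(id = c("a", "b"), sex = c("F", "M"))
  expect_length(attr(balance_sexes(even, seed = 1), "removed"), 0L)
  expect_error(balance_sexes(tibble::tibble(id = "a", sex = "F"), 1),
               "both sexes")
})

test_that("X haplotype-pair count matches brute-force enumeration", {
  expect_equal(npairs_x(2, 3), 19)
  expect_equal(npairs_x(1, 1), 2)
  expect_equal(npairs_x(0, 5), 10)
  for (nf in 0:8) {
    for (nm in 0:8) {
      expect_equal(npairs_x(nf, nm), enumerate_x_pairs(nf, nm))
    }
  }
  expect_error(npairs_x(-1, 2), "non-negative")
})

test_that("relative removal drops segments and decrements npairs by pair type", {
  sexes <- tibble::tibble(id = c("f1", "f2", "m1", "m2", "f3", "m3"),
                          sex = c("F", "F", "M", "M", "F", "M"))
  seg <- dplyr::bind_rows(
    make_segment("f1", 1, "f2", 2),
    make_segment("f2", 1, "f1", 1),   # same pair, reversed order
    make_segment("f1", 1, "m1", 1),
    make_segment("f3", 1, "m3", 1)
  )
  np0 <- npairs_x(3, 3)
  # one female-female pair: npairs drops by 4, both its segments go
  r <- remove_relatives(seg, tibble::tibble(id1 = "f1", id2 = "f2"), sexes, np0)
  expect_equal(np0 - r$npairs, 4)
  expect_equal(r$n_removed_segments, 2L)
  # male-female: 2; male-male: 1
  r <- remove_relatives(seg, tibble::tibble(id1 = "m1", id2 = "f1"), sexes, np0)
  expect_equal(np0 - r$npairs, 2)
  r <- remove_relatives(seg, tibble::tibble(id1 = "m1", id2 = "m2"), sexes, np0)
  expect_equal(np0 - r$npairs, 1)
  # several pairs accumulate; duplicates (either order) are an error
  r <- remove_relatives(seg, tibble::tibble(id1 = c("f1", "m1"),
                                            id2 = c("f2", "m2")), sexes, np0)
  expect_equal(np0 - r$npairs, 5)
  expect_error(remove_relatives(seg, tibble::tibble(id1 = c("f1", "f2"),
                                                    id2 = c("f2", "f1")),
                                sexes, np0),
               "more than once")
})

test_that("equal-cM splitting relabels, splits at boundaries, conserves length", {
  gmap <- toy_map(len_cm = 120)   # uniform 1 cM/Mb
  # strictly inside piece 3 (cM 40..60)
  inside <- make_segment(start_bp = 45e6, end_bp = 50e6, length_cm = 5)
  out <- split_into_pieces(inside, gmap, 6)
  expect_equal(nrow(out), 1L)
  expect_equal(out$chrom, "3")
  expect_equal(out$length_cm, 5, tolerance = 1e-9)
  # spanning the 60 cM boundary: two subsegments conserving total length
  cross <- make_segment(start_bp = 55e6, end_bp = 70e6, length_cm = 15)
  out <- split_into_pieces(cross, gmap, 6)
  expect_equal(nrow(out), 2L)
  expect_equal(out$chrom, c("3", "4"))
  expect_equal(sum(out$length_cm), 15, tolerance = 1e-6)
  expect_equal(out$start_bp[2], out$end_bp[1])
  # K = 1 keeps everything, relabelled "1"
  out <- split_into_pieces(cross, gmap, 1)
  expect_equal(nrow(out), 1L)
  expect_equal(out$chrom, "1")
  # random segments: total cM conserved to 1e-6
  withr::with_seed(17, {
    a <- runif(50, 1, 110e6); b <- a + runif(50, 1e5, 9e6)
    segs <- make_segment(id1 = sprintf("a%d", 1:50), id2 = sprintf("b%d", 1:50),
                         start_bp = a, end_bp = b,
                         length_cm = (b - a) / 1e6)
    out <- split_into_pieces(segs, gmap, 6)
    expect_equal(sum(out$length_cm), sum(segs$length_cm), tolerance = 1e-6)
    # every subsegment lies within its labelled piece (up to bp rounding)
    cm_lo <- interpolate_cm(gmap, out$start_bp)
    cm_hi <- interpolate_cm(gmap, out$end_bp)
    p <- as.integer(out$chrom)
    tol <- 1e-3
    expect_true(all(cm_lo >= 20 * (p - 1) - tol & cm_hi <= 20 * p + tol))
  })
  expect_error(split_into_pieces(make_segment(start_bp = 1, end_bp = 130e6),
                                 gmap, 6), "outside")
})
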