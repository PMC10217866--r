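test_that("hit BED is BED6 with a track header and round-trips", {
  hits <- tibble::tibble(chrom = "chr9", start = 100L, end = 106L,
                         strand = "+", motif_id = "TGCCGC")
  out <- withr::local_tempfile(fileext = ".bed")
  write_hit_bed(hits, "ZFBS", out)
  lines <- readLines(out)
  expect_match(lines[1], "^track ")
  expect_equal(lines[2], "chr9\t100\t106\tTGCCGC\t0\t+")
  expect_equal(length(lines), nrow(hits) + 1L)

  back <- read_bed(out)
  expect_equal(back$start, hits$start)
  expect_equal(back$end, hits$end)
  expect_equal(back$strand, hits$strand)

  # empty hit list: header-only file
  empty_out <- withr::local_tempfile(fileext = ".bed")
  write_hit_bed(hits[0, ], "ZFBS", empty_out)
  expect_equal(length(readLines(empty_out)), 1L)
})

test_that("bed writer round-trips random hit sets exactly", {
  set.seed(13)
  for (i in 1:10) {
    s <- rand_dna(800)
    ms <- add_complements(motif_set(rand_word(4)))
    hits <- scan_motifs(tibble::tibble(chrom = "cR", sequence = s), ms)
    out <- withr::local_tempfile(fileext = ".bed")
    write_hit_bed(hits, "t", out)
    back <- read_bed(out)
    expect_equal(nrow(back), nrow(hits))
    if (nrow(hits) > 0L) {
      expect_equal(back$start, hits$start)
      expect_equal(back$end, hits$end)
      expect_equal(back$strand, hits$strand)
      expect_true(all(back$start >= 0 & back$start < back$end &
                        back$end <= 800))
    }
  }
})

test_that("wiggle output is 1-based fixedStep and round-trips", {
  h <- toy_hits(c(0, 400, 840))
  d <- window_counts(h, 2000L, 850L, 850L)
  out <- withr::local_tempfile(fileext = ".wig")
  write_density_wig(d, out)
  lines <- readLines(out)
  expect_match(lines[2], "fixedStep chrom=chrT start=1 step=850 span=850")
  expect_equal(lines[3], "3")

  back <- read_density_wig(out)
  full <- tibble::as_tibble(d)
  expect_equal(back, full[full$count > 0, ], ignore_attr = TRUE)

  # all-zero track with zero suppression: no value blocks
  z <- window_counts(toy_hits(0), 2000L, 850L, 850L)
  zout <- withr::local_tempfile(fileext = ".wig")
  write_density_wig(z, zout)
  expect_equal(length(readLines(zout)), 1L)

  # zero runs split the track into several blocks
  h2 <- toy_hits(c(0, 100, 5000, 5100))
  d2 <- window_counts(h2, 7000L, 850L, 425L)
  out2 <- withr::local_tempfile(fileext = ".wig")
  write_density_wig(d2, out2)
  expect_gte(sum(grepl("^fixedStep", readLines(out2))), 2L)
  expect_equal(read_density_wig(out2),
               tibble::as_tibble(d2)[d2$count > 0, ], ignore_attr = TRUE)
})

test_that("peak BED carries class:count names and count scores", {
  p <- call_peaks(toy_hits(c(0, 100, 200)), 850)
  out <- withr::local_tempfile(fileext = ".bed")
  write_peak_bed(p, out)
  expect_equal(readLines(out)[2], "chrT\t0\t206\trobust:3\t3")

  w <- call_peaks(toy_hits(c(0, 500)), 850)
  wout <- withr::local_tempfile(fileext = ".bed")
  write_peak_bed(w, wout)
  expect_match(readLines(wout)[2], "weak:2\t2$")

  shuffled <- p[c(1), ]
  two <- call_peaks(toy_hits(c(0, 100, 3000, 3100)), 850)
  disordered <- two[c(2, 1), ]
  expect_error(write_peak_bed(disordered, withr::local_tempfile()),
               class = "icrscan_state_error")
})

test_that("the track bundle emits exactly three custom tracks", {
  h <- toy_hits(c(0, 100, 200))
  hz <- toy_hits(c(10, 50))
  d <- window_counts(h, 2000L, 850L, 85L)
  p <- call_peaks(h, 850L)
  dir <- withr::local_tempdir()
  manifest <- bundle_tracks(hz, h, d, dir, peaks = p)
  expect_equal(nrow(manifest), 3L)
  expect_true(all(file.exists(manifest$path)))
  mlines <- readLines(attr(manifest, "manifest"))
  expect_true("n_tracks=3" %in% mlines)
  # peak BED is written alongside as derived output
  expect_true(file.exists(file.path(dir, "candidate_icr_peaks.bed")))
  expect_error(bundle_tracks(NULL, h, d, dir),
               class = "icrscan_input_error", regexp = "hits_zfbs")
})

test_that("unwritable paths raise an I/O error", {
  h <- toy_hits(0)
  expect_error(write_hit_bed(h, "t", file.path(tempdir(), "no", "dir.bed")),
               class = "icrscan_io_error")
})
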