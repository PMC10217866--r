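test_that("window counts tally hit starts and suppress isolated sites", {
  h <- toy_hits(c(0, 400, 840))
  d <- window_counts(h, chrom_length = 2000L, window = 850L, step = 850L)
  expect_equal(d$count[d$window_start == 0], 3L)
  expect_equal(d$window_start, c(0L, 850L, 1700L))  # trailing partial window

  # a lone occurrence is background noise: every count is zero
  lone <- window_counts(toy_hits(0), 5000L, 850L, 850L)
  expect_true(all(lone$count == 0L))
  # no count of exactly 1 ever survives
  set.seed(12)
  for (i in 1:10) {
    h <- toy_hits(sample(0:4000, sample(1:12, 1)))
    d <- window_counts(h, 5000L, 850L, sample(c(85L, 425L, 850L), 1))
    expect_false(any(d$count == 1L))
    expect_true(all(d$count >= 0L))
    expect_true(all(diff(d$window_start) > 0))
  }

  empty <- window_counts(toy_hits(integer(0)), 1000L, 850L, 85L)
  expect_true(all(empty$count == 0L))
  expect_error(window_counts(toy_hits(0), 1000L, window = 100L, step = 200L),
               class = "icrscan_config_error")
})

test_that("peak calling chains clusters and classifies robust vs weak", {
  p <- call_peaks(toy_hits(c(0, 100, 200)), window = 850)
  expect_equal(nrow(p), 1L)
  expect_equal(c(p$start, p$end), c(0L, 206L))
  expect_equal(p$count, 3L)
  expect_equal(p$klass, "robust")

  # two far-apart singles: both isolated, no peaks
  expect_equal(nrow(call_peaks(toy_hits(c(0, 5000)), window = 850)), 0L)

  # a pair within the window is a weak peak: true or false positive
  weak <- call_peaks(toy_hits(c(0, 500)), window = 850)
  expect_equal(weak$count, 2L)
  expect_equal(weak$klass, "weak")
})

test_that("peak calling agrees with brute-force transitive clustering", {
  set.seed(31)
  for (i in 1:40) {
    n <- sample(0:15, 1)
    h <- toy_hits(sample(0:6000, n))
    w <- sample(c(100L, 400L, 850L), 1)
    got <- tidy(call_peaks(h, window = w))
    expect_equal(as.data.frame(got), as.data.frame(brute_peaks(h, w)),
                 info = paste("case", i))
  }
})

test_that("hits partition into peak members plus isolated sites", {
  set.seed(59)
  for (i in 1:15) {
    h <- toy_hits(sample(0:9000, sample(1:20, 1)))
    p <- call_peaks(h, window = 850)
    in_peaks <- sum(p$count)
    isolated <- sum(!h$start %in% unlist(lapply(p$hits, `[[`, "start")))
    expect_equal(in_peaks + isolated, nrow(h))
    # robust peaks admit an 850-base window holding at least two members
    for (j in seq_len(nrow(p))) {
      if (p$klass[j] != "robust") next
      starts <- p$hits[[j]]$start
      expect_true(any(diff(sort(starts)) <= 850))
    }
  }
})

test_that("suppression in window counts matches singleton clusters", {
  # a hit is isolated (shares no step-1 window with any other hit) iff it
  # forms a singleton cluster; window co-occupancy means start gap < window,
  # so test away from the exact-boundary gap == window
  set.seed(71)
  for (i in 1:15) {
    w <- 300L
    starts <- unique(sample(0:4000, sample(2:10, 1)))
    gaps_ok <- !any(abs(outer(starts, starts, "-")) == w)
    if (!gaps_ok) next
    h <- toy_hits(starts)
    p <- call_peaks(h, window = w)
    member <- unlist(lapply(p$hits, `[[`, "start"))
    for (s in starts) {
      shares <- any(abs(setdiff(starts, s) - s) < w)
      expect_equal(s %in% member, shares, info = paste("start", s))
    }
  }
})

test_that("growing the window merges clusters without losing members", {
  set.seed(83)
  for (i in 1:10) {
    h <- toy_hits(sample(0:8000, 12))
    w1 <- 200L; w2 <- 900L
    p1 <- call_peaks(h, window = w1)
    p2 <- call_peaks(h, window = w2)
    # cluster count (peaks + singletons) never increases
    n1 <- nrow(p1) + (nrow(h) - sum(p1$count))
    n2 <- nrow(p2) + (nrow(h) - sum(p2$count))
    expect_lte(n2, n1)
    # every small-window peak sits inside a large-window peak of >= count
    for (j in seq_len(nrow(p1))) {
      container <- which(p2$start <= p1$start[j] & p2$end >= p1$end[j])
      expect_length(container, 1L)
      expect_gte(p2$count[container], p1$count[j])
    }
  }
})

test_that("peak summaries partition counts and handle empties", {
  h <- toy_hits(c(0, 10, 20, 2000, 2100, 9000, 9100, 9200, 9300, 9400))
  p <- call_peaks(h, window = 850)
  s <- summarize_peaks(p)
  expect_equal(s$n_peaks, s$n_robust + s$n_weak)
  expect_equal(s$max_count, 5L)
  g <- glance(p)
  expect_equal(g$n_peaks, 3L)
  expect_equal(g$window, 850L)
  e <- summarize_peaks(call_peaks(toy_hits(integer(0))))
  expect_equal(e$n_peaks, 0L)
  td <- tidy(p)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("chrom", "start", "end", "count", "klass"))
})

test_that("density autoplot returns a ggplot with peak shading", {
  h <- toy_hits(c(0, 100, 200))
  d <- window_counts(h, 2000L, 850L, 85L)
  p <- call_peaks(h, 850L)
  gg <- autoplot(d, peaks = p)
  expect_s3_class(gg, "ggplot")
  expect_s3_class(plot_density(d), "ggplot")
})
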