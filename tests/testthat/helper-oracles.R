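# Independent brute-force oracles and small fixture generators. These are
# deliberately written without reusing the package's scanning/clustering
# code paths.

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

rand_word <- function(k) {
  paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
}

# Naive all-offsets exact search: substring comparison at every position.
naive_scan <- function(chrom, sequence, ms) {
  n <- nchar(sequence)
  rows <- list()
  for (j in seq_len(nrow(ms))) {
    w <- ms$word[j]
    k <- nchar(w)
    if (k > n) next
    starts1 <- 1:(n - k + 1)
    subs <- substring(sequence, starts1, starts1 + k - 1)
    at <- which(subs == w)
    if (length(at) == 0L) next
    rows[[length(rows) + 1L]] <- tibble::tibble(
      chrom = chrom, start = at - 1L, end = at - 1L + k,
      strand = if (ms$origin[j] == "complement") "-" else "+",
      motif_id = ms$id[j]
    )
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), strand = character(),
                          motif_id = character()))
  }
  dplyr::arrange(out, chrom, start, end, motif_id)
}

# Brute-force clustering: connected components of the graph joining any
# two hits whose starts differ by <= window (transitive closure by
# repeated sweeps, no sorting-based chaining).
brute_clusters <- function(starts, window) {
  n <- length(starts)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (abs(starts[i] - starts[j]) <= window &&
            comp[j] != comp[i]) {
          new <- min(comp[i], comp[j])
          comp[comp == comp[i] | comp == comp[j]] <- new
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  comp
}

brute_peaks <- function(hits, window, robust_min = 3L) {
  if (nrow(hits) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), count = integer(),
                          klass = character()))
  }
  out <- list()
  for (ch in unique(hits$chrom)) {
    h <- hits[hits$chrom == ch, ]
    comp <- brute_clusters(h$start, window)
    for (cc in unique(comp)) {
      member <- h[comp == cc, ]
      if (nrow(member) < 2L) next
      out[[length(out) + 1L]] <- tibble::tibble(
        chrom = ch, start = min(member$start), end = max(member$end),
        count = nrow(member),
        klass = if (nrow(member) >= robust_min) "robust" else "weak"
      )
    }
  }
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), count = integer(),
                          klass = character()))
  }
  dplyr::arrange(out, chrom, start)
}

# Brute-force overlap-merge oracle: pads both words into a common frame
# with placeholder dots and keeps frames where all doubly-covered
# positions agree and the overlap is long enough.
brute_overlaps <- function(z, m, min_overlap) {
  lz <- nchar(z); lm <- nchar(m)
  words <- character(0)
  for (off in -(lm - 1):(lz - 1)) {
    lo <- min(0, off); hi <- max(lz, off + lm)
    frame_z <- rep(".", hi - lo); frame_m <- rep(".", hi - lo)
    frame_z[(1 - lo):(lz - lo)] <- strsplit(z, "")[[1]]
    frame_m[(off + 1 - lo):(off + lm - lo)] <- strsplit(m, "")[[1]]
    both <- frame_z != "." & frame_m != "."
    if (sum(both) < min_overlap) next
    if (!all(frame_z[both] == frame_m[both])) next
    merged <- ifelse(frame_z != ".", frame_z, frame_m)
    words <- c(words, paste(merged, collapse = ""))
  }
  cg <- vapply(words, function(w) {
    length(gregexpr("(?=CG)", w, perl = TRUE)[[1]][
      gregexpr("(?=CG)", w, perl = TRUE)[[1]] > 0])
  }, integer(1))
  sort(unique(words[cg >= 2L]))
}

toy_hits <- function(starts, chrom = "chrT", k = 6L) {
  starts <- sort(as.integer(starts))
  tibble::tibble(chrom = chrom, start = starts, end = starts + k,
                 strand = "+", motif_id = "m")
}
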