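#' Simulate a chromosome with planted motif clusters and ground truth
#'
#' Generates an i.i.d. background sequence with the requested GC fraction,
#' overwrites it with planted copies of `motif` — clusters of `n` copies
#' spread over `span` bases, and isolated single sites — and then scrubs
#' the background: any chance occurrence of the motif or its reverse
#' complement outside the planted sites is resampled away, so the emitted
#' ground truth is exact rather than probabilistic. Planted elements are
#' pairwise separated by more than `separation` bases; when starts are not
#' given they are placed deterministically at equal spacing.
#'
#' @param length Chromosome length in bases.
#' @param gc Background GC fraction in `[0, 1]`.
#' @param clusters Tibble/data frame with columns `n` (copies, >= 2) and
#'   `span` (bases the copies spread over, at most `window`), optionally
#'   `start`. `NULL` for none.
#' @param isolated Integer vector of isolated-site starts, or a single
#'   count to auto-place (wrap a single explicit start in `I()`).
#'   `NULL`/`0` for none.
#' @param motif Planted DNA word (default the ZFP57 hexamer `TGCCGC`).
#' @param window Scan window the truth is calibrated to (default 850);
#'   cluster spans must not exceed it.
#' @param seed RNG seed (required; there is no hidden global randomness).
#' @param separation Minimum hull-to-hull gap between planted elements;
#'   defaults to `window + 1` so distinct elements never chain together.
#' @param chrom Chromosome name for the emitted record.
#' @return List with `genome` (single-row tibble: `chrom`, `sequence`,
#'   `length`) and `truth` (list: `clusters` tibble with `chrom`, `start`,
#'   `n`, `span` and list-column `sites` of planted starts; `isolated`
#'   tibble with `chrom`, `start`; plus `seed`, `gc`, `length`, `motif`,
#'   `window`).
#' @examples
#' sim <- simulate_genome(20000, clusters = data.frame(n = 3, span = 500),
#'                        isolated = 1, seed = 1)
#' @export
simulate_genome <- function(length, gc = 0.42, clusters = NULL,
                            isolated = NULL, motif = "TGCCGC",
                            window = 850L, seed,
                            separation = window + 1L,
                            chrom = "chrSim") {
  if (missing(seed) || !is_count(seed, 0L)) {
    stop_config("a non-negative integer seed is required")
  }
  if (!is_count(length, 1L)) stop_config("length must be a positive integer")
  if (!is.numeric(gc) || gc < 0 || gc > 1) {
    stop_config("gc must lie in [0, 1]")
  }
  motif <- toupper(motif)
  if (grepl("[^ACGT]", motif)) stop_alpha("motif must be over A/C/G/T")
  k <- nchar(motif)

  clusters <- normalize_clusters(clusters, window, k)
  n_iso <- if (is.null(isolated)) 0L
           else if (length(isolated) == 1L && is.null(names(isolated)) &&
                    isolated[1] >= 0 && !is_placed(isolated)) as.integer(isolated)
           else length(isolated)
  iso_starts <- if (!is.null(isolated) && is_placed(isolated)) {
    as.integer(isolated)
  } else NULL

  placed <- place_elements(length, clusters, n_iso, iso_starts, k,
                           separation)
  clusters <- placed$clusters
  iso_starts <- placed$isolated

  # planted element site positions
  site_tbl <- planted_sites(clusters, iso_starts, k)
  withr::with_seed(seed, {
    seq_chars <- sample(c("A", "T", "G", "C"), length, replace = TRUE,
                        prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
    mot_chars <- strsplit(motif, "")[[1]]
    for (s in site_tbl$start) {
      seq_chars[(s + 1L):(s + k)] <- mot_chars
    }
    seq_chars <- scrub_background(seq_chars, motif, site_tbl$start, gc)
  })
  sequence <- paste(seq_chars, collapse = "")

  truth <- list(
    clusters = if (nrow(clusters) > 0L) {
      tibble::tibble(chrom = chrom, start = clusters$start,
                     n = clusters$n, span = clusters$span,
                     sites = clusters$sites)
    } else {
      tibble::tibble(chrom = character(), start = integer(), n = integer(),
                     span = integer(), sites = list())
    },
    isolated = tibble::tibble(chrom = rep(chrom, length(iso_starts)),
                              start = iso_starts),
    seed = seed, gc = gc, length = as.integer(length), motif = motif,
    window = as.integer(window)
  )
  list(
    genome = tibble::tibble(chrom = chrom, sequence = sequence,
                            length = as.integer(length)),
    truth = truth
  )
}

is_placed <- function(x) length(x) > 1L || inherits(x, "AsIs")

normalize_clusters <- function(clusters, window, k) {
  if (is.null(clusters) || nrow(as.data.frame(clusters)) == 0L) {
    return(tibble::tibble(start = integer(), n = integer(),
                          span = integer(), sites = list()))
  }
  cl <- tibble::as_tibble(clusters)
  stopifnot(all(c("n", "span") %in% names(cl)))
  if (any(cl$n < 2L)) {
    stop_config("planted clusters need n >= 2 (plant size-1 as isolated)")
  }
  if (any(cl$span > window)) {
    stop_config("cluster span must not exceed the scan window")
  }
  # within-cluster copies must not abut: scrubbing needs a free base
  if (any(cl$span < (cl$n - 1L) * (k + 1L) + k)) {
    stop_config("cluster span too small for n non-adjacent motif copies")
  }
  if (!"start" %in% names(cl)) cl$start <- NA_integer_
  cl$sites <- vector("list", nrow(cl))
  cl
}

place_elements <- function(length, clusters, n_iso, iso_starts, k,
                           separation) {
  n_cl <- nrow(clusters)
  auto_iso <- is.null(iso_starts) && n_iso > 0L
  widths <- c(clusters$span, rep(k, if (auto_iso) n_iso else 0L))
  if (any(is.na(clusters$start)) || auto_iso) {
    n_el <- length(widths)
    need <- sum(widths) + (n_el + 1L) * separation
    if (n_el > 0L && need > length) {
      stop_config(sprintf(
        "infeasible packing: %d planted elements with separation %d need %d bases, chromosome has %d",
        n_el, separation, need, length))
    }
    gap <- (length - sum(widths)) %/% (n_el + 1L)
    pos <- integer(n_el)
    cur <- gap
    for (i in seq_len(n_el)) {
      pos[i] <- cur
      cur <- cur + widths[i] + gap
    }
    if (n_cl > 0L) {
      fill <- is.na(clusters$start)
      clusters$start[fill] <- pos[seq_len(n_cl)][fill]
    }
    if (auto_iso) iso_starts <- pos[n_cl + seq_len(n_iso)]
  }
  if (is.null(iso_starts)) iso_starts <- integer(0)
  # deterministic, evenly spread copies within each cluster
  if (n_cl > 0L) {
    clusters$sites <- purrr::map(seq_len(n_cl), function(i) {
      n <- clusters$n[i]
      clusters$start[i] +
        as.integer(round(seq(0, clusters$span[i] - k, length.out = n)))
    })
  }
  check_separation(clusters, iso_starts, k, separation, length)
  list(clusters = clusters, isolated = as.integer(iso_starts))
}

check_separation <- function(clusters, iso_starts, k, separation, length) {
  hulls <- rbind(
    if (nrow(clusters) > 0L)
      cbind(clusters$start, clusters$start + clusters$span),
    if (length(iso_starts) > 0L) cbind(iso_starts, iso_starts + k)
  )
  if (is.null(hulls) || nrow(hulls) < 1L) return(invisible(TRUE))
  if (any(hulls[, 1] < 0L) || any(hulls[, 2] > length)) {
    stop_config("planted element falls outside the chromosome")
  }
  if (nrow(hulls) > 1L) {
    hulls <- hulls[order(hulls[, 1]), , drop = FALSE]
    gaps <- hulls[-1, 1] - hulls[-nrow(hulls), 2]
    if (any(gaps < separation)) {
      stop_config("infeasible packing: planted elements closer than the required separation")
    }
  }
  invisible(TRUE)
}

planted_sites <- function(clusters, iso_starts, k) {
  starts <- c(unlist(clusters$sites, use.names = FALSE), iso_starts)
  tibble::tibble(start = as.integer(starts))
}

# Resample background bases until no occurrence of the motif or its
# reverse complement survives outside the planted sites. Planted bases
# are never touched.
scrub_background <- function(seq_chars, motif, planted_starts, gc,
                             max_iter = 100L) {
  k <- nchar(motif)
  protected <- logical(length(seq_chars))
  for (s in planted_starts) protected[(s + 1L):(s + k)] <- TRUE
  words <- unique(c(motif, reverse_complement(motif)))
  for (iter in seq_len(max_iter)) {
    seq_str <- paste(seq_chars, collapse = "")
    spurious <- integer(0)
    for (w in words) {
      occ <- gregexpr(paste0("(?=", w, ")"), seq_str, perl = TRUE)[[1]]
      occ <- occ[occ > 0]
      occ0 <- occ - 1L  # 0-based starts
      spurious <- c(spurious, setdiff(occ0, planted_starts))
    }
    spurious <- unique(spurious)
    if (length(spurious) == 0L) return(seq_chars)
    for (s in spurious) {
      idx <- (s + 1L):(s + k)
      free <- idx[!protected[idx]]
      if (length(free) == 0L) {
        stop_config("cannot scrub a motif occurrence made entirely of planted bases; increase within-cluster spacing")
      }
      seq_chars[free] <- sample(
        c("A", "T", "G", "C"), length(free), replace = TRUE,
        prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
    }
  }
  stop_config("background scrubbing did not converge")
}

#' Compare called peaks against planted ground truth
#'
#' A planted cluster is recovered when some peak's hull intersects the
#' cluster span and the peak's element count equals the planted copy
#' number. Peaks matching no planted cluster are false peaks; the report
#' also states whether every isolated planted site was suppressed (no
#' peak hull touches it).
#'
#' @param peaks An `icr_peaks` tibble from [call_peaks()].
#' @param truth The `truth` component of [simulate_genome()].
#' @param window Scan window used for calling (for the report echo).
#' @return List with `clusters` (per-cluster tibble adding `recovered`)
#'   and `summary` (one-row tibble: `n_planted`, `n_recovered`,
#'   `n_missed`, `recovery_pct`, `false_peaks`, `isolated_suppressed`).
#' @export
truth_compare <- function(peaks, truth, window = truth$window) {
  cl <- truth$clusters
  ptbl <- tibble::as_tibble(peaks)
  matched_peak <- logical(nrow(ptbl))
  recovered <- logical(nrow(cl))
  for (i in seq_len(nrow(cl))) {
    lo <- cl$start[i]
    hi <- cl$start[i] + cl$span[i]
    hit <- which(ptbl$chrom == cl$chrom[i] & ptbl$start < hi &
                   ptbl$end > lo & ptbl$count == cl$n[i])
    if (length(hit) > 0L) {
      recovered[i] <- TRUE
      matched_peak[hit] <- TRUE
    }
  }
  iso <- truth$isolated
  k <- nchar(truth$motif)
  iso_hit <- vapply(seq_len(nrow(iso)), function(i) {
    any(ptbl$chrom == iso$chrom[i] & ptbl$start < iso$start[i] + k &
          ptbl$end > iso$start[i])
  }, logical(1))
  summary <- tibble::tibble(
    n_planted = nrow(cl),
    n_recovered = sum(recovered),
    n_missed = sum(!recovered),
    recovery_pct = if (nrow(cl) > 0L) 100 * sum(recovered) / nrow(cl)
                   else NA_real_,
    false_peaks = sum(!matched_peak),
    isolated_suppressed = !any(iso_hit),
    window = as.integer(window)
  )
  cl$recovered <- recovered
  list(clusters = cl, summary = summary)
}

#' Write planted ground truth as a BED file
#'
#' One line per planted element (every cluster member site and every
#' isolated site), named `cluster<i>` or `isolated`.
#'
#' @param truth The `truth` component of [simulate_genome()].
#' @param out Output path.
#' @return `out`, invisibly.
#' @export
write_truth_bed <- function(truth, out) {
  k <- nchar(truth$motif)
  lines <- character(0)
  cl <- truth$clusters
  for (i in seq_len(nrow(cl))) {
    lines <- c(lines, sprintf("%s\t%d\t%d\tcluster%d\t%d\t+",
                              cl$chrom[i], cl$sites[[i]],
                              cl$sites[[i]] + k, i, cl$n[i]))
  }
  iso <- truth$isolated
  if (nrow(iso) > 0L) {
    lines <- c(lines, sprintf("%s\t%d\t%d\tisolated\t1\t+", iso$chrom,
                              iso$start, iso$start + k))
  }
  writeLines(lines, out)
  invisible(out)
}
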