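#' Sliding-window density of composite-element occurrences
#'
#' Counts, for every window `[w, w + window)` placed at multiples of
#' `step` along a chromosome, the number of hits whose start lies in the
#' window, then suppresses isolated occurrences: any window count of
#' exactly 1 is set to 0. This is the density signal in which peaks mark
#' candidate imprinting control regions; the suppression step is what
#' removes background noise from sporadic single sites. The trailing
#' partial window is included.
#'
#' @param hits Sorted, deduplicated hit tibble for one chromosome.
#' @param chrom_length Chromosome length in bases.
#' @param window Window size in bases; default 850, the scan width within
#'   which clustered elements mark an ICR.
#' @param step Window step in bases; `step > window` is a configuration
#'   error (gaps would drop hits from every window).
#' @return An `icr_density` tibble with columns `chrom`, `window_start`
#'   (0-based, multiples of `step`) and `count`; attributes `window`,
#'   `step` and `chrom_length`.
#' @export
window_counts <- function(hits, chrom_length, window = 850L, step = window) {
  if (!is_count(window, 1L)) stop_config("window must be a positive integer")
  if (!is_count(step, 1L) || step > window) {
    stop_config("step must satisfy 1 <= step <= window")
  }
  if (!is_count(chrom_length, 1L)) {
    stop_config("chrom_length must be a positive integer")
  }
  chrom <- if (nrow(hits) > 0L) hits$chrom[1] else NA_character_
  if (nrow(hits) > 0L && length(unique(hits$chrom)) > 1L) {
    stop_config("window_counts expects hits from a single chromosome")
  }
  starts <- seq.int(0L, by = as.integer(step),
                    length.out = ceiling(chrom_length / step))
  counts <- if (nrow(hits) == 0L) {
    integer(length(starts))
  } else {
    idx <- findInterval(hits$start, starts)
    base <- tabulate(idx, nbins = length(starts))
    if (step < window) {
      # window spans several steps: a hit at position p is counted by every
      # window start in (p - window, p]
      vapply(seq_along(starts), function(i) {
        w <- starts[i]
        sum(hits$start >= w & hits$start < w + window)
      }, integer(1))
    } else {
      base
    }
  }
  counts[counts == 1L] <- 0L
  out <- tibble::tibble(chrom = chrom, window_start = starts, count = counts)
  structure(out, class = c("icr_density", class(tibble::tibble())),
            window = as.integer(window), step = as.integer(step),
            chrom_length = as.integer(chrom_length))
}

#' Call candidate-ICR peaks from composite-element hits
#'
#' Chains hits into maximal clusters in which consecutive hit starts are
#' at most `window` bases apart, discards singleton clusters (isolated
#' occurrences never form peaks), and reports each surviving cluster as a
#' peak spanning the hull of its member hits. A peak encompassing
#' `robust_min` (default 3) or more elements is classified `robust` — the
#' candidate-ICR call; a peak covering exactly two is `weak` and may be a
#' true or a false positive.
#'
#' @param hits Sorted, deduplicated hit tibble (one or more chromosomes).
#' @param window Maximum start-to-start gap chaining two hits into one
#'   cluster; default 850 bases.
#' @param robust_min Minimum element count for a robust peak (default 3).
#' @return An `icr_peaks` tibble with columns `chrom`, `start`, `end`
#'   (hull of member hits, 0-based half-open), `count`, `klass`
#'   (`"robust"`/`"weak"`) and a list-column `hits` of member hits,
#'   sorted by `(chrom, start)`.
#' @examples
#' h <- tibble::tibble(chrom = "chrT", start = c(0L, 100L, 200L),
#'                     end = c(6L, 106L, 206L), strand = "+",
#'                     motif_id = "m")
#' call_peaks(h, window = 850)
#' @export
call_peaks <- function(hits, window = 850L, robust_min = 3L) {
  if (!is_count(window, 1L)) stop_config("window must be a positive integer")
  if (!is_count(robust_min, 2L)) {
    stop_config("robust_min must be an integer >= 2")
  }
  empty <- tibble::tibble(
    chrom = character(), start = integer(), end = integer(),
    count = integer(), klass = character(),
    hits = list()
  )
  if (nrow(hits) == 0L) {
    return(new_icr_peaks(empty, window, robust_min))
  }
  peaks <- hits |>
    dplyr::group_by(.data$chrom) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(cluster = cumsum(
      c(1L, as.integer(diff(.data$start) > window))
    )) |>
    dplyr::group_by(.data$chrom, .data$cluster) |>
    dplyr::summarise(
      hits = list(dplyr::pick("start", "end", "strand", "motif_id")),
      start = min(.data$start), end = max(.data$end),
      count = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$count >= 2L) |>
    dplyr::mutate(klass = dplyr::if_else(.data$count >= robust_min,
                                         "robust", "weak")) |>
    dplyr::select("chrom", "start", "end", "count", "klass", "hits") |>
    dplyr::arrange(.data$chrom, .data$start)
  new_icr_peaks(peaks, window, robust_min)
}

new_icr_peaks <- function(tbl, window, robust_min) {
  structure(tbl, class = c("icr_peaks", class(tibble::tibble())),
            window = as.integer(window), robust_min = as.integer(robust_min))
}

#' Summarise called peaks per chromosome
#'
#' @param peaks An `icr_peaks` tibble from [call_peaks()].
#' @return A tibble with one row per chromosome: `chrom`, `n_peaks`,
#'   `n_robust`, `n_weak`, `max_count`, `median_width`. An empty input
#'   yields a single all-zero row with `chrom = NA`.
#' @export
summarize_peaks <- function(peaks) {
  if (nrow(peaks) == 0L) {
    return(tibble::tibble(chrom = NA_character_, n_peaks = 0L,
                          n_robust = 0L, n_weak = 0L, max_count = 0L,
                          median_width = 0))
  }
  peaks |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(
      n_peaks = dplyr::n(),
      n_robust = sum(.data$klass == "robust"),
      n_weak = sum(.data$klass == "weak"),
      max_count = max(.data$count),
      median_width = stats::median(.data$end - .data$start),
      .groups = "drop"
    )
}

#' @method tidy icr_peaks
#' @export
tidy.icr_peaks <- function(x, ...) {
  tibble::tibble(chrom = x$chrom, start = x$start, end = x$end,
                 count = x$count, klass = x$klass)
}

#' @method glance icr_peaks
#' @export
glance.icr_peaks <- function(x, ...) {
  s <- summarize_peaks(x)
  tibble::tibble(
    n_peaks = sum(s$n_peaks), n_robust = sum(s$n_robust),
    n_weak = sum(s$n_weak),
    max_count = max(s$max_count),
    window = attr(x, "window"), robust_min = attr(x, "robust_min")
  )
}

#' Plot a composite-element density track
#'
#' Step plot of suppressed window counts along the chromosome, optionally
#' shading called peaks (robust and weak in different colours), mirroring
#' the genome-browser density view.
#'
#' @param object An `icr_density` tibble from [window_counts()].
#' @param peaks Optional `icr_peaks` tibble to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot icr_density
#' @export
autoplot.icr_density <- function(object, peaks = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object)) +
    ggplot2::geom_step(ggplot2::aes(x = .data$window_start,
                                    y = .data$count)) +
    ggplot2::labs(x = "position (bp)",
                  y = sprintf("elements per %d-bp window",
                              attr(object, "window")),
                  title = unique(object$chrom)) +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = tidy(peaks),
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf, fill = .data$klass),
      alpha = 0.2, inherit.aes = FALSE
    ) +
      ggplot2::scale_fill_manual(
        values = c(robust = "firebrick", weak = "steelblue"),
        name = "peak class"
      )
  }
  p
}

#' @rdname autoplot.icr_density
#' @param density An `icr_density` tibble.
#' @export
plot_density <- function(density, peaks = NULL) {
  autoplot.icr_density(density, peaks = peaks)
}
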