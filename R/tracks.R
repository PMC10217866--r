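# UCSC custom-track writers. BED is 0-based half-open and wiggle is
# 1-based (both per the UCSC formats); the conversion lives only here.

track_header <- function(name, description, type = NULL) {
  paste0(
    if (!is.null(type)) paste0("track type=", type, " ") else "track ",
    'name="', name, '" description="', description, '"'
  )
}

#' Write motif hits as a UCSC BED6 custom track
#'
#' One line per hit: `chrom start end motif_id 0 strand`, preceded by a
#' `track` header line.
#'
#' @param hits Sorted hit tibble from [scan_motifs()]/[dedupe_hits()].
#' @param track_name Track name for the header.
#' @param out Output path.
#' @param description Track description (defaults to the name).
#' @return `out`, invisibly.
#' @export
write_hit_bed <- function(hits, track_name, out,
                          description = track_name) {
  con <- open_out(out)
  on.exit(close(con))
  writeLines(track_header(track_name, description), con)
  if (nrow(hits) > 0L) {
    writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", hits$chrom, hits$start,
                       hits$end, hits$motif_id, hits$strand), con)
  }
  invisible(out)
}

#' Write a density track as a fixedStep wiggle file
#'
#' Emits `fixedStep chrom=<c> start=<s+1> step=<step> span=<step>` blocks
#' (wiggle positions are 1-based) followed by one count per line. With
#' `suppress_zeros` (the default) runs of zero counts are omitted and the
#' track is split into multiple fixedStep blocks, which keeps genome-scale
#' files small.
#'
#' @param track An `icr_density` tibble from [window_counts()].
#' @param out Output path.
#' @param track_name Track name for the header.
#' @param suppress_zeros Omit zero-count windows.
#' @return `out`, invisibly.
#' @export
write_density_wig <- function(track, out,
                              track_name = "ZFBS_morph_density",
                              suppress_zeros = TRUE) {
  step <- attr(track, "step")
  con <- open_out(out)
  on.exit(close(con))
  writeLines(track_header(track_name,
                          "composite-element density (isolated sites suppressed)",
                          type = "wiggle_0"), con)
  tbl <- tibble::as_tibble(track)
  if (suppress_zeros) tbl <- tbl[tbl$count > 0L, , drop = FALSE]
  if (nrow(tbl) == 0L) return(invisible(out))
  # contiguous runs (by chrom and step spacing) become one fixedStep block
  brk <- c(TRUE, tbl$chrom[-1] != tbl$chrom[-nrow(tbl)] |
             diff(tbl$window_start) != step)
  block <- cumsum(brk)
  for (b in unique(block)) {
    rows <- tbl[block == b, , drop = FALSE]
    writeLines(sprintf("fixedStep chrom=%s start=%d step=%d span=%d",
                       rows$chrom[1], rows$window_start[1] + 1L,
                       step, step), con)
    writeLines(as.character(rows$count), con)
  }
  invisible(out)
}

#' Parse a fixedStep wiggle file written by [write_density_wig()]
#'
#' Inverse of the writer (round-trip tested); returns 0-based window
#' starts.
#'
#' @param path Wiggle file path.
#' @return Tibble with `chrom`, `window_start`, `count`.
#' @export
read_density_wig <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^track", lines)]
  out <- list()
  chrom <- NULL; pos <- NA_integer_; step <- NA_integer_
  for (ln in lines) {
    if (grepl("^fixedStep", ln)) {
      get <- function(k) sub(paste0(".*", k, "=([^ ]+).*"), "\\1", ln)
      chrom <- get("chrom")
      pos <- as.integer(get("start")) - 1L
      step <- as.integer(get("step"))
    } else if (nzchar(trimws(ln))) {
      out[[length(out) + 1L]] <- tibble::tibble(
        chrom = chrom, window_start = pos, count = as.integer(ln))
      pos <- pos + step
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(chrom = character(), window_start = integer(),
                          count = integer()))
  }
  dplyr::bind_rows(out)
}

#' Write called peaks as a UCSC BED5 custom track
#'
#' One line per peak: `chrom start end klass:count count`; the score
#' column carries the element count so browser shading tracks peak
#' intensity.
#'
#' @param peaks An `icr_peaks` tibble sorted by `(chrom, start)`
#'   (out-of-order input is a contract error).
#' @param out Output path.
#' @param track_name Track name for the header.
#' @return `out`, invisibly.
#' @export
write_peak_bed <- function(peaks, out, track_name = "candidate_ICRs") {
  if (nrow(peaks) > 1L) {
    o <- order(peaks$chrom, peaks$start)
    if (!identical(o, seq_len(nrow(peaks)))) {
      stop_state("peaks must be sorted by (chrom, start)")
    }
  }
  con <- open_out(out)
  on.exit(close(con))
  writeLines(track_header(track_name,
                          "candidate ICR peaks (robust >= 3 elements)"), con)
  if (nrow(peaks) > 0L) {
    writeLines(sprintf("%s\t%d\t%d\t%s:%d\t%d", peaks$chrom, peaks$start,
                       peaks$end, peaks$klass, peaks$count, peaks$count),
               con)
  }
  invisible(out)
}

#' Parse a BED track written by this package
#'
#' Skips `track` header lines; returns the first six columns that are
#' present.
#'
#' @param path BED file path.
#' @return Tibble with `chrom`, `start`, `end` and, when present, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n <- min(lengths(parts))
  col <- function(i) vapply(parts, `[[`, character(1), i)
  out <- tibble::tibble(chrom = col(1), start = as.integer(col(2)),
                        end = as.integer(col(3)))
  if (n >= 4L) out$name <- col(4)
  if (n >= 5L) out$score <- as.integer(col(5))
  if (n >= 6L) out$strand <- col(6)
  out
}

open_out <- function(out) {
  con <- tryCatch(file(out, open = "wt"),
                  error = function(e) NULL,
                  warning = function(w) NULL)
  if (is.null(con)) stop_io(paste0("cannot open '", out, "' for writing"))
  con
}

#' Write the three browser custom tracks plus a manifest
#'
#' Emits the three custom tracks of a genome-wide run — the ZFP57 hexamer
#' hit BED, the composite-element hit BED and the density wiggle — plus a
#' key-value manifest listing them. A peak BED is written alongside when
#' `peaks` is supplied, as derived output rather than one of the three
#' tracks.
#'
#' @param hits_zfbs Hexamer hit tibble.
#' @param hits_overlap Composite-element hit tibble.
#' @param density An `icr_density` tibble (or a list of them, one per
#'   chromosome, concatenated into one wiggle).
#' @param out_dir Output directory (created if needed).
#' @param peaks Optional `icr_peaks` tibble.
#' @param radius Annotation radius recorded in the manifest.
#' @return Tibble manifest with columns `key`, `path` (the three tracks),
#'   invisibly returns the manifest file path as attribute `manifest`.
#' @export
bundle_tracks <- function(hits_zfbs, hits_overlap, density, out_dir,
                          peaks = NULL, radius = 10000L) {
  for (nm in c("hits_zfbs", "hits_overlap", "density")) {
    if (is.null(get(nm))) stop_input(paste0("missing component: ", nm))
  }
  check_writable_dir(out_dir)
  p_zfbs <- file.path(out_dir, "zfbs_hits.bed")
  p_over <- file.path(out_dir, "zfbs_morph_overlap_hits.bed")
  p_wig <- file.path(out_dir, "overlap_density.wig")
  write_hit_bed(hits_zfbs, "ZFBS_TGCCGC", p_zfbs,
                "positions of the ZFP57 binding hexamer")
  write_hit_bed(hits_overlap, "ZFBS_morph_overlaps", p_over,
                "positions of ZFBS-morph overlap elements")
  if (is.data.frame(density)) density <- list(density)
  con <- open_out(p_wig)
  close(con)
  first <- TRUE
  for (d in density) {
    tmp <- tempfile(fileext = ".wig")
    write_density_wig(d, tmp)
    lines <- readLines(tmp)
    if (!first) lines <- lines[!grepl("^track", lines)]
    cat(lines, file = p_wig, sep = "\n", append = !first)
    cat("\n", file = p_wig, append = TRUE)
    first <- FALSE
    unlink(tmp)
  }
  manifest <- tibble::tibble(
    key = c("track_zfbs_bed", "track_overlap_bed", "track_density_wig"),
    path = c(p_zfbs, p_over, p_wig)
  )
  extra <- character()
  if (!is.null(peaks)) {
    p_peaks <- file.path(out_dir, "candidate_icr_peaks.bed")
    write_peak_bed(peaks, p_peaks)
    extra <- c(derived_peak_bed = p_peaks)
  }
  mpath <- file.path(out_dir, "manifest.txt")
  writeLines(c(
    paste0(manifest$key, "=", manifest$path),
    if (length(extra)) paste0(names(extra), "=", extra),
    paste0("annotation_radius=", radius),
    paste0("n_tracks=", nrow(manifest))
  ), mpath)
  attr(manifest, "manifest") <- mpath
  manifest
}
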