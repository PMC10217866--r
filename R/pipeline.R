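#' Run configuration for a genome-wide scan
#'
#' Centralises the tunable parameters of the workflow with their
#' defaults: the 850-base density window, a wiggle step of one tenth of
#' the window, the robust-peak threshold of three elements, a 10 kb
#' gene-annotation radius, and strand-duplicate removal before density.
#' Values from a key-value config file override the defaults, and named
#' arguments override the file (precedence: arguments > file > defaults).
#'
#' @param file Optional path to a `key = value` config file (`#`
#'   comments allowed). Recognised keys: `genome`, `zfbs_file`,
#'   `morpheme_file`, `overlap_file`, `genes`, `out_dir`, `window`,
#'   `wig_step`, `robust_min`, `min_overlap`, `radius`, `dedupe`, `seed`.
#' @param ... Named overrides for the same keys.
#' @return Named list of configuration values.
#' @examples
#' icr_config()$window  # 850
#' @export
icr_config <- function(file = NULL, ...) {
  defaults <- list(
    genome = NULL, zfbs_file = NULL, morpheme_file = NULL,
    overlap_file = NULL, genes = NULL, out_dir = ".",
    window = 850L, wig_step = 85L, robust_min = 3L, min_overlap = 1L,
    radius = 10000L, dedupe = TRUE, seed = 1L
  )
  cfg <- defaults
  if (!is.null(file)) {
    if (!file.exists(file)) {
      stop_input(paste0("config file not found: '", file, "'"))
    }
    lines <- readLines(file, warn = FALSE)
    lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2L) {
        stop_format(paste0("config line is not 'key = value': '", ln, "'"))
      }
      key <- trimws(kv[1]); val <- trimws(kv[2])
      cfg[[key]] <- coerce_config_value(key, val)
    }
  }
  dots <- list(...)
  for (key in names(dots)) cfg[[key]] <- dots[[key]]
  validate_config(cfg)
  cfg
}

coerce_config_value <- function(key, val) {
  int_keys <- c("window", "wig_step", "robust_min", "min_overlap",
                "radius", "seed")
  if (key %in% int_keys) return(as.integer(val))
  if (key == "dedupe") return(toupper(val) %in% c("TRUE", "1", "YES"))
  val
}

validate_config <- function(cfg) {
  if (!is_count(cfg$window, 1L)) stop_config("window must be >= 1")
  if (!is_count(cfg$robust_min, 2L)) stop_config("robust_min must be >= 2")
  if (!is_count(cfg$wig_step, 1L) || cfg$wig_step > cfg$window) {
    stop_config("wig_step must satisfy 1 <= wig_step <= window")
  }
  if (!is_count(cfg$radius, 0L)) stop_config("radius must be >= 0")
  for (key in c("genome", "zfbs_file", "morpheme_file", "overlap_file",
                "genes")) {
    p <- cfg[[key]]
    if (!is.null(p) && !file.exists(p)) {
      stop_input(paste0(key, " path does not exist: '", p, "'"))
    }
  }
  invisible(cfg)
}

#' Run the full candidate-ICR workflow on a genome
#'
#' End-to-end driver: read the genome, load and complement-expand the two
#' motif sets (the ZFP57 hexamer set and the composite-overlap set), scan
#' every chromosome for both, remove strand-duplicate composite hits,
#' compute the suppressed density and call peaks per chromosome, write
#' the three browser tracks plus the peak BED and a per-chromosome
#' summary TSV, and (when gene models are given) an annotated-peak TSV.
#'
#' @param genome A genome tibble from [read_fasta()] or a FASTA path.
#' @param config A list from [icr_config()]; individual `...` overrides
#'   are applied on top.
#' @param ... Named [icr_config()] overrides.
#' @return Invisibly, a list with `hits_zfbs`, `hits_overlap` (deduped),
#'   `density` (list per chromosome), `peaks`, `summary`, `manifest`,
#'   `annotated` (or `NULL`), and `config`.
#' @export
run_icr_pipeline <- function(genome, config = icr_config(), ...) {
  dots <- list(...)
  for (key in names(dots)) config[[key]] <- dots[[key]]
  validate_config(config)
  if (is.character(genome)) genome <- read_fasta(genome)

  zfbs <- if (!is.null(config$zfbs_file)) {
    read_motifs(config$zfbs_file, origin = "zfbs")
  } else default_zfbs()
  overlaps <- if (!is.null(config$overlap_file)) {
    read_motifs(config$overlap_file, origin = "overlap")
  } else default_overlaps()

  zfbs_x <- add_complements(zfbs)
  over_x <- add_complements(overlaps)

  hits_zfbs <- scan_motifs(genome, zfbs_x)
  hits_over <- scan_motifs(genome, over_x)
  if (isTRUE(config$dedupe)) hits_over <- dedupe_hits(hits_over)

  density <- purrr::map(seq_len(nrow(genome)), function(i) {
    h <- hits_over[hits_over$chrom == genome$chrom[i], , drop = FALSE]
    window_counts(h, genome$length[i], window = config$window,
                  step = config$wig_step)
  })
  peaks <- call_peaks(hits_over, window = config$window,
                      robust_min = config$robust_min)
  summary <- summarize_peaks(peaks)

  check_writable_dir(config$out_dir)
  manifest <- bundle_tracks(hits_zfbs, hits_over, density,
                            config$out_dir, peaks = peaks,
                            radius = config$radius)
  utils::write.table(summary, file.path(config$out_dir, "peak_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  annotated <- NULL
  if (!is.null(config$genes)) {
    genes <- read_genes(config$genes)
    annotated <- annotate_peaks(peaks, genes, radius = config$radius)
    utils::write.table(annotated,
                       file.path(config$out_dir, "annotated_peaks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(hits_zfbs = hits_zfbs, hits_overlap = hits_over,
                 density = density, peaks = peaks, summary = summary,
                 manifest = manifest, annotated = annotated,
                 config = config))
}
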