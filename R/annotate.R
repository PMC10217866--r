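#' Read gene models from BED or GFF3
#'
#' Genes in the vicinity of candidate-ICR peaks are the potential
#' imprinted genes, so peak annotation needs a gene table. BED input uses
#' columns 1-4 and 6; GFF3 input keeps features of type `gene` and names
#' them from the `Name` attribute, falling back to `ID`. Coordinates are
#' returned 0-based half-open.
#'
#' @param path Path to a `.bed`, `.gff`/`.gff3` gene-model file.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @return Tibble with columns `chrom`, `start`, `end`, `strand`,
#'   `gene_name`.
#' @export
read_genes <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_input(paste0("gene-model file not found: '", path, "'"))
  }
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3"
              else "bed"
  }
  if (format == "bed") {
    tbl <- read_bed(path)
    if (nrow(tbl) == 0L) {
      return(empty_genes())
    }
    tibble::tibble(
      chrom = tbl$chrom, start = tbl$start, end = tbl$end,
      strand = if ("strand" %in% names(tbl)) tbl$strand else "+",
      gene_name = if ("name" %in% names(tbl)) tbl$name
                  else paste0("gene", seq_len(nrow(tbl)))
    )
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type == "gene"]
    if (length(gr) == 0L) return(empty_genes())
    nm <- as.character(gr$Name)
    if (all(is.na(nm)) || is.null(gr$Name)) nm <- rep(NA_character_, length(gr))
    id <- if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_
    nm[is.na(nm)] <- id[is.na(nm)]
    tibble::tibble(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      gene_name = nm
    )
  }
}

empty_genes <- function() {
  tibble::tibble(chrom = character(), start = integer(), end = integer(),
                 strand = character(), gene_name = character())
}

#' Annotate peaks with genes in their vicinity
#'
#' For each peak, lists every gene whose interval lies within `radius`
#' bases of the peak hull, sorted by absolute distance. Distances are
#' hull-to-hull: 0 for overlapping (or abutting) intervals, positive when
#' the gene starts after the peak ends, negative when it ends before the
#' peak starts. Peaks on chromosomes absent from the gene table get an
#' empty annotation with a warning.
#'
#' @param peaks An `icr_peaks` tibble from [call_peaks()].
#' @param genes Gene tibble from [read_genes()].
#' @param radius Search radius in bases (default 10000).
#' @return Tibble with one row per (peak, nearby gene) pair — peaks with
#'   no gene in range keep one row with `gene_name = NA` — and columns
#'   `chrom`, `start`, `end`, `count`, `klass`, `gene_name`, `distance`.
#' @export
annotate_peaks <- function(peaks, genes, radius = 10000L) {
  if (!is_count(radius, 0L)) stop_config("radius must be a non-negative integer")
  ptbl <- tibble::as_tibble(peaks)[, c("chrom", "start", "end", "count",
                                       "klass")]
  if (nrow(ptbl) == 0L) {
    return(dplyr::mutate(ptbl, gene_name = character(0),
                         distance = integer(0)))
  }
  missing_chrom <- setdiff(unique(ptbl$chrom), unique(genes$chrom))
  if (length(missing_chrom) > 0L) {
    warning("no gene models for chromosome(s): ",
            paste(missing_chrom, collapse = ", "),
            "; peaks there get empty annotations", call. = FALSE)
  }
  rows <- purrr::map(seq_len(nrow(ptbl)), function(i) {
    p <- ptbl[i, ]
    g <- genes[genes$chrom == p$chrom, , drop = FALSE]
    if (nrow(g) > 0L) {
      d <- interval_distance(p$start, p$end, g$start, g$end)
      keep <- abs(d) <= radius
      g <- g[keep, , drop = FALSE]
      d <- d[keep]
    } else {
      d <- integer(0)
    }
    if (nrow(g) == 0L) {
      return(dplyr::mutate(p, gene_name = NA_character_,
                           distance = NA_integer_))
    }
    o <- order(abs(d), d)
    out <- p[rep(1L, length(o)), ]
    out$gene_name <- g$gene_name[o]
    out$distance <- d[o]
    out
  })
  dplyr::bind_rows(rows)
}

# Signed hull-to-hull distance between [ps, pe) and each [gs, ge):
# 0 when they overlap, gs - pe when the gene is downstream,
# -(ps - ge) when upstream.
interval_distance <- function(ps, pe, gs, ge) {
  d <- integer(length(gs))
  after <- gs >= pe
  before <- ge <= ps
  d[after] <- gs[after] - pe
  d[before] <- -(ps - ge[before])
  d
}
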