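#' Find every exact motif occurrence on both strands
#'
#' Runs one forward pass over each chromosome with a complement-expanded
#' motif set: complement-origin motifs report `-` strand hits, all others
#' `+`. Overlapping and self-overlapping occurrences are all reported;
#' windows containing `N` never match. Coordinates are 0-based half-open.
#'
#' @param genome Tibble from [read_fasta()] (columns `chrom`, `sequence`),
#'   or any tibble with those columns.
#' @param ms A complement-expanded `motif_set` (see [add_complements()]);
#'   scanning an unexpanded set is an error, since it would silently miss
#'   minus-strand occurrences.
#' @return A tibble of hits with columns `chrom`, `start` (0-based),
#'   `end` (exclusive), `strand`, `motif_id`, sorted by
#'   `(chrom, start, end, motif_id)`.
#' @examples
#' g <- tibble::tibble(chrom = "chrT", sequence = "TGCCGCGGCA")
#' scan_motifs(g, add_complements(motif_set("TGCCGC")))
#' @export
scan_motifs <- function(genome, ms) {
  if (!is_complemented(ms)) {
    stop_state(paste0(
      "motif set must be complement-expanded before scanning ",
      "(call add_complements()); otherwise minus-strand hits are lost"
    ))
  }
  stopifnot(all(c("chrom", "sequence") %in% names(genome)))
  hits <- purrr::map(seq_len(nrow(genome)), function(i) {
    subject <- Biostrings::DNAString(genome$sequence[i])
    per_motif <- purrr::map(seq_len(nrow(ms)), function(j) {
      mm <- Biostrings::matchPattern(ms$word[j], subject, fixed = TRUE)
      if (length(mm) == 0L) return(NULL)
      tibble::tibble(
        chrom = genome$chrom[i],
        start = Biostrings::start(mm) - 1L,
        end = Biostrings::end(mm),
        strand = if (ms$origin[j] == "complement") "-" else "+",
        motif_id = ms$id[j]
      )
    })
    dplyr::bind_rows(per_motif)
  })
  hits <- dplyr::bind_rows(hits)
  if (nrow(hits) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), strand = character(),
                          motif_id = character()))
  }
  dplyr::arrange(hits, .data$chrom, .data$start, .data$end, .data$motif_id)
}

#' Collapse strand-duplicate hits
#'
#' A word and its reverse complement can match the identical genomic
#' interval; the density stage must count such an element once. Hits with
#' identical `(chrom, start, end)` collapse to one record keeping strand
#' `+` if any member is `+`, with motif ids concatenated (`,`).
#'
#' @param hits Sorted hit tibble from [scan_motifs()].
#' @return The deduplicated hit tibble, same columns and order.
#' @export
dedupe_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  hits |>
    dplyr::group_by(.data$chrom, .data$start, .data$end) |>
    dplyr::summarise(
      strand = if (any(.data$strand == "+")) "+" else "-",
      motif_id = paste(unique(.data$motif_id), collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::select("chrom", "start", "end", "strand", "motif_id") |>
    dplyr::arrange(.data$chrom, .data$start, .data$end, .data$motif_id)
}
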