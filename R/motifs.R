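#' Construct a motif set
#'
#' A motif set is a tibble of named DNA words with one row per motif and an
#' attribute recording whether reverse complements have been added. Words
#' must be unique, at least 4 bases long, and contain only `A`/`C`/`G`/`T`.
#'
#' @param words Character vector of DNA words.
#' @param ids Optional character vector of labels (defaults to the words).
#' @param origin Origin tag for every motif: `"zfbs"`, `"morpheme"`,
#'   `"overlap"` or `"complement"`.
#' @param complemented Whether the set is already closed under reverse
#'   complement (see [add_complements()]).
#' @return A `motif_set` tibble with columns `id`, `word`, `origin`,
#'   `source_id`.
#' @export
motif_set <- function(words, ids = words, origin = "zfbs",
                      complemented = FALSE) {
  words <- toupper(words)
  bad <- grepl("[^ACGT]", words, perl = TRUE)
  if (any(bad)) {
    stop_alpha(paste0("motif word '", words[which(bad)[1]],
                      "' contains letters outside A/C/G/T"))
  }
  if (any(nchar(words) < 4L)) {
    stop_format("motif words must be at least 4 bases long")
  }
  if (anyDuplicated(words)) {
    stop_format(paste0("duplicate motif word '",
                       words[duplicated(words)][1], "'"))
  }
  out <- tibble::tibble(
    id = as.character(ids),
    word = words,
    origin = rep_len(origin, length(words)),
    source_id = NA_character_
  )
  new_motif_set(out, complemented = complemented)
}

new_motif_set <- function(tbl, complemented = FALSE) {
  class(tbl) <- c("motif_set", class(tibble::as_tibble(tbl)))
  attr(tbl, "complemented") <- complemented
  tbl
}

is_complemented <- function(ms) isTRUE(attr(ms, "complemented"))

#' Load a motif file
#'
#' Reads a plain-text motif file: one motif per line, either a bare word or
#' `id<TAB>word`; lines starting with `#` are comments. Words are
#' uppercased and validated against `{A,C,G,T}`; duplicates are rejected.
#'
#' @param path Path to the motif file.
#' @param origin Origin tag recorded on every motif.
#' @return A `motif_set` tibble (not complement-expanded).
#' @export
read_motifs <- function(path, origin = "zfbs") {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop_input(paste0("motif file not found: '", path, "'"))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  if (length(keep) == 0L) stop_format(paste0("'", path, "' lists no motifs"))
  parts <- strsplit(trimws(lines[keep]), "\t")
  ids <- vapply(parts, function(p) if (length(p) >= 2L) p[[1]] else toupper(p[[1]]),
                character(1))
  words <- toupper(vapply(parts, function(p) p[[length(p)]], character(1)))
  bad <- grepl("[^ACGT]", words, perl = TRUE)
  if (any(bad)) {
    i <- which(bad)[1]
    stop_alpha(paste0("invalid motif letter at line ", keep[i], " of '",
                      path, "': '", words[i], "'"))
  }
  if (anyDuplicated(words)) {
    i <- which(duplicated(words))[1]
    stop_format(paste0("duplicate motif word at line ", keep[i], " of '",
                       path, "': '", words[i], "'"))
  }
  motif_set(words, ids = ids, origin = origin)
}

#' Add reverse-complement motifs to a set
#'
#' Closes a motif set under reverse complement, so that a single forward
#' scanning pass finds occurrences on both strands. Palindromic words are
#' kept once; each added motif records `origin = "complement"` and the id
#' of its source motif in `source_id`.
#'
#' @param ms A `motif_set` that has not been complement-expanded.
#' @return The complement-closed `motif_set`.
#' @examples
#' add_complements(motif_set("TGCCGC"))
#' @export
add_complements <- function(ms) {
  if (is_complemented(ms)) {
    stop_state("motif set is already complement-expanded")
  }
  rc <- reverse_complement(ms$word)
  keep <- !(rc %in% ms$word) & !duplicated(rc)
  extra <- tibble::tibble(
    id = paste0(ms$id[keep], "_rc"),
    word = rc[keep],
    origin = "complement",
    source_id = ms$id[keep]
  )
  new_motif_set(dplyr::bind_rows(tibble::as_tibble(ms), extra),
                complemented = TRUE)
}

#' Generate composite overlap motifs from two word sets
#'
#' Enumerates every way a binding-site word `z` and a morpheme word `m` can
#' occupy overlapping intervals of one merged word: the morpheme's prefix
#' overlapping the binding site's suffix, its suffix overlapping the
#' binding site's prefix, or either word contained in the other
#' (containment counts as an overlap of the contained word's full length).
#' A placement is kept when the overlap is at least `min_overlap` bases and
#' the two words agree letter-for-letter on it; each kept placement yields
#' the shortest superstring for that placement. Merged words carrying fewer
#' than two CpG dinucleotides are excluded, since the composite elements
#' the density scan targets are defined by their CpG richness.
#'
#' @param zfbs Un-complemented `motif_set` of binding-site words.
#' @param morphemes Un-complemented `motif_set` of morpheme words.
#' @param min_overlap Minimum overlap in bases (default 1: any overlap).
#' @return A `motif_set` of distinct merged words with `origin =
#'   "overlap"`; `id` records every `(z, m, offset)` derivation of the
#'   word, separated by `;`.
#' @examples
#' overlap_motifs(motif_set("TGCCGC"), motif_set("CGCGCG", origin = "morpheme"),
#'                min_overlap = 3)
#' @export
overlap_motifs <- function(zfbs, morphemes, min_overlap = 1L) {
  if (is_complemented(zfbs) || is_complemented(morphemes)) {
    stop_state("overlap generation expects un-complemented motif sets")
  }
  if (!is_count(min_overlap, min = 1L)) {
    stop_config("min_overlap must be a positive integer")
  }
  if (nrow(zfbs) == 0L || nrow(morphemes) == 0L) {
    return(new_motif_set(
      tibble::tibble(id = character(), word = character(),
                     origin = character(), source_id = character())
    ))
  }
  pairs <- tidyr::expand_grid(
    z = seq_len(nrow(zfbs)), m = seq_len(nrow(morphemes))
  )
  merged <- purrr::pmap(pairs, function(z, m) {
    merge_words(zfbs$word[z], morphemes$word[m],
                zfbs$id[z], morphemes$id[m], min_overlap)
  })
  merged <- dplyr::bind_rows(merged)
  if (nrow(merged) == 0L) {
    return(new_motif_set(
      tibble::tibble(id = character(), word = character(),
                     origin = character(), source_id = character())
    ))
  }
  merged <- merged[cpg_count(merged$word) >= 2L, , drop = FALSE]
  out <- merged |>
    dplyr::group_by(.data$word) |>
    dplyr::summarise(id = paste(.data$id, collapse = ";"),
                     .groups = "drop") |>
    dplyr::arrange(.data$word) |>
    dplyr::transmute(id = .data$id, word = .data$word,
                     origin = "overlap", source_id = NA_character_)
  new_motif_set(out)
}

# All merged words for one (z, m) pair. offset is m's start relative to
# z's start; negative offsets put the morpheme first.
merge_words <- function(z, m, z_id, m_id, min_overlap) {
  lz <- nchar(z)
  lm <- nchar(m)
  zc <- strsplit(z, "")[[1]]
  mc <- strsplit(m, "")[[1]]
  res <- list()
  for (off in seq(-(lm - 1L), lz - 1L)) {
    lo <- max(0L, off)
    hi <- min(lz, off + lm)
    ov <- hi - lo
    if (ov < min_overlap) next
    z_part <- zc[(lo + 1L):hi]
    m_part <- mc[(lo - off + 1L):(hi - off)]
    if (!all(z_part == m_part)) next
    span_lo <- min(0L, off)
    span_hi <- max(lz, off + lm)
    word <- character(span_hi - span_lo)
    word[(1L - span_lo):(lz - span_lo)] <- zc
    word[(off + 1L - span_lo):(off + lm - span_lo)] <- mc
    res[[length(res) + 1L]] <- tibble::tibble(
      id = paste0(z_id, "|", m_id, "|", off),
      word = paste(word, collapse = "")
    )
  }
  dplyr::bind_rows(res)
}

#' Report CpG content of a motif set
#'
#' For each motif, counts CpG (`CG`) dinucleotides and flags
#' overlap-origin motifs carrying fewer than two, which violate the
#' defining property of the composite elements.
#'
#' @param ms A `motif_set`.
#' @return A list with `report` (tibble: `id`, `word`, `origin`,
#'   `cpg_count`, `flagged`) and `min_cpg` (minimum count over the set;
#'   `NA` for an empty set).
#' @export
validate_overlaps <- function(ms) {
  if (nrow(ms) == 0L) {
    return(list(
      report = tibble::tibble(id = character(), word = character(),
                              origin = character(), cpg_count = integer(),
                              flagged = logical()),
      min_cpg = NA_integer_
    ))
  }
  report <- tibble::tibble(
    id = ms$id, word = ms$word, origin = ms$origin,
    cpg_count = cpg_count(ms$word),
    flagged = ms$origin == "overlap" & cpg_count(ms$word) < 2L
  )
  list(report = report, min_cpg = min(report$cpg_count))
}

#' Packaged default motif sets
#'
#' `default_zfbs()` returns the ZFP57 binding hexamer TGCCGC. The packaged
#' morpheme and overlap lists are synthetic stand-ins generated with
#' [overlap_motifs()] from an illustrative CpG-rich morpheme set (see the
#' files under `inst/extdata/`, named `*_synthetic.txt`); replace them with
#' a published word list via the `zfbs_file`/`morpheme_file`/`overlap_file`
#' options of the pipeline for real analyses.
#'
#' @return A `motif_set` tibble.
#' @export
default_zfbs <- function() {
  read_motifs(system.file("extdata", "zfbs_hexamer.txt",
                          package = "icrscan"), origin = "zfbs")
}

#' @rdname default_zfbs
#' @export
default_morphemes <- function() {
  read_motifs(system.file("extdata", "mll_morphemes_synthetic.txt",
                          package = "icrscan"), origin = "morpheme")
}

#' @rdname default_zfbs
#' @export
default_overlaps <- function() {
  read_motifs(system.file("extdata", "zfbs_morph_overlaps_synthetic.txt",
                          package = "icrscan"), origin = "overlap")
}
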