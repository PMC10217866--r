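#' Read chromosome sequences from a FASTA file
#'
#' Reads a (possibly multi-record, wrapped, mixed-case) FASTA file and
#' normalises every record for motif scanning: residues are uppercased and
#' any letter outside `A`/`C`/`G`/`T`/`N` (ambiguity codes such as `R`, `Y`,
#' soft-mask artefacts) is replaced by `N`, which never matches a motif.
#' The record name is the first whitespace-delimited token of the header.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with one row per record and columns `chrom` (record
#'   name), `sequence` (normalised residue string) and `length` (bases),
#'   in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chrT", "acgt", "ACGT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop_input(paste0("FASTA file not found: '", path, "'"))
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop_format(paste0("'", path, "' contains no FASTA records"))
  }
  chrom <- vapply(strsplit(names(set), "[ \t]"), `[[`, character(1), 1L)
  seqs <- unname(normalize_residues(as.character(set)))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop_format(paste0(
      "FASTA record with zero residues: '", chrom[which(empty)[1]], "'"
    ))
  }
  tibble::tibble(chrom = chrom, sequence = unname(seqs),
                 length = nchar(seqs))
}

#' Write chromosome sequences to a FASTA file
#'
#' Companion writer for [read_fasta()]: a read/write round trip is the
#' identity on `(chrom, sequence)`.
#'
#' @param genome Tibble with columns `chrom` and `sequence`.
#' @param path Output path.
#' @param width Line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 60L) {
  stopifnot(all(c("chrom", "sequence") %in% names(genome)))
  set <- Biostrings::BStringSet(genome$sequence)
  names(set) <- genome$chrom
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

normalize_residues <- function(x) {
  x <- toupper(x)
  gsub("[^ACGTN]", "N", x, perl = TRUE)
}

#' Reverse complement of DNA strings
#'
#' Standard reverse complement over the `{A,C,G,T,N}` alphabet; `N` maps to
#' `N`. Vectorised; an involution that preserves length.
#'
#' @param s Character vector of DNA strings over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("TGCCGC")  # "GCGGCA"
#' @export
reverse_complement <- function(s) {
  stopifnot(is.character(s))
  bad <- grepl("[^ACGTN]", s, perl = TRUE)
  if (any(bad)) {
    stop_alpha(paste0(
      "invalid DNA letter in '", s[which(bad)[1]],
      "' (alphabet is A/C/G/T/N)"
    ))
  }
  comp <- chartr("ACGTN", "TGCAN", s)
  vapply(comp, function(w) {
    intToUtf8(rev(utf8ToInt(w)))
  }, character(1), USE.NAMES = FALSE)
}
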