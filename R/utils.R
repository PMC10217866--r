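# Shared helpers: classed conditions and small validators.

abort_icr <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "icrscan_error"), ...)
}

stop_input  <- function(msg, ...) abort_icr(msg, "icrscan_input_error", ...)
stop_format <- function(msg, ...) abort_icr(msg, "icrscan_format_error", ...)
stop_alpha  <- function(msg, ...) abort_icr(msg, "icrscan_alphabet_error", ...)
stop_state  <- function(msg, ...) abort_icr(msg, "icrscan_state_error", ...)
stop_config <- function(msg, ...) abort_icr(msg, "icrscan_config_error", ...)
stop_io     <- function(msg, ...) abort_icr(msg, "icrscan_io_error", ...)

is_count <- function(x, min = 0L) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == as.integer(x) && x >= min
}

# Count non-overlapping CpG dinucleotides in each word ("CG" cannot
# self-overlap, so fixed counting is exact).
cpg_count <- function(words) {
  stringr::str_count(words, stringr::fixed("CG"))
}

check_writable_dir <- function(path) {
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_io(paste0("cannot create output directory '", path, "'"))
  }
  invisible(path)
}
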