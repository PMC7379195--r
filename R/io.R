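#' Export results to plain-text files
#'
#' ERPs and difference waves go to long-format CSV (`channel`,
#' `time_ms`, `uv`, plus any constant metadata columns), amplitude
#' summaries to CSV, and exclusion reports to JSON.
#'
#' @param erp An `erp_average`.
#' @param path Output file path.
#' @param ... Constant metadata columns to prepend (e.g.
#'   `subject = "s01"`, `condition = "deviant"`).
#' @return The input, invisibly.
#' @export
write_erp_csv <- function(erp, path, ...) {
  d <- erp_to_tibble(erp)
  meta <- list(...)
  for (nm in names(meta)) d[[nm]] <- meta[[nm]]
  d <- dplyr::relocate(d, dplyr::all_of(names(meta)))
  readr::write_csv(d, path)
  invisible(erp)
}

#' @rdname write_erp_csv
#' @param summary An `amplitude_summary`.
#' @export
write_amplitude_summary_csv <- function(summary, path) {
  readr::write_csv(summary$contrasts, path)
  invisible(summary)
}

#' @rdname write_erp_csv
#' @param exclusions An exclusion report tibble from
#'   [apply_exclusions()].
#' @export
write_exclusions_json <- function(exclusions, path) {
  jsonlite::write_json(exclusions, path, auto_unbox = FALSE, digits = NA)
  invisible(exclusions)
}
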