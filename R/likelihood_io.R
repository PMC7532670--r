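#' Write / read a patch-likelihood table TSV
#'
#' Header `slide_id`, `grid_x`, `grid_y`, `likelihood` (extra columns such as
#' `is_key` are carried through).
#'
#' @param table Patch-likelihood tibble.
#' @param path TSV path.
#' @return `path` / the tibble.
#' @export
write_likelihood_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_likelihood_table
#' @export
read_likelihood_table <- function(path) {
  tb <- as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                    stringsAsFactors = FALSE))
  if (!all(c("slide_id", "likelihood") %in% names(tb))) {
    stop_pathomsi("likelihood table needs slide_id and likelihood columns")
  }
  tb$slide_id <- as.character(tb$slide_id)
  tb
}
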