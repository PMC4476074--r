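#' Stable short hash of a configuration object
#'
#' Used to stamp output files so a result can be traced back to the exact
#' parameter set that produced it.
#'
#' @param params Any serializable R object.
#' @return An 8-character hexadecimal string.
#' @export
config_hash <- function(params) {
  substr(digest::digest(params, algo = "sha1"), 1, 8)
}

#' Write a result table as TSV with a provenance header
#'
#' The first line is a comment naming the producing subcommand and the
#' configuration hash; the table follows as plain TSV.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param producer Name of the producing step (e.g. `"call"`).
#' @param params The parameter set, hashed into the header.
#' @return `path`, invisibly.
#' @export
write_ir_tsv <- function(x, path, producer = "export", params = list()) {
  writeLines(sprintf("# irdetect %s config=%s", producer,
                     config_hash(params)), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_ir_tsv()]
#'
#' @param path Input path.
#' @return A tibble; comment lines are skipped.
#' @export
read_ir_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}
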