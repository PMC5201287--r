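## Table and config I/O.
##
## CSV is the single tabular interchange format.  Numeric columns are
## written with 17 significant digits so every table round-trips through
## write/read losslessly (bit-identical doubles).

#' Write a table as headered CSV, losslessly
#' @param x data.frame
#' @param path output path
#' @export
write_table_csv <- function(x, path) {
  y <- x
  for (j in seq_along(y)) {
    if (is.double(y[[j]])) {
      v <- sprintf("%.17g", y[[j]])
      v[is.na(y[[j]])] <- NA_character_
      y[[j]] <- v
    }
  }
  utils::write.csv(y, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read a headered CSV written by [write_table_csv()]
#' @param path input path
#' @return data.frame
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Serialize a population specification to JSON
#' @param spec a `population_spec`
#' @param path output path
#' @export
write_population_spec <- function(spec, path) {
  x <- unclass(spec)
  x$household_size_distribution <- as.list(x$household_size_distribution)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' Read a population specification from JSON
#' @param path input path
#' @return a `population_spec`
#' @export
read_population_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  h <- unlist(x$household_size_distribution)
  population_spec(
    n_agents = x$n_agents,
    age_sex_marginals = as.data.frame(x$age_sex_marginals),
    household_size_distribution = h,
    income_gamma_shape = x$income_gamma_shape,
    income_gamma_scale = x$income_gamma_scale,
    target_poverty_headcount = x$target_poverty_headcount,
    background_mortality = x$background_mortality,
    fertility_rate = x$fertility_rate
  )
}
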