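#' Round half away from zero
#'
#' Commercial rounding as used in the printed signal tables: 0.005 rounds to
#' 0.01, not 0.00. Base R's `round()` rounds half to even, which disagrees
#' with how pharmacovigilance tables are typically typeset.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# normalize a term/drug name for matching: trim, squeeze whitespace, lower
norm_name <- function(x) {
  x <- gsub("[[:space:]]+", " ", trimws(as.character(x)))
  tolower(x)
}

#' Read a term list file
#'
#' One preferred term per line; blank lines and lines starting with `#` are
#' ignored. Used for exclusion lists and IME/DME lists.
#'
#' @param path file path.
#' @return character vector of terms.
#' @export
read_term_file <- function(path) {
  if (!file.exists(path)) stop("term file not found: ", path)
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

# path to a packaged example file
pvscreen_extdata <- function(file) {
  system.file("extdata", file, package = "pvscreen", mustWork = TRUE)
}
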