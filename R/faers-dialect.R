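# Reading and writing the FAERS quarterly ASCII dialect:
# "$"-delimited, first line is the header, no quoting mechanism. Because the
# dialect has no escape, fields containing "$" cannot be represented and are
# rejected at write time rather than silently corrupted.

#' Write a table in the FAERS dollar-delimited dialect
#'
#' @param df data.frame; all columns are serialized with `as.character`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_faers_table <- function(df, path) {
  mat <- vapply(df, as.character, character(nrow(df)))
  if (nrow(df) == 1L) mat <- matrix(mat, nrow = 1L)
  if (nrow(df) > 0 && any(grepl("$", mat, fixed = TRUE)))
    stop("field contains the '$' delimiter; the FAERS dialect has no escape")
  lines <- c(paste(names(df), collapse = "$"),
             if (nrow(df) > 0) apply(mat, 1L, paste, collapse = "$"))
  con <- file(path, open = "wb")  # fixed newline convention => reproducible
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a table in the FAERS dollar-delimited dialect
#'
#' One record per non-header line. Lines whose field count differs from the
#' header are malformed: they are counted (attribute `n_malformed`) and
#' reported via a warning, never silently dropped without trace.
#'
#' @param path input file path.
#' @param required_cols column names that must be present.
#' @return data.frame of character columns with attribute `n_malformed`.
#' @export
read_faers_table <- function(path, required_cols = character()) {
  if (!file.exists(path)) stop("cannot read FAERS table: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty file (no header line): ", path)
  header <- strsplit(lines[1], "$", fixed = TRUE)[[1]]
  missing <- setdiff(required_cols, header)
  if (length(missing))
    stop("missing mandatory column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "))
  body <- lines[-1]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "$", fixed = TRUE)
  # strsplit drops a trailing empty field; pad records that are short by it
  nf <- lengths(parts)
  trailing <- nf == length(header) - 1L & endsWith(body, "$")
  parts[trailing] <- lapply(parts[trailing], function(p) c(p, ""))
  nf <- lengths(parts)
  ok <- nf == length(header)
  n_malformed <- sum(!ok)
  if (n_malformed > 0)
    warning(sprintf("%d malformed line(s) in %s (field count != %d)",
                    n_malformed, basename(path), length(header)))
  good <- parts[ok]
  df <- as.data.frame(do.call(rbind, c(good, list(deparse.level = 0))),
                      stringsAsFactors = FALSE)
  if (length(good) == 0)
    df <- as.data.frame(matrix(character(0), nrow = 0, ncol = length(header)),
                        stringsAsFactors = FALSE)
  names(df) <- header
  attr(df, "n_malformed") <- n_malformed
  df
}
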