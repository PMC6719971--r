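#' Write a pipeline result to disk
#'
#' Deterministic writers for every result type the pipeline produces: column
#' order is fixed by the result type, floats are rendered at 6 significant
#' digits, and writing the same object twice yields byte-identical files.
#' JSON run summaries carry the package version, a configuration hash and the
#' RNG seed so a run can be traced.
#'
#' @param obj A pipeline result: a tibble/data.frame report, a [module_set]
#'   or a `run_summary`.
#' @param path Output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(obj, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  UseMethod("write_report")
}

#' @export
write_report.default <- function(obj, path, format = c("tsv", "json")) {
  abort(sprintf("don't know how to write an object of class <%s>",
                paste(class(obj), collapse = "/")))
}

#' @export
write_report.data.frame <- function(obj, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(obj)
  # list-columns (enzyme classes, member lists) render as ;-joined strings
  for (col in names(df)) {
    if (is.list(df[[col]])) {
      df[[col]] <- vapply(df[[col]], function(v) paste(v, collapse = ";"), character(1))
    } else if (is.double(df[[col]])) {
      df[[col]] <- fmt_num(df[[col]])
    }
  }
  if (format == "tsv") {
    lines <- c(paste(names(df), collapse = "\t"),
               do.call(paste, c(lapply(df, as.character), sep = "\t")))
    writeLines(lines, path)
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @export
write_report.module_set <- function(obj, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  write_report(tidy(obj), path, format)
}

#' @export
write_report.run_summary <- function(obj, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format != "json") abort("a run summary is written as JSON")
  payload <- unclass(obj)
  payload$version <- as.character(utils::packageVersion("clustermod"))
  payload$config_hash <- config_hash(obj$config)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(path)
}

# Stable hash of a config list: serialize deparsed key=value lines and sum a
# simple polynomial rolling hash. Enough to detect config drift between runs
# without pulling in a digest dependency.
config_hash <- function(config) {
  flat <- unlist(config, use.names = TRUE)
  txt <- paste(names(flat), as.character(flat), sep = "=", collapse = ";")
  bytes <- as.integer(charToRaw(txt))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
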