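# Machine-readable reports: deterministic JSON/CSV serialization of
# pipeline outputs together with the configuration, seed and input
# digests that produced them.

md5_text <- function(text) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(text, f)
  unname(tools::md5sum(f))
}

# sort names recursively so serialization has stable key ordering
sort_keys <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x) && !is.null(names(x)) && all(nzchar(names(x)))) {
    x <- x[order(names(x))]
    return(lapply(x, sort_keys))
  }
  if (is.list(x)) return(lapply(x, sort_keys))
  x
}

#' Render pipeline results as a report
#'
#' Serializes any stage's outputs together with the analysis
#' configuration, its seed, and MD5 digests of the input texts. JSON
#' output has stable (sorted) key ordering, so identical inputs and
#' configuration yield byte-identical reports.
#'
#' @param results Named list (JSON) or data frame (CSV) of stage outputs.
#' @param format `"json"` or `"csv"`.
#' @param config Optional [analysis_config()] recorded in the report.
#' @param inputs Optional named character vector of raw input texts;
#'   their MD5 digests are recorded.
#' @return Report text.
#' @export
render_report <- function(results, format = c("json", "csv"),
                          config = NULL, inputs = NULL) {
  format <- match.arg(format)
  digests <- if (!is.null(inputs))
    as.list(vapply(inputs, md5_text, "")) else NULL
  if (format == "json") {
    body <- list(
      config = if (!is.null(config)) unclass(config) else NULL,
      seed = if (!is.null(config)) config$seed else NULL,
      digests = digests,
      results = results)
    body <- body[!vapply(body, is.null, TRUE)]
    paste0(jsonlite::toJSON(sort_keys(body), auto_unbox = TRUE, digits = NA,
                            pretty = TRUE, null = "null", na = "null"),
           "\n")
  } else {
    if (!is.data.frame(results))
      results <- tryCatch(as.data.frame(results),
                          error = function(e)
                            stop_arg("CSV reports need tabular results"))
    header <- character(0)
    if (!is.null(config))
      header <- c(header,
                  sprintf("# config: %s",
                          paste(sprintf("%s=%s", names(unclass(config)),
                                        vapply(unclass(config), as.character, "")),
                                collapse = " ")))
    if (!is.null(digests))
      header <- c(header, sprintf("# digest %s: %s", names(digests),
                                  unlist(digests)))
    con <- textConnection("out", "w", local = TRUE)
    write.csv(results, con, row.names = FALSE)
    close(con)
    paste(c(header, out, ""), collapse = "\n")
  }
}
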