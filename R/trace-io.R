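# Trace readers/writers: CSV with a units header comment, and JSON.

#' Write a trace as CSV
#'
#' The first line is a comment with column units; columns are time, the
#' state variables, and the applied stimulus.
#'
#' @param trace a trace object.
#' @param path output file.
#' @param model optional `ode_system` supplying state units for the header.
#' @return path, invisibly.
#' @export
write_trace_csv <- function(trace, path, model = NULL) {
  df <- as.data.frame(trace)
  units <- c("ms", if (!is.null(model)) unname(model$state_units)
             else rep("", ncol(trace$states)),
             if (!is.null(trace$stimulus)) "uA/cm^2")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# units: ", paste(units, collapse = ",")), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a trace written by [write_trace_csv()]
#' @param path CSV file.
#' @return a trace object.
#' @export
read_trace_csv <- function(path) {
  first <- readLines(path, n = 1L)
  skip <- if (startsWith(first, "#")) 1L else 0L
  df <- utils::read.csv(path, skip = skip, check.names = FALSE)
  stim <- df[["i_stim"]]
  scols <- setdiff(names(df), c("time", "i_stim"))
  new_trace(df$time, as.matrix(df[scols]), stimulus = stim,
            metadata = list(source = path, v_name = scols[1]))
}

#' Write a trace as JSON (times, states, stimulus, metadata)
#' @inheritParams write_trace_csv
#' @return path, invisibly.
#' @export
write_trace_json <- function(trace, path) {
  payload <- list(times = trace$times,
                  state_names = colnames(trace$states),
                  states = unname(trace$states),
                  stimulus = trace$stimulus,
                  metadata = trace$metadata[setdiff(names(trace$metadata), "carry")])
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a trace written by [write_trace_json()]
#' @param path JSON file.
#' @return a trace object.
#' @export
read_trace_json <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  states <- matrix(p$states, ncol = length(p$state_names),
                   dimnames = list(NULL, p$state_names))
  new_trace(p$times, states, stimulus = p$stimulus,
            metadata = as.list(p$metadata))
}
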