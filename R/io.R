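# Trace CSV + JSON-sidecar input/output. The CSV carries the samples at
# full precision; the sidecar carries the protocol annotation, which is
# validated against the protocol invariants on read.

#' Write and read fluorescence traces
#'
#' Traces are stored as a CSV with the exact header `time_s,f495,f440`
#' (period decimal separator, UTF-8, one row per sample, full double
#' precision) plus a JSON sidecar of the same base name holding the
#' protocol segments and sampling plan.
#'
#' @param trace a [fluorescence_trace()].
#' @param path CSV path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return `write_trace()` returns `path` invisibly; `read_trace()`
#'   returns a [fluorescence_trace()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "phiflux_fluor"))
  lines <- c("time_s,f495,f440",
             sprintf("%.17g,%.17g,%.17g",
                     trace$time_s, trace$f495, trace$f440))
  writeLines(lines, path, useBytes = TRUE)
  write_protocol(trace_protocol(trace), sidecar_path(path))
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path))
    stop("format error: ", path, ": file not found", call. = FALSE)
  hdr <- readLines(path, n = 1)
  if (!identical(hdr, "time_s,f495,f440"))
    stop("format error: ", path, ": line 1: header must be exactly ",
         "'time_s,f495,f440' (got '", hdr, "')", call. = FALSE)
  d <- utils::read.csv(path, colClasses = "numeric")
  if (anyNA(d))
    stop("format error: ", path, ": line ",
         which(rowSums(is.na(d)) > 0)[1] + 1, ": non-numeric value",
         call. = FALSE)
  if (any(diff(d$time_s) <= 0))
    stop("format error: ", path, ": line ",
         which(diff(d$time_s) <= 0)[1] + 2,
         ": time_s not strictly increasing", call. = FALSE)
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("format error: missing annotation sidecar ", sc, call. = FALSE)
  fluorescence_trace(d$time_s, d$f495, d$f440, read_protocol(sc))
}

#' Write and read protocol annotations as JSON
#'
#' @param protocol a [protocol_spec()].
#' @param path JSON path.
#' @return `read_protocol()` returns a validated [protocol_spec()].
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "phiflux_protocol"))
  jsonlite::write_json(list(segments = protocol$segments,
                            sampling = protocol$sampling),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  if (!file.exists(path))
    stop("format error: ", path, ": file not found", call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$segments))
    stop("format error: ", path, ": no 'segments' entry", call. = FALSE)
  protocol_spec(as.data.frame(obj$segments),
                if (!is.null(obj$sampling)) as.data.frame(obj$sampling))
}

sidecar_path <- function(path)
  paste0(tools::file_path_sans_ext(path), ".json")

#' Read a chromatogram peak-height table
#'
#' Tab-separated table with columns `sample_id`, `test_a`, `test_b`,
#' `gdna_a`, `gdna_b` and optionally `material` (`cdna` or `faire`).
#'
#' @param path TSV path.
#' @return data.frame suitable for [cohort_imbalance()] (filter by
#'   `material` first when both assay types are present).
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path))
    stop("format error: ", path, ": file not found", call. = FALSE)
  d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "test_a", "test_b", "gdna_a", "gdna_b")
  if (!all(need %in% names(d)))
    stop("format error: ", path, ": columns must include ",
         paste(need, collapse = ", "), call. = FALSE)
  d
}
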