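#' Write an ensemble of traces as TSV files plus a manifest
#'
#' One file per trace with columns `frame`, `donor`, `acceptor`
#' (tab-separated, header row, '.' decimal separator, full double
#' precision), and `manifest.tsv` with `trace_id`, `file`, and
#' `true_pattern` when the traces are synthetic.
#'
#' @param traces list of `fluorescence_trace` objects (e.g. from
#'   [simulate_trace_ensemble()]).
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest data.frame.
#' @export
write_traces <- function(traces, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  man <- attr(traces, "manifest")
  ids <- if (!is.null(man)) man$trace_id
         else sprintf("trace_%05d", seq_along(traces))
  patterns <- if (!is.null(man)) man$true_pattern
              else rep(NA_character_, length(traces))
  files <- paste0(ids, ".tsv")
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    write_table_checked(
      data.frame(frame = tr$frames, donor = tr$donor,
                 acceptor = tr$acceptor),
      file.path(dir, files[i]))
  }
  manifest <- data.frame(trace_id = ids, file = files,
                         true_pattern = patterns,
                         stringsAsFactors = FALSE)
  write_table_checked(manifest, file.path(dir, "manifest.tsv"))
  invisible(manifest)
}

#' Read an ensemble of traces written by [write_traces()]
#'
#' @param dir directory containing `manifest.tsv` and the per-trace
#'   TSV files.
#' @return A list of `fluorescence_trace` objects with a `manifest`
#'   attribute.
#' @export
read_traces <- function(dir) {
  manifest <- read_table_checked(file.path(dir, "manifest.tsv"),
                                 c("trace_id", "file"))
  traces <- lapply(seq_len(nrow(manifest)), function(i) {
    df <- read_table_checked(file.path(dir, manifest$file[i]),
                             c("frame", "donor", "acceptor"))
    if (nrow(df) > 0L && !identical(as.integer(df$frame),
                                    0:(nrow(df) - 1L))) {
      stop(sprintf("%s: frames must be contiguous from 0",
                   manifest$file[i]), call. = FALSE)
    }
    structure(list(frames = as.integer(df$frame), donor = df$donor,
                   acceptor = df$acceptor,
                   metadata = list(trace_id = manifest$trace_id[i])),
              class = "fluorescence_trace")
  })
  attr(traces, "manifest") <- manifest
  traces
}

#' Write a data.frame as TSV at full double precision
#'
#' @param df data.frame.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_table_checked <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  out <- df
  out[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV, checking that required columns are present and numeric
#' columns parse cleanly
#'
#' @param path input path.
#' @param required character vector of required column names.
#' @return A data.frame; an empty file yields a zero-row data.frame
#'   with the required columns.
#' @export
read_table_checked <- function(path, required = character(0)) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  if (file.size(path) == 0L) {
    df <- as.data.frame(stats::setNames(
      replicate(length(required), numeric(0), simplify = FALSE),
      required))
    return(df)
  }
  df <- tryCatch(
    utils::read.delim(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE,
                      colClasses = NA, check.names = FALSE),
    error = function(e) stop(sprintf("malformed TSV %s: %s", path,
                                     conditionMessage(e)),
                             call. = FALSE))
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  num_expected <- intersect(required,
                            c("frame", "donor", "acceptor",
                              "concentration_nM", "repaired_fraction",
                              "x", "y", "z", "spots_before",
                              "spots_after", "linker_nt"))
  for (col in num_expected) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]
      stop(sprintf("%s: non-numeric value in column '%s' at data line %d",
                   path, col, if (is.na(bad)) 1L else bad),
           call. = FALSE)
    }
  }
  df
}
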