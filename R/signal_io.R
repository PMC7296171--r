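#' @title Channel layouts, recordings and epoch sets
#' @name signal_io
#' @description Constructors, validators and on-disk formats for the core
#'   data containers: electrode layouts (`.sfp`-style "name x y z" files),
#'   multichannel recordings (delimited matrix plus JSON sidecar, or the
#'   named-array container), and epoch sets cut from a recording.
NULL

#' Construct an electrode layout
#'
#' A layout holds ordered channel names from the 10-20 nomenclature and
#' head-centered 3-D positions. Only relative geometry is consumed
#' downstream (distance-based mixing gains, scalp topographies), so the
#' length unit is arbitrary. Convention: +x right, +y anterior (nose),
#' +z up through the vertex.
#'
#' @param names character vector of unique channel labels.
#' @param positions numeric matrix, one row per channel, columns x, y, z.
#' @return An object of class `channel_layout` with elements `names` and
#'   `positions`.
#' @examples
#' channel_layout(c("Cz", "Fz"), rbind(c(0, 0, 1), c(0, 0.7, 0.7)))
#' @export
channel_layout <- function(names, positions) {
  names <- as.character(names)
  positions <- as.matrix(positions)
  if (length(names) < 2L)
    stop("layout error: at least 2 channels required", call. = FALSE)
  if (anyDuplicated(names))
    stop("layout error: duplicate channel name '",
         names[duplicated(names)][1L], "'", call. = FALSE)
  if (nrow(positions) != length(names) || ncol(positions) != 3L)
    stop("layout error: positions must be a ", length(names), "x3 matrix",
         call. = FALSE)
  storage.mode(positions) <- "double"
  if (!all(is.finite(positions)))
    stop("layout error: non-finite electrode position", call. = FALSE)
  dimnames(positions) <- list(names, c("x", "y", "z"))
  structure(list(names = names, positions = positions),
            class = "channel_layout")
}

#' @export
print.channel_layout <- function(x, ...) {
  cat("<channel_layout> ", length(x$names), " channels: ",
      paste(utils::head(x$names, 8L), collapse = " "),
      if (length(x$names) > 8L) " ..." else "", "\n", sep = "")
  invisible(x)
}

#' Read an electrode layout from an .sfp-style file
#'
#' One record per line: `name x y z`, whitespace-separated. Blank lines and
#' lines starting with `#` are ignored.
#'
#' @param path path to the layout file.
#' @return A [channel_layout()].
#' @export
read_channel_layout <- function(path) {
  if (!file.exists(path)) stop("layout error: no such file: ", path,
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 2L)
    stop("layout error: fewer than 2 channel records in ", path,
         call. = FALSE)
  parts <- strsplit(lines, "[ \t]+")
  bad <- which(vapply(parts, length, 1L) != 4L)
  if (length(bad))
    stop("layout error: line ", bad[1L], " does not have 4 fields",
         call. = FALSE)
  nm <- vapply(parts, `[[`, "", 1L)
  xyz <- t(vapply(parts, function(p) {
    v <- suppressWarnings(as.numeric(p[2:4]))
    if (anyNA(v)) stop("layout error: non-numeric coordinate for channel '",
                       p[[1L]], "'", call. = FALSE)
    v
  }, numeric(3L)))
  channel_layout(nm, xyz)
}

#' Write an electrode layout to an .sfp-style file
#'
#' @param layout a [channel_layout()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_channel_layout <- function(layout, path) {
  stopifnot(inherits(layout, "channel_layout"))
  writeLines(sprintf("%s %.17g %.17g %.17g", layout$names,
                     layout$positions[, 1L], layout$positions[, 2L],
                     layout$positions[, 3L]), path)
  invisible(path)
}

#' Construct a multichannel recording
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param fs sampling rate in Hz.
#' @param layout optional [channel_layout()]; if given, its channel count
#'   must match `nrow(data)`.
#' @return An object of class `recording` with elements `data`, `fs`,
#'   `layout`.
#' @export
recording <- function(data, fs, layout = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("recording error: fs must be a positive number", call. = FALSE)
  if (!all(is.finite(data)))
    stop("recording error: non-finite sample values", call. = FALSE)
  if (!is.null(layout)) {
    stopifnot(inherits(layout, "channel_layout"))
    if (length(layout$names) != nrow(data))
      stop("layout error: recording has ", nrow(data),
           " channels but layout has ", length(layout$names), call. = FALSE)
    rownames(data) <- layout$names
  }
  structure(list(data = data, fs = as.numeric(fs), layout = layout),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat("<recording> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$fs, " Hz (",
      round(ncol(x$data) / x$fs, 2), " s)\n", sep = "")
  invisible(x)
}

#' Read a recording from disk
#'
#' Two formats are supported. `"delimited"` is a whitespace-delimited
#' channels-x-samples matrix with a JSON sidecar `<path>.json` holding
#' `fs` and `channel_names`. `"container"` is the named-array container
#' written by [write_recording()] (see [write_container()]); it
#' round-trips sample values bit-exactly.
#'
#' @param path data file path.
#' @param format `"delimited"` or `"container"`.
#' @param layout optional [channel_layout()] to attach (channel counts must
#'   agree).
#' @return A [recording()].
#' @export
read_recording <- function(path, format = c("delimited", "container"),
                           layout = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("format error: no such file: ", path,
                               call. = FALSE)
  if (format == "delimited") {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar))
      stop("format error: missing metadata sidecar ", sidecar, call. = FALSE)
    meta <- jsonlite::fromJSON(sidecar)
    if (is.null(meta$fs))
      stop("format error: sidecar lacks 'fs'", call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    rows <- strsplit(trimws(lines), "[ \t,]+")
    n <- length(rows[[1L]])
    dat <- matrix(NA_real_, length(rows), n)
    for (r in seq_along(rows)) {
      if (length(rows[[r]]) != n)
        stop("format error: row ", r, " has ", length(rows[[r]]),
             " values, expected ", n, call. = FALSE)
      v <- suppressWarnings(as.numeric(rows[[r]]))
      if (anyNA(v))
        stop("format error: non-numeric token at row ", r, ", column ",
             which(is.na(v))[1L], call. = FALSE)
      dat[r, ] <- v
    }
    if (!is.null(meta$channel_names) &&
        length(meta$channel_names) != nrow(dat))
      stop("format error: sidecar names ", length(meta$channel_names),
           " channels, data has ", nrow(dat), call. = FALSE)
    recording(dat, meta$fs, layout)
  } else {
    arrs <- read_container(path)
    if (is.null(arrs$data) || is.null(arrs$fs))
      stop("format error: container lacks 'data'/'fs' arrays", call. = FALSE)
    recording(arrs$data, as.numeric(arrs$fs), layout)
  }
}

#' Write a recording to disk
#'
#' @inheritParams read_recording
#' @param rec a [recording()].
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("delimited", "container")) {
  stopifnot(inherits(rec, "recording"))
  format <- match.arg(format)
  if (format == "delimited") {
    con <- file(path, "w")
    on.exit(close(con))
    for (r in seq_len(nrow(rec$data)))
      writeLines(paste(sprintf("%.17g", rec$data[r, ]), collapse = "\t"), con)
    meta <- list(fs = rec$fs)
    if (!is.null(rec$layout)) meta$channel_names <- rec$layout$names
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  } else {
    write_container(path, list(data = rec$data, fs = rec$fs))
  }
  invisible(path)
}

#' Cut fixed-length epochs out of a recording
#'
#' Epoch t is the exact slice `rec$data[, onset_t:(onset_t + length - 1)]`
#' (1-based, inclusive). Epochs with adjacent onsets therefore concatenate
#' back to the parent segment sample for sample.
#'
#' @param rec a [recording()].
#' @param onsets integer vector of 1-based onset samples.
#' @param length epoch length in samples.
#' @param labels optional character vector of per-trial labels.
#' @return An object of class `epoch_set`: `epochs` (trials x channels x
#'   samples array), `fs`, `onsets`, `labels`, `layout`.
#' @export
segment_epochs <- function(rec, onsets, length, labels = NULL) {
  stopifnot(inherits(rec, "recording"))
  onsets <- as.integer(onsets)
  length <- as.integer(length)
  N <- ncol(rec$data)
  if (length < 1L) stop("bounds error: epoch length must be >= 1",
                        call. = FALSE)
  bad <- onsets < 1L | (onsets + length - 1L) > N
  if (any(bad))
    stop("bounds error: onset ", onsets[bad][1L], " with length ", length,
         " exceeds recording of ", N, " samples", call. = FALSE)
  if (!is.null(labels) && base::length(labels) != base::length(onsets))
    stop("bounds error: one label per onset required", call. = FALSE)
  ep <- array(0, c(base::length(onsets), nrow(rec$data), length))
  for (t in seq_along(onsets))
    ep[t, , ] <- rec$data[, onsets[t]:(onsets[t] + length - 1L)]
  structure(list(epochs = ep, fs = rec$fs, onsets = onsets,
                 labels = labels, layout = rec$layout),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$epochs)
  cat("<epoch_set> ", d[1L], " trials x ", d[2L], " channels x ", d[3L],
      " samples @ ", x$fs, " Hz\n", sep = "")
  invisible(x)
}

# concatenate epochs along time into a channels x (trials*samples) matrix
epochs_to_matrix <- function(eps) {
  stopifnot(inherits(eps, "epoch_set"))
  d <- dim(eps$epochs)
  out <- matrix(0, d[2L], d[1L] * d[3L])
  for (t in seq_len(d[1L]))
    out[, ((t - 1L) * d[3L] + 1L):(t * d[3L])] <- eps$epochs[t, , ]
  out
}

#' Write named numeric arrays to a single-file container
#'
#' The container is a JSON document holding each array's dimensions and
#' values. Values are serialised as C99 `%.17g` strings, which round-trip
#' IEEE doubles bit-exactly, so `read_container(write_container(x)) `
#' reproduces every array identically. Complex arrays are stored as
#' separate real and imaginary parts.
#'
#' @param path output path.
#' @param arrays named list of numeric or complex vectors/matrices/arrays.
#' @return `path`, invisibly.
#' @export
write_container <- function(path, arrays) {
  if (is.null(names(arrays)) || any(!nzchar(names(arrays))))
    stop("container error: all arrays must be named", call. = FALSE)
  enc <- lapply(arrays, function(a) {
    d <- dim(a)
    if (is.null(d)) d <- length(a)
    if (is.complex(a)) {
      list(dim = as.integer(d), type = "complex",
           re = sprintf("%.17g", Re(a)), im = sprintf("%.17g", Im(a)))
    } else {
      list(dim = as.integer(d), type = "double",
           data = sprintf("%.17g", as.numeric(a)))
    }
  })
  jsonlite::write_json(list(container = "eegbss-arrays/1", arrays = enc),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a named-array container written by [write_container()]
#'
#' @param path container path.
#' @return Named list of arrays with dimensions restored.
#' @export
read_container <- function(path) {
  if (!file.exists(path)) stop("container error: no such file: ", path,
                               call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(doc$container) || !grepl("^eegbss-arrays/", doc$container[1L]))
    stop("container error: not an eegbss array container", call. = FALSE)
  lapply(doc$arrays, function(e) {
    d <- as.integer(e$dim)
    if (identical(e$type[1L], "complex")) {
      a <- complex(real = as.numeric(e$re), imaginary = as.numeric(e$im))
    } else {
      a <- as.numeric(e$data)
    }
    if (length(d) > 1L) dim(a) <- d
    a
  })
}
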