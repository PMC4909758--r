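#' Streamline tractograms in MRtrix TCK format
#'
#' A tractogram is an ordered collection of streamlines, each an n x 3 matrix
#' of world-space coordinates in millimetres (RAS convention: +x right,
#' +y anterior, +z superior). The TCK container stores a plain-text header
#' ("key: value" lines between a \code{mrtrix tracks} magic line and
#' \code{END}) followed by a stream of 32-bit float coordinate triplets in
#' which a (NaN,NaN,NaN) triplet closes each streamline and an
#' (Inf,Inf,Inf) triplet closes the file.
#'
#' Streamline coordinates are interpreted in the same world space as the
#' NIfTI affine of any companion label volume; no axis flips are applied on
#' read or write (TCK and NIfTI both define scanner/world-mm semantics --
#' unlike TrackVis TRK, which is not supported).
#'
#' @param streamlines list of numeric matrices, each with 3 columns and at
#'   least 2 rows; coordinates in world mm.
#' @param header named list of header metadata. \code{count} and
#'   \code{datatype} are maintained automatically.
#' @return An object of class \code{bg_tractogram}: a list with elements
#'   \code{streamlines} and \code{header}.
#' @examples
#' tr <- tractogram(list(cbind(c(0, 1), c(0, 0), c(0, 0))))
#' n_streamlines(tr)
#' @export
tractogram <- function(streamlines = list(), header = list()) {
  streamlines <- lapply(seq_along(streamlines), function(i) {
    m <- streamlines[[i]]
    if (is.data.frame(m)) m <- as.matrix(m)
    if (!is.matrix(m) || ncol(m) != 3L)
      stopf("streamline %d is not an n x 3 matrix", i)
    storage.mode(m) <- "double"
    if (nrow(m) < 2L)
      stopf("streamline %d has fewer than 2 points", i)
    if (!all(is.finite(m)))
      stopf("streamline %d contains non-finite coordinates", i)
    d <- m[-1L, , drop = FALSE] - m[-nrow(m), , drop = FALSE]
    if (any(rowSums(d * d) == 0))
      stopf("streamline %d has coincident consecutive points", i)
    dimnames(m) <- NULL
    m
  })
  header$count <- length(streamlines)
  header$datatype <- header$datatype %||% "Float32LE"
  structure(list(streamlines = streamlines, header = header),
            class = "bg_tractogram")
}

#' @rdname tractogram
#' @param x a \code{bg_tractogram}.
#' @export
n_streamlines <- function(x) length(x$streamlines)

#' @export
print.bg_tractogram <- function(x, ...) {
  np <- vapply(x$streamlines, nrow, 0L)
  cat(sprintf("TCK tractogram: %d streamlines, %d points total\n",
              length(np), sum(np)))
  invisible(x)
}

#' Read an MRtrix TCK track file
#'
#' Supports Float32LE and Float32BE payloads. The header \code{count} field,
#' when present, is checked against the number of streamlines actually
#' decoded; a mismatch or a payload ending without the Inf terminator raises
#' a corrupt-file error.
#'
#' @param path path to a \code{.tck} file.
#' @return A \code{\link{tractogram}}.
#' @export
read_tck <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  magic <- charToRaw("mrtrix tracks\n")
  if (length(bytes) < length(magic) ||
      !identical(bytes[seq_along(magic)], magic))
    stopf("not a TCK file (missing 'mrtrix tracks' magic line): %s", path)
  # Locate the header's END line in the raw bytes (the binary payload that
  # follows is not text-safe): first newline followed by "END\n".
  nl <- which(bytes == as.raw(0x0A))
  end_nl <- nl[nl + 4L <= length(bytes) &
                 bytes[nl + 1L] == as.raw(0x45) &   # E
                 bytes[nl + 2L] == as.raw(0x4E) &   # N
                 bytes[nl + 3L] == as.raw(0x44) &   # D
                 bytes[nl + 4L] == as.raw(0x0A)]
  if (length(end_nl) == 0L)
    stopf("corrupt TCK header (no END line): %s", path)
  hdr_lines <- strsplit(rawToChar(bytes[seq_len(end_nl[1L] - 1L)]),
                        "\n", fixed = TRUE)[[1L]]
  if (length(hdr_lines) == 0L ||
      !identical(trimws(hdr_lines[1L]), "mrtrix tracks"))
    stopf("not a TCK file (missing 'mrtrix tracks' magic line): %s", path)
  header <- list()
  offset <- NA_real_
  for (line in hdr_lines[-1L]) {
    kv <- regmatches(line, regexpr(":", line), invert = TRUE)[[1L]]
    if (length(kv) != 2L) next
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    if (key == "file") {
      part <- strsplit(val, "[[:space:]]+")[[1L]]
      offset <- as.numeric(part[length(part)])
    }
    header[[key]] <- if (is.null(header[[key]])) val else c(header[[key]], val)
  }
  if (!is.finite(offset) || offset >= length(bytes))
    stopf("corrupt TCK header (no valid 'file' offset): %s", path)
  dtype <- header$datatype %||% "Float32LE"
  endian <- switch(dtype,
                   Float32LE = "little",
                   Float32BE = "big",
                   stopf("unsupported TCK datatype '%s' (Float32LE/BE only)",
                         dtype))
  payload <- bytes[(offset + 1L):length(bytes)]
  if (length(payload) %% 4L != 0L)
    stopf("corrupt TCK payload (byte count not float-aligned): %s", path)
  raw_vals <- readBin(payload, "numeric", n = length(payload) %/% 4L,
                      size = 4L, endian = endian)
  if (length(raw_vals) %% 3L != 0L)
    stopf("corrupt TCK payload (byte count not a triplet multiple): %s", path)
  m <- matrix(raw_vals, ncol = 3L, byrow = TRUE)
  xs <- m[, 1L]
  term <- which(is.infinite(xs))
  if (length(term) == 0L)
    stopf("corrupt TCK payload (missing Inf terminator): %s", path)
  term <- term[1L]
  delim <- which(is.nan(xs[seq_len(term - 1L)]))
  starts <- c(1L, delim + 1L)
  ends <- c(delim - 1L, term - 1L)
  keep <- starts <= ends
  streamlines <- Map(function(s, e) m[s:e, , drop = FALSE],
                     starts[keep], ends[keep])
  if (!is.null(header$count)) {
    declared <- as.integer(header$count[[1L]])
    if (!is.na(declared) && declared != length(streamlines))
      stopf("corrupt TCK file: header count %d but %d streamlines decoded",
            declared, length(streamlines))
  }
  header$count <- length(streamlines)
  header$datatype <- dtype
  tractogram(streamlines, header)
}

#' Write a tractogram as an MRtrix TCK file
#'
#' Coordinates are written as Float32LE triplets, each streamline followed
#' by a NaN triplet and the stream closed by an Inf triplet, so the file is
#' readable by MRtrix, nibabel and \code{\link{read_tck}}. The header records
#' the generating tool and an optional configuration digest.
#'
#' An empty tractogram is valid and produces a zero-count file whose payload
#' is just the Inf terminator.
#'
#' @param x a \code{\link{tractogram}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_tck <- function(x, path) {
  stopifnot(inherits(x, "bg_tractogram"))
  header <- x$header
  header$count <- length(x$streamlines)
  header$datatype <- "Float32LE"
  if (is.null(header$bgtract_version))
    header$bgtract_version <- as.character(utils::packageVersion("bgtract"))
  keys <- setdiff(names(header), "file")
  lines <- unlist(lapply(keys, function(k)
    paste0(k, ": ", as.character(header[[k]]))))
  # The 'file' key records the payload byte offset, which depends on the
  # header's own length; grow the offset field until it is self-consistent.
  base_len <- nchar("mrtrix tracks\n", type = "bytes") +
    sum(nchar(lines, type = "bytes") + 1L) +
    nchar("file: . \nEND\n", type = "bytes")
  offset <- base_len
  repeat {
    total <- base_len + nchar(as.character(offset), type = "bytes")
    if (total == offset) break
    offset <- total
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(paste(c("mrtrix tracks", lines, paste0("file: . ", offset),
                        "END"), collapse = "\n"), "\n")
  writeChar(hdr, con, eos = NULL)
  nan3 <- rep(NaN, 3L)
  payload <- c(unlist(lapply(x$streamlines, function(m)
    c(t(m), nan3))), rep(Inf, 3L))
  writeBin(payload, con, size = 4L, endian = "little")
  invisible(path)
}
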