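#' Write a tractogram in MRtrix .tck format
#'
#' Emits the text header (`mrtrix tracks` magic line, key-value entries,
#' `file: . <offset>` byte offset, `END`), then Float32 little-endian
#' point triplets with a `(NaN, NaN, NaN)` triplet after each streamline
#' and an `(Inf, Inf, Inf)` terminator.
#'
#' @param tractogram a `tractogram`.
#' @param path output path.
#' @param provenance named character vector of extra header entries.
#' @return `path`, invisibly.
#' @export
write_tck <- function(tractogram, path, provenance = character()) {
  n <- length(tractogram)
  lines <- c("mrtrix tracks", "datatype: Float32LE",
             sprintf("count: %d", n))
  if (length(provenance))
    lines <- c(lines, paste0(names(provenance), ": ",
                             as.character(provenance)))
  # the offset depends on its own digit count; iterate until stable
  offset <- 0L
  repeat {
    hdr <- c(lines, sprintf("file: . %d", offset), "END")
    nb <- sum(nchar(hdr, type = "bytes") + 1L)
    if (nb == offset) break
    offset <- nb
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writLines <- paste0(c(lines, sprintf("file: . %d", offset), "END"), "\n")
  writeBin(charToRaw(paste(writLines, collapse = "")), con)
  for (m in tractogram$streamlines) {
    writeBin(as.numeric(t(m)), con, size = 4L, endian = "little")
    writeBin(as.numeric(rep(NaN, 3)), con, size = 4L, endian = "little")
  }
  writeBin(as.numeric(rep(Inf, 3)), con, size = 4L, endian = "little")
  invisible(path)
}

tck_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "tck_error", "error")))
}

#' Read an MRtrix .tck streamline file
#'
#' Parses the text header and the binary point stream: 3-float triplets
#' in the declared endianness, `(NaN,NaN,NaN)` separating streamlines and
#' `(Inf,Inf,Inf)` terminating the stream.  Points are world-mm
#' coordinates.
#'
#' @param path file path.
#' @param grid optional `volume_grid` to attach to the tractogram.
#' @return a `tractogram` (with the header key-values in the `header`
#'   field).
#' @export
read_tck <- function(path, grid = NULL) {
  if (!file.exists(path)) tck_error("file does not exist", "tck_error_io")
  raw <- readBin(path, "raw", n = file.size(path))
  nl <- which(raw == charToRaw("\n"))
  if (!length(nl)) tck_error("missing magic line", "tck_error_magic")
  first <- rawToChar(raw[seq_len(nl[1] - 1L)])
  if (!identical(trimws(first), "mrtrix tracks"))
    tck_error("missing 'mrtrix tracks' magic line", "tck_error_magic")
  # collect header lines until END
  header <- character()
  offset <- NA_integer_
  end_seen <- FALSE
  prev <- nl[1]
  for (k in nl[-1]) {
    line <- rawToChar(raw[(prev + 1L):(k - 1L)])
    prev <- k
    if (identical(trimws(line), "END")) { end_seen <- TRUE; break }
    header <- c(header, line)
    if (k > 4096L) break # header must terminate promptly
  }
  if (!end_seen) tck_error("header END line not found", "tck_error_end")
  kv <- strsplit(header, ":\\s*")
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = ": "), character(1))
  names(vals) <- keys
  datatype <- vals[["datatype"]]
  if (!datatype %in% c("Float32LE", "Float32BE"))
    tck_error(paste("unsupported datatype:", datatype),
              "tck_error_datatype")
  endian <- if (datatype == "Float32LE") "little" else "big"
  fileent <- vals[["file"]]
  off <- suppressWarnings(as.integer(sub("^\\.\\s+", "", fileent)))
  if (is.na(off)) tck_error("malformed file offset entry", "tck_error_end")
  nbytes <- length(raw) - off
  if (nbytes < 12L || nbytes %% 12L != 0L)
    tck_error("truncated binary section", "tck_error_truncated")
  v <- readBin(raw[(off + 1L):length(raw)], "numeric", n = nbytes / 4L,
               size = 4L, endian = endian)
  triplets <- matrix(v, ncol = 3L, byrow = TRUE)
  inf_rows <- which(!is.na(triplets[, 1]) & is.infinite(triplets[, 1]))
  if (!length(inf_rows))
    tck_error("missing (Inf,Inf,Inf) terminator", "tck_error_truncated")
  triplets <- triplets[seq_len(inf_rows[1] - 1L), , drop = FALSE]
  sep <- is.nan(triplets[, 1])
  streamlines <- list()
  start <- 1L
  for (i in seq_len(nrow(triplets))) {
    if (sep[i]) {
      if (i > start)
        streamlines[[length(streamlines) + 1L]] <-
          triplets[start:(i - 1L), , drop = FALSE]
      start <- i + 1L
    }
  }
  if (start <= nrow(triplets))
    streamlines[[length(streamlines) + 1L]] <-
      triplets[start:nrow(triplets), , drop = FALSE]
  declared <- suppressWarnings(as.integer(vals[["count"]]))
  if (is.na(declared) || declared != length(streamlines))
    tck_error(sprintf("count mismatch: header %s, read %d",
                      vals[["count"]], length(streamlines)),
              "tck_error_count")
  tg <- new_tractogram(streamlines, grid, params = NULL,
                       n_requested = declared, seeding = NULL,
                       status_counts = NULL, attempts = NA,
                       budget_exhausted = FALSE)
  tg$header <- vals
  tg
}

#' Read per-streamline weights (SIFT2 text convention)
#'
#' Whitespace- or newline-separated ASCII floats, one per streamline in
#' .tck order.
#'
#' @param path file path.
#' @param n expected number of weights.
#' @return numeric vector of length `n`.
#' @export
read_weights <- function(path, n) {
  w <- scan(path, what = numeric(), quiet = TRUE)
  if (length(w) != n)
    stop(sprintf("weight count mismatch: expected %d, found %d", n,
                 length(w)))
  if (any(!is.finite(w)) || any(w < 0))
    stop("weights must be finite and >= 0")
  w
}

#' Write per-streamline weights (SIFT2 text convention)
#' @param weights numeric vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path) {
  writeLines(paste(sprintf("%.17g", as.numeric(weights)), collapse = " "),
             path)
  invisible(path)
}
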