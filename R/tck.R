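#' Read an MRtrix TCK tractogram
#'
#' Parses the ASCII key:value header (must begin with the `mrtrix tracks`
#' magic line) and the little-endian float32 point stream, in which
#' streamlines are delimited by a NaN triplet and the stream is terminated by
#' an Inf triplet. Coordinates are scanner-space mm.
#'
#' @param path Path to a `.tck` file.
#' @param space_id Spatial reference tag to attach to the result (TCK files
#'   do not carry one; default `"unknown"`).
#' @return A [tractogram()].
#' @export
read_tractogram <- function(path, space_id = "unknown") {
  if (!file.exists(path))
    stop(sprintf("TCK file not found: '%s'", path), call. = FALSE)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  magic <- rawToChar(raw[seq_len(min(13L, length(raw)))])
  if (!identical(magic, "mrtrix tracks"))
    stop(sprintf("'%s' is not a TCK file: missing 'mrtrix tracks' magic header", path),
         call. = FALSE)
  end_pat <- charToRaw("\nEND\n")
  end_at <- NA_integer_
  limit <- min(length(raw) - 4L, 65536L)
  for (i in seq_len(max(limit, 0L))) {
    if (identical(raw[i:(i + 4L)], end_pat)) { end_at <- i; break }
  }
  if (is.na(end_at))
    stop(sprintf("corrupt TCK header in '%s': no END marker", path), call. = FALSE)
  header <- rawToChar(raw[seq_len(end_at - 1L)])
  lines <- strsplit(header, "\n", fixed = TRUE)[[1]][-1L]
  kv <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  keys <- vapply(kv, function(m) if (length(m) == 3L) trimws(m[2]) else NA_character_,
                 character(1))
  vals <- vapply(kv, function(m) if (length(m) == 3L) trimws(m[3]) else NA_character_,
                 character(1))
  getval <- function(key) vals[match(key, keys)]
  datatype <- getval("datatype")
  if (is.na(datatype) || !identical(datatype, "Float32LE"))
    stop(sprintf("unsupported TCK datatype '%s' (only Float32LE)", datatype),
         call. = FALSE)
  filefield <- getval("file")
  if (is.na(filefield) || !grepl("^\\. [0-9]+$", filefield))
    stop("corrupt TCK header: missing or malformed 'file' field", call. = FALSE)
  offset <- as.integer(sub("^\\. ", "", filefield))
  if (offset > length(raw))
    stop(sprintf("corrupt TCK file: data offset %d beyond file size %d",
                 offset, length(raw)), call. = FALSE)
  body <- raw[(offset + 1L):length(raw)]
  nfloat <- length(body) %/% 4L
  if (length(body) %% 4L != 0L)
    stop(sprintf("truncated TCK stream in '%s': %d trailing bytes at byte offset %d",
                 path, length(body) %% 4L, offset + 4L * nfloat), call. = FALSE)
  v <- readBin(body, "double", n = nfloat, size = 4L, endian = "little")
  if (nfloat %% 3L != 0L)
    stop(sprintf("truncated TCK stream in '%s': incomplete point triplet at byte offset %d",
                 path, offset + 4L * (nfloat - nfloat %% 3L)), call. = FALSE)
  pts <- matrix(v, ncol = 3L, byrow = TRUE)
  is_nan <- rowSums(is.nan(pts)) > 0L
  is_inf <- is.infinite(pts[, 1]) & !is_nan
  term <- which(is_inf)
  if (length(term) == 0L)
    stop(sprintf("truncated TCK stream in '%s': no Inf terminator before byte offset %d",
                 path, offset + 4L * nfloat), call. = FALSE)
  pts <- pts[seq_len(term[1L] - 1L), , drop = FALSE]
  is_nan <- is_nan[seq_len(term[1L] - 1L)]
  breaks <- which(is_nan)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks - 1L, nrow(pts))
  keep <- starts <= ends
  sl <- mapply(function(a, b) pts[a:b, , drop = FALSE],
               starts[keep], ends[keep], SIMPLIFY = FALSE)
  tractogram(sl, space_id = space_id)
}

#' Write an MRtrix TCK tractogram
#'
#' Writes the standard `mrtrix tracks` header followed by little-endian
#' float32 point triplets, NaN-delimited per streamline and Inf-terminated.
#' Point values are stored at float32 precision.
#'
#' @param t A [tractogram()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tractogram <- function(t, path) {
  stopifnot(inherits(t, "tractogram"))
  n <- length(t)
  fixed <- c("mrtrix tracks",
             "datatype: Float32LE",
             sprintf("count: %d", n),
             "tractlesion_space: " %+% t$space_id)
  # the 'file' field records the byte offset of the binary section, which
  # depends on the header length including itself; iterate until stable
  offset <- 0L
  for (it in 1:5) {
    hdr <- paste(c(fixed, sprintf("file: . %d", offset), "END"), collapse = "\n")
    hdr <- paste0(hdr, "\n")
    if (nchar(hdr, type = "bytes") == offset) break
    offset <- nchar(hdr, type = "bytes")
  }
  vals <- unlist(lapply(t$streamlines, function(s) c(t(s), NaN, NaN, NaN)))
  vals <- c(vals, Inf, Inf, Inf)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL)
  writeBin(vals, con, size = 4L, endian = "little")
  invisible(path)
}

`%+%` <- function(a, b) paste0(a, b)
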