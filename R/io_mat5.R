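# Minimal MAT v5 (Level 5) container support: uncompressed numeric 2-D
# arrays only. Enough to exchange CapnoBase-style per-subject containers
# (PPG waveform + breath-label vectors); compressed or cell/struct elements
# are rejected with a format error.

.mat5_types <- c(miINT8 = 1L, miUINT8 = 2L, miINT16 = 3L, miUINT16 = 4L,
                 miINT32 = 5L, miUINT32 = 6L, miSINGLE = 7L, miDOUBLE = 9L,
                 miMATRIX = 14L, miCOMPRESSED = 15L, miUTF8 = 16L)

#' Read a minimal MAT v5 container
#'
#' Parses uncompressed numeric matrices (double/single/integer classes) from
#' a Level 5 MAT-file and returns them as a named list of numeric matrices.
#'
#' @param path MAT-file path.
#' @return Named list of numeric matrices.
#' @export
read_mat5 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 128L)
  if (length(header) < 128L) {
    stop("format error: MAT header truncated", call. = FALSE)
  }
  endian_ind <- rawToChar(header[127:128])
  endian <- if (endian_ind == "IM") "little" else if (endian_ind == "MI") "big"
  else stop("format error: not a MAT v5 file", call. = FALSE)

  out <- list()
  repeat {
    tag <- readBin(con, "integer", 2L, size = 4L, endian = endian)
    if (length(tag) < 2L) break
    type <- tag[1L]; nbytes <- tag[2L]
    if (type == .mat5_types[["miCOMPRESSED"]]) {
      stop("format error: compressed MAT elements are not supported",
           call. = FALSE)
    }
    if (type != .mat5_types[["miMATRIX"]]) {
      # skip unknown top-level element (padded to 8 bytes)
      seek(con, where = nbytes + (-nbytes %% 8), origin = "current")
      next
    }
    payload <- readBin(con, "raw", nbytes)
    pad <- -nbytes %% 8
    if (pad > 0) readBin(con, "raw", pad)
    el <- .mat5_parse_matrix(payload, endian)
    if (!is.null(el)) out[[el$name]] <- el$value
  }
  out
}

.mat5_parse_matrix <- function(raw, endian) {
  pos <- 0L
  next_sub <- function() {
    first <- readBin(raw[pos + 1:4], "integer", 1L, 4L, endian = endian)
    small_len <- bitwAnd(bitwShiftR(first, 16L), 0xffffL)
    if (small_len > 0L) {
      type <- bitwAnd(first, 0xffffL)
      data <- raw[pos + 5:8][seq_len(small_len)]
      pos <<- pos + 8L
    } else {
      type <- first
      len <- readBin(raw[pos + 5:8], "integer", 1L, 4L, endian = endian)
      data <- if (len > 0) raw[pos + 8L + seq_len(len)] else raw[0]
      pos <<- pos + 8L + len + (-len %% 8L)
    }
    list(type = type, data = data)
  }
  flags <- next_sub()
  class_id <- as.integer(flags$data[1L])
  dims_sub <- next_sub()
  dims <- readBin(dims_sub$data, "integer", length(dims_sub$data) %/% 4L,
                  4L, endian = endian)
  name_sub <- next_sub()
  name <- rawToChar(name_sub$data)
  if (!class_id %in% c(6L, 7L, 8L:15L)) return(NULL)  # numeric classes only
  data_sub <- next_sub()
  vals <- .mat5_decode_numeric(data_sub$type, data_sub$data, endian)
  if (length(dims) == 2L) dim(vals) <- dims
  list(name = name, value = vals)
}

.mat5_decode_numeric <- function(type, data, endian) {
  tt <- .mat5_types
  switch(as.character(type),
    "9" = readBin(data, "double", length(data) %/% 8L, 8L, endian = endian),
    "7" = readBin(data, "double", length(data) %/% 4L, 4L, endian = endian),
    "5" = as.numeric(readBin(data, "integer", length(data) %/% 4L, 4L,
                             endian = endian)),
    "6" = as.numeric(readBin(data, "integer", length(data) %/% 4L, 4L,
                             endian = endian)),
    "3" = as.numeric(readBin(data, "integer", length(data) %/% 2L, 2L,
                             signed = TRUE, endian = endian)),
    "4" = as.numeric(readBin(data, "integer", length(data) %/% 2L, 2L,
                             signed = FALSE, endian = endian)),
    "1" = as.numeric(readBin(data, "integer", length(data), 1L,
                             signed = TRUE)),
    "2" = as.numeric(readBin(data, "integer", length(data), 1L,
                             signed = FALSE)),
    stop(sprintf("format error: unsupported MAT data type %d", type),
         call. = FALSE)
  )
}

#' Write a minimal MAT v5 container
#'
#' Writes a named list of numeric vectors/matrices as uncompressed
#' double-precision MAT v5 elements (little-endian).
#'
#' @param vars Named list of numeric vectors or matrices.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mat5 <- function(vars, path) {
  stopifnot(is.list(vars), length(names(vars)) == length(vars),
            all(nzchar(names(vars))))
  con <- file(path, "wb")
  on.exit(close(con))
  desc <- sprintf("MATLAB 5.0 MAT-file, written by ppgrr on %s",
                  format(Sys.time(), "%Y-%m-%d"))
  header <- charToRaw(desc)
  header <- c(header, rep(as.raw(0x20), 116L - length(header)))
  writeBin(header, con)
  writeBin(rep(as.raw(0), 8L), con)                      # subsys offset
  writeBin(as.raw(c(0x00, 0x01)), con)                   # version 0x0100
  writeBin(charToRaw("IM"), con)                         # endian indicator
  for (nm in names(vars)) {
    writeBin(.mat5_encode_matrix(nm, vars[[nm]]), con)
  }
  invisible(path)
}

.mat5_encode_matrix <- function(name, value) {
  v <- as.numeric(value)
  dims <- if (is.matrix(value)) dim(value) else c(length(v), 1L)
  sub_el <- function(type, data_raw) {
    len <- length(data_raw)
    c(writeBin(c(type, len), raw(), size = 4L, endian = "little"),
      data_raw, rep(as.raw(0), -len %% 8L))
  }
  flags <- writeBin(c(6L, 0L), raw(), size = 4L, endian = "little")  # mxDOUBLE
  body <- c(
    sub_el(6L, flags),
    sub_el(5L, writeBin(as.integer(dims), raw(), size = 4L,
                        endian = "little")),
    sub_el(1L, charToRaw(name)),
    sub_el(9L, writeBin(v, raw(), size = 8L, endian = "little"))
  )
  c(writeBin(c(14L, length(body)), raw(), size = 4L, endian = "little"),
    body)
}
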