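# Raster I/O: PNG and PGM readers producing [0, 1] luminance matrices, a
# 16-bit PGM writer for real-valued response maps, and a binary-PNG writer
# for edge maps.

#' Load a grayscale image
#'
#' Reads a PNG or PGM file into a luminance matrix in \[0, 1\]. Color PNGs
#' are converted with the rec. 601 weights (0.299, 0.587, 0.114); an alpha
#' channel is dropped.
#'
#' @param path file path (`.png`, `.pgm`).
#' @return numeric matrix in \[0, 1\].
#' @export
load_gray_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- tryCatch(png::readPNG(path),
                  error = function(e) stop("cannot read image: ", path, " (",
                                           conditionMessage(e), ")"))
    if (length(dim(a)) == 3L) {
      if (dim(a)[3L] >= 3L)
        a <- 0.299 * a[, , 1L] + 0.587 * a[, , 2L] + 0.114 * a[, , 3L]
      else a <- a[, , 1L]
    }
    img <- a
  } else if (ext == "pgm") {
    img <- read_pgm(path)
  } else stop("unsupported image format: ", path)
  img <- pmin(pmax(img, 0), 1)
  check_gray(img)
  img
}

#' Read a PGM file
#'
#' Supports ASCII (P2) and binary (P5) portable graymaps with maxval up to
#' 65535; values are rescaled to \[0, 1\].
#'
#' @param path file path.
#' @return numeric matrix in \[0, 1\].
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || ch == "") break
      if (ch == "#") {                       # comment to end of line
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "" || ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) break else next
      }
      tok <- paste0(tok, ch)
    }
    tok
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  w <- as.integer(read_token()); h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  if (anyNA(c(w, h, maxval)) || w < 1L || h < 1L || maxval < 1L)
    stop("malformed PGM header: ", path)
  n <- w * h
  if (magic == "P2") {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE)
  } else {
    bytes_per <- if (maxval > 255L) 2L else 1L
    raw <- readBin(con, "raw", n * bytes_per)
    if (length(raw) < n * bytes_per) stop("truncated PGM data: ", path)
    vals <- if (bytes_per == 2L)
      as.integer(raw[c(TRUE, FALSE)]) * 256L + as.integer(raw[c(FALSE, TRUE)])
    else as.integer(raw)
  }
  if (length(vals) < n) stop("truncated PGM data: ", path)
  matrix(vals / maxval, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a matrix as a 16-bit ASCII PGM
#'
#' Values are clamped to \[0, `max_value`\], scaled to 16 bits and written
#' as a P2 graymap; the quantization step is `max_value / 65535`.
#'
#' @param mat numeric matrix.
#' @param path output path.
#' @param max_value value mapped to white; default `max(mat, 1)` so
#'   responses keep relative scale.
#' @return invisibly, the path.
#' @export
write_pgm16 <- function(mat, path, max_value = max(mat, 1)) {
  stopifnot(is.matrix(mat))
  v <- round(pmin(pmax(mat / max_value, 0), 1) * 65535)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(mat), nrow(mat)), "65535"), con)
  writeLines(apply(v, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' Write a binary edge map as PNG
#'
#' @param mat 0/1 matrix.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_binary_png <- function(mat, path) {
  stopifnot(is.matrix(mat))
  png::writePNG(matrix(as.numeric(mat != 0), nrow(mat), ncol(mat)), path)
  invisible(path)
}
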