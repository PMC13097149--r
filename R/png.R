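# Minimal PNG codec: 8-bit greyscale (colour type 0) and RGB (colour type 2),
# no interlace. Writing always uses filter type 0; reading understands the
# five standard scanline filters so externally produced masks/images load too.
# Compression goes through R's zlib bindings (memCompress / memDecompress).

int_to_raw_be <- function(x, n = 4L) {
  out <- raw(n)
  for (i in seq_len(n)) {
    out[n - i + 1L] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

raw_to_int_be <- function(r) {
  sum(as.integer(r) * 256^(rev(seq_along(r)) - 1))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  crc <- crc32_cpp(body)
  c(int_to_raw_be(length(data)), body, int_to_raw_be(crc))
}

#' Write an image to a PNG file
#'
#' Accepts a numeric matrix (written as 8-bit greyscale) or an H x W x 3
#' array (written as 8-bit RGB). Values are clamped to \[0, 1\] and quantized
#' to 8 bits by rounding.
#'
#' @param img numeric matrix (H x W) or array (H x W x 3) with values in
#'   \[0, 1\].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_png <- function(img, path) {
  if (is.matrix(img)) img <- array(img, dim = c(dim(img), 1L))
  stopifnot(length(dim(img)) == 3L, dim(img)[3] %in% c(1L, 3L))
  h <- dim(img)[1]; w <- dim(img)[2]; nc <- dim(img)[3]
  bytes <- as.integer(round(pmin(pmax(img, 0), 1) * 255))
  # interleave channels within each row, rows top to bottom, filter byte 0
  px <- aperm(array(bytes, dim = c(h, w, nc)), c(3L, 2L, 1L))
  scan <- matrix(0L, nrow = 1L + w * nc, ncol = h)
  scan[-1L, ] <- matrix(px, nrow = w * nc, ncol = h)
  idat <- memCompress(as.raw(scan), type = "gzip")
  ihdr <- c(int_to_raw_be(w), int_to_raw_be(h),
            as.raw(c(8L, if (nc == 3L) 2L else 0L, 0L, 0L, 0L)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)), con)
  writeBin(png_chunk("IHDR", ihdr), con)
  writeBin(png_chunk("IDAT", idat), con)
  writeBin(png_chunk("IEND", raw(0)), con)
  invisible(path)
}

png_unfilter <- function(dat, h, w, bpp) {
  stride <- w * bpp
  out <- matrix(0L, nrow = stride, ncol = h)
  pos <- 1L
  prev <- integer(stride)
  for (r in seq_len(h)) {
    ft <- as.integer(dat[pos])
    row <- as.integer(dat[pos + seq_len(stride)])
    pos <- pos + stride + 1L
    row <- switch(as.character(ft),
      "0" = row,
      "1" = { # Sub: sequential, do per pixel group
        for (i in (bpp + 1L):stride) row[i] <- (row[i] + row[i - bpp]) %% 256L
        row
      },
      "2" = (row + prev) %% 256L,
      "3" = {
        for (i in seq_len(stride)) {
          a <- if (i > bpp) row[i - bpp] else 0L
          row[i] <- (row[i] + (a + prev[i]) %/% 2L) %% 256L
        }
        row
      },
      "4" = {
        for (i in seq_len(stride)) {
          a <- if (i > bpp) row[i - bpp] else 0L
          b <- prev[i]
          cc <- if (i > bpp) prev[i - bpp] else 0L
          p <- a + b - cc
          pa <- abs(p - a); pb <- abs(p - b); pc <- abs(p - cc)
          pr <- if (pa <= pb && pa <= pc) a else if (pb <= pc) b else cc
          row[i] <- (row[i] + pr) %% 256L
        }
        row
      },
      stop("unsupported PNG filter type: ", ft)
    )
    out[, r] <- row
    prev <- row
  }
  out
}

#' Read a PNG file
#'
#' Supports 8-bit greyscale and RGB, non-interlaced. Returns values scaled
#' to \[0, 1\]: a matrix for greyscale, an H x W x 3 array for RGB.
#'
#' @param path PNG file path.
#' @return numeric matrix or H x W x 3 array in \[0, 1\].
#' @export
read_png <- function(path) {
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  if (!identical(as.integer(raw_all[1:8]),
                 c(137L, 80L, 78L, 71L, 13L, 10L, 26L, 10L)))
    stop("not a PNG file: ", path)
  pos <- 9L
  idat <- list()
  w <- h <- nc <- NULL
  while (pos < length(raw_all)) {
    len <- raw_to_int_be(raw_all[pos:(pos + 3L)])
    type <- rawToChar(raw_all[(pos + 4L):(pos + 7L)])
    data <- if (len > 0) raw_all[(pos + 8L):(pos + 7L + len)] else raw(0)
    pos <- pos + 12L + len
    if (type == "IHDR") {
      w <- raw_to_int_be(data[1:4]); h <- raw_to_int_be(data[5:8])
      depth <- as.integer(data[9]); ct <- as.integer(data[10])
      if (depth != 8L || !(ct %in% c(0L, 2L)) || as.integer(data[13]) != 0L)
        stop("only 8-bit non-interlaced greyscale/RGB PNG supported")
      nc <- if (ct == 2L) 3L else 1L
    } else if (type == "IDAT") {
      idat[[length(idat) + 1L]] <- data
    } else if (type == "IEND") break
  }
  dat <- memDecompress(do.call(c, idat), type = "gzip")
  px <- png_unfilter(dat, h, w, nc)  # (w*nc) x h, channel-interleaved
  arr <- aperm(array(px, dim = c(nc, w, h)), c(3L, 2L, 1L)) / 255
  if (nc == 1L) arr <- arr[, , 1L] else arr
}
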