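# Minimal baseline TIFF 6.0 support: uncompressed 16-bit grayscale
# multi-page stacks, little-endian, one strip per page. Covers exactly the
# movie format this package emits; not a general TIFF library.

uint16_to_raw <- function(v) {
  as.raw(rbind(v %% 256L, v %/% 256L))
}

#' Write a movie stack to a multi-page 16-bit TIFF with JSON sidecar
#'
#' Writes an uncompressed little-endian grayscale TIFF (one page per frame)
#' plus a `<path>.json` sidecar holding `pixel_size_nm`, `frame_interval_s`
#' and any extra metadata supplied.
#'
#' @param movie a `movie_stack` from [render_movie()], or a numeric array
#'   (rows x cols x frames) with values in 0..65535
#' @param path output file path (`.tif`)
#' @param metadata named list merged into the sidecar
#' @return `path`, invisibly
#' @export
write_movie_tiff <- function(movie, path, metadata = list()) {
  if (inherits(movie, "movie_stack")) {
    frames <- movie$frames
    metadata <- c(list(pixel_size_nm = movie$spec$pixel_size_nm,
                       frame_interval_s = movie$spec$frame_interval_s),
                  metadata)
  } else frames <- movie
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  if (any(frames < 0 | frames > 65535)) stop("pixel values outside 0..65535")
  nr <- dim(frames)[1]; nc <- dim(frames)[2]; nf <- dim(frames)[3]
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  # header: II, magic 42, offset of first IFD
  writeBin(charToRaw("II"), con)
  w2(42L)
  hdr_len <- 8L
  page_data_len <- nr * nc * 2L
  n_entries <- 8L
  ifd_len <- 2L + n_entries * 12L + 4L
  # layout: header | data1 | ifd1 | data2 | ifd2 | ...
  data_off <- function(i) hdr_len + (i - 1L) * (page_data_len + ifd_len)
  ifd_off <- function(i) data_off(i) + page_data_len
  w4(ifd_off(1L))
  entry <- function(tag, type, count, value) {
    w2(tag); w2(type); w4(count)
    if (type == 3L) { w2(value); w2(0L) } else w4(value)
  }
  for (i in seq_len(nf)) {
    fr <- round(frames[, , i])
    writeBin(uint16_to_raw(as.integer(t(fr))), con)
    w2(n_entries)
    entry(256L, 3L, 1L, nc)              # ImageWidth
    entry(257L, 3L, 1L, nr)              # ImageLength
    entry(258L, 3L, 1L, 16L)             # BitsPerSample
    entry(259L, 3L, 1L, 1L)              # Compression = none
    entry(262L, 3L, 1L, 1L)              # Photometric = BlackIsZero
    entry(273L, 4L, 1L, data_off(i))     # StripOffsets
    entry(278L, 3L, 1L, nr)              # RowsPerStrip
    entry(279L, 4L, 1L, page_data_len)   # StripByteCounts
    w4(if (i < nf) ifd_off(i + 1L) else 0L)  # next IFD
  }
  jsonlite::write_json(metadata, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-page 16-bit grayscale TIFF stack
#'
#' Reads uncompressed little-endian 16-bit grayscale TIFFs (the format
#' written by [write_movie_tiff()]). The JSON sidecar, if present, is
#' attached as the `metadata` attribute.
#'
#' @param path TIFF file path
#' @return numeric array (rows x cols x frames) with attribute `metadata`
#' @export
read_movie_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  u16 <- function(off) as.integer(raw[off + 1]) + 256L * as.integer(raw[off + 2])
  u32 <- function(off) {
    b <- as.numeric(raw[off + (1:4)])
    b[1] + 256 * b[2] + 65536 * b[3] + 16777216 * b[4]
  }
  if (rawToChar(raw[1:2]) != "II" || u16(2) != 42L)
    stop("not a little-endian TIFF file")
  pages <- list()
  ifd <- u32(4)
  while (ifd != 0) {
    n <- u16(ifd)
    tags <- list()
    for (e in seq_len(n)) {
      off <- ifd + 2 + (e - 1) * 12
      tag <- u16(off); type <- u16(off + 2); cnt <- u32(off + 4)
      val <- if (type == 3L && cnt == 1L) u16(off + 8) else u32(off + 8)
      tags[[as.character(tag)]] <- list(type = type, count = cnt, value = val)
    }
    need <- c("256", "257", "273", "279")
    if (!all(need %in% names(tags))) stop("unsupported TIFF: missing tags")
    if (!is.null(tags[["259"]]) && tags[["259"]]$value != 1)
      stop("unsupported TIFF: compressed data")
    if (!is.null(tags[["258"]]) && tags[["258"]]$value != 16)
      stop("unsupported TIFF: not 16-bit")
    nc <- tags[["256"]]$value; nr <- tags[["257"]]$value
    # single strip (possibly multi-strip written contiguously)
    get_vec <- function(tg) {
      if (tg$count == 1L) return(tg$value)
      sz <- if (tg$type == 3L) 2 else 4
      sapply(seq_len(tg$count) - 1, function(k)
        if (sz == 2) u16(tg$value + 2 * k) else u32(tg$value + 4 * k))
    }
    offs <- get_vec(tags[["273"]]); cnts <- get_vec(tags[["279"]])
    bytes <- unlist(lapply(seq_along(offs), function(k)
      raw[(offs[k] + 1):(offs[k] + cnts[k])]), use.names = FALSE)
    lo <- as.integer(bytes[seq(1, length(bytes), 2)])
    hi <- as.integer(bytes[seq(2, length(bytes), 2)])
    pages[[length(pages) + 1]] <- matrix(lo + 256L * hi, nrow = nr,
                                         ncol = nc, byrow = TRUE)
    ifd <- u32(ifd + 2 + n * 12)
  }
  out <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) out[, , i] <- pages[[i]]
  side <- paste0(path, ".json")
  if (file.exists(side))
    attr(out, "metadata") <- jsonlite::read_json(side, simplifyVector = TRUE)
  out
}
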