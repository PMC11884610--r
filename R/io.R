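# Stack IO: a minimal baseline-TIFF codec (little-endian, uncompressed,
# grayscale, one strip per page, uint16 or float32). The pre-installed R
# stack has no TIFF package, so the subset needed for SPRM stacks is
# implemented here; round trips are cross-checked against an independent
# reader in the test suite. Acquisition metadata travels in the first
# page's ImageDescription tag as JSON.

TIFF_TYPE_SHORT <- 3L
TIFF_TYPE_LONG <- 4L
TIFF_TYPE_ASCII <- 2L

tiff_entry <- function(tag, type, count, value) {
  list(tag = tag, type = type, count = count, value = value)
}

write_u16 <- function(con, x) writeBin(as.integer(x), con, size = 2,
                                       endian = "little")
write_u32 <- function(con, x) writeBin(as.integer(x), con, size = 4,
                                       endian = "little")

#' Write an image sequence as a multi-page TIFF
#'
#' Grayscale, uncompressed, little-endian. `float32` (default) round-trips
#' intensities losslessly; `uint16` clamps to `[0, 65535]` and rounds.
#' Pixel size and frame interval are stored in the ImageDescription tag.
#'
#' @param seq An [image_sequence()].
#' @param path Output path.
#' @param dtype `"float32"` or `"uint16"`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(seq, path, dtype = c("float32", "uint16")) {
  dtype <- match.arg(dtype)
  d <- dim(seq$frames)
  nT <- d[1]; H <- d[2]; W <- d[3]
  bps <- if (dtype == "float32") 32L else 16L
  bytes <- bps / 8L
  fmt <- if (dtype == "float32") 3L else 1L
  desc <- jsonlite::toJSON(list(pixel_size = seq$pixel_size,
                                frame_interval = seq$frame_interval),
                           auto_unbox = TRUE)
  desc_raw <- c(charToRaw(as.character(desc)), as.raw(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  write_u16(con, 42L)
  write_u32(con, 8L)                    # first IFD right after header
  pos <- 8L
  strip_len <- H * W * bytes
  for (t in seq_len(nT)) {
    entries <- list(
      tiff_entry(256L, TIFF_TYPE_LONG, 1L, W),
      tiff_entry(257L, TIFF_TYPE_LONG, 1L, H),
      tiff_entry(258L, TIFF_TYPE_SHORT, 1L, bps),
      tiff_entry(259L, TIFF_TYPE_SHORT, 1L, 1L),
      tiff_entry(262L, TIFF_TYPE_SHORT, 1L, 1L)
    )
    desc_here <- t == 1L
    # + strip offset/count, samples/pixel, rows/strip, sample format
    n_entries <- length(entries) + 5L + desc_here
    ifd_len <- 2L + 12L * n_entries + 4L
    data_off <- pos + ifd_len + if (desc_here) length(desc_raw) else 0L
    if (desc_here)
      entries <- c(entries, list(tiff_entry(270L, TIFF_TYPE_ASCII,
                                            length(desc_raw),
                                            pos + ifd_len)))
    entries <- c(entries, list(
      tiff_entry(273L, TIFF_TYPE_LONG, 1L, data_off),
      tiff_entry(277L, TIFF_TYPE_SHORT, 1L, 1L),
      tiff_entry(278L, TIFF_TYPE_LONG, 1L, H),
      tiff_entry(279L, TIFF_TYPE_LONG, 1L, strip_len)
    ))
    entries <- c(entries, list(tiff_entry(339L, TIFF_TYPE_SHORT, 1L, fmt)))
    entries <- entries[order(vapply(entries, `[[`, integer(1), "tag"))]
    next_ifd <- if (t < nT) data_off + strip_len else 0L
    write_u16(con, length(entries))
    for (e in entries) {
      write_u16(con, e$tag)
      write_u16(con, e$type)
      write_u32(con, e$count)
      if (e$type == TIFF_TYPE_SHORT && e$count == 1L) {
        write_u16(con, e$value); write_u16(con, 0L)
      } else {
        write_u32(con, e$value)
      }
    }
    write_u32(con, next_ifd)
    if (desc_here) writeBin(desc_raw, con)
    frame <- t(array(seq$frames[t, , ], c(H, W)))   # row-major scanlines
    if (dtype == "float32") {
      writeBin(as.numeric(frame), con, size = 4, endian = "little")
    } else {
      v <- round(pmax(pmin(as.numeric(frame), 65535), 0))
      write_u16(con, v)
    }
    pos <- data_off + strip_len
  }
  invisible(path)
}

read_u16 <- function(r, off) {
  as.integer(r[off + 1]) + 256L * as.integer(r[off + 2])
}
read_u32 <- function(r, off) {
  as.numeric(r[off + 1]) + 256 * as.numeric(r[off + 2]) +
    65536 * as.numeric(r[off + 3]) + 16777216 * as.numeric(r[off + 4])
}

#' Read a multi-page grayscale TIFF stack
#'
#' Supports the baseline subset written by [write_stack()] (plus multiple
#' strips): little-endian, uncompressed, single-sample grayscale, uint8/16
#' or float32. A single image is promoted to a one-frame stack. RGB or
#' compressed files are rejected with a descriptive error.
#'
#' @param path Input path.
#' @return An [image_sequence()] (signed; differential stacks are valid).
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "'")
  r <- readBin(path, "raw", file.size(path))
  if (length(r) < 8 || rawToChar(r[1:2]) != "II" || read_u16(r, 2) != 42)
    stop("not a little-endian TIFF file")
  off <- read_u32(r, 4)
  frames <- list()
  meta <- list()
  while (off != 0) {
    n <- read_u16(r, off)
    tags <- list()
    for (i in seq_len(n)) {
      e <- off + 2 + (i - 1) * 12
      tag <- read_u16(r, e)
      type <- read_u16(r, e + 2)
      count <- read_u32(r, e + 4)
      val <- if (type == TIFF_TYPE_SHORT && count == 1) read_u16(r, e + 8)
      else read_u32(r, e + 8)
      tags[[as.character(tag)]] <- list(type = type, count = count,
                                        value = val, at = e + 8)
    }
    g <- function(tag, default = NULL) {
      t <- tags[[as.character(tag)]]
      if (is.null(t)) default else t$value
    }
    W <- g(256); H <- g(257)
    if (is.null(W) || is.null(H)) stop("malformed TIFF: missing dimensions")
    if (g(259, 1) != 1) stop("compressed TIFF not supported")
    if (g(277, 1) != 1) stop("grayscale only: SamplesPerPixel must be 1")
    bps <- g(258, 1); fmt <- g(339, 1)
    # strip offsets/counts may be arrays stored out of line
    get_vec <- function(tag) {
      t <- tags[[as.character(tag)]]
      if (is.null(t)) stop("malformed TIFF: missing strip info")
      if (t$count == 1) return(t$value)
      sz <- if (t$type == TIFF_TYPE_SHORT) 2 else 4
      base <- t$value
      vapply(seq_len(t$count), function(k) {
        if (sz == 2) read_u16(r, base + (k - 1) * 2)
        else read_u32(r, base + (k - 1) * 4)
      }, numeric(1))
    }
    offs <- get_vec(273); cnts <- get_vec(279)
    buf <- unlist(lapply(seq_along(offs), function(k)
      r[(offs[k] + 1):(offs[k] + cnts[k])]), use.names = FALSE)
    vals <- if (fmt == 3 && bps == 32) {
      readBin(buf, "double", H * W, size = 4, endian = "little")
    } else if (fmt %in% c(1, 4) && bps == 16) {
      readBin(buf, "integer", H * W, size = 2, signed = FALSE,
              endian = "little")
    } else if (fmt %in% c(1, 4) && bps == 8) {
      as.integer(buf[seq_len(H * W)])
    } else stop("unsupported TIFF sample type (bits=", bps,
                ", format=", fmt, ")")
    frames[[length(frames) + 1]] <- t(matrix(vals, W, H))
    dsc <- tags[["270"]]
    if (!is.null(dsc) && !length(meta)) {
      raw_txt <- r[(dsc$value + 1):(dsc$value + dsc$count)]
      txt <- rawToChar(raw_txt[raw_txt != as.raw(0)])
      meta <- tryCatch(jsonlite::fromJSON(txt), error = function(e) list())
    }
    off <- read_u32(r, off + 2 + n * 12)
  }
  H <- nrow(frames[[1]]); W <- ncol(frames[[1]])
  arr <- array(0, c(length(frames), H, W))
  for (t in seq_along(frames)) arr[t, , ] <- frames[[t]]
  image_sequence(arr,
                 frame_interval = if (!is.null(meta$frame_interval))
                   meta$frame_interval else 2,
                 pixel_size = if (!is.null(meta$pixel_size))
                   meta$pixel_size else 0.108,
                 signed = TRUE)
}

#' Write / read a ground-truth or trajectory table
#' @param df A data.frame.
#' @param path CSV path.
#' @return `read_table_csv` returns the data.frame.
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) utils::read.csv(path)

#' Read / write a run configuration
#'
#' Run configurations are plain YAML mappings with per-stage parameter
#' blocks (`optical`, `noise`, `scene`, `denoiser`, `training`, `analysis`)
#' plus a global `seed`, `out_dir` and `log_level`. Round trips are
#' lossless for scalar/list content.
#'
#' @param config A named list.
#' @param path YAML file path.
#' @return `read_config` returns the named list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) yaml::read_yaml(path)
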