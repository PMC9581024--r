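## Readers and writers: localisation tables, float TIFFs (greyscale,
## uncompressed, the dialect sum-projection stacks arrive in), PLY/XYZ point
## clouds, JSON run configs and plain-text run logs. No TIFF package ships
## with this R stack, so the baseline float TIFF dialect is implemented
## directly with readBin/writeBin.

#' Read a localisation table
#'
#' Reads a delimited text table of fluorophore localisations (one structure
#' per file) with header-named `x` and `y` columns. The delimiter (comma or
#' tab) is auto-detected. Coordinates given in nanometres are converted to
#' pixels through `scale`; the result is centred on the structure centroid,
#' ready for rendering.
#'
#' @param path file path.
#' @param units `"px"` or `"nm"`.
#' @param scale nm per pixel; required when `units = "nm"` (the expansion
#'   centriole data, for instance, is 14 nm per pixel).
#' @return An object of class `localisation_set` with fields `points`
#'   (M x 2, pixels, centroid at the origin), `scale` and `source_id`.
#' @export
read_localisations <- function(path, units = c("px", "nm"), scale = NULL) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("format error in '", path, "': need a header row plus data rows")
  sep <- if (lengths(regmatches(lines[1], gregexpr("\t", lines[1]))) > 0)
    "\t" else ","
  header <- trimws(tolower(strsplit(lines[1], sep, fixed = TRUE)[[1]]))
  ix <- match("x", header); iy <- match("y", header)
  if (is.na(ix) || is.na(iy))
    stop("format error in '", path, "': header must name 'x' and 'y' columns")
  n <- length(lines) - 1L
  pts <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i + 1L], sep, fixed = TRUE)[[1]]
    if (length(f) < max(ix, iy))
      stop("format error in '", path, "', line ", i + 1L,
           ": too few fields")
    v <- suppressWarnings(as.numeric(f[c(ix, iy)]))
    if (any(is.na(v)))
      stop("format error in '", path, "', line ", i + 1L,
           ": non-numeric x/y value")
    pts[i, ] <- v
  }
  if (units == "nm") {
    if (is.null(scale) || scale <= 0)
      stop("`scale` (nm per pixel, > 0) is required for nm units")
    pts <- pts / scale
  } else if (is.null(scale)) scale <- 1
  pts <- sweep(pts, 2, colMeans(pts))
  structure(list(points = pts, scale = as.numeric(scale),
                 source_id = basename(path)),
            class = "localisation_set")
}

#' Sum-project an image stack and crop around the structure
#'
#' Sums an X x Y x Z stack along z (discarding axial information, as for the
#' expansion-microscopy centriole stacks) and optionally centre-crops to
#' `crop` x `crop` pixels around the intensity centroid of the projection.
#'
#' @param stack 3D numeric array, or a path to a multi-page TIFF.
#' @param crop optional crop size in pixels (e.g. 60).
#' @return 2D matrix.
#' @export
sum_project_stack <- function(stack, crop = NULL) {
  if (is.character(stack)) stack <- read_tiff(stack)
  if (length(dim(stack)) != 3L) stop("`stack` must be a 3D array")
  proj <- rowSums(stack, dims = 2L)
  if (is.null(crop)) return(proj)
  crop <- as.integer(crop)
  if (crop > nrow(proj) || crop > ncol(proj))
    stop("`crop` (", crop, ") exceeds the frame (", nrow(proj), " x ",
         ncol(proj), ")")
  tot <- sum(proj)
  if (tot <= 0) stop("all-zero stack: no intensity centroid to crop around")
  cy <- sum(seq_len(nrow(proj)) * rowSums(proj)) / tot
  cx <- sum(seq_len(ncol(proj)) * colSums(proj)) / tot
  r0 <- min(max(1L, as.integer(round(cy - crop / 2))), nrow(proj) - crop + 1L)
  c0 <- min(max(1L, as.integer(round(cx - crop / 2))), ncol(proj) - crop + 1L)
  proj[r0:(r0 + crop - 1L), c0:(c0 + crop - 1L)]
}

#' Lossless cardinal-direction augmentation
#'
#' Rotates a square pixel image by 0, 90, 180 and 270 degrees. Unlike
#' arbitrary-angle rotation of a bitmap, these need no resampling and
#' introduce no artefacts, which is why pixel-based (as opposed to
#' localisation-based) data is augmented only this way.
#'
#' @param img square numeric matrix.
#' @return List of 4 matrices (0, 90, 180, 270 degrees clockwise).
#' @export
augment_cardinal <- function(img) {
  img <- as_pixels(img)
  if (nrow(img) != ncol(img)) stop("`img` must be square")
  r90 <- function(m) t(m[nrow(m):1, , drop = FALSE])
  a <- r90(img); b <- r90(a); c <- r90(b)
  list(img, a, b, c)
}

#' Pre-render localisation sets at every scheduled sigma
#'
#' Training with a stepped per-epoch input-sigma means every structure is
#' only ever rendered at a small set of distinct sigmas, so the renders are
#' computed once and cached on disk (as 64-bit float TIFF, hence bit-exact
#' on re-read). Cache entries are keyed by an MD5 content hash of
#' (structure id, sigma).
#'
#' @param locsets list of `localisation_set` objects.
#' @param schedule a [sigma_schedule()] or numeric vector of sigmas.
#' @param config a [render_config()].
#' @param dir cache directory.
#' @return A `prerender_cache` object (directory plus index data frame).
#' @export
prerender_cache <- function(locsets, schedule, config, dir) {
  sigmas <- if (inherits(schedule, "sigma_schedule"))
    schedule_sigmas(schedule) else as.numeric(schedule)
  if (!all(is.finite(sigmas)) || any(sigmas <= 0))
    stop("schedule sigmas must be finite and positive")
  sigmas <- unique(sigmas)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (ls in locsets) {
    world <- ls$points / pixel_scale(config)
    for (s in sigmas) {
      key <- cache_key(ls$source_id, s)
      f <- file.path(dir, paste0(key, ".tif"))
      if (!file.exists(f))
        write_tiff(splat(world, s, config)$pixels, f, bits = 64)
      rows[[length(rows) + 1L]] <-
        data.frame(source_id = ls$source_id, sigma = s, file = basename(f))
    }
  }
  index <- do.call(rbind, rows)
  utils::write.table(index, file.path(dir, "index.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  structure(list(dir = dir, index = index), class = "prerender_cache")
}

cache_key <- function(id, sigma) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(sprintf("%s|%.12g", id, sigma), tf)
  unname(tools::md5sum(tf))
}

#' Fetch an image from a pre-render cache
#'
#' @param cache a `prerender_cache`.
#' @param source_id structure identifier.
#' @param sigma rendering sigma.
#' @return 2D pixel matrix.
#' @export
cache_fetch <- function(cache, source_id, sigma) {
  hit <- cache$index$source_id == source_id &
    abs(cache$index$sigma - sigma) < 1e-12
  if (!any(hit)) stop("no cache entry for (", source_id, ", ", sigma, ")")
  read_tiff(file.path(cache$dir, cache$index$file[which(hit)[1]]))
}

#' Write a point cloud to PLY or XYZ
#'
#' ASCII formats; coordinates round-trip through [read_pointcloud()] to
#' better than 1e-6.
#'
#' @param points a `point_cloud` or N x 3 matrix.
#' @param path output path.
#' @param format `"PLY"` or `"XYZ"`.
#' @return Invisibly, `path`.
#' @export
write_pointcloud <- function(points, path, format = c("PLY", "XYZ")) {
  format <- match.arg(toupper(format[1]), c("PLY", "XYZ"))
  v <- as_vertices(points)
  if (nrow(v) < 1L) stop("empty point cloud")
  body <- sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3])
  if (format == "PLY") {
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property float x", "property float y", "property float z",
                 "end_header", body), path)
  } else writeLines(body, path)
  invisible(path)
}

#' Read a PLY or XYZ point cloud
#'
#' @param path file path; the format is detected from the content.
#' @return A `point_cloud`.
#' @export
read_pointcloud <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) && trimws(lines[1]) == "ply") {
    end <- match("end_header", trimws(lines))
    nline <- grep("^element vertex", trimws(lines), value = TRUE)
    if (is.na(end) || !length(nline)) stop("malformed PLY header in ", path)
    n <- as.integer(sub("element vertex\\s+", "", nline[1]))
    body <- lines[(end + 1L):(end + n)]
  } else body <- lines[nzchar(trimws(lines))]
  v <- do.call(rbind, lapply(body, function(l) {
    x <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:3]))
    if (any(is.na(x))) stop("non-numeric vertex record in ", path)
    x
  }))
  point_cloud(v, basename(path))
}

## ---- minimal float TIFF (little-endian, uncompressed, greyscale) --------

#' Write a 32/64-bit float greyscale TIFF
#'
#' @param img 2D matrix or 3D array (multi-page along the third dimension).
#' @param path output path.
#' @param bits 32 or 64.
#' @return Invisibly, `path`.
#' @export
write_tiff <- function(img, path, bits = 32) {
  img <- if (inherits(img, "rendered_image")) img$pixels else img
  if (!bits %in% c(32, 64)) stop("`bits` must be 32 or 64")
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 1L))
  H <- dim(img)[1]; W <- dim(img)[2]; Z <- dim(img)[3]
  bytes <- bits / 8
  page_bytes <- H * W * bytes
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  entry <- function(tag, type, count, value) {
    w2(tag); w2(type); w4(count)
    if (type == 3) { w2(value); w2(0) } else w4(value)
  }
  # layout: 8-byte header | Z pages of pixel data | Z IFDs
  data_off <- 8
  ifd_off <- 8 + Z * page_bytes
  ifd_size <- 2 + 10 * 12 + 4
  writeBin(charToRaw("II"), con); w2(42L); w4(ifd_off)
  for (z in seq_len(Z))
    writeBin(as.numeric(t(img[, , z])), con, size = bytes, endian = "little")
  for (z in seq_len(Z)) {
    w2(10L)
    entry(256, 4, 1, W)                        # ImageWidth
    entry(257, 4, 1, H)                        # ImageLength
    entry(258, 3, 1, bits)                     # BitsPerSample
    entry(259, 3, 1, 1)                        # Compression: none
    entry(262, 3, 1, 1)                        # Photometric: BlackIsZero
    entry(273, 4, 1, data_off + (z - 1) * page_bytes)  # StripOffsets
    entry(277, 3, 1, 1)                        # SamplesPerPixel
    entry(278, 4, 1, H)                        # RowsPerStrip
    entry(279, 4, 1, page_bytes)               # StripByteCounts
    entry(339, 3, 1, 3)                        # SampleFormat: IEEE float
    w4(if (z < Z) ifd_off + z * ifd_size else 0)
  }
  invisible(path)
}

#' Read an uncompressed greyscale TIFF (float or unsigned integer)
#'
#' Supports the dialect written by [write_tiff()] plus common single-sample
#' uncompressed variants (8/16-bit unsigned, multi-strip, either byte
#' order). Multi-page files return a 3D array.
#'
#' @param path file path.
#' @return 2D matrix, or 3D array for a multi-page file.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 8) stop("not a TIFF: ", path)
  en <- rawToChar(raw[1:2])
  endian <- if (en == "II") "little" else if (en == "MM") "big"
    else stop("not a TIFF: ", path)
  int_at <- function(off, size, n = 1)
    readBin(raw[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = endian, signed = size >= 4)
  if (int_at(2, 2) != 42L) stop("not a TIFF: ", path)
  ifd <- int_at(4, 4)
  pages <- list()
  while (ifd != 0) {
    nent <- int_at(ifd, 2)
    tags <- list()
    for (i in seq_len(nent)) {
      e <- ifd + 2 + (i - 1) * 12
      tag <- int_at(e, 2); type <- int_at(e + 2, 2); cnt <- int_at(e + 4, 4)
      tsz <- c(1, 1, 2, 4, 8)[type]
      vals <- if (tsz * cnt <= 4) int_at(e + 8, tsz, cnt)
        else int_at(int_at(e + 8, 4), tsz, cnt)
      tags[[as.character(tag)]] <- vals
    }
    g <- function(t, d = NULL) {
      v <- tags[[as.character(t)]]
      if (is.null(v)) d else v
    }
    W <- g(256); H <- g(257); bits <- g(258, 1)[1]
    if (is.null(W) || is.null(H)) stop("TIFF missing dimensions: ", path)
    if (g(259, 1) != 1) stop("compressed TIFF not supported: ", path)
    if (g(277, 1) != 1) stop("multi-sample TIFF not supported: ", path)
    fmt <- g(339, 1)
    offs <- g(273); cnts <- g(279, H * W * bits / 8)
    buf <- unlist(lapply(seq_along(offs), function(k)
      raw[(offs[k] + 1):(offs[k] + cnts[k])]), use.names = FALSE)
    px <- if (fmt == 3) {
      readBin(buf, "numeric", n = H * W, size = bits / 8, endian = endian)
    } else if (fmt == 1 && bits %in% c(8, 16)) {
      readBin(buf, "integer", n = H * W, size = bits / 8, endian = endian,
              signed = FALSE)
    } else stop("unsupported TIFF sample format (", fmt, "/", bits,
                " bit): ", path)
    pages[[length(pages) + 1L]] <- t(matrix(px, W, H))  # stored row-major
    nxt <- ifd + 2 + nent * 12
    ifd <- int_at(nxt, 4)
  }
  if (length(pages) == 1L) pages[[1]]
  else array(unlist(pages, use.names = FALSE),
             c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
}

## ---- run configs and logs -----------------------------------------------

#' Write / read a run configuration as JSON
#'
#' @param config named list of run settings.
#' @param path file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   the named list.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Append a line to a plain-text run log
#'
#' @param path log file path.
#' @param ... values pasted into one line, prefixed with a timestamp.
#' @return Invisibly, `path`.
#' @export
log_line <- function(path, ...) {
  cat(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), paste0(..., collapse = ""),
      "\n", sep = "", file = path, append = TRUE)
  invisible(path)
}
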