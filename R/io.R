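# Volume and section I/O: MHD/RAW, NRRD (raw encoding), minimal baseline
# TIFF (uncompressed, little-endian, 8/16-bit integer or 32-bit float,
# grayscale multi-page or single-page RGB) and PNG for RGB sections.
# No TIFF library exists in this R environment, so the TIFF codec here is
# a deliberate minimal implementation of baseline TIFF 6.0.

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, spacing_um, extra = list()) {
  jsonlite::write_json(c(list(spacing_um = spacing_um), extra),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
}

read_sidecar <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) return(NULL)
  jsonlite::read_json(sc, simplifyVector = TRUE)
}

# ---- MHD/RAW --------------------------------------------------------------

mhd_type <- function(storage, signed = FALSE) {
  switch(storage, uchar = "MET_UCHAR", ushort = "MET_USHORT",
         float = "MET_FLOAT", double = "MET_DOUBLE",
         stop("unsupported element type"))
}

pick_storage <- function(arr, labels) {
  v <- as.numeric(arr)
  if (labels || (all(v == round(v)) && min(v) >= 0 && max(v) <= 255)) "uchar"
  else if (all(v == round(v)) && min(v) >= 0 && max(v) <= 65535) "ushort"
  else "double"
}

write_raw_payload <- function(con, arr, storage) {
  v <- as.numeric(arr)
  switch(storage,
    uchar = writeBin(as.integer(v), con, size = 1, endian = "little"),
    ushort = writeBin(as.integer(v), con, size = 2, endian = "little"),
    float = writeBin(v, con, size = 4, endian = "little"),
    double = writeBin(v, con, size = 8, endian = "little"))
}

read_raw_payload <- function(con, n, met_type) {
  switch(met_type,
    MET_UCHAR = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE,
                                   endian = "little")),
    MET_USHORT = as.numeric(readBin(con, "integer", n, size = 2, signed = FALSE,
                                    endian = "little")),
    MET_SHORT = as.numeric(readBin(con, "integer", n, size = 2, signed = TRUE,
                                   endian = "little")),
    MET_FLOAT = readBin(con, "double", n, size = 4, endian = "little"),
    MET_DOUBLE = readBin(con, "double", n, size = 8, endian = "little"),
    stop(sprintf("unsupported MHD ElementType '%s'", met_type)))
}

write_mhd <- function(vol, path) {
  arr <- as_plain(vol)
  storage <- pick_storage(arr, inherits(vol, "labelvol"))
  raw_path <- sub("\\.mhd$", ".raw", path, ignore.case = TRUE)
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           paste("DimSize =", paste(dim(arr), collapse = " ")),
           paste("ElementSpacing =", paste(rep(spacing_um(vol), 3),
                                           collapse = " ")),
           "ElementSpacingUnits = um",
           paste("ElementType =", mhd_type(storage)),
           paste("ElementDataFile =", basename(raw_path)))
  writeLines(hdr, path)
  con <- file(raw_path, "wb"); on.exit(close(con))
  write_raw_payload(con, arr, storage)
  invisible(path)
}

read_mhd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = " "), "")
  get <- function(k) vals[match(k, keys)]
  dims <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
  spac <- as.numeric(strsplit(get("ElementSpacing"), "\\s+")[[1]])
  if (any(is.na(spac)))
    stop(sprintf("read_mhd: missing ElementSpacing in '%s'", path))
  met <- get("ElementType")
  raw_path <- file.path(dirname(path), get("ElementDataFile"))
  con <- file(raw_path, "rb"); on.exit(close(con))
  v <- read_raw_payload(con, prod(dims), met)
  labels <- met %in% c("MET_UCHAR")
  vol3d(array(v, dims), spac[1], labels = labels)
}

# ---- NRRD (attached raw encoding) ----------------------------------------

write_nrrd <- function(vol, path) {
  arr <- as_plain(vol)
  storage <- pick_storage(arr, inherits(vol, "labelvol"))
  type <- switch(storage, uchar = "uint8", ushort = "uint16",
                 double = "double")
  hdr <- c("NRRD0004",
           paste("type:", type),
           "dimension: 3",
           paste("sizes:", paste(dim(arr), collapse = " ")),
           paste("spacings:", paste(rep(spacing_um(vol), 3), collapse = " ")),
           "encoding: raw", "endian: little", "")
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  write_raw_payload(con, arr, storage)
  invisible(path)
}

read_nrrd <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- character(0)
  repeat {
    ln <- readLines(con, n = 1, warn = FALSE)
    if (!length(ln) || ln == "") break
    hdr <- c(hdr, ln)
  }
  field <- function(k) {
    hit <- grep(paste0("^", k, ":"), hdr, value = TRUE)
    if (!length(hit)) return(NA_character_)
    trimws(sub(paste0("^", k, ":"), "", hit[1]))
  }
  dims <- as.integer(strsplit(field("sizes"), "\\s+")[[1]])
  spac <- as.numeric(strsplit(field("spacings"), "\\s+")[[1]])
  if (any(is.na(spac)))
    stop(sprintf("read_nrrd: missing spacings in '%s'", path))
  if (field("encoding") != "raw")
    stop("read_nrrd: only raw encoding is supported")
  met <- switch(field("type"), uint8 = "MET_UCHAR", uint16 = "MET_USHORT",
                int16 = "MET_SHORT", float = "MET_FLOAT",
                double = "MET_DOUBLE",
                stop("read_nrrd: unsupported type"))
  v <- read_raw_payload(con, prod(dims), met)
  vol3d(array(v, dims), spac[1], labels = met == "MET_UCHAR")
}

# ---- minimal baseline TIFF ------------------------------------------------

tiff_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
tiff_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

# one IFD entry: tag, type (3 = SHORT, 4 = LONG), count, value
tiff_entry <- function(tag, type, count, value) {
  val <- if (type == 3) c(tiff_u16(value), tiff_u16(0)) else tiff_u32(value)
  c(tiff_u16(tag), tiff_u16(type), tiff_u32(count), val)
}

write_tiff <- function(pages, path, bits = 8, samples = 1, float = FALSE) {
  # pages: list of nx x ny (x fastest) numeric matrices/arrays
  nx <- dim(pages[[1]])[1]; ny <- dim(pages[[1]])[2]
  npix <- nx * ny * samples
  bytes_pp <- bits / 8
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(c(charToRaw("II"), as.raw(c(42, 0))), con)
  n_entries <- 10L
  ifd_size <- 2 + n_entries * 12 + 4
  data_size <- npix * bytes_pp
  # layout: header, then per page [strip data][IFD]
  strip_offsets <- 8 + cumsum(c(0, rep(ifd_size + data_size,
                                       length(pages) - 1)))
  ifd_offsets <- strip_offsets + data_size
  writeBin(tiff_u32(ifd_offsets[1]), con)
  for (p in seq_along(pages)) {
    v <- as.numeric(pages[[p]])
    if (samples == 3) {
      a <- pages[[p]]
      v <- as.numeric(aperm(a, c(3, 1, 2)))     # interleave RGB per pixel
    }
    if (float) writeBin(v, con, size = 4, endian = "little")
    else writeBin(as.integer(round(v)), con, size = bytes_pp, endian = "little")
    entries <- c(
      tiff_entry(256, 3, 1, nx), tiff_entry(257, 3, 1, ny),
      tiff_entry(258, 3, 1, bits), tiff_entry(259, 3, 1, 1),
      tiff_entry(262, 3, 1, if (samples == 3) 2 else 1),
      tiff_entry(273, 4, 1, strip_offsets[p]),
      tiff_entry(277, 3, 1, samples), tiff_entry(278, 3, 1, ny),
      tiff_entry(279, 4, 1, data_size),
      tiff_entry(339, 3, 1, if (float) 3 else 1))
    nxt <- if (p < length(pages)) ifd_offsets[p + 1] else 0
    writeBin(c(tiff_u16(n_entries), entries, tiff_u32(nxt)), con)
  }
  invisible(path)
}

read_tiff <- function(path) {
  raw_all <- readBin(path, "raw", file.info(path)$size)
  u16 <- function(off) sum(as.integer(raw_all[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.integer(raw_all[off + 1:4]) * c(1, 256, 65536, 16777216))
  if (rawToChar(raw_all[1:2]) != "II")
    stop("read_tiff: only little-endian TIFF is supported")
  ifd <- u32(4)
  pages <- list()
  meta <- NULL
  while (ifd != 0) {
    n <- u16(ifd)
    tags <- list()
    for (e in seq_len(n)) {
      base <- ifd + 2 + (e - 1) * 12
      tag <- u16(base); type <- u16(base + 2)
      val <- if (type == 3) u16(base + 8) else u32(base + 8)
      tags[[as.character(tag)]] <- val
    }
    nx <- tags[["256"]]; ny <- tags[["257"]]
    bits <- if (is.null(tags[["258"]])) 8 else tags[["258"]]
    samples <- if (is.null(tags[["277"]])) 1 else tags[["277"]]
    fmt <- if (is.null(tags[["339"]])) 1 else tags[["339"]]
    comp <- if (is.null(tags[["259"]])) 1 else tags[["259"]]
    if (comp != 1) stop("read_tiff: only uncompressed TIFF is supported")
    off <- tags[["273"]]
    npix <- nx * ny * samples
    con <- rawConnection(raw_all[off + seq_len(npix * bits / 8)])
    v <- if (fmt == 3) readBin(con, "double", npix, size = 4, endian = "little")
    else readBin(con, "integer", npix, size = bits / 8, signed = FALSE,
                 endian = "little")
    close(con)
    pages[[length(pages) + 1]] <-
      if (samples == 3) aperm(array(v, c(3, nx, ny)), c(2, 3, 1))
      else matrix(v, nx, ny)
    meta <- list(bits = bits, samples = samples)
    ifd <- u32(ifd + 2 + n * 12)
  }
  list(pages = pages, meta = meta)
}

# ---- public volume / section I/O -----------------------------------------

vol_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, mhd = "mhd", nrrd = "nrrd", tif = "tiff", tiff = "tiff",
         png = "png",
         stop(sprintf("unknown volume/section extension '.%s' for '%s'",
                      ext, path)))
}

#' Write a volume (multi-page TIFF, MHD/RAW or NRRD)
#'
#' TIFF stores 8-bit (labels / byte data) or 16-bit integers, or 32-bit
#' floats, one z-slice per page, with a JSON sidecar holding the spacing;
#' MHD and NRRD carry the spacing in their headers.  Integer data
#' round-trips bit-exactly through every format.
#'
#' @param vol a `vol3d`.
#' @param path output path (`.mhd`, `.nrrd`, `.tif`/`.tiff`).
#' @param labels optional named label table recorded in the JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, labels = NULL) {
  stopifnot(inherits(vol, "vol3d"))
  fmt <- vol_format(path)
  if (fmt == "png") stop("write_volume: PNG is for 2D sections")
  switch(fmt,
    mhd = write_mhd(vol, path),
    nrrd = write_nrrd(vol, path),
    tiff = {
      arr <- as_plain(vol)
      storage <- pick_storage(arr, inherits(vol, "labelvol"))
      pages <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k])
      if (storage == "double") write_tiff(pages, path, bits = 32, float = TRUE)
      else write_tiff(pages, path, bits = if (storage == "uchar") 8 else 16)
    })
  extra <- list(kind = if (inherits(vol, "labelvol")) "labels" else "intensity")
  if (!is.null(labels)) extra$labels <- as.list(labels)
  write_sidecar(path, spacing_um(vol), extra)
  invisible(path)
}

#' Read a volume written by [write_volume()]
#'
#' @param path `.mhd`, `.nrrd` or `.tif`/`.tiff` file.  TIFF requires the
#'   JSON sidecar for the voxel spacing.
#' @return a `vol3d` (a `labelvol` when the sidecar marks label data or the
#'   payload is 8-bit).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_volume: no such file '%s'", path))
  fmt <- vol_format(path)
  sc <- read_sidecar(path)
  out <- switch(fmt,
    mhd = read_mhd(path),
    nrrd = read_nrrd(path),
    tiff = {
      if (is.null(sc) || is.null(sc$spacing_um))
        stop(sprintf("read_volume: missing spacing metadata for '%s' (no sidecar '%s')",
                     path, sidecar_path(path)))
      tf <- read_tiff(path)
      arr <- array(unlist(tf$pages), c(dim(tf$pages[[1]]), length(tf$pages)))
      if (tf$meta$bits != 8) storage.mode(arr) <- "double"
      vol3d(arr, sc$spacing_um, labels = tf$meta$bits == 8)
    },
    png = stop("read_volume: PNG is for 2D sections"))
  if (!is.null(sc) && !is.null(sc$kind))
    out <- vol3d(as_plain(out), spacing_um(out), labels = sc$kind == "labels")
  out
}

#' Write a 2D section (PNG or TIFF) with a JSON spacing sidecar
#'
#' @param section a `section2d` (grayscale or RGB, 0-255 scale).
#' @param path `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_section <- function(section, path) {
  stopifnot(inherits(section, "section2d"))
  fmt <- vol_format(path)
  a <- as_plain(section)
  if (fmt == "png") {
    img <- if (is_rgb(a)) aperm(a, c(2, 1, 3)) else t(a)
    img <- img / 255
    img[img < 0] <- 0
    img[img > 1] <- 1
    png::writePNG(img, path)
  } else {
    if (is_rgb(a)) write_tiff(list(a), path, bits = 8, samples = 3)
    else write_tiff(list(a), path,
                    bits = if (max(a) > 255 || any(a != round(a))) 32 else 8,
                    float = max(a) > 255 || any(a != round(a)))
  }
  write_sidecar(path, spacing_um(section), list(kind = "section"))
  invisible(path)
}

#' Read a 2D section written by [write_section()]
#' @param path `.png`, `.tif` or `.tiff` (sidecar required for spacing).
#' @return a `section2d` on the 0-255 scale.
#' @export
read_section <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_section: no such file '%s'", path))
  sc <- read_sidecar(path)
  if (is.null(sc) || is.null(sc$spacing_um))
    stop(sprintf("read_section: missing spacing metadata for '%s'", path))
  fmt <- vol_format(path)
  if (fmt == "png") {
    img <- png::readPNG(path)
    a <- if (length(dim(img)) == 3)
      aperm(img[, , 1:3, drop = FALSE], c(2, 1, 3)) * 255
    else t(img) * 255
    section2d(a, sc$spacing_um)
  } else {
    tf <- read_tiff(path)
    section2d(tf$pages[[1]], sc$spacing_um)
  }
}
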