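#' Read a point cloud from disk
#'
#' Reads ASCII XYZ (whitespace-separated, optional fourth label column),
#' PLY (ASCII or binary little-endian) and LAS 1.2+ files into a
#' [point_cloud()]. Coordinates are returned in meters; the LAS scale and
#' offset are applied on read. Per-point plant labels survive the round
#' trip: the fourth XYZ column, an integer `plant_label`/`label` vertex
#' property in PLY, and the point-source-ID field in LAS.
#'
#' @param path file to read.
#' @param format one of `"xyz"`, `"ply"`, `"las"`; guessed from the file
#'   extension when omitted.
#' @return A [point_cloud()].
#' @seealso [write_cloud()]
#' @export
read_cloud <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- format %||% guess_format(path)
  switch(match.arg(format, c("xyz", "ply", "las")),
         xyz = read_xyz(path),
         ply = read_ply(path),
         las = read_las(path))
}

#' Write a point cloud to disk
#'
#' @param cloud a [point_cloud()].
#' @param path output file.
#' @param format one of `"xyz"`, `"ply"`, `"las"`; guessed from the file
#'   extension when omitted.
#' @param binary for PLY: write `binary_little_endian` (default) rather
#'   than ASCII.
#' @return `path`, invisibly.
#' @export
write_cloud <- function(cloud, path, format = NULL, binary = TRUE) {
  stopifnot(inherits(cloud, "stalk_cloud"))
  format <- format %||% guess_format(path)
  switch(match.arg(format, c("xyz", "ply", "las")),
         xyz = write_xyz(cloud, path),
         ply = write_ply(cloud, path, binary = binary),
         las = write_las(cloud, path))
  invisible(path)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "laz")
    stop("compressed LAZ is not supported; decompress to LAS first")
  if (ext %in% c("xyz", "txt", "asc")) return("xyz")
  if (ext %in% c("ply", "las")) return(ext)
  stop("cannot guess point-cloud format from extension '.", ext,
       "'; pass `format` explicitly (xyz, ply or las)")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- ASCII XYZ ------------------------------------------------------------

read_xyz <- function(path) {
  if (file.size(path) == 0L)
    return(point_cloud(matrix(numeric(0), ncol = 3L)))
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, colClasses = "numeric",
                      showProgress = FALSE),
    error = function(e) stop("malformed XYZ file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(dt) == 0L) return(point_cloud(matrix(numeric(0), ncol = 3L)))
  if (ncol(dt) < 3L)
    stop("malformed XYZ file '", path, "': expected >= 3 columns, got ",
         ncol(dt))
  label <- if (ncol(dt) >= 4L) as.integer(dt[[4L]])
  point_cloud(as.matrix(dt[, 1:3]), label = label)
}

write_xyz <- function(cloud, path) {
  n <- n_points(cloud)
  if (n == 0L) { cat("", file = path); return(invisible(path)) }
  df <- data.table::as.data.table(cloud$xyz)
  # fixed 7-decimal output keeps the round trip within 1e-6 m
  for (j in 1:3) data.table::set(df, j = j, value = sprintf("%.7f", df[[j]]))
  if (!is.null(cloud$label)) df[["label"]] <- cloud$label
  data.table::fwrite(df, path, sep = " ", col.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- PLY ------------------------------------------------------------------

ply_type_size <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                   short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                   int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(magic, "ply")) stop("not a PLY file (bad magic): ", path)
  fmt <- NULL; nvert <- NA_integer_
  props <- character(); types <- character()
  in_vertex <- FALSE
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("malformed PLY header (no end_header): ", path)
    tok <- strsplit(trimws(line), "\\s+")[[1L]]
    if (length(tok) == 0L) next
    if (tok[1L] == "comment") next
    if (tok[1L] == "format") fmt <- tok[2L]
    else if (tok[1L] == "element") {
      in_vertex <- tok[2L] == "vertex"
      if (in_vertex) nvert <- as.integer(tok[3L])
    } else if (tok[1L] == "property" && in_vertex) {
      if (tok[2L] == "list") stop("list properties on vertices unsupported: ", path)
      props <- c(props, tok[3L]); types <- c(types, tok[2L])
    } else if (tok[1L] == "end_header") break
  }
  if (is.null(fmt) || is.na(nvert)) stop("malformed PLY header: ", path)
  if (!all(c("x", "y", "z") %in% props))
    stop("PLY vertex element lacks x/y/z properties: ", path)
  label_prop <- intersect(c("plant_label", "label", "scalar_PlantID"), props)[1L]
  cols <- if (fmt == "ascii") {
    txt <- readLines(con)
    txt <- txt[nzchar(trimws(txt))]
    if (length(txt) < nvert) stop("PLY vertex records truncated at line ",
                                  length(txt), ": ", path)
    dt <- data.table::fread(text = txt[seq_len(nvert)], header = FALSE)
    if (ncol(dt) != length(props))
      stop("PLY vertex record has ", ncol(dt), " fields, header declares ",
           length(props), ": ", path)
    stats::setNames(as.list(dt), props)
  } else if (fmt == "binary_little_endian") {
    sizes <- ply_type_size[types]
    if (anyNA(sizes)) stop("unknown PLY property type in header: ", path)
    rec <- sum(sizes)
    raw <- readBin(con, "raw", n = rec * nvert)
    if (length(raw) < rec * nvert)
      stop("PLY binary payload truncated (record ",
           length(raw) %/% rec + 1L, "): ", path)
    off <- cumsum(c(0L, sizes))
    out <- vector("list", length(props))
    for (i in seq_along(props)) {
      sel <- as.vector(outer(seq_len(sizes[i]) + off[i],
                             (seq_len(nvert) - 1L) * rec, "+"))
      bytes <- raw[sel]
      out[[i]] <- switch(types[i],
        float = , float32 = readBin(bytes, "double", nvert, size = 4L,
                                    endian = "little"),
        double = , float64 = readBin(bytes, "double", nvert, size = 8L,
                                     endian = "little"),
        char = , int8 = readBin(bytes, "integer", nvert, size = 1L,
                                signed = TRUE),
        uchar = , uint8 = readBin(bytes, "integer", nvert, size = 1L,
                                  signed = FALSE),
        short = , int16 = readBin(bytes, "integer", nvert, size = 2L,
                                  signed = TRUE, endian = "little"),
        ushort = , uint16 = readBin(bytes, "integer", nvert, size = 2L,
                                    signed = FALSE, endian = "little"),
        readBin(bytes, "integer", nvert, size = 4L, endian = "little"))
    }
    stats::setNames(out, props)
  } else stop("unsupported PLY format '", fmt, "' (big-endian not handled): ",
              path)
  xyz <- cbind(as.numeric(cols$x), as.numeric(cols$y), as.numeric(cols$z))
  label <- if (!is.na(label_prop)) as.integer(cols[[label_prop]])
  point_cloud(xyz, label = label)
}

write_ply <- function(cloud, path, binary = TRUE) {
  n <- n_points(cloud)
  has_label <- !is.null(cloud$label)
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
           paste("element vertex", n),
           "property double x", "property double y", "property double z",
           if (has_label) "property int plant_label",
           "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (n == 0L) return(invisible(path))
  if (binary) {
    coord <- matrix(writeBin(as.vector(t(cloud$xyz)), raw(), size = 8L,
                             endian = "little"), nrow = 24L)
    rec <- if (has_label)
      rbind(coord, matrix(writeBin(cloud$label, raw(), size = 4L,
                                   endian = "little"), nrow = 4L))
    else coord
    writeBin(as.vector(rec), con)
  } else {
    lines <- sprintf("%.7f %.7f %.7f", cloud$xyz[, 1], cloud$xyz[, 2],
                     cloud$xyz[, 3])
    if (has_label) lines <- paste(lines, cloud$label)
    writeLines(lines, con)
  }
  invisible(path)
}

## ---- LAS 1.2 --------------------------------------------------------------

# Minimal LAS 1.2 reader/writer, point record format 0 on write (labels in
# the point-source-ID field); on read any format whose record starts with
# the standard 20-byte core is accepted.

read_las <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (rawToChar(readBin(con, "raw", 4L)) != "LASF")
    stop("not a LAS file (bad signature): ", path)
  seek(con, 24L)
  ver <- readBin(con, "integer", 2L, size = 1L, signed = FALSE)
  seek(con, 96L)
  offset_data <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  seek(con, 104L)
  pdrf <- readBin(con, "integer", 1L, size = 1L, signed = FALSE)
  reclen <- readBin(con, "integer", 1L, size = 2L, signed = FALSE,
                    endian = "little")
  npts <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  seek(con, 131L)
  scale <- readBin(con, "double", 3L, size = 8L, endian = "little")
  offs <- readBin(con, "double", 3L, size = 8L, endian = "little")
  if (pdrf > 127L) stop("LAZ-compressed payload not supported: ", path)
  if (reclen < 20L) stop("malformed LAS: point record length ", reclen)
  seek(con, offset_data)
  raw <- readBin(con, "raw", n = as.numeric(reclen) * npts)
  if (length(raw) < reclen * npts)
    stop("LAS point records truncated (record ",
         length(raw) %/% reclen + 1L, "): ", path)
  if (npts == 0L) return(point_cloud(matrix(numeric(0), ncol = 3L)))
  base <- (seq_len(npts) - 1L) * reclen
  grab_i32 <- function(off) {
    sel <- as.vector(outer(off + 1:4, base, "+"))
    readBin(raw[sel], "integer", npts, size = 4L, endian = "little")
  }
  grab_u16 <- function(off) {
    sel <- as.vector(outer(off + 1:2, base, "+"))
    readBin(raw[sel], "integer", npts, size = 2L, signed = FALSE,
            endian = "little")
  }
  xyz <- cbind(grab_i32(0L) * scale[1] + offs[1],
               grab_i32(4L) * scale[2] + offs[2],
               grab_i32(8L) * scale[3] + offs[3])
  psid <- grab_u16(18L)
  label <- if (any(psid != 0L)) as.integer(psid)
  point_cloud(xyz, label = label)
}

write_las <- function(cloud, path) {
  n <- n_points(cloud)
  if (!is.null(cloud$label) && any(cloud$label > 65535L))
    stop("LAS point-source-ID labels must be <= 65535")
  scale <- 1e-6
  if (n > 0L && max(abs(cloud$xyz)) > 2000)
    stop("coordinates exceed +/-2000 m; not representable at 1e-6 m LAS scale")
  con <- file(path, "wb")
  on.exit(close(con))
  w8  <- function(x) writeBin(as.integer(x), con, size = 1L)
  w16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wd  <- function(x) writeBin(as.double(x), con, size = 8L, endian = "little")
  writeBin(charToRaw("LASF"), con)
  w16(0L); w16(0L)                      # source id, global encoding
  writeBin(raw(16L), con)               # GUID
  w8(1L); w8(2L)                        # version 1.2
  writeBin(raw(64L), con)               # system id + generating software
  w16(1L); w16(2026L)                   # day / year
  w16(227L)                             # header size
  w32(227L)                             # offset to point data
  w32(0L)                               # number of VLRs
  w8(0L)                                # point data record format 0
  w16(20L)                              # record length
  w32(n)                                # number of points
  w32(c(n, 0L, 0L, 0L, 0L))             # points by return
  wd(rep(scale, 3L))                    # x/y/z scale
  wd(c(0, 0, 0))                        # x/y/z offset
  rng <- if (n > 0L) apply(cloud$xyz, 2L, range) else matrix(0, 2L, 3L)
  wd(c(rng[2, 1], rng[1, 1], rng[2, 2], rng[1, 2], rng[2, 3], rng[1, 3]))
  if (n == 0L) return(invisible(path))
  ixyz <- round(t(cloud$xyz) / scale)
  if (any(abs(ixyz) >= 2^31)) stop("coordinate overflow at LAS scale")
  coord <- matrix(writeBin(as.integer(ixyz), raw(), size = 4L,
                           endian = "little"), nrow = 12L)
  mid <- matrix(raw(6L), nrow = 6L, ncol = n)   # intensity, flags, class, ...
  mid[3L, ] <- as.raw(0x09)                     # return 1 of 1
  psid <- matrix(writeBin(as.integer(cloud$label %||% rep(0L, n)), raw(),
                          size = 2L, endian = "little"), nrow = 2L)
  writeBin(as.vector(rbind(coord, mid, psid)), con)
  invisible(path)
}
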