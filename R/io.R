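# Volume I/O: MetaImage (.mha/.mhd+.raw), NRRD (.nrrd/.nhdr), NIfTI
# (.nii/.nii.gz). Vector fields are stored with the component axis fastest
# on disk (MetaImage channels, NRRD leading vector axis, NIfTI 5th dim);
# internally the package always keeps three separate planar grids.

detect_format <- function(path) {
  p <- tolower(path)
  if (grepl("\\.(mha|mhd)$", p)) return("metaimage")
  if (grepl("\\.(nrrd|nhdr)$", p)) return("nrrd")
  if (grepl("\\.nii(\\.gz)?$", p)) return("nifti")
  stop("cannot auto-detect format from extension: ", path)
}

check_format <- function(format, path) {
  format <- match.arg(format, c("auto", "metaimage", "nrrd", "nifti", "jpeg",
                                "png", "dicom"))
  if (format == "auto") format <- detect_format(path)
  if (!format %in% c("metaimage", "nrrd", "nifti"))
    stop("unsupported format: ", format)
  format
}

#' Read a displacement vector field
#'
#' Reads a 3-component 3-D vector volume from MetaImage, NRRD or NIfTI.
#' The on-disk component axis is detected from the header and normalised;
#' the result always holds three planar grids with components ordered along
#' the first, second, third physical axes. Displacements are assumed stored
#' in mm; see the `units` argument.
#'
#' @param path file to read.
#' @param format `"metaimage"`, `"nrrd"`, `"nifti"`, or `"auto"` (from the
#'   extension).
#' @param units `"mm"` (default) or `"voxels"`; voxel displacements are
#'   converted to mm by multiplying with the per-axis spacing on load.
#' @return A [vector_field()].
#' @export
read_field <- function(path, format = "auto", units = c("mm", "voxels")) {
  units <- match.arg(units)
  raw <- read_any(path, format)
  if (raw$ncomp == 1L)
    stop("not a vector field: ", path, " holds a scalar volume")
  if (raw$ncomp != 3L)
    stop("component count must be 3, found ", raw$ncomp, " in ", path)
  a <- raw$data  # shape (nx, ny, nz, 3)
  if (units == "voxels")
    for (k in 1:3) a[, , , k] <- a[, , , k] * raw$spacing[k]
  vector_field(a[, , , 1], a[, , , 2], a[, , , 3],
               spacing = raw$spacing, origin = raw$origin,
               direction = raw$direction)
}

#' Read a scalar image volume
#'
#' @param path file to read.
#' @param format as in [read_field()].
#' @return An [image_volume()].
#' @export
read_image <- function(path, format = "auto") {
  raw <- read_any(path, format)
  if (raw$ncomp != 1L)
    stop("not a scalar volume: ", path, " holds ", raw$ncomp, " components")
  image_volume(raw$data[, , , 1], spacing = raw$spacing, origin = raw$origin,
               direction = raw$direction)
}

#' Write a displacement vector field
#'
#' @param field a [vector_field()].
#' @param path output file; the parent directory must exist.
#' @param format `"metaimage"`, `"nrrd"`, `"nifti"`, or `"auto"`.
#' @export
write_field <- function(field, path, format = "auto") {
  stopifnot(inherits(field, "vector_field"))
  a <- array(0, c(field$shape, 3L))
  a[, , , 1] <- field$u; a[, , , 2] <- field$v; a[, , , 3] <- field$w
  write_any(a, header_of(field), path, format)
}

#' Write a scalar volume (image, mask, or vortex map)
#'
#' @param map an [image_volume()] / `vortex_map`, or a list with `values`
#'   plus grid header fields.
#' @param path output file.
#' @param format `"metaimage"`, `"nrrd"`, `"nifti"`, or `"auto"`.
#' @export
write_scalar_map <- function(map, path, format = "auto") {
  a <- array(map$values, c(dim(map$values), 1L))
  write_any(a, header_of(map), path, format)
}

# ---- shared low-level plumbing -------------------------------------------

read_any <- function(path, format) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- check_format(format, path)
  switch(format,
         metaimage = read_metaimage(path),
         nrrd = read_nrrd(path),
         nifti = read_nifti_any(path))
}

write_any <- function(data4, header, path, format) {
  format <- check_format(format, path)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory not writable: ", dir)
  switch(format,
         metaimage = write_metaimage(data4, header, path),
         nrrd = write_nrrd(data4, header, path),
         nifti = write_nifti_any(data4, header, path))
  invisible(NULL)
}

# ---- MetaImage ------------------------------------------------------------

met_types <- c(MET_DOUBLE = 8L, MET_FLOAT = 4L, MET_SHORT = 2L,
               MET_USHORT = 2L, MET_INT = 4L, MET_UINT = 4L,
               MET_CHAR = 1L, MET_UCHAR = 1L)

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("malformed MetaImage header: ", path)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) next
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr[["NDims"]], "3")) stop("non-3D data in ", path)
  dims <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  ncomp <- as.integer(hdr[["ElementNumberOfChannels"]] %||% "1")
  spacing <- as.numeric(strsplit(hdr[["ElementSpacing"]] %||% "1 1 1",
                                 "\\s+")[[1]])
  origin <- as.numeric(strsplit(hdr[["Offset"]] %||% "0 0 0", "\\s+")[[1]])
  direction <- if (!is.null(hdr[["TransformMatrix"]]))
    matrix(as.numeric(strsplit(hdr[["TransformMatrix"]], "\\s+")[[1]]),
           3, 3, byrow = TRUE) else diag(3)
  type <- hdr[["ElementType"]]
  if (!type %in% names(met_types)) stop("unsupported ElementType ", type)
  msb <- identical(tolower(hdr[["BinaryDataByteOrderMSB"]] %||% "false"),
                   "true")
  compressed <- identical(tolower(hdr[["CompressedData"]] %||% "false"),
                          "true")
  n <- prod(dims) * ncomp
  datafile <- hdr[["ElementDataFile"]]
  if (identical(datafile, "LOCAL")) {
    buf <- read_voxel_buffer(con, n, type, msb, compressed)
  } else {
    dpath <- file.path(dirname(path), datafile)
    if (!file.exists(dpath)) stop("raw data file not found: ", dpath)
    dcon <- file(dpath, "rb"); on.exit(close(dcon), add = TRUE)
    buf <- read_voxel_buffer(dcon, n, type, msb, compressed)
  }
  # channel-interleaved on disk -> (nx, ny, nz, ncomp) planar
  data4 <- if (ncomp > 1L)
    aperm(array(buf, c(ncomp, dims)), c(2, 3, 4, 1))
  else array(buf, c(dims, 1L))
  list(data = data4, ncomp = ncomp, spacing = spacing, origin = origin,
       direction = direction)
}

read_voxel_buffer <- function(con, n, type, msb, compressed) {
  endian <- if (msb) "big" else "little"
  size <- met_types[[type]]
  what <- if (type %in% c("MET_DOUBLE", "MET_FLOAT")) "double" else "integer"
  signed <- !type %in% c("MET_UCHAR", "MET_USHORT")
  if (compressed) {
    raw <- readBin(con, "raw", n = n * size + 1024L)
    raw <- memDecompress(raw, type = "gzip")
    readBin(raw, what, n = n, size = size, endian = endian, signed = signed)
  } else {
    readBin(con, what, n = n, size = size, endian = endian, signed = signed)
  }
}

write_metaimage <- function(data4, header, path) {
  dims <- dim(data4)[1:3]; ncomp <- dim(data4)[4]
  is_mhd <- grepl("\\.mhd$", tolower(path))
  datafile <- if (is_mhd) paste0(sub("\\.mhd$", "", basename(path),
                                     ignore.case = TRUE), ".raw") else "LOCAL"
  lines <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("TransformMatrix =",
          paste(format(as.vector(t(header$direction)), digits = 17),
                collapse = " ")),
    paste("Offset =", paste(format(header$origin, digits = 17),
                            collapse = " ")),
    "CenterOfRotation = 0 0 0",
    paste("ElementSpacing =", paste(format(header$spacing, digits = 17),
                                    collapse = " ")),
    paste("DimSize =", paste(dims, collapse = " ")))
  if (ncomp > 1L)
    lines <- c(lines, paste("ElementNumberOfChannels =", ncomp))
  lines <- c(lines, "ElementType = MET_DOUBLE",
             paste("ElementDataFile =", datafile))
  buf <- if (ncomp > 1L) as.vector(aperm(data4, c(4, 1, 2, 3)))
         else as.vector(data4[, , , 1])
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(lines, con)
  if (is_mhd) {
    rcon <- file(file.path(dirname(path), datafile), "wb")
    on.exit(close(rcon), add = TRUE)
    writeBin(buf, rcon, size = 8L, endian = "little")
  } else {
    writeBin(buf, con, size = 8L, endian = "little")
  }
}

# ---- NRRD -----------------------------------------------------------------

nrrd_types <- list(
  "double" = list(size = 8L, what = "double"),
  "float"  = list(size = 4L, what = "double"),
  "int"    = list(size = 4L, what = "integer"),
  "short"  = list(size = 2L, what = "integer"),
  "uchar"  = list(size = 1L, what = "integer"))

parse_nrrd_vector <- function(s) {
  # "(a,b,c)" -> numeric; "none" -> NULL
  s <- trimws(s)
  if (identical(s, "none")) return(NULL)
  as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]])
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (!grepl("^NRRD000", magic)) stop("not a NRRD file: ", path)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L || nchar(line) == 0L) break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexpr(":=?", line), invert = TRUE)[[1]]
    hdr[[trimws(kv[1])]] <- trimws(kv[2])
  }
  ndim <- as.integer(hdr[["dimension"]])
  sizes <- as.integer(strsplit(hdr[["sizes"]], "\\s+")[[1]])
  kinds <- strsplit(hdr[["kinds"]] %||% "", "\\s+")[[1]]
  sd_raw <- if (!is.null(hdr[["space directions"]]))
    regmatches(hdr[["space directions"]],
               gregexpr("\\([^)]*\\)|none", hdr[["space directions"]]))[[1]]
  else NULL
  if (ndim == 3L) {
    vec_axis <- 0L
  } else if (ndim == 4L) {
    # the non-space axis is the component axis
    vec_axis <- if (!is.null(sd_raw)) which(sd_raw == "none")
                else which(kinds %in% c("vector", "3-vector", "covariant-vector"))
    if (length(vec_axis) != 1L)
      stop("cannot identify the vector axis in ", path)
  } else stop("non-3D data in ", path, " (dimension ", ndim, ")")
  sp_axes <- setdiff(seq_len(ndim), vec_axis)
  dims <- sizes[sp_axes]
  ncomp <- if (ndim == 3L) 1L else sizes[vec_axis]
  # space directions: column i = direction[, i] * spacing[i]
  if (!is.null(sd_raw)) {
    cols <- lapply(sd_raw[sp_axes], parse_nrrd_vector)
    M <- do.call(cbind, cols)
    spacing <- sqrt(colSums(M^2))
    direction <- sweep(M, 2, spacing, "/")
  } else {
    spacing <- if (!is.null(hdr[["spacings"]]))
      as.numeric(strsplit(hdr[["spacings"]], "\\s+")[[1]])[sp_axes]
    else c(1, 1, 1)
    direction <- diag(3)
  }
  origin <- if (!is.null(hdr[["space origin"]]))
    parse_nrrd_vector(hdr[["space origin"]]) else c(0, 0, 0)
  type <- hdr[["type"]]
  if (!type %in% names(nrrd_types)) stop("unsupported NRRD type ", type)
  tinfo <- nrrd_types[[type]]
  endian <- if (identical(hdr[["endian"]], "big")) "big" else "little"
  n <- prod(sizes)
  enc <- hdr[["encoding"]] %||% "raw"
  buf <- if (enc == "raw") {
    readBin(con, tinfo$what, n = n, size = tinfo$size, endian = endian)
  } else if (enc %in% c("gzip", "gz")) {
    raw <- readBin(con, "raw", n = file.size(path))
    readBin(memDecompress(raw, type = "gzip"), tinfo$what, n = n,
            size = tinfo$size, endian = endian)
  } else stop("unsupported NRRD encoding ", enc)
  arr <- array(buf, sizes)
  data4 <- if (ndim == 3L) array(arr, c(dims, 1L))
           else aperm(arr, c(sp_axes, vec_axis))
  list(data = data4, ncomp = ncomp, spacing = spacing, origin = origin,
       direction = direction)
}

write_nrrd <- function(data4, header, path) {
  dims <- dim(data4)[1:3]; ncomp <- dim(data4)[4]
  M <- header$direction %*% diag(header$spacing)
  svec <- function(v) sprintf("(%s)", paste(format(v, digits = 17),
                                            collapse = ","))
  sd_cols <- vapply(1:3, function(i) svec(M[, i]), "")
  if (ncomp > 1L) {
    head <- c("NRRD0004", "type: double", "dimension: 4",
              "space: left-posterior-superior",
              paste("sizes:", ncomp, paste(dims, collapse = " ")),
              paste("space directions: none", paste(sd_cols, collapse = " ")),
              "kinds: vector domain domain domain",
              "endian: little", "encoding: raw",
              paste("space origin:", svec(header$origin)))
    buf <- as.vector(aperm(data4, c(4, 1, 2, 3)))
  } else {
    head <- c("NRRD0004", "type: double", "dimension: 3",
              "space: left-posterior-superior",
              paste("sizes:", paste(dims, collapse = " ")),
              paste("space directions:", paste(sd_cols, collapse = " ")),
              "kinds: domain domain domain",
              "endian: little", "encoding: raw",
              paste("space origin:", svec(header$origin)))
    buf <- as.vector(data4[, , , 1])
  }
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(c(head, ""), con)
  writeBin(buf, con, size = 8L, endian = "little")
}

# ---- NIfTI (via RNifti) ---------------------------------------------------

read_nifti_any <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 3L) {
    data4 <- array(as.array(img), c(d, 1L)); ncomp <- 1L
  } else if (length(d) == 5L && d[4] == 1L) {
    data4 <- array(as.array(img), c(d[1:3], d[5])); ncomp <- d[5]
  } else if (length(d) == 4L) {
    data4 <- as.array(img); ncomp <- d[4]
  } else stop("non-3D data in ", path)
  af <- RNifti::xform(img)
  M <- af[1:3, 1:3]
  spacing <- sqrt(colSums(M^2))
  list(data = data4, ncomp = ncomp, spacing = spacing,
       origin = af[1:3, 4], direction = sweep(M, 2, spacing, "/"))
}

write_nifti_any <- function(data4, header, path) {
  ncomp <- dim(data4)[4]
  arr <- if (ncomp > 1L) array(data4, c(dim(data4)[1:3], 1L, ncomp))
         else array(data4[, , , 1], dim(data4)[1:3])
  img <- RNifti::asNifti(arr)
  af <- diag(4)
  af[1:3, 1:3] <- header$direction %*% diag(header$spacing)
  af[1:3, 4] <- header$origin
  # set only the sform: RNifti's qform<- re-derives pixdim and drops
  # anisotropic scale from a previously assigned sform
  RNifti::`sform<-`(img, structure(af, code = 2L)) -> img
  if (ncomp > 1L) img$intent_code <- 1007L
  RNifti::writeNifti(img, path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
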