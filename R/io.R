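# File I/O and run plumbing: a minimal NIfTI-1 reader/writer (no suitable
# dependency is available, so the 348-byte header is handled directly),
# JSON protocol files, CSV tables, and deterministic seed streams.
# All times in files are seconds; never milliseconds.

#' Write a 3-D/4-D array as an uncompressed NIfTI-1 file
#'
#' Little-endian `.nii` with a float32 payload and voxel spacing in the
#' `pixdim` fields. Covers exactly what the pipeline needs; it is not a
#' general NIfTI implementation.
#'
#' @param x numeric array, 3 or 4 dimensions.
#' @param path output path ending in `.nii`.
#' @param spacing voxel spacing `(dx, dy, dz)` in mm.
#' @export
write_nifti <- function(x, path, spacing = c(1.6, 1.6, 5)) {
  x <- as.array(x)
  nd <- length(dim(x))
  if (!nd %in% c(3L, 4L)) stop("array must be 3-D or 4-D", call. = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v, size) writeBin(as.integer(v), con, size = size, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")
  wi(348L, 4)                                   # sizeof_hdr
  writeBin(raw(35), con)                        # unused through dim_info
  wi(1L, 1)                                     # dim_info (none)
  dims <- c(nd, dim(x), rep(1L, 7 - nd))
  wi(dims, 2)                                   # dim[8]
  wf(c(0, 0, 0))                                # intent_p1..p3
  wi(0L, 2)                                     # intent_code
  wi(16L, 2)                                    # datatype = float32
  wi(32L, 2)                                    # bitpix
  wi(0L, 2)                                     # slice_start
  wf(c(1, spacing, 1, 1, 1, 1))                 # pixdim[8] (qfac 1)
  wf(352)                                       # vox_offset
  wf(1); wf(0)                                  # scl_slope, scl_inter
  wi(0L, 2); wi(0L, 1); wi(2L, 1)               # slice_end, slice_code, xyzt_units (mm)
  wf(c(0, 0, 0))                                # cal_max, cal_min, slice_duration
  wf(0)                                         # toffset
  wi(c(0L, 0L), 4)                              # glmax, glmin
  writeBin(raw(80 + 24), con)                   # descrip, aux_file
  wi(c(0L, 0L), 2)                              # qform_code, sform_code
  wf(rep(0, 6))                                 # quatern b,c,d, qoffset x,y,z
  wf(c(spacing[1], 0, 0, 0))                    # srow_x
  wf(c(0, spacing[2], 0, 0))                    # srow_y
  wf(c(0, 0, spacing[3], 0))                    # srow_z
  writeBin(raw(16), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  writeBin(raw(4), con)                         # extension flag
  writeBin(as.numeric(x), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an uncompressed NIfTI-1 file
#'
#' Supports little-endian files with int16/int32/float32/float64 payloads
#' and applies any scl_slope/scl_inter scaling.
#'
#' @param path `.nii` path.
#' @return List with `data` (array) and `spacing` (mm).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n, size) readBin(con, "integer", n = n, size = size, endian = "little")
  rf <- function(n) readBin(con, "numeric", n = n, size = 4, endian = "little")
  hdr_size <- ri(1, 4)
  if (!identical(hdr_size, 348L))
    stop("not a little-endian NIfTI-1 file", call. = FALSE)
  invisible(readBin(con, "raw", 36))
  dims <- ri(8, 2)
  invisible(rf(3)); invisible(ri(1, 2))
  datatype <- ri(1, 2)
  invisible(ri(1, 2)); invisible(ri(1, 2))
  pixdim <- rf(8)
  vox_offset <- rf(1)
  scl_slope <- rf(1); scl_inter <- rf(1)
  nd <- dims[1]
  shape <- dims[2:(1 + nd)]
  n <- prod(shape)
  seek(con, where = vox_offset, origin = "start")
  data <- switch(as.character(datatype),
    "4" = readBin(con, "integer", n = n, size = 2, endian = "little"),
    "8" = readBin(con, "integer", n = n, size = 4, endian = "little"),
    "16" = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    "64" = readBin(con, "numeric", n = n, size = 8, endian = "little"),
    stop(sprintf("unsupported NIfTI datatype %d", datatype), call. = FALSE))
  data <- as.numeric(data)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  list(data = array(data, shape), spacing = pixdim[2:4])
}

#' Read and write image series (NIfTI + times sidecar)
#'
#' The contrast times have no home in the NIfTI header, so they travel in a
#' JSON sidecar named `<path>.times.json` with key `times_s`. Reading fails
#' with the expected sidecar name when it is missing.
#'
#' @param series an `image_series`.
#' @param path `.nii` path.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "image_series"))
  write_nifti(series$data, path, series$spacing)
  jsonlite::write_json(list(times_s = series$times),
                       paste0(path, ".times.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  sidecar <- paste0(path, ".times.json")
  if (!file.exists(sidecar))
    stop(sprintf("missing sidecar with contrast times: expected %s", sidecar),
         call. = FALSE)
  nii <- read_nifti(path)
  if (length(dim(nii$data)) != 4L)
    stop("expected a 4-D series (x, y, z, contrast)", call. = FALSE)
  times <- as.numeric(jsonlite::read_json(sidecar, simplifyVector = TRUE)$times_s)
  image_series(nii$data, times, nii$spacing)
}

#' Write and read quantitative maps (value + SE + exclusion volumes)
#'
#' Three NIfTI files: `<stem>.nii`, `<stem>_se.nii`, `<stem>_excl.nii`
#' (exclusion as 0/1). Excluded voxels carry NA values in memory and 0 on
#' disk.
#'
#' @param map a `quant_map`.
#' @param stem output path without extension.
#' @export
write_map <- function(map, stem) {
  stopifnot(inherits(map, "quant_map"))
  v <- map$values; v[!is.finite(v)] <- 0
  s <- map$standard_errors; s[!is.finite(s)] <- 0
  write_nifti(v, paste0(stem, ".nii"), map$spacing)
  write_nifti(s, paste0(stem, "_se.nii"), map$spacing)
  write_nifti(array(as.numeric(map$exclusion), dim(map$values)),
              paste0(stem, "_excl.nii"), map$spacing)
  jsonlite::write_json(list(kind = map$kind), paste0(stem, ".json"),
                       auto_unbox = TRUE)
  invisible(stem)
}

#' @rdname write_map
#' @export
read_map <- function(stem) {
  v <- read_nifti(paste0(stem, ".nii"))
  s <- read_nifti(paste0(stem, "_se.nii"))
  e <- read_nifti(paste0(stem, "_excl.nii"))
  kind <- jsonlite::read_json(paste0(stem, ".json"))$kind
  vals <- v$data
  excl <- e$data > 0.5
  vals[excl] <- NA_real_
  quant_map(vals, s$data, excl, kind = kind, spacing = v$spacing)
}

#' Protocol files
#'
#' JSON with keys `kind`, `times_s`, `tr_s`, `inversion_scale`. The package
#' ships the in vivo T1/T2 protocols in
#' `system.file("extdata", "protocols_invivo.json", package = "qmrfit")`.
#'
#' @param protocol a `relax_protocol`.
#' @param path JSON path.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "relax_protocol"))
  jsonlite::write_json(list(kind = protocol$kind,
                            times_s = protocol$times,
                            tr_s = protocol$tr,
                            inversion_scale = protocol$inversion_scale),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_protocol
#' @param name for multi-protocol files, the entry to load.
#' @export
read_protocol <- function(path, name = NULL) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(name)) j <- j[[name]]
  for (key in c("kind", "times_s", "tr_s", "inversion_scale"))
    if (is.null(j[[key]]))
      stop(sprintf("protocol file missing key '%s'", key), call. = FALSE)
  relax_protocol(j$kind, as.numeric(j$times_s), j$tr_s, j$inversion_scale)
}

#' CSV tables with required-column checking
#'
#' UTF-8 CSV, `.` decimal separator.
#'
#' @param path CSV path.
#' @param required character vector of column names that must be present.
#' @export
read_table_checked <- function(path, required = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("missing column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  df
}

#' @rdname read_table_checked
#' @param df data.frame to write.
#' @export
write_table_checked <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Derive a child seed from a master seed
#'
#' Deterministic 31-bit hash of the master seed and any extra keys, so each
#' stochastic stage gets its own reproducible stream and scores stay
#' comparable across runs and argument orders.
#'
#' @param master integer master seed.
#' @param ... additional keys (numbers or strings).
#' @return Integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  m <- 2147483647
  h <- as.numeric(master) %% m
  for (key in list(...)) {
    codes <- utf8ToInt(paste0(as.character(key), "|"))
    for (cc in codes) h <- (h * 31 + cc) %% m
  }
  as.integer(max(1, h))
}
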