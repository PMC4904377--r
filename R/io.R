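#' Read and write tilt-angle text files
#'
#' One angle in degrees per line, ascending (the IMOD `.rawtlt` dialect).
#'
#' @param path file path.
#' @return for the reader, an `angle_set`.
#' @export
read_tilt_angles <- function(path) {
  a <- scan(path, what = numeric(), quiet = TRUE)
  angle_set(a, scheme = "uniform")
}

#' @param a an `angle_set` to write.
#' @rdname read_tilt_angles
#' @export
write_tilt_angles <- function(a, path) {
  stopifnot(inherits(a, "angle_set"))
  writeLines(formatC(a$angles_deg, format = "f", digits = 2), path)
  invisible(path)
}

mrc_mode_float <- 2L

#' Write a volume as an MRC2014 file
#'
#' Float32 payload in x-fastest order (NX = n_x, NY = n_y, NZ = n_z), with
#' dimensions, pixel size, density statistics and the MRC2014 machine stamp
#' recorded in the 1024-byte header.
#'
#' @param v an `n_x x n_y x n_z` array (a matrix is treated as `n_y = 1`).
#' @param path output path.
#' @param pixel_size physical pixel size recorded in the cell dimensions.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(v, path, pixel_size = 1) {
  if (is.matrix(v)) v <- array(v, dim = c(nrow(v), 1, ncol(v)))
  stopifnot(is.array(v), length(dim(v)) == 3)
  d <- dim(v)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                                            # 0: NX NY NZ
  wi(mrc_mode_float)                               # 12: MODE 2 = float32
  wi(c(0, 0, 0))                                   # 16: NXSTART..
  wi(d)                                            # 28: MX MY MZ
  wf(d * pixel_size)                               # 40: CELLA
  wf(c(90, 90, 90))                                # 52: CELLB
  wi(c(1, 2, 3))                                   # 64: MAPC MAPR MAPS
  wf(c(min(v), max(v), mean(v)))                   # 76: DMIN DMAX DMEAN
  wi(c(0, 0))                                      # 88: ISPG, NSYMBT
  writeBin(raw(8), con)                            # 96: EXTRA
  writeChar("MRCO", con, nchars = 4, eos = NULL)   # 104: EXTTYP
  wi(20140L)                                       # 108: NVERSION
  writeBin(raw(84), con)                           # 112: EXTRA
  wf(c(0, 0, 0))                                   # 196: ORIGIN
  writeChar("MAP ", con, nchars = 4, eos = NULL)   # 208
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con) # 212: MACHST little-endian
  wf(sd(v))                                        # 216: RMS
  wi(0L)                                           # 220: NLABL
  writeBin(raw(800), con)                          # 224: labels
  writeBin(as.numeric(v), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRC2014 volume
#'
#' Accepts mode 2 (float32) files written by [write_mrc()] or other tools;
#' returns the payload as an `n_x x n_y x n_z` array.
#'
#' @param path input path.
#' @return list with `volume` (array) and `pixel_size`.
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  if (length(d) < 3 || any(d <= 0) || any(d > 1e5))
    stop("malformed MRC header: implausible dimensions (NX NY NZ = ",
         paste(d, collapse = " "), ")")
  if (mode != mrc_mode_float)
    stop("malformed MRC header: unsupported MODE ", mode,
         " (only float32 mode 2 is handled)")
  ri(3)                    # NXSTART
  mx <- ri(3)              # MX MY MZ
  cella <- rf(3)
  pixel_size <- if (mx[1] > 0) cella[1] / mx[1] else 1
  seek(con, 92)
  nsymbt <- ri(1)
  seek(con, 1024 + nsymbt)
  n <- prod(d)
  vals <- rf(n)
  if (length(vals) < n)
    stop("malformed MRC file: payload truncated (", length(vals), " of ",
         n, " voxels)")
  list(volume = array(vals, dim = d), pixel_size = pixel_size)
}

#' Write a volume as a (float32) TIFF stack
#'
#' One directory per y-slice is not used; the stack holds n_z sections of
#' `n_x x n_y` images, matching the MRC layout.
#'
#' @param v an `n_x x n_y x n_z` array.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(v, path) {
  stopifnot(is.array(v), length(dim(v)) == 3)
  d <- dim(v)
  imgs <- lapply(seq_len(d[3]), function(k) t(v[, , k]))  # rows = y
  tiff::writeTIFF(imgs, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  invisible(path)
}

#' @rdname write_tiff_stack
#' @export
read_tiff_stack <- function(path) {
  imgs <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(imgs)) imgs <- list(imgs)
  d1 <- dim(imgs[[1]])
  v <- array(0, dim = c(d1[2], d1[1], length(imgs)))
  for (k in seq_along(imgs)) v[, , k] <- t(imgs[[k]])
  v
}

#' Write a tilt series (projection stack + angle file)
#'
#' The stack is stored as an MRC file with one section per tilt: section a
#' holds the `sigma x n_y` projection image at angle a (detector bins along
#' x, the tilt axis along y).
#'
#' @param sinos list of `sinogram` objects, one per y-slice.
#' @param path_mrc,path_angles output paths for the stack and `.rawtlt` file.
#' @return `path_mrc`, invisibly.
#' @export
write_tilt_series <- function(sinos, path_mrc, path_angles) {
  stopifnot(length(sinos) >= 1, inherits(sinos[[1]], "sinogram"))
  tau <- nrow(sinos[[1]]$data); sigma <- ncol(sinos[[1]]$data)
  stack <- array(0, dim = c(sigma, length(sinos), tau))
  for (iy in seq_along(sinos)) stack[, iy, ] <- t(sinos[[iy]]$data)
  write_mrc(stack, path_mrc)
  write_tilt_angles(sinos[[1]]$angles, path_angles)
  invisible(path_mrc)
}

#' Read a tilt series into per-slice sinograms
#'
#' @param path_mrc MRC projection stack (one section per tilt).
#' @param path_angles matching `.rawtlt` angle file.
#' @return list with `sinograms` (one per y-slice) and `angles`.
#' @export
read_tilt_series <- function(path_mrc, path_angles) {
  stack <- read_mrc(path_mrc)$volume
  angles <- read_tilt_angles(path_angles)
  if (dim(stack)[3] != length(angles))
    stop("tilt series mismatch: stack has ", dim(stack)[3],
         " projections but angle file lists ", length(angles))
  sinos <- lapply(seq_len(dim(stack)[2]), function(iy)
    sinogram(t(stack[, iy, ]), angles))
  list(sinograms = sinos, angles = angles)
}

run_config_keys <- c("kind", "seed", "dims", "max_tilt", "increment",
                     "undersample", "method", "modality", "nu", "lambda_tv",
                     "lambda_i", "lambda_w", "outer", "inner", "noise",
                     "workers", "filter", "iters", "relax", "output")

#' Read and write YAML run configurations
#'
#' A flat key-value configuration mirroring the command-line flags; unknown
#' keys are rejected so that configs round-trip losslessly.
#'
#' @param path YAML file path.
#' @return for the reader, a named list of settings.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  bad <- setdiff(names(cfg), run_config_keys)
  if (length(bad) > 0)
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  cfg
}

#' @param cfg named list of settings to write.
#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  bad <- setdiff(names(cfg), run_config_keys)
  if (length(bad) > 0)
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  yaml::write_yaml(cfg, path)
  invisible(path)
}
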