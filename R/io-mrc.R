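#' Volume grid
#'
#' 3D scalar volume with physical coordinate convention: the center of voxel
#' (i, j, k) (0-based indices) sits at \code{origin + (i, j, k) * voxel_size}
#' Angstrom. The value array is indexed \code{values[i+1, j+1, k+1]} with x
#' fastest, matching MRC column/row/section order for the standard axis
#' mapping (mapc, mapr, maps) = (1, 2, 3).
#'
#' @param values 3D numeric array.
#' @param voxel_size voxel edge lengths (Angstrom), length 1 or 3.
#' @param origin physical position (Angstrom) of the center of voxel
#'   (0, 0, 0), length 3.
#' @return an object of class \code{volume_grid}.
#' @export
volume_grid <- function(values, voxel_size = 1, origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3) stop("values must be a 3D array")
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  if (any(voxel_size <= 0)) stop("voxel_size components must be > 0")
  structure(list(values = values, voxel_size = voxel_size,
                 origin = rep_len(as.numeric(origin), 3)),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume_grid: %s voxels, voxel size %s A\n",
              paste(dim(x$values), collapse = " x "),
              paste(signif(x$voxel_size, 4), collapse = " x ")))
  invisible(x)
}

mrc_mode_of <- function(values) 2L  # float32 on write

#' Read an MRC2014 volume
#'
#' Minimal MRC2014 reader covering the modes used for segmentation masks and
#' density maps: 0 (int8), 1 (int16), 2 (float32). Voxel size is taken as
#' cella / (mx, my, mz); the origin is read from the ORIGIN header words.
#' Requires the standard axis mapping (mapc, mapr, maps) = (1, 2, 3).
#'
#' @param path file path.
#' @return a \code{\link{volume_grid}}.
#' @export
read_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 1024)
  if (length(hdr_raw) < 1024)
    stop("format error: MRC header truncated (", length(hdr_raw), " bytes)")
  int_at <- function(w, n = 1)
    readBin(hdr_raw[(4 * (w - 1) + 1):(4 * (w - 1) + 4 * n)], "integer",
            n = n, size = 4, endian = "little")
  flt_at <- function(w, n = 1)
    readBin(hdr_raw[(4 * (w - 1) + 1):(4 * (w - 1) + 4 * n)], "numeric",
            n = n, size = 4, endian = "little")
  nxyz <- int_at(1, 3)
  mode <- int_at(4)
  mxyz <- int_at(8, 3)
  cella <- flt_at(11, 3)
  map_axes <- int_at(17, 3)
  origin <- flt_at(50, 3)
  map_id <- rawToChar(hdr_raw[(4 * 52 + 1):(4 * 52 + 3)])
  if (any(nxyz <= 0))
    stop("format error: non-positive dimension field nx/ny/nz")
  if (!identical(map_axes, c(1L, 2L, 3L)))
    stop("format error: unsupported axis order (mapc,mapr,maps) = ",
         paste(map_axes, collapse = ","))
  n <- prod(nxyz)
  vals <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = n, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n = n, size = 2,
                             endian = "little")),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    stop("format error: unsupported MRC mode ", mode))
  if (length(vals) < n)
    stop("format error: data section truncated (expected ", n, " voxels, got ",
         length(vals), ")")
  voxel <- ifelse(mxyz > 0, cella / mxyz, 1)
  volume_grid(array(vals, dim = nxyz), voxel_size = voxel, origin = origin)
}

#' Write an MRC2014 volume (mode 2, float32)
#'
#' @param vol a \code{\link{volume_grid}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_grid"))
  d <- dim(vol$values)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  v <- as.numeric(vol$values)
  wi(d)                       # nx ny nz
  wi(2L)                      # mode float32
  wi(c(0L, 0L, 0L))           # nxstart
  wi(d)                       # mx my mz
  wf(vol$voxel_size * d)      # cella
  wf(c(90, 90, 90))           # cellb
  wi(c(1L, 2L, 3L))           # mapc mapr maps
  wf(c(min(v), max(v), mean(v)))
  wi(c(0L, 0L))               # ispg, nsymbt
  wi(rep(0L, 25))             # extra (words 25-49)
  wf(vol$origin)              # origin (words 50-52)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian machst
  wf(stats::sd(v))
  wi(0L)                      # nlabl
  writeBin(raw(800), con)     # labels
  wf(v)
  invisible(path)
}

#' Extract a point cloud from a segmentation mask
#'
#' Each voxel with value above \code{threshold} becomes one point at the
#' voxel-center physical coordinate (0-based indices, see
#' \code{\link{volume_grid}}).
#'
#' @param vol a \code{\link{volume_grid}}.
#' @param threshold density threshold; must be finite. The segmentation
#'   criterion used on any particular map must be supplied by the caller.
#' @param leaflet leaflet label for the resulting cloud.
#' @return a \code{\link{leaflet_cloud}}.
#' @export
mask_to_points <- function(vol, threshold, leaflet = "upper") {
  stopifnot(inherits(vol, "volume_grid"), is.finite(threshold))
  idx <- which(vol$values > threshold, arr.ind = TRUE)
  if (nrow(idx) == 0)
    stop("empty-cloud error: no voxels above threshold ", threshold)
  xyz <- sweep(sweep(idx - 1, 2, vol$voxel_size, "*"), 2, vol$origin, "+")
  leaflet_cloud(xyz, leaflet = leaflet,
                provenance = sprintf("mask threshold %g", threshold))
}
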