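#' Read or write leaflet point tables (CSV, columns x,y,z in Angstrom)
#'
#' @param path file path.
#' @param leaflet leaflet label for the cloud read.
#' @return \code{read_points}: a \code{\link{leaflet_cloud}}.
#' @export
read_points <- function(path, leaflet = "upper") {
  df <- utils::read.csv(path)
  if (!all(c("x", "y", "z") %in% names(df)))
    stop("format error: point table must have columns x,y,z")
  leaflet_cloud(as.matrix(df[, c("x", "y", "z")]), leaflet = leaflet,
                provenance = path)
}

#' @param cloud a \code{\link{leaflet_cloud}}.
#' @rdname read_points
#' @export
write_points <- function(cloud, path) {
  utils::write.csv(data.frame(x = cloud$x, y = cloud$y, z = cloud$z),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a field or map as CSV (long format x,y,value)
#'
#' @param field a \code{height_field} or \code{scalar_map}.
#' @param path output path.
#' @export
write_field <- function(field, path) {
  xy <- field_xy(field)
  utils::write.csv(data.frame(x = as.numeric(xy$x), y = as.numeric(xy$y),
                              value = as.numeric(field$z),
                              valid = as.logical(field$valid)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a field written by write_field
#'
#' @param path CSV path.
#' @param what "height_field" or "scalar_map".
#' @return the reconstructed field.
#' @export
read_field <- function(path, what = c("height_field", "scalar_map")) {
  what <- match.arg(what)
  df <- utils::read.csv(path)
  xs <- sort(unique(df$x)); ys <- sort(unique(df$y))
  g <- grid_spec(range(xs), range(ys), spacing = min(diff(xs)))
  o <- order(df$y, df$x)
  z <- matrix(df$value[o], length(xs), length(ys))
  valid <- matrix(df$valid[o], length(xs), length(ys))
  if (what == "height_field") height_field(g, z, valid)
  else scalar_map(g, z, valid)
}

# ---- multi-frame trajectory formats ----------------------------------------

#' Write a trajectory as multi-frame GRO or XYZ
#'
#' GRO stores positions in nanometres (converted from the Angstrom
#' coordinates held internally); XYZ stays in Angstrom.
#'
#' @param traj a \code{\link{lipid_trajectory}}.
#' @param path output path; format chosen by extension (.gro or .xyz).
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "lipid_trajectory"))
  ext <- tolower(tools::file_ext(path))
  na <- dim(traj$coords)[1]; nf <- dim(traj$coords)[3]
  atoms <- traj$atoms
  resid <- if (!is.null(atoms$lipid)) atoms$lipid else seq_len(na)
  resname <- if (!is.null(atoms$resname)) atoms$resname else "LIP"
  name <- if (!is.null(atoms$name)) atoms$name else "X"
  con <- file(path, "wt")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    co <- traj$coords[, , f, drop = FALSE]
    dim(co) <- c(na, 3)
    if (ext == "gro") {
      writeLines(sprintf("frame t=%g", traj$time[f]), con)
      writeLines(sprintf("%5d", na), con)
      writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                         resid %% 100000L, substr(resname, 1, 5),
                         substr(name, 1, 5), seq_len(na) %% 100000L,
                         co[, 1] / 10, co[, 2] / 10, co[, 3] / 10), con)
      box <- if (is.null(traj$box)) c(0, 0, 0) else traj$box[, f]
      writeLines(sprintf("%10.5f%10.5f%10.5f", box[1] / 10, box[2] / 10,
                         box[3] / 10), con)
    } else if (ext == "xyz") {
      writeLines(as.character(na), con)
      writeLines(sprintf("frame t=%g", traj$time[f]), con)
      writeLines(sprintf("%-5s %12.6f %12.6f %12.6f", name,
                         co[, 1], co[, 2], co[, 3]), con)
    } else stop("unsupported trajectory format: .", ext)
  }
  invisible(path)
}

#' Read a multi-frame GRO or XYZ trajectory
#'
#' All frames must have the same atom count. GRO coordinates (nm) are
#' converted to Angstrom. Atom annotations come from the first frame; richer
#' annotations (lipid ids, roles) can be attached afterwards or supplied via
#' \code{atoms}.
#'
#' @param path .gro or .xyz file.
#' @param atoms optional replacement annotation table (e.g. from the
#'   generating \code{trajectory_spec}).
#' @return a \code{\link{lipid_trajectory}}.
#' @export
read_trajectory <- function(path, atoms = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path)
  frames <- list(); boxes <- list(); times <- c(); ann <- NULL
  i <- 1L; f <- 0L
  while (i <= length(lines)) {
    f <- f + 1L
    if (ext == "gro") {
      if (i + 1L > length(lines)) stop("format error: truncated GRO at line ", i)
      na <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
      if (is.na(na)) stop("format error: bad atom count at line ", i + 1L)
      if (i + 1L + na + 1L > length(lines))
        stop("format error: truncated GRO frame at line ", i)
      rows <- lines[(i + 2L):(i + 1L + na)]
      co <- 10 * cbind(as.numeric(substr(rows, 21, 28)),
                       as.numeric(substr(rows, 29, 36)),
                       as.numeric(substr(rows, 37, 44)))
      if (any(is.na(co)))
        stop("format error: unparsable coordinate near line ",
             i + 1L + which(rowSums(is.na(co)) > 0)[1])
      if (is.null(ann))
        ann <- data.frame(
          lipid = as.integer(substr(rows, 1, 5)),
          resname = trimws(substr(rows, 6, 10)),
          name = trimws(substr(rows, 11, 15)),
          stringsAsFactors = FALSE)
      box <- 10 * as.numeric(strsplit(trimws(lines[i + 2L + na]),
                                      "\\s+")[[1]])[1:3]
      frames[[f]] <- co; boxes[[f]] <- box
      times[f] <- f
      i <- i + 3L + na
    } else if (ext == "xyz") {
      na <- suppressWarnings(as.integer(trimws(lines[i])))
      if (is.na(na)) stop("format error: bad atom count at line ", i)
      if (i + 1L + na > length(lines))
        stop("format error: truncated XYZ frame at line ", i)
      rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + na)]), "\\s+")
      co <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
      if (any(is.na(co)))
        stop("format error: unparsable coordinate near line ", i + 2L)
      if (is.null(ann))
        ann <- data.frame(name = vapply(rows, `[`, "", 1),
                          stringsAsFactors = FALSE)
      frames[[f]] <- co; boxes[[f]] <- rep(NA_real_, 3)
      times[f] <- f
      i <- i + 2L + na
    } else stop("unsupported trajectory format: .", ext)
  }
  nas <- vapply(frames, nrow, 0L)
  if (length(unique(nas)) != 1)
    stop("consistency error: atom counts differ between frames (",
         paste(unique(nas), collapse = ", "), ")")
  coords <- array(unlist(frames), c(nas[1], 3, length(frames)))
  if (!is.null(atoms)) ann <- atoms
  box <- if (all(is.na(unlist(boxes)))) NULL else
    matrix(unlist(boxes), 3, length(frames))
  lipid_trajectory(coords, ann, box = box, time = times)
}
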