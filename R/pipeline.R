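known_cryoet_keys <- c("upper", "lower", "threshold", "spacing", "span",
                       "degree", "center", "region_radius", "exclude_radius",
                       "out_dir", "seed")
known_md_keys <- c("trajectory", "topology", "spacing", "carbons",
                   "hysteresis_gap", "mixture_k", "seed", "out_dir",
                   "gate_a", "gate_b", "rmsd_reference", "center",
                   "region_radius")

validate_config <- function(cfg, known) {
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0)
    stop("validation error: unknown config key(s): ",
         paste(bad, collapse = ", "))
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file.
#' @return the configuration as a named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

load_leaflet_input <- function(x, threshold = NULL, leaflet = "upper") {
  if (inherits(x, "leaflet_cloud")) return(x)
  if (!is.character(x) || !file.exists(x))
    stop("configuration error: missing leaflet input (", x, ")")
  ext <- tolower(tools::file_ext(x))
  if (ext %in% c("mrc", "map")) {
    if (is.null(threshold))
      stop("configuration error: MRC leaflet input requires a threshold")
    mask_to_points(read_volume(x), threshold, leaflet = leaflet)
  } else read_points(x, leaflet = leaflet)
}

#' Cryo-ET-style membrane pipeline: leaflet clouds to curvature and thickness
#'
#' End-to-end run: load or accept two leaflet point sets (CSV tables or MRC
#' masks plus a threshold), reconstruct smooth height fields
#' (\code{\link{fit_leaflet}}), derive mean-curvature and thickness maps,
#' and summarize the region around a given lateral center (regional radius
#' of curvature within \code{region_radius}, far-field radius outside
#' \code{exclude_radius}, mean thickness near and far). Deterministic given
#' the config; the summary carries the config hash.
#'
#' @param cfg named list (or YAML read by \code{\link{read_config}}) with
#'   keys: \code{upper}, \code{lower} (paths or \code{leaflet_cloud}s),
#'   optional \code{threshold}, \code{spacing} (default 4), \code{span}
#'   (default 0.2), \code{degree} (default 2), \code{center} (lateral c(x,y),
#'   default grid center), \code{region_radius} (default 40, the
#'   protein-vicinity radius), \code{exclude_radius} (default
#'   2 x region_radius), optional \code{out_dir}.
#' @return list with the fitted fields, maps, and a \code{summary} list;
#'   written as JSON/CSV files when \code{out_dir} is set.
#' @export
run_cryoet_pipeline <- function(cfg) {
  cfg <- validate_config(cfg, known_cryoet_keys)
  if (is.null(cfg$upper) || is.null(cfg$lower))
    stop("configuration error: both 'upper' and 'lower' leaflet inputs are required")
  spacing <- cfg$spacing %||% 4
  lcfg <- loess_config(span_fraction = cfg$span %||% 0.2,
                       degree = cfg$degree %||% 2)
  up_pts <- load_leaflet_input(cfg$upper, cfg$threshold, "upper")
  lo_pts <- load_leaflet_input(cfg$lower, cfg$threshold, "lower")
  grid <- grid_for_points(up_pts, spacing = spacing)
  up <- fit_leaflet(up_pts, grid, lcfg)
  lo <- fit_leaflet(lo_pts, grid, lcfg)
  H_up <- mean_curvature_map(up)
  H_lo <- mean_curvature_map(lo)
  th <- thickness_map(up, lo)
  center <- cfg$center %||% c(mean(range(grid$x)), mean(range(grid$y)))
  rr <- cfg$region_radius %||% 40
  er <- cfg$exclude_radius %||% (2 * rr)
  near_lo <- radius_of_curvature(H_lo, center, radius = rr)
  far_up <- radius_of_curvature(H_up, center, radius = Inf,
                                exclude_radius = er)
  xy <- field_xy(th)
  rdist <- sqrt((xy$x - center[1])^2 + (xy$y - center[2])^2)
  th_near <- mean(th$z[th$valid & rdist <= rr])
  th_far <- mean(th$z[th$valid & rdist >= er])
  summary <- list(
    config_hash = config_hash(cfg[setdiff(names(cfg), "out_dir")]),
    center = center, region_radius = rr, exclude_radius = er,
    radius_near_lumenal = near_lo$radius, mean_H_near = near_lo$mean_H,
    radius_far_cytosolic = far_up$radius, mean_H_far = far_up$mean_H,
    thickness_near = th_near, thickness_far = th_far,
    n_points_upper = nrow(up_pts), n_points_lower = nrow(lo_pts))
  out <- list(upper = up, lower = lo, curvature_upper = H_up,
              curvature_lower = H_lo, thickness = th, summary = summary)
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(out, cfg$out_dir)
  out
}

#' MD-style membrane pipeline: trajectory to order, thickness and events
#'
#' End-to-end trajectory run: phosphate height fields per leaflet, thickness
#' map and pooled per-frame thickness samples with a two-component Gaussian
#' mixture fit, order-parameter profile and local order maps, flip-flop event
#' log, and (when selections are configured) lateral-gate distance and
#' superposition RMSD series.
#'
#' @param cfg named list with keys: \code{trajectory} (path or
#'   \code{lipid_trajectory}), optional \code{topology} (annotation table for
#'   file input), \code{spacing} (default 10), \code{carbons} (default 2:15),
#'   \code{hysteresis_gap} (default 10), \code{mixture_k} (default 2),
#'   \code{seed} (default 0), optional \code{gate_a}/\code{gate_b} and
#'   \code{rmsd_reference}, optional \code{out_dir}.
#' @return list of results with a \code{summary} list.
#' @export
run_md_pipeline <- function(cfg) {
  cfg <- validate_config(cfg, known_md_keys)
  traj <- cfg$trajectory
  if (is.null(traj)) stop("configuration error: 'trajectory' is required")
  if (is.character(traj)) traj <- read_trajectory(traj, atoms = cfg$topology)
  if (n_frames(traj) < 1) stop("input error: empty trajectory")
  spacing <- cfg$spacing %||% 10
  heads <- which(traj$atoms$role == "head")
  hx <- range(traj$coords[heads, 1, ]); hy <- range(traj$coords[heads, 2, ])
  grid <- grid_spec(hx, hy, spacing = spacing)
  up <- phosphate_height_field(traj, "upper", grid)
  lo <- phosphate_height_field(traj, "lower", grid)
  th <- thickness_map(up, lo)
  # pooled per-frame thickness samples: per-cell upper minus lower mean head z
  samples <- as.numeric(th$z[th$valid])
  mix <- if (sum(is.finite(samples)) >= 10 * (cfg$mixture_k %||% 2))
    fit_gaussian_mixture(samples, k = cfg$mixture_k %||% 2,
                         seed = cfg$seed %||% 0) else NULL
  carbons <- cfg$carbons %||% 2:15
  has_chain <- any(traj$atoms$role == "H")
  ord <- if (has_chain) order_parameters(traj, carbons) else NULL
  omap <- if (has_chain) local_order_map(traj, grid, carbons) else NULL
  events <- detect_flipflops(traj, cfg$hysteresis_gap %||% 10)
  gate <- if (!is.null(cfg$gate_a) && !is.null(cfg$gate_b))
    gate_distance(traj, cfg$gate_a, cfg$gate_b) else NULL
  rmsd <- if (!is.null(cfg$rmsd_reference))
    superpose_rmsd(traj, cfg$rmsd_reference) else NULL
  summary <- list(
    config_hash = config_hash(cfg[setdiff(names(cfg),
                                          c("trajectory", "topology",
                                            "rmsd_reference", "out_dir"))]),
    n_frames = n_frames(traj), n_lipids = length(heads),
    mean_thickness = mean(samples),
    mixture_means = if (!is.null(mix)) mix$means else NULL,
    mixture_sds = if (!is.null(mix)) mix$sds else NULL,
    chain_average_SCD = if (!is.null(ord)) attr(ord, "chain_average") else NULL,
    n_flipflops = nrow(events$events),
    mean_gate_distance = if (!is.null(gate)) mean(gate) else NULL,
    mean_rmsd = if (!is.null(rmsd)) mean(rmsd) else NULL)
  out <- list(upper = up, lower = lo, thickness = th, mixture = mix,
              order_profile = ord, order_map = omap, events = events,
              gate = gate, rmsd = rmsd, summary = summary)
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(out, cfg$out_dir)
  out
}

write_pipeline_outputs <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(out)) {
    x <- out[[nm]]
    if (inherits(x, "mem_field"))
      write_field(x, file.path(dir, paste0(nm, ".csv")))
  }
  if (!is.null(out$events))
    utils::write.csv(out$events$events, file.path(dir, "flipflops.csv"),
                     row.names = FALSE)
  jsonlite::write_json(out$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
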