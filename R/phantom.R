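# Synthetic 3D vascular phantoms with ground-truth vessel geometry.
#
# The phantom stands in for dye-labelled cortical vasculature: cylindrical
# vessels (piecewise-linear centerlines) embedded in a weakly fluorescent
# background volume. Coordinates are in micrometres; the z axis is depth,
# with z = 0 at the tissue surface (optionally offset via `z_offset_um` so a
# deep band of tissue can be modelled without voxelising everything above it).

#' Phantom configuration
#'
#' @param volume_shape Integer vector `c(nx, ny, nz)` of voxels.
#' @param voxel_size_um Isotropic voxel edge length, micrometres.
#' @param vessel_count Number of vessels to place.
#' @param diameter_range_um Length-2 numeric, min/max vessel diameter (um).
#'   Cortical capillaries and small vessels span roughly 3-10 um.
#' @param dye_concentration Relative dye concentration inside vessels.
#' @param background_concentration Relative concentration outside vessels
#'   (residual plasma signal); must not exceed `dye_concentration`.
#' @param z_offset_um Depth of the shallowest voxel plane below the tissue
#'   surface (um). 0 means the volume starts at the pia.
#' @param axial_fraction Probability that a vessel runs along the depth
#'   axis (a penetrating arteriole/venule) rather than laterally; axial
#'   vessels cross every slice of the volume.
#' @param seed Integer seed; each vessel draws from its own substream so
#'   vessel k is reproducible regardless of `vessel_count`.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(volume_shape = c(64L, 64L, 64L),
                           voxel_size_um = 2,
                           vessel_count = 5L,
                           diameter_range_um = c(3, 10),
                           dye_concentration = 1,
                           background_concentration = 0.02,
                           z_offset_um = 0,
                           axial_fraction = 0.3,
                           seed = 1L) {
  stopifnot(length(volume_shape) == 3L, all(volume_shape >= 1))
  assert_scalar_pos(voxel_size_um, "voxel_size_um")
  stopifnot(length(diameter_range_um) == 2L)
  if (any(diameter_range_um <= 0)) {
    stop("`diameter_range_um` must be positive", call. = FALSE)
  }
  lateral_um <- min(volume_shape[1:2]) * voxel_size_um
  if (max(diameter_range_um) >= lateral_um) {
    stop("`diameter_range_um` must lie within (0, min lateral extent)",
         call. = FALSE)
  }
  assert_scalar_pos(dye_concentration, "dye_concentration", strict = FALSE)
  assert_scalar_pos(background_concentration, "background_concentration",
                    strict = FALSE)
  if (background_concentration > dye_concentration) {
    stop("`background_concentration` must not exceed `dye_concentration`",
         call. = FALSE)
  }
  assert_scalar_pos(z_offset_um, "z_offset_um", strict = FALSE)
  assert_fraction(axial_fraction, "axial_fraction")
  if (vessel_count < 0) stop("`vessel_count` must be >= 0", call. = FALSE)
  structure(
    list(volume_shape = as.integer(volume_shape),
         voxel_size_um = voxel_size_um,
         vessel_count = as.integer(vessel_count),
         diameter_range_um = as.numeric(diameter_range_um),
         dye_concentration = dye_concentration,
         background_concentration = background_concentration,
         z_offset_um = z_offset_um,
         axial_fraction = axial_fraction,
         seed = as.integer(seed)),
    class = "phantom_config")
}

# Extents of the volume in micrometres (x, y, z-local).
phantom_extent_um <- function(config) config$volume_shape * config$voxel_size_um

# Sample one vessel geometry from its own RNG substream. The vessel runs
# across the volume along a lateral principal axis with a random depth tilt
# and a mid-point lateral bow, giving a smoothly curved cylinder that stays
# fully inside the volume (centerline inset by radius + one voxel).
sample_vessel <- function(config, k) {
  ext <- phantom_extent_um(config)
  with_seed(substream_seed(config$seed, paste0("vessel-", k)), {
    radius <- stats::runif(1, config$diameter_range_um[1] / 2,
                           config$diameter_range_um[2] / 2)
    margin <- radius + config$voxel_size_um
    if (any(ext <= 2 * margin)) {
      stop("phantom volume too small to place a vessel of radius ",
           signif(radius, 3), " um", call. = FALSE)
    }
    af <- config$axial_fraction
    axis <- sample(1:3, 1L, prob = c((1 - af) / 2, (1 - af) / 2, af))
    p0 <- p1 <- numeric(3)
    p0[axis] <- margin
    p1[axis] <- ext[axis] - margin
    for (d in setdiff(1:3, axis)) {
      p0[d] <- stats::runif(1, margin, ext[d] - margin)
      # modest tilt: end point near the start in the transverse directions
      p1[d] <- min(max(p0[d] + stats::runif(1, -0.15, 0.15) * ext[d], margin),
                   ext[d] - margin)
    }
    mid <- (p0 + p1) / 2
    bow <- setdiff(1:3, axis)
    for (d in bow) {
      mid[d] <- min(max(mid[d] + stats::runif(1, -0.05, 0.05) * ext[d], margin),
                    ext[d] - margin)
    }
    # quadratic Bezier through p0, mid, p1 discretised to a polyline
    t <- seq(0, 1, length.out = 9L)
    centerline <- outer((1 - t)^2, p0) + outer(2 * t * (1 - t), mid) +
      outer(t^2, p1)
    colnames(centerline) <- c("x", "y", "z")
    centerline[, 3] <- centerline[, 3] + config$z_offset_um
    list(radius_um = radius, centerline = centerline)
  })
}

# Minimum distance from points (n x 3 matrix, um) to a polyline (m x 3).
dist_to_polyline <- function(points, polyline) {
  d2 <- rep(Inf, nrow(points))
  for (i in seq_len(nrow(polyline) - 1L)) {
    a <- polyline[i, ]
    ab <- polyline[i + 1L, ] - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    ap1 <- points[, 1] - a[1]; ap2 <- points[, 2] - a[2]; ap3 <- points[, 3] - a[3]
    t <- pmin(pmax((ap1 * ab[1] + ap2 * ab[2] + ap3 * ab[3]) / len2, 0), 1)
    seg2 <- (ap1 - t * ab[1])^2 + (ap2 - t * ab[2])^2 + (ap3 - t * ab[3])^2
    d2 <- pmin(d2, seg2)
  }
  sqrt(d2)
}

#' Build a phantom from an explicit vessel list
#'
#' Voxels whose centres fall within a vessel radius of its centerline take
#' the dye concentration; all others keep the background concentration
#' (centre-of-voxel inclusion, no anti-aliasing).
#'
#' @param config A [phantom_config()].
#' @param vessels List of `list(radius_um =, centerline =)` entries;
#'   centerlines are n x 3 matrices in absolute micrometres (z includes
#'   `z_offset_um`).
#' @return An object of class `snspd_phantom` with elements `concentration`
#'   (array `nx x ny x nz`), `vessels` (tibble), `depth_axis_um`, `config`.
#' @export
phantom_from_vessels <- function(config, vessels) {
  shp <- config$volume_shape
  vox <- config$voxel_size_um
  conc <- array(config$background_concentration, dim = shp)
  if (length(vessels)) {
    xs <- (seq_len(shp[1]) - 0.5) * vox
    ys <- (seq_len(shp[2]) - 0.5) * vox
    zs <- (seq_len(shp[3]) - 0.5) * vox + config$z_offset_um
    pts <- cbind(rep(xs, times = shp[2] * shp[3]),
                 rep(rep(ys, each = shp[1]), times = shp[3]),
                 rep(zs, each = shp[1] * shp[2]))
    for (v in vessels) {
      # restrict the distance evaluation to the vessel's bounding box
      lo <- apply(v$centerline, 2, min) - v$radius_um - vox
      hi <- apply(v$centerline, 2, max) + v$radius_um + vox
      inbox <- pts[, 1] >= lo[1] & pts[, 1] <= hi[1] &
        pts[, 2] >= lo[2] & pts[, 2] <= hi[2] &
        pts[, 3] >= lo[3] & pts[, 3] <= hi[3]
      idx <- which(inbox)
      if (!length(idx)) next
      d <- dist_to_polyline(pts[idx, , drop = FALSE], v$centerline)
      conc[idx[d <= v$radius_um]] <- config$dye_concentration
    }
  }
  vt <- tibble::tibble(
    vessel = seq_along(vessels),
    radius_um = vapply(vessels, function(v) v$radius_um, numeric(1)),
    centerline = lapply(vessels, function(v) v$centerline))
  structure(
    list(concentration = conc,
         vessels = vt,
         depth_axis_um = (seq_len(shp[3]) - 0.5) * vox + config$z_offset_um,
         config = config),
    class = "snspd_phantom")
}

#' Generate a synthetic vascular phantom
#'
#' Places `vessel_count` smoothly curved cylindrical vessels (diameters drawn
#' uniformly from `diameter_range_um`) fully inside the volume and rasterises
#' them onto the voxel grid. Deterministic for a fixed seed; vessel k uses an
#' independent RNG substream, so it is identical whatever the total count.
#'
#' @param config A [phantom_config()].
#' @return An `snspd_phantom`; see [phantom_from_vessels()].
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  vessels <- lapply(seq_len(config$vessel_count),
                    function(k) sample_vessel(config, k))
  phantom_from_vessels(config, vessels)
}

#' @export
print.snspd_phantom <- function(x, ...) {
  shp <- x$config$volume_shape
  cat(sprintf("<snspd_phantom> %d x %d x %d voxels (%.3g um), %d vessel(s), depth %.0f-%.0f um\n",
              shp[1], shp[2], shp[3], x$config$voxel_size_um,
              nrow(x$vessels), min(x$depth_axis_um), max(x$depth_axis_um)))
  invisible(x)
}

# Nearest voxel z-plane index for an absolute depth (um).
phantom_slice_index <- function(phantom, slice_z_um) {
  z <- phantom$depth_axis_um
  if (slice_z_um < z[1] - phantom$config$voxel_size_um / 2 ||
      slice_z_um > z[length(z)] + phantom$config$voxel_size_um / 2) {
    stop("slice depth ", slice_z_um, " um is outside the phantom volume",
         call. = FALSE)
  }
  which.min(abs(z - slice_z_um))
}

#' Ground-truth signal and background masks for one depth slice
#'
#' Signal pixels lie within a vessel radius of any centerline at the slice
#' depth; background pixels are at least `dilation_um` away from every vessel
#' surface and from the slice border. The two masks are disjoint by
#' construction, with a conservative exclusion band between them.
#'
#' @param phantom An `snspd_phantom`.
#' @param slice_z_um Absolute slice depth (um); must lie within the volume.
#' @param dilation_um Width of the exclusion band (um).
#' @param grid Optional sampling grid `list(nx =, ny =, fov_um =)` matching a
#'   reconstructed image; defaults to the phantom voxel grid.
#' @return `list(signal, background)` of logical `nx x ny` matrices, with
#'   attribute `empty_signal` flagging a vessel-free slice.
#' @export
ground_truth_masks <- function(phantom, slice_z_um, dilation_um = 0,
                               grid = NULL) {
  stopifnot(inherits(phantom, "snspd_phantom"))
  assert_scalar_pos(dilation_um, "dilation_um", strict = FALSE)
  phantom_slice_index(phantom, slice_z_um) # validates depth
  cfg <- phantom$config
  if (is.null(grid)) {
    grid <- list(nx = cfg$volume_shape[1], ny = cfg$volume_shape[2],
                 fov_um = cfg$volume_shape[1] * cfg$voxel_size_um)
  }
  px <- grid$fov_um / grid$nx
  py <- grid$fov_um / grid$ny
  xs <- (seq_len(grid$nx) - 0.5) * px
  ys <- (seq_len(grid$ny) - 0.5) * py
  pts <- cbind(rep(xs, times = grid$ny), rep(ys, each = grid$nx), slice_z_um)
  surf_dist <- rep(Inf, nrow(pts)) # distance to nearest vessel surface
  for (i in seq_len(nrow(phantom$vessels))) {
    d <- dist_to_polyline(pts, phantom$vessels$centerline[[i]])
    surf_dist <- pmin(surf_dist, d - phantom$vessels$radius_um[i])
  }
  signal <- matrix(surf_dist <= 0, grid$nx, grid$ny)
  border <- pmin(pts[, 1], grid$fov_um - pts[, 1],
                 pts[, 2], grid$fov_um - pts[, 2])
  background <- matrix(surf_dist >= dilation_um & border >= dilation_um,
                       grid$nx, grid$ny)
  if (!any(signal)) {
    warning("slice at ", slice_z_um, " um contains no vessel signal",
            call. = FALSE)
  }
  structure(list(signal = signal, background = background),
            empty_signal = !any(signal))
}

#' Save / load a phantom as multi-page TIFF plus JSON sidecar
#'
#' The concentration volume is written one z-plane per TIFF page (32-bit
#' float, normalised to the volume maximum); vessel geometry, voxel size and
#' normalisation are stored in `<path>.json`.
#'
#' @param phantom An `snspd_phantom`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
save_phantom <- function(phantom, path) {
  shp <- phantom$config$volume_shape
  mx <- max(phantom$concentration)
  scale <- if (mx > 0) mx else 1
  pages <- lapply(seq_len(shp[3]), function(k) {
    phantom$concentration[, , k] / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  sidecar <- list(
    voxel_size_um = phantom$config$voxel_size_um,
    volume_shape = shp,
    z_offset_um = phantom$config$z_offset_um,
    scale = scale,
    dye_concentration = phantom$config$dye_concentration,
    background_concentration = phantom$config$background_concentration,
    diameter_range_um = phantom$config$diameter_range_um,
    axial_fraction = phantom$config$axial_fraction,
    seed = phantom$config$seed,
    vessels = lapply(seq_len(nrow(phantom$vessels)), function(i) {
      list(radius_um = phantom$vessels$radius_um[i],
           centerline = phantom$vessels$centerline[[i]])
    }))
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_phantom
#' @export
load_phantom <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = FALSE)
  meta[c("volume_shape", "voxel_size_um", "z_offset_um", "scale",
         "dye_concentration", "background_concentration",
         "diameter_range_um", "axial_fraction", "seed")] <-
    lapply(meta[c("volume_shape", "voxel_size_um", "z_offset_um", "scale",
                  "dye_concentration", "background_concentration",
                  "diameter_range_um", "axial_fraction", "seed")],
           function(x) unlist(x))
  shp <- as.integer(meta$volume_shape)
  conc <- array(0, dim = shp)
  for (k in seq_len(shp[3])) conc[, , k] <- pages[[k]] * meta$scale
  vessels <- lapply(meta$vessels, function(v) {
    cl <- do.call(rbind, lapply(v$centerline, unlist))
    colnames(cl) <- c("x", "y", "z")
    list(radius_um = unlist(v$radius_um), centerline = cl)
  })
  cfg <- phantom_config(
    volume_shape = shp, voxel_size_um = meta$voxel_size_um,
    vessel_count = length(vessels),
    diameter_range_um = as.numeric(meta$diameter_range_um),
    dye_concentration = meta$dye_concentration,
    background_concentration = meta$background_concentration,
    z_offset_um = meta$z_offset_um,
    axial_fraction = if (is.null(meta$axial_fraction)) 0.3
                     else meta$axial_fraction,
    seed = meta$seed)
  ph <- phantom_from_vessels(cfg, vessels)
  ph$concentration <- conc # keep the stored field verbatim
  ph
}
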