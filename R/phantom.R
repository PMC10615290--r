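#' Point-scatterer phantom
#'
#' A phantom is a list of point scatterers at (lateral, depth) positions in
#' meters with dimensionless reflectivities, plus optional named binary
#' region masks defined on an image grid and free-form metadata.
#'
#' @param positions Two-column matrix (lateral, depth) in meters.
#' @param reflectivities Numeric vector of finite amplitudes.
#' @param region_masks Named list of logical matrices (all same shape), or
#'   `NULL`.
#' @param metadata Free-form provenance list (seed, generator, geometry).
#' @return A `phantom` object.
#' @export
phantom <- function(positions, reflectivities,
                    region_masks = NULL, metadata = list()) {
  positions <- matrix(as.numeric(positions), ncol = 2)
  if (nrow(positions) < 1L) stop_invalid("phantom needs >= 1 scatterer")
  if (any(positions[, 2] <= 0))
    stop_invalid("scatterer depths must be strictly positive")
  if (length(reflectivities) != nrow(positions))
    stop_invalid("reflectivities length must match scatterer count")
  if (!all(is.finite(reflectivities)))
    stop_invalid("reflectivities must be finite")
  if (!is.null(region_masks)) {
    dims <- unique(lapply(region_masks, dim))
    if (length(dims) > 1L)
      stop_invalid("region masks must share one grid shape")
  }
  structure(list(positions = positions,
                 reflectivities = as.numeric(reflectivities),
                 region_masks = region_masks,
                 metadata = metadata), class = "phantom")
}

#' Merge phantoms (scatterer union)
#' @param a,b Phantoms.
#' @return Combined `phantom`; masks/metadata from `a` are kept.
#' @export
merge_phantoms <- function(a, b) {
  phantom(rbind(a$positions, b$positions),
          c(a$reflectivities, b$reflectivities),
          region_masks = a$region_masks,
          metadata = a$metadata)
}

#' Wire resolution phantom
#'
#' Single unit-reflectivity scatterer on axis, emulating a 30 um wire in
#' water used for point-spread-function FWHM characterization.
#'
#' @param depth Wire depth in meters (default 10 mm).
#' @return A `phantom` with one scatterer at (0, depth).
#' @export
wire_phantom <- function(depth = 10e-3) {
  phantom(cbind(0, depth), 1,
          metadata = list(generator = "wire", depth = depth))
}

# -- tooth/gingiva scene ------------------------------------------------------

smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

# piecewise-linear curve resampled by arc length from the margin
polyline_arclength <- function(xy) {
  seg <- sqrt(rowSums(diff(xy)^2))
  c(0, cumsum(seg))
}

#' Tooth/gingiva scene geometry
#'
#' Parametric stand-in for a buccal cross-section: a gently curved tooth
#' surface descending from the gingival margin, and a gingiva surface
#' constructed as a normal offset of the tooth surface. The offset width
#' ramps from 0 at the margin to `thickness_mm` and is constant beyond the
#' ramp, so the perpendicular tooth-to-gingiva distance at the measurement
#' point equals `thickness_mm` by construction.
#'
#' @param thickness_mm Target gingival thickness in mm (0.5-3).
#' @param margin Gingival-margin position (lateral, depth) in meters.
#' @param angle_deg Tooth-surface inclination from vertical, degrees.
#' @param curvature Signed curvature of the tooth surface (1/m).
#' @param length_mm Arc length of the modeled tooth surface, mm.
#' @param ramp_mm Arc length over which gingiva width ramps up, mm.
#' @param n_vertices Polyline sampling of each curve.
#' @return A `tooth_scene` with `tooth_curve`, `gingiva_curve` (two-column
#'   matrices ordered by arc length from the margin), and `margin`.
#' @export
tooth_scene <- function(thickness_mm, margin = c(1.2e-3, 2.0e-3),
                        angle_deg = 25, curvature = 40, length_mm = 7,
                        ramp_mm = 1.2, n_vertices = 400L) {
  if (thickness_mm < 0.5 || thickness_mm > 3)
    stop_invalid("thickness must lie in [0.5, 3] mm")
  s <- seq(0, length_mm * 1e-3, length.out = n_vertices)
  # heading from vertical; curvature bends the surface smoothly
  a0 <- angle_deg * pi / 180
  ang <- a0 + curvature * s
  # tooth surface: margin + integral of direction (-sin a, cos a)
  ds <- diff(s)[1]
  dirx <- -sin(ang); dirz <- cos(ang)
  tx <- margin[1] + c(0, cumsum((dirx[-1] + dirx[-length(s)]) / 2 * ds))
  tz <- margin[2] + c(0, cumsum((dirz[-1] + dirz[-length(s)]) / 2 * ds))
  tooth <- cbind(tx, tz)
  # unit normal pointing to the shallow (gingiva) side
  nx <- -cos(ang); nz <- -sin(ang)
  w <- thickness_mm * 1e-3 * smoothstep(s / (ramp_mm * 1e-3))
  gingiva <- cbind(tx + w * nx, tz + w * nz)
  structure(list(tooth_curve = tooth, gingiva_curve = gingiva,
                 margin = c(margin[1], margin[2]),
                 thickness_mm = thickness_mm, ramp_mm = ramp_mm,
                 arc = s), class = "tooth_scene")
}

# point on a polyline at arc distance d from its first vertex, plus unit
# tangent there (linear interpolation between vertices)
polyline_point_at <- function(xy, d) {
  al <- polyline_arclength(xy)
  if (d < 0 || d > al[length(al)])
    stop_invalid("arc distance beyond the modeled surface")
  i <- findInterval(d, al, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(xy) - 1L)
  seg <- xy[i + 1L, ] - xy[i, ]
  len <- sqrt(sum(seg^2))
  tang <- seg / len
  list(point = xy[i, ] + (d - al[i]) * tang, tangent = tang)
}

ray_segment_intersection <- function(p, dir, a, b) {
  # solve p + t dir = a + u (b - a), t > 1e-12, 0 <= u <= 1
  m <- cbind(dir, a - b)
  det <- m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
  if (abs(det) < 1e-18) return(NA_real_)
  rhs <- a - p
  t <- (rhs[1] * m[2, 2] - m[1, 2] * rhs[2]) / det
  u <- (m[1, 1] * rhs[2] - rhs[1] * m[2, 1]) / det
  if (t > 1e-9 && u >= -1e-9 && u <= 1 + 1e-9) t else NA_real_
}

#' Automated gingival-thickness measurement
#'
#' Reproduces the manual rule in software: locate the point on the tooth
#' surface at a given arc distance from the gingival margin (2 mm by
#' convention), draw the perpendicular to the tooth surface there, and
#' measure along it to the first intersection with the gingiva surface.
#' The result is reported at 0.01 mm precision.
#'
#' @param scene A `tooth_scene`.
#' @param distance_from_margin_mm Arc distance from the margin along the
#'   tooth surface, mm (default 2).
#' @return Thickness in mm, rounded to 0.01 mm.
#' @export
measure_thickness <- function(scene, distance_from_margin_mm = 2) {
  stopifnot(inherits(scene, "tooth_scene"))
  at <- polyline_point_at(scene$tooth_curve, distance_from_margin_mm * 1e-3)
  nrm <- c(-at$tangent[2], at$tangent[1])
  # orient the normal toward the gingiva side (toward the gingiva centroid)
  toward <- colMeans(scene$gingiva_curve) - at$point
  if (sum(nrm * toward) < 0) nrm <- -nrm
  g <- scene$gingiva_curve
  ts <- vapply(seq_len(nrow(g) - 1L), function(i)
    ray_segment_intersection(at$point, nrm, g[i, ], g[i + 1L, ]), numeric(1))
  ts <- ts[is.finite(ts)]
  if (length(ts) == 0L)
    stop_invalid("tooth-surface normal does not intersect the gingiva surface")
  round(min(ts) * 1e3, 2)
}

# vectorized even-odd point-in-polygon (polygon as closed two-column matrix)
points_in_polygon <- function(px, pz, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; zi <- poly[i, 2]
    xj <- poly[j, 1]; zj <- poly[j, 2]
    cross <- ((zi > pz) != (zj > pz)) &
      (px < (xj - xi) * (pz - zi) / (zj - zi + 1e-300) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

gingiva_polygon <- function(scene) {
  rbind(scene$tooth_curve, scene$gingiva_curve[rev(seq_len(
    nrow(scene$gingiva_curve))), ])
}

#' Tooth/gingiva speckle phantom
#'
#' Bright specular scatterers along the tooth surface, moderate ones along
#' the gingiva surface, and diffuse sub-resolution speckle (Poisson count,
#' Gaussian reflectivity) filling the gingiva between them. The
#' perpendicular gingival thickness at 2 mm from the margin equals
#' `thickness_mm` by construction; a "gingiva" region mask on `grid` is
#' attached when a grid is given.
#'
#' @param thickness_mm Gingival thickness at the 2 mm measurement point.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @param scene Optional pre-built `tooth_scene`; built from
#'   `thickness_mm` plus jittered geometry when `NULL`.
#' @param density Speckle scatterer density per mm^2 (default 40).
#' @param contrast Interface-to-speckle reflectivity ratio (default 8).
#' @param grid Optional `image_grid` on which to rasterize region masks.
#' @return A `phantom` carrying the `tooth_scene` in its metadata.
#' @export
tooth_phantom <- function(thickness_mm, seed = 1L, scene = NULL,
                          density = 40, contrast = 8, grid = NULL,
                          length_mm = 7,
                          margin_x = c(0.8e-3, 1.6e-3),
                          margin_z = c(1.6e-3, 2.6e-3)) {
  rng <- local_rng(seed)
  if (is.null(scene)) {
    scene <- tooth_scene(
      thickness_mm,
      margin = c(runif(1, margin_x[1], margin_x[2]),
                 runif(1, margin_z[1], margin_z[2])),
      angle_deg = runif(1, 15, 35),
      curvature = runif(1, 10, 60),
      length_mm = length_mm)
  }
  lam <- 1480 / 28e6   # wavelength scale for interface sampling
  tooth_pts <- resample_polyline(scene$tooth_curve, lam / 2)
  ging_pts <- resample_polyline(scene$gingiva_curve, lam / 2)
  poly <- gingiva_polygon(scene)
  area_mm2 <- abs(polygon_area(poly)) * 1e6
  n_speckle <- stats::rpois(1, density * area_mm2)
  sp <- sample_in_polygon(n_speckle, poly)
  pos <- rbind(tooth_pts, ging_pts, sp)
  refl <- c(rep(contrast, nrow(tooth_pts)),
            rep(contrast / 2, nrow(ging_pts)),
            rnorm(nrow(sp)))
  masks <- NULL
  if (!is.null(grid)) {
    gx <- grid_lateral(grid); gz <- grid_depth(grid)
    pts <- expand.grid(z = gz, x = gx)
    m <- matrix(points_in_polygon(pts$x, pts$z, poly),
                nrow = grid$n_rows, ncol = grid$n_cols)
    masks <- list(gingiva = m)
  }
  phantom(pos, refl, region_masks = masks,
          metadata = list(generator = "tooth", seed = seed, scene = scene,
                          thickness_mm = thickness_mm, density = density,
                          contrast = contrast))
}

polygon_area <- function(poly) {
  x <- poly[, 1]; z <- poly[, 2]
  0.5 * sum(x * c(z[-1], z[1]) - c(x[-1], x[1]) * z)
}

sample_in_polygon <- function(n, poly) {
  if (n == 0L) return(matrix(numeric(0), ncol = 2))
  xr <- range(poly[, 1]); zr <- range(poly[, 2])
  out <- matrix(numeric(0), ncol = 2)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 32L)
    px <- runif(m, xr[1], xr[2]); pz <- runif(m, zr[1], zr[2])
    keep <- points_in_polygon(px, pz, poly)
    out <- rbind(out, cbind(px[keep], pz[keep]))
  }
  out[seq_len(n), , drop = FALSE]
}

resample_polyline <- function(xy, spacing) {
  al <- polyline_arclength(xy)
  s <- seq(0, al[length(al)], by = spacing)
  t(vapply(s, function(d) polyline_point_at(xy, d)$point, numeric(2)))
}

#' Negative-control phantoms
#'
#' Non-tooth scenes emulating the study's negative-control inputs: an
#' anechoic vessel lumen in speckle (`"vessel"`), layered muscle-like
#' speckle bands (`"muscle"`), or a structureless uniform scatterer cloud
#' (`"noise"`). No "gingiva" mask is attached.
#'
#' @param kind One of `"vessel"`, `"muscle"`, `"noise"`.
#' @param seed Integer seed.
#' @param lateral_extent,depth_range Scene bounds in meters.
#' @param density Scatterer density per mm^2.
#' @return A `phantom`.
#' @export
negative_control_phantom <- function(kind = c("vessel", "muscle", "noise"),
                                     seed = 1L,
                                     lateral_extent = c(-3e-3, 3e-3),
                                     depth_range = c(1e-3, 9e-3),
                                     density = 40) {
  kind <- match.arg(kind)
  rng <- local_rng(seed)
  area_mm2 <- diff(lateral_extent) * diff(depth_range) * 1e6
  n <- stats::rpois(1, density * area_mm2)
  px <- runif(n, lateral_extent[1], lateral_extent[2])
  pz <- runif(n, depth_range[1], depth_range[2])
  amp <- rnorm(n)
  if (kind == "vessel") {
    cx <- mean(lateral_extent); cz <- mean(depth_range)
    rx <- diff(lateral_extent) / 6; rz <- diff(depth_range) / 6
    keep <- ((px - cx) / rx)^2 + ((pz - cz) / rz)^2 > 1
    px <- px[keep]; pz <- pz[keep]; amp <- amp[keep]
    meta <- list(ellipse = c(cx = cx, cz = cz, rx = rx, rz = rz))
  } else if (kind == "muscle") {
    band <- floor((pz - depth_range[1]) / (diff(depth_range) / 6))
    amp <- amp * ifelse(band %% 2 == 0, 1, 0.35)
    meta <- list(bands = 6)
  } else {
    meta <- list()
  }
  phantom(cbind(px, pz), amp,
          metadata = c(list(generator = kind, seed = seed), meta))
}

# seed-scoped RNG that restores the caller's stream when `env` exits
local_rng <- function(seed, env = parent.frame()) {
  withr::local_seed(as.integer(seed), .local_envir = env)
  invisible(NULL)
}
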