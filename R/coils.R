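# Loop-coil geometry and Biot-Savart sensitivity simulation.
#
# Each receive coil is a circular loop discretized into straight segments; the
# magnetic field at a pixel is the Biot-Savart sum over segments (unit current,
# the constant mu0*I/4pi dropped — sensitivities are normalized afterwards).
# The complex sensitivity uses the transverse field components, s = Bx - i*By,
# and the coil set is root-sum-of-squares normalized inside the support.

#' Place loop coils on a ring around the field of view
#'
#' Coil centers sit on a circle of radius `ring_radius` in the image plane,
#' outside the square field of view, with loop normals pointing at the FOV
#' center (the loop plane therefore contains the through-plane axis).
#'
#' @param n_coils number of loops (6 for the brain-like setup, 8 for knee-like).
#' @param loop_radius loop radius in mm (default 100).
#' @param fov field-of-view edge length in mm.
#' @param ring_radius distance of loop centers from the FOV center in mm;
#'   default `0.8 * fov`, which keeps every center outside the FOV square.
#' @param n_segments straight segments per loop (>= 16).
#' @return object of class `coil_geometry` with a `loops` list of
#'   `(center, normal, radius)` and `n_segments`.
#' @export
ring_coil_geometry <- function(n_coils = 6L, loop_radius = 100, fov = 256,
                               ring_radius = 0.8 * fov, n_segments = 64L) {
  if (loop_radius <= 0) stop_invalid("loop radius must be positive")
  if (n_segments < 16) stop_invalid("n_segments must be >= 16")
  ang <- 2 * pi * (seq_len(n_coils) - 1) / n_coils
  loops <- lapply(ang, function(a) {
    ctr <- c(ring_radius * cos(a), ring_radius * sin(a), 0)
    list(center = ctr, normal = -ctr / sqrt(sum(ctr^2)), radius = loop_radius)
  })
  geom <- structure(list(loops = loops, n_segments = as.integer(n_segments), fov = fov),
                    class = "coil_geometry")
  validate_coil_geometry(geom, fov)
  geom
}

loop_points <- function(loop, n_segments) {
  nrm <- loop$normal / sqrt(sum(loop$normal^2))
  # orthonormal basis of the loop plane; pick u away from the normal direction
  ref <- if (abs(nrm[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- ref - sum(ref * nrm) * nrm
  u <- u / sqrt(sum(u^2))
  v <- c(nrm[2] * u[3] - nrm[3] * u[2],
         nrm[3] * u[1] - nrm[1] * u[3],
         nrm[1] * u[2] - nrm[2] * u[1])
  th <- 2 * pi * (0:n_segments) / n_segments
  t(sapply(th, function(a) loop$center + loop$radius * (cos(a) * u + sin(a) * v)))
}

validate_coil_geometry <- function(geom, fov) {
  half <- fov / 2
  for (loop in geom$loops) {
    ctr <- loop$center
    if (abs(ctr[1]) <= half && abs(ctr[2]) <= half && abs(ctr[3]) <= half)
      stop_invalid("loop center lies inside the field of view")
    pts <- loop_points(loop, geom$n_segments)
    # a segment crossing the z = 0 plane inside the FOV square intersects the
    # image plane: reject such geometries
    for (i in seq_len(nrow(pts) - 1)) {
      z1 <- pts[i, 3]; z2 <- pts[i + 1, 3]
      if (z1 * z2 <= 0) {
        t <- if (z1 == z2) 0 else z1 / (z1 - z2)
        xc <- pts[i, 1] + t * (pts[i + 1, 1] - pts[i, 1])
        yc <- pts[i, 2] + t * (pts[i + 1, 2] - pts[i, 2])
        if (abs(xc) < half && abs(yc) < half)
          stop_invalid("loop intersects the image plane inside the FOV")
      }
    }
  }
  invisible(geom)
}

#' Biot-Savart field of a single current loop
#'
#' Discretized line-integral field (unit current, constant factors dropped) at
#' arbitrary 3D points. Mostly useful for validation: on the loop axis the
#' magnitude follows the closed form `2*pi*R^2 / (R^2 + z^2)^(3/2)`.
#'
#' @param center,normal,radius loop definition (mm; normal need not be unit).
#' @param points N x 3 matrix of evaluation points (mm).
#' @param n_segments discretization (>= 16).
#' @return N x 3 matrix of field vectors (Bx, By, Bz).
#' @export
loop_b_field <- function(center, normal, radius, points, n_segments = 64L) {
  if (radius <= 0) stop_invalid("radius must be positive")
  if (n_segments < 16) stop_invalid("n_segments must be >= 16")
  pts <- loop_points(list(center = center, normal = normal, radius = radius),
                     n_segments)
  points <- matrix(points, ncol = 3)
  B <- matrix(0, nrow(points), 3)
  for (i in seq_len(n_segments)) {
    dl <- pts[i + 1, ] - pts[i, ]
    mid <- (pts[i + 1, ] + pts[i, ]) / 2
    rx <- points[, 1] - mid[1]; ry <- points[, 2] - mid[2]; rz <- points[, 3] - mid[3]
    r3 <- (rx^2 + ry^2 + rz^2)^1.5
    B[, 1] <- B[, 1] + (dl[2] * rz - dl[3] * ry) / r3
    B[, 2] <- B[, 2] + (dl[3] * rx - dl[1] * rz) / r3
    B[, 3] <- B[, 3] + (dl[1] * ry - dl[2] * rx) / r3
  }
  B
}

#' Simulate coil sensitivities by the Biot-Savart law
#'
#' Evaluates each loop's field on the image plane (z = 0), forms the complex
#' sensitivity from the transverse components (`Bx - i*By`) and normalizes the
#' set so the root-sum-of-squares magnitude equals 1 at every pixel with a
#' nonzero field.
#'
#' @param geometry a `coil_geometry`.
#' @param rows,cols image grid size in pixels.
#' @param fov field-of-view edge length in mm.
#' @return object of class `coil_sensitivities`: `maps` (complex C x H x W,
#'   RSS-normalized), `support` (logical H x W), `raw` (unnormalized maps).
#' @export
biot_savart_sensitivities <- function(geometry, rows, cols, fov = geometry$fov) {
  if (fov <= 0) stop_invalid("fov must be positive")
  validate_coil_geometry(geometry, fov)
  n_coils <- length(geometry$loops)
  y <- seq(-fov / 2, fov / 2, length.out = rows)
  x <- seq(-fov / 2, fov / 2, length.out = cols)
  pts <- cbind(rep(x, each = rows), rep(y, times = cols), 0)

  raw <- array(0i, c(n_coils, rows, cols))
  for (ci in seq_len(n_coils)) {
    B <- loop_b_field(geometry$loops[[ci]]$center, geometry$loops[[ci]]$normal,
                      geometry$loops[[ci]]$radius, pts, geometry$n_segments)
    raw[ci, , ] <- matrix(complex(real = B[, 1], imaginary = -B[, 2]), rows, cols)
  }
  rss <- sqrt(apply(Mod(raw)^2, c(2, 3), sum))
  support <- rss > 0
  maps <- raw
  for (ci in seq_len(n_coils)) {
    m <- maps[ci, , ]
    m[support] <- m[support] / rss[support]
    m[!support] <- 0i
    maps[ci, , ] <- m
  }
  structure(list(maps = maps, support = support, raw = raw, fov = fov),
            class = "coil_sensitivities")
}

#' Uniform single-coil sensitivity (identity coil)
#'
#' Convenience constructor used in tests and single-coil reductions: one coil
#' with sensitivity 1 everywhere.
#' @param rows,cols grid size.
#' @return a `coil_sensitivities` object.
#' @export
uniform_sensitivities <- function(rows, cols) {
  maps <- array(1 + 0i, c(1, rows, cols))
  structure(list(maps = maps, support = matrix(TRUE, rows, cols),
                 raw = maps, fov = NA_real_),
            class = "coil_sensitivities")
}
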