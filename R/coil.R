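# Filament ("wire grid") coil model: geometry builders, Biot-Savart primary
# fields, and Neumann-formula inductances.

#' Filament coil
#'
#' A coil represented as a wire grid of short straight current filaments.
#' Each segment carries the fractional current `weight * I0`; a bundle of
#' `n` parallel filaments modeling a Litz conductor uses `weight = 1/n`.
#'
#' @param segments data frame (or tibble) with columns `xs, ys, zs`
#'   (segment start, m), `xe, ye, ze` (segment end, m) and `weight`
#'   (fractional current, dimensionless). A `filament` id column is kept if
#'   present.
#' @param I0 terminal current in amperes
#' @return an object of class `filament_coil`
#' @export
filament_coil <- function(segments, I0 = 1) {
  req <- c("xs", "ys", "zs", "xe", "ye", "ze", "weight")
  if (!all(req %in% names(segments)))
    rlang::abort(paste("`segments` must have columns", paste(req, collapse = ", ")))
  s0 <- unname(as.matrix(segments[, c("xs", "ys", "zs")]))
  s1 <- unname(as.matrix(segments[, c("xe", "ye", "ze")]))
  w <- as.numeric(segments$weight)
  len <- row_norms(s1 - s0)
  if (any(len <= 0)) rlang::abort("all segment lengths must be positive")
  structure(list(start = s0, end = s1, weight = w, I0 = I0,
                 filament = segments$filament %||% rep(1L, nrow(s0))),
            class = "filament_coil")
}

#' @export
print.filament_coil <- function(x, ...) {
  cat(sprintf("<filament_coil> %d segments, %d filament path(s), I0 = %g A\n",
              nrow(x$start), length(unique(x$filament)), x$I0))
  invisible(x)
}

#' @export
format.filament_coil <- function(x, ...) {
  sprintf("filament_coil(%d segments)", nrow(x$start))
}

#' Coerce a filament coil to a tibble of segments
#' @param x a `filament_coil`
#' @param ... unused
#' @export
as_tibble.filament_coil <- function(x, ...) {
  tibble::tibble(filament = x$filament,
                 xs = x$start[, 1], ys = x$start[, 2], zs = x$start[, 3],
                 xe = x$end[, 1], ye = x$end[, 2], ze = x$end[, 3],
                 weight = x$weight)
}

coil_midpoints <- function(coil) (coil$start + coil$end) / 2
coil_svec <- function(coil) coil$end - coil$start

# Concentric-ring placement of n filaments uniformly filling a disc of
# radius a. Ring radii sit at annulus mid-lines; counts follow annulus areas.
cross_section_offsets <- function(a, n) {
  if (n <= 1L || a <= 0) return(matrix(0, 1, 2))
  K <- max(1L, round(sqrt(n / 3)))
  wts <- 2 * seq_len(K) - 1
  counts <- round(n * wts / K^2)
  counts[K] <- counts[K] + (n - sum(counts))
  while (any(counts < 1)) {  # guarantee every ring populated
    i <- which.min(counts); j <- which.max(counts)
    counts[i] <- counts[i] + 1L; counts[j] <- counts[j] - 1L
  }
  out <- lapply(seq_len(K), function(j) {
    r <- a * (j - 0.5) / K
    th <- 2 * pi * (seq_len(counts[j]) - 1) / counts[j] + (j %% 2) * pi / counts[j]
    cbind(r * cos(th), r * sin(th))
  })
  do.call(rbind, out)
}

#' Circular loop coil
#'
#' Builds a single-turn circular loop of Litz wire in the z = 0 plane,
#' centered at the origin. The conductor cross-section (radius
#' `wire_radius`) is filled with `n_filaments` parallel filaments in
#' concentric rings, each carrying current `I0 / n_filaments` (uniform
#' current model).
#'
#' @param radius loop radius in m
#' @param wire_radius conductor radius in m (0 for an infinitely thin loop)
#' @param n_segments azimuthal segments per filament (at least 8)
#' @param n_filaments filaments filling the cross-section
#' @param I0 terminal current in A
#' @return a [filament_coil()]
#' @export
circular_loop_coil <- function(radius, wire_radius = 0, n_segments = 256L,
                               n_filaments = 1L, I0 = 1) {
  if (radius <= 0 || wire_radius < 0 || n_segments < 8L || n_filaments < 1L)
    rlang::abort("loop dimensions and discretization must be positive")
  off <- cross_section_offsets(wire_radius, n_filaments)
  th <- seq(0, 2 * pi, length.out = n_segments + 1L)
  segs <- lapply(seq_len(nrow(off)), function(f) {
    r <- radius + off[f, 1]          # radial offset
    z <- off[f, 2]                   # axial offset
    x <- r * cos(th); y <- r * sin(th)
    tibble::tibble(filament = f,
                   xs = x[-length(x)], ys = y[-length(y)], zs = z,
                   xe = x[-1], ye = y[-1], ze = z,
                   weight = 1 / nrow(off))
  })
  filament_coil(do.call(rbind, segs), I0 = I0)
}

#' Helical spiral coil
#'
#' Builds a (possibly skewed) helical spiral of Litz wire: the centerline
#' winds `n_turns` times at the given radius while advancing along z by a
#' per-turn pitch. The Litz bundle of radius `bundle_radius` is filled with
#' `n_bundle_filaments` filaments in concentric rings; a finite
#' `twist_pitch` (m per full twist) winds the bundle filaments about the
#' centerline as in a twisted Litz wire, which slightly lengthens each
#' filament and increases the inductance.
#'
#' @param radius spiral radius in m
#' @param n_turns number of turns
#' @param pitch per-turn axial advance in m: a scalar or a vector with one
#'   entry per turn (a pitch profile)
#' @param skew_angle skew of the winding template in radians: the x
#'   coordinate is sheared by `z * tan(skew_angle)`
#' @param bundle_radius Litz bundle radius in m
#' @param n_bundle_filaments filaments in the bundle
#' @param twist_pitch length of one full bundle twist in m (`Inf` = untwisted)
#' @param n_segments_per_turn segments per turn per filament (at least 16)
#' @param phase starting azimuth in radians (e.g. `pi` for a winding rotated
#'   by 180 degrees)
#' @param I0 terminal current in A
#' @return a [filament_coil()]
#' @export
helical_spiral_coil <- function(radius, n_turns, pitch, skew_angle = 0,
                                bundle_radius = 0, n_bundle_filaments = 1L,
                                twist_pitch = Inf, n_segments_per_turn = 64L,
                                phase = 0, I0 = 1) {
  if (radius <= 0 || n_turns < 1L || any(pitch <= 0) || bundle_radius < 0)
    rlang::abort("spiral dimensions must be positive")
  if (n_segments_per_turn < 16L) rlang::abort("need at least 16 segments per turn")
  if (length(pitch) == 1L) pitch <- rep(pitch, n_turns)
  if (length(pitch) < n_turns)
    rlang::abort("pitch profile must have one entry per turn")
  nseg <- n_turns * n_segments_per_turn
  u <- seq(0, n_turns, length.out = nseg + 1L)       # turn coordinate
  zknots <- c(0, cumsum(pitch[seq_len(n_turns)]))
  z <- stats::approx(0:n_turns, zknots, xout = u)$y
  th <- 2 * pi * u + phase
  cx <- radius * cos(th) + z * tan(skew_angle)
  cy <- radius * sin(th)
  cl <- cbind(cx, cy, z)
  # local frame along the centerline
  tang <- rbind(cl[2, ] - cl[1, ], (cl[-1, , drop = FALSE] - cl[-nrow(cl), , drop = FALSE]))
  tang[2:nseg, ] <- (cl[3:(nseg + 1L), ] - cl[1:(nseg - 1L), ]) / 2
  tang <- tang / row_norms(tang)
  zhat <- matrix(rep(c(0, 0, 1), each = nrow(tang)), ncol = 3)
  n1 <- cross_rows(tang, zhat)
  bad <- row_norms(n1) < 1e-12
  n1[bad, ] <- matrix(rep(c(1, 0, 0), sum(bad)), ncol = 3, byrow = TRUE)
  n1 <- n1 / row_norms(n1)
  n2 <- cross_rows(tang, n1)
  n2 <- n2 / row_norms(n2)
  arclen <- c(0, cumsum(row_norms(cl[-1, , drop = FALSE] - cl[-nrow(cl), , drop = FALSE])))
  twist <- if (is.finite(twist_pitch)) 2 * pi * arclen / twist_pitch else numeric(nrow(cl))
  off <- cross_section_offsets(bundle_radius, n_bundle_filaments)
  segs <- lapply(seq_len(nrow(off)), function(f) {
    co <- cos(twist) * off[f, 1] - sin(twist) * off[f, 2]
    so <- sin(twist) * off[f, 1] + cos(twist) * off[f, 2]
    pts <- cl + n1 * co + n2 * so
    tibble::tibble(filament = f,
                   xs = pts[-nrow(pts), 1], ys = pts[-nrow(pts), 2], zs = pts[-nrow(pts), 3],
                   xe = pts[-1, 1], ye = pts[-1, 2], ze = pts[-1, 3],
                   weight = 1 / nrow(off))
  })
  filament_coil(do.call(rbind, segs), I0 = I0)
}

#' Helmholtz coil pair
#'
#' Two coaxial single-turn loops of radius `R` at `z = -R/2` and `z = +R/2`
#' carrying the same current sense: the field near the center is uniform to
#' fourth order in the distance from the midpoint. Used as an
#' almost-uniform applied field for closed-form sphere validation.
#'
#' @param radius loop radius in m
#' @param n_segments azimuthal segments per loop
#' @param I0 terminal current in A
#' @return a [filament_coil()]
#' @export
helmholtz_pair <- function(radius, n_segments = 128L, I0 = 1) {
  lo <- as_tibble.filament_coil(circular_loop_coil(radius, n_segments = n_segments))
  up <- lo
  lo$zs <- lo$zs - radius / 2; lo$ze <- lo$ze - radius / 2
  up$zs <- up$zs + radius / 2; up$ze <- up$ze + radius / 2
  up$filament <- up$filament + 1L
  filament_coil(rbind(lo, up), I0 = I0)
}

# Best-known circle-in-circle packing ratios r/R (small-circle over container
# radius). Exact values where known; n = 100 from the packing tables used for
# Litz bundle sizing.
litz_packing_table <- c(`1` = 1, `2` = 0.5, `3` = 2 * sqrt(3) - 3,
                        `4` = sqrt(2) - 1, `7` = 1 / 3, `100` = 0.0902)

#' Litz bundle radius from the packing tables
#'
#' Given the radius of a single strand and the strand count, returns the
#' radius of the smallest container circle from the best-known
#' circle-in-circle packing ratio: `bundle = single_wire_radius / ratio(n)`.
#'
#' @param single_wire_radius strand radius in m
#' @param n_wires strand count; must be present in the bundled packing table
#'   (`1, 2, 3, 4, 7, 100`)
#' @return bundle radius in m
#' @export
litz_bundle_radius <- function(single_wire_radius, n_wires) {
  if (single_wire_radius <= 0) rlang::abort("`single_wire_radius` must be positive")
  key <- as.character(n_wires)
  if (!key %in% names(litz_packing_table))
    rlang::abort(sprintf("no packing ratio tabulated for n = %s wires", key),
                 class = "coremag_unsupported_count")
  single_wire_radius / litz_packing_table[[key]]
}

# Internal matrix-valued primary fields (A in V*s/m, B in T) at points (n x 3)
coil_AB <- function(coil, points, guard = 1e-9) {
  pts <- as_point_matrix(points)
  res <- cpp_filament_fields(coil$start, coil$end, coil$weight, pts, guard)
  k <- MU0 * coil$I0 / (4 * pi)
  list(A = k * res$A, B = k * res$B)
}

#' Primary fields of a filament coil
#'
#' Free-space vector potential, flux density and field intensity of the coil
#' at the given observation points, by Biot-Savart summation over filament
#' segments (midpoint rule: each segment acts as a point source of moment
#' `I0 * weight * s`).
#'
#' @param coil a [filament_coil()]
#' @param points observation points: n-by-3 matrix or data frame with
#'   `x, y, z` columns, in meters
#' @param guard minimum allowed distance to a segment midpoint (m)
#' @return a tibble with the point coordinates and columns `Ax..Az`
#'   (V s/m), `Bx..Bz` (T), `Hx..Hz` (A/m)
#' @export
coil_fields <- function(coil, points, guard = 1e-9) {
  pts <- as_point_matrix(points)
  f <- coil_AB(coil, pts, guard)
  tibble::tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                 Ax = f$A[, 1], Ay = f$A[, 2], Az = f$A[, 3],
                 Bx = f$B[, 1], By = f$B[, 2], Bz = f$B[, 3],
                 Hx = f$B[, 1] / MU0, Hy = f$B[, 2] / MU0, Hz = f$B[, 3] / MU0)
}

#' Primary induced electric field of a coil
#'
#' In the quasistatic approximation `E = -(dI/dt) * A(r) / I0`, where A is
#' the vector potential per unit terminal current.
#'
#' @inheritParams coil_fields
#' @param dIdt current change rate in A/s
#' @return a tibble with point coordinates and `Ex, Ey, Ez` in V/m
#' @export
coil_E <- function(coil, points, dIdt, guard = 1e-9) {
  pts <- as_point_matrix(points)
  f <- coil_AB(coil, pts, guard)
  E <- -dIdt / coil$I0 * f$A
  tibble::tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                 Ex = E[, 1], Ey = E[, 2], Ez = E[, 3])
}

resolution_advisory <- function(coil) {
  mids <- coil_midpoints(coil)
  len <- row_norms(coil_svec(coil))
  nfil <- length(unique(coil$filament))
  if (nfil < 2L) {
    rlang::warn(paste("single-filament coil: with the m = n Neumann terms omitted,",
                      "the self-inductance of an infinitely thin loop grows with",
                      "segment count (log divergence); fill the conductor",
                      "cross-section with filaments for a converged value"),
                class = "coremag_thin_loop")
    return(invisible(NULL))
  }
  idx <- seq_len(min(nrow(mids), 1500L))
  d <- as.matrix(stats::dist(mids[idx, , drop = FALSE]))
  diag(d) <- Inf
  spacing <- stats::median(apply(d, 1, min))
  if (mean(len) < spacing)
    rlang::warn(sprintf(paste("average segment length (%.3g m) is below the average",
                              "inter-filament spacing (%.3g m); refine the azimuthal",
                              "discretization for precise Neumann inductances"),
                        mean(len), spacing),
                class = "coremag_resolution_advisory")
  invisible(NULL)
}

#' Self-inductance by the Neumann double filament sum
#'
#' `L = (mu0 / 4 pi) * sum_m | (w_m s_m) . sum_{n != m} w_n s_n / |r_m - r_n| |`
#' with the singular m = n terms set to zero, which is justified for finely
#' subdivided conductors whose cross-section is filled with filaments. The
#' result is independent of the terminal current.
#'
#' @param coil a [filament_coil()]
#' @param check if `TRUE`, emit advisory warnings for thin single-filament
#'   loops and under-resolved segment/spacing ratios
#' @return inductance in henry
#' @export
self_inductance <- function(coil, check = TRUE) {
  if (nrow(coil$start) < 2L) rlang::abort("coil needs at least two segments")
  if (check) resolution_advisory(coil)
  MU0 / (4 * pi) * cpp_neumann_self(coil_midpoints(coil), coil_svec(coil), coil$weight)
}

#' Mutual inductance of two filament coils
#'
#' Cross-coil Neumann double sum; symmetric in its arguments.
#'
#' @param coil_a,coil_b [filament_coil()] objects (must not intersect)
#' @param guard minimum allowed filament separation in m
#' @return mutual inductance in henry
#' @export
mutual_inductance <- function(coil_a, coil_b, guard = 1e-9) {
  MU0 / (4 * pi) * cpp_neumann_mutual(coil_midpoints(coil_a), coil_svec(coil_a), coil_a$weight,
                                      coil_midpoints(coil_b), coil_svec(coil_b), coil_b$weight,
                                      guard)
}

#' Rigidly transform a coil
#'
#' @param coil a [filament_coil()]
#' @param rotation 3x3 rotation matrix
#' @param translation length-3 translation in m
#' @return the transformed [filament_coil()]
#' @export
transform_coil <- function(coil, rotation = diag(3), translation = c(0, 0, 0)) {
  tr <- function(p) sweep(p %*% t(rotation), 2, -translation)
  coil$start <- tr(coil$start)
  coil$end <- tr(coil$end)
  coil
}

#' Write / read filament coils as CSV
#'
#' The CSV holds one row per segment with columns
#' `filament, xs, ys, zs, xe, ye, ze, weight` (meters, dimensionless weight).
#'
#' @param coil a [filament_coil()]
#' @param path file path
#' @param I0 terminal current assigned on read
#' @return `read_coil_csv` returns a [filament_coil()];
#'   `write_coil_csv` returns `path` invisibly
#' @export
write_coil_csv <- function(coil, path) {
  utils::write.csv(as_tibble.filament_coil(coil), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_coil_csv
#' @export
read_coil_csv <- function(path, I0 = 1) {
  filament_coil(utils::read.csv(path), I0 = I0)
}
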