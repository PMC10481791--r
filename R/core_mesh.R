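# Tetrahedral core meshes and the all-faces topology used by the
# surface-charge solver.

tet_signed_volumes <- function(V, T4) {
  a <- V[T4[, 2], , drop = FALSE] - V[T4[, 1], , drop = FALSE]
  b <- V[T4[, 3], , drop = FALSE] - V[T4[, 1], , drop = FALSE]
  c3 <- V[T4[, 4], , drop = FALSE] - V[T4[, 1], , drop = FALSE]
  rowSums(cross_rows(a, b) * c3) / 6
}

#' Tetrahedral core mesh
#'
#' @param vertices n-by-3 matrix of vertex coordinates in meters
#' @param tets m-by-4 matrix of 1-based vertex indices; tets with negative
#'   signed volume are reordered on construction, degenerate tets are an error
#' @return an object of class `tet_mesh` with per-tet `volume` (m^3) and
#'   `centroid` (m)
#' @export
tet_mesh <- function(vertices, tets) {
  V <- unname(as.matrix(vertices)); storage.mode(V) <- "double"
  T4 <- unname(as.matrix(tets)); storage.mode(T4) <- "integer"
  if (ncol(V) != 3L || ncol(T4) != 4L) rlang::abort("vertices must be n x 3, tets m x 4")
  vol <- tet_signed_volumes(V, T4)
  flip <- vol < 0
  if (any(flip)) {
    tmp <- T4[flip, 3L]; T4[flip, 3L] <- T4[flip, 4L]; T4[flip, 4L] <- tmp
    vol <- abs(vol)
  }
  scale <- max(row_norms(sweep(V, 2, colMeans(V)))) ^ 3
  if (any(vol <= 1e-14 * scale)) rlang::abort("mesh contains degenerate (zero-volume) tets")
  cen <- (V[T4[, 1], , drop = FALSE] + V[T4[, 2], , drop = FALSE] +
          V[T4[, 3], , drop = FALSE] + V[T4[, 4], , drop = FALSE]) / 4
  structure(list(vertices = V, tets = T4, volume = vol, centroid = cen),
            class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("<tet_mesh> %d vertices, %d tets, volume %.6g m^3\n",
              nrow(x$vertices), nrow(x$tets), sum(x$volume)))
  invisible(x)
}

# ---- structured generators --------------------------------------------------

# Kuhn 6-tet split of one hex cell given its 8 vertex indices in
# (i, j, k) binary order: idx[1 + di + 2*dj + 4*dk]. All six tets share the
# main diagonal (0,0,0)-(1,1,1), which makes the decomposition conforming
# across a structured grid.
kuhn_split <- function(idx) {
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  e <- c(1L, 2L, 4L)  # index increments for +x, +y, +z
  out <- matrix(0L, 6, 4)
  for (p in seq_len(6)) {
    a <- 1L
    b <- a + e[perms[p, 1]]
    c3 <- b + e[perms[p, 2]]
    out[p, ] <- c(idx[a], idx[b], idx[c3], idx[8L])
  }
  out
}

structured_hex_mesh <- function(n, lower, upper, keep_cell = NULL, map = NULL) {
  nx <- n[1]; ny <- n[2]; nz <- n[3]
  xs <- seq(lower[1], upper[1], length.out = nx + 1L)
  ys <- seq(lower[2], upper[2], length.out = ny + 1L)
  zs <- seq(lower[3], upper[3], length.out = nz + 1L)
  V <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  vid <- function(i, j, k) i + (nx + 1L) * (j - 1L) + (nx + 1L) * (ny + 1L) * (k - 1L) +
    (i - 1L) * 0L  # i runs fastest in expand.grid
  cells <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz))
  if (!is.null(keep_cell)) {
    cx <- (xs[cells$i] + xs[cells$i + 1L]) / 2
    cy <- (ys[cells$j] + ys[cells$j + 1L]) / 2
    cz <- (zs[cells$k] + zs[cells$k + 1L]) / 2
    cells <- cells[keep_cell(cx, cy, cz), , drop = FALSE]
    if (nrow(cells) == 0L) rlang::abort("resolution/dimensions yield an empty mesh")
  }
  tet_list <- vector("list", nrow(cells))
  for (r in seq_len(nrow(cells))) {
    i <- cells$i[r]; j <- cells$j[r]; k <- cells$k[r]
    idx <- c(vid(i, j, k), vid(i + 1L, j, k), vid(i, j + 1L, k), vid(i + 1L, j + 1L, k),
             vid(i, j, k + 1L), vid(i + 1L, j, k + 1L), vid(i, j + 1L, k + 1L),
             vid(i + 1L, j + 1L, k + 1L))
    tet_list[[r]] <- kuhn_split(idx)
  }
  T4 <- do.call(rbind, tet_list)
  used <- sort(unique(as.vector(T4)))
  remap <- integer(nrow(V)); remap[used] <- seq_along(used)
  T4 <- matrix(remap[T4], ncol = 4L)
  V <- V[used, , drop = FALSE]
  if (!is.null(map)) V <- map(V)
  tet_mesh(V, T4)
}

# radial stretch mapping of the square [-1,1]^2 onto the unit disc
square_to_disc <- function(xy) {
  m <- pmax(abs(xy[, 1]), abs(xy[, 2]))
  r <- sqrt(xy[, 1]^2 + xy[, 2]^2)
  s <- ifelse(r > 0, m / r, 0)
  xy * s
}

#' Generate a primitive tetrahedral core mesh
#'
#' Structured, watertight tet meshes for the built-in core shapes:
#'
#' * `"cuboid"`: `dimensions = list(lx, ly, lz)` (m), centered at the origin;
#'   `resolution = list(n = c(nx, ny, nz))` cells, each split into 6 tets.
#' * `"cylinder"`: `dimensions = list(radius, height)`, axis along z and
#'   centered at the origin; a structured grid on the cross-section square is
#'   mapped radially onto the disc, so the boundary is a polygonal prism with
#'   `8 * nxy` sides; `resolution = list(nxy = 8, nz = 4)`.
#' * `"c_shape"`: a rectangular frame in the xy plane with a gap: `dimensions
#'   = list(width, height, depth, thickness, gap)` (m); the gap removes the
#'   `|y| < gap/2` portion of the `x > 0` leg; `resolution = list(h = ...)`
#'   target cell size in m.
#'
#' @param shape `"cylinder"`, `"cuboid"` or `"c_shape"`
#' @param dimensions named list of dimensions in meters (see above)
#' @param resolution named list controlling the cell counts (see above)
#' @return a [tet_mesh()]
#' @export
generate_core <- function(shape = c("cylinder", "cuboid", "c_shape"),
                          dimensions, resolution = list()) {
  shape <- match.arg(shape)
  d <- dimensions
  if (any(unlist(d) < 0) || !all(vapply(d, is.finite, TRUE)))
    rlang::abort("core dimensions must be positive and finite")
  switch(shape,
    cuboid = {
      if (!all(c("lx", "ly", "lz") %in% names(d))) rlang::abort("cuboid needs lx, ly, lz")
      if (min(d$lx, d$ly, d$lz) <= 0) rlang::abort("cuboid dimensions must be positive")
      n <- as.integer(resolution$n %||% c(5L, 5L, 5L))
      structured_hex_mesh(n, -c(d$lx, d$ly, d$lz) / 2, c(d$lx, d$ly, d$lz) / 2)
    },
    cylinder = {
      if (!all(c("radius", "height") %in% names(d))) rlang::abort("cylinder needs radius, height")
      if (d$radius <= 0 || d$height <= 0) rlang::abort("cylinder dimensions must be positive")
      nxy <- as.integer(resolution$nxy %||% 8L)
      nz <- as.integer(resolution$nz %||% 4L)
      structured_hex_mesh(
        c(2L * nxy, 2L * nxy, nz), c(-1, -1, -d$height / 2), c(1, 1, d$height / 2),
        map = function(V) cbind(square_to_disc(V[, 1:2]) * d$radius, V[, 3]))
    },
    c_shape = {
      need <- c("width", "height", "depth", "thickness", "gap")
      if (!all(need %in% names(d))) rlang::abort("c_shape needs width, height, depth, thickness, gap")
      if (min(d$width, d$height, d$depth, d$thickness) <= 0 || d$gap < 0)
        rlang::abort("c_shape dimensions must be positive (gap may be zero)")
      h <- resolution$h %||% (d$thickness / 2)
      n <- pmax(2L, ceiling(c(d$width, d$height, d$depth) / h))
      structured_hex_mesh(
        n, -c(d$width, d$height, d$depth) / 2, c(d$width, d$height, d$depth) / 2,
        keep_cell = function(cx, cy, cz) {
          in_hole <- abs(cx) < d$width / 2 - d$thickness & abs(cy) < d$height / 2 - d$thickness
          in_gap <- d$gap > 0 & cx > 0 & abs(cy) < d$gap / 2
          !in_hole & !in_gap
        })
    })
}

#' Tetrahedral ball mesh for validation runs
#'
#' A structured cube grid mapped smoothly onto the ball (each vertex is
#' scaled radially by `max-norm / 2-norm`), giving a watertight sphere
#' approximation with `12 n^2` boundary triangles. Used by the
#' magnetized-sphere closed-form validation fixture.
#'
#' @param radius sphere radius in m
#' @param n cells per cube edge
#' @return a [tet_mesh()]
#' @export
ball_mesh <- function(radius, n = 8L) {
  if (radius <= 0 || n < 2L) rlang::abort("radius must be positive and n >= 2")
  # spherified-cube map: smooth, near-uniform facets (the cube surface maps
  # exactly onto the sphere, interior points follow continuously)
  structured_hex_mesh(c(n, n, n), rep(-1, 3), rep(1, 3), map = function(V) {
    x <- V[, 1]; y <- V[, 2]; z <- V[, 3]
    cbind(x * sqrt(pmax(0, 1 - y^2 / 2 - z^2 / 2 + y^2 * z^2 / 3)),
          y * sqrt(pmax(0, 1 - z^2 / 2 - x^2 / 2 + z^2 * x^2 / 3)),
          z * sqrt(pmax(0, 1 - x^2 / 2 - y^2 / 2 + x^2 * y^2 / 3))) * radius
  })
}

# ---- all-faces topology -----------------------------------------------------

#' Unique-face topology of a tetrahedral mesh
#'
#' Enumerates all unique triangular faces (inner and boundary) of the mesh
#' with the orientation convention of the charge solver: every face stores a
#' "plus" and (for inner faces) a "minus" adjacent tet; the unit normal
#' points from plus to minus, and outward on boundary faces. The plus tet is
#' the lower tet index (the initial choice is arbitrary and the solution is
#' invariant under relabeling).
#'
#' @param mesh a [tet_mesh()]
#' @return an object of class `face_set`: `faces` (m x 3 vertex indices),
#'   `normal` (unit, m x 3), `area` (m^2), `center` (m), `plus_tet`,
#'   `minus_tet` (NA on boundary), `is_boundary`, plus the vertex matrix
#' @export
build_faces <- function(mesh) {
  stopifnot(inherits(mesh, "tet_mesh"))
  V <- mesh$vertices; T4 <- mesh$tets
  nt <- nrow(T4)
  locf <- rbind(c(2, 3, 4), c(1, 3, 4), c(1, 2, 4), c(1, 2, 3))
  allf <- rbind(T4[, locf[1, ]], T4[, locf[2, ]], T4[, locf[3, ]], T4[, locf[4, ]])
  tet_of <- rep(seq_len(nt), times = 4L)
  lo <- pmin(allf[, 1], allf[, 2], allf[, 3])
  hi <- pmax(allf[, 1], allf[, 2], allf[, 3])
  mid <- allf[, 1] + allf[, 2] + allf[, 3] - lo - hi
  nv <- nrow(V)
  key <- (lo - 1) * (nv + 1)^2 + (mid - 1) * (nv + 1) + (hi - 1)
  ord <- order(key, tet_of)
  key_s <- key[ord]
  first <- !duplicated(key_s)
  grp <- cumsum(first)
  cnt <- tabulate(grp)
  if (any(cnt > 2L)) rlang::abort("non-manifold mesh: a face is shared by more than two tets")
  nf <- max(grp)
  plus_tet <- integer(nf); minus_tet <- rep(NA_integer_, nf)
  t_s <- tet_of[ord]
  plus_tet[grp[first]] <- t_s[first]
  second <- which(!first)
  minus_tet[grp[second]] <- t_s[second]
  fv <- cbind(lo, mid, hi)[ord, , drop = FALSE][first, , drop = FALSE]
  is_boundary <- is.na(minus_tet)
  e1 <- V[fv[, 2], ] - V[fv[, 1], ]
  e2 <- V[fv[, 3], ] - V[fv[, 1], ]
  nraw <- cross_rows(e1, e2)
  area <- row_norms(nraw) / 2
  normal <- nraw / (2 * area)
  center <- (V[fv[, 1], ] + V[fv[, 2], ] + V[fv[, 3], ]) / 3
  # orient from plus toward minus (outward on the boundary)
  dir <- center - mesh$centroid[plus_tet, , drop = FALSE]
  flip <- rowSums(normal * dir) < 0
  normal[flip, ] <- -normal[flip, ]
  fs <- structure(list(faces = unname(fv), normal = normal, area = area,
                       center = center, plus_tet = plus_tet, minus_tet = minus_tet,
                       is_boundary = is_boundary, vertices = V, n_tets = nt),
                  class = "face_set")
  check_boundary_closed(fs)
  fs
}

check_boundary_closed <- function(fs) {
  bf <- fs$faces[fs$is_boundary, , drop = FALSE]
  ed <- rbind(bf[, c(1, 2)], bf[, c(2, 3)], bf[, c(1, 3)])
  ekey <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  tab <- table(ekey)
  if (any(tab != 2L))
    rlang::abort(paste("boundary surface is not closed: edges",
                       paste(utils::head(names(tab)[tab != 2L], 5L), collapse = "; "),
                       "are not shared by exactly two boundary faces"))
  invisible(TRUE)
}

#' @export
print.face_set <- function(x, ...) {
  cat(sprintf("<face_set> %d faces (%d boundary, %d inner) over %d tets\n",
              length(x$area), sum(x$is_boundary), sum(!x$is_boundary), x$n_tets))
  invisible(x)
}

#' Coerce a face set to a tibble
#' @param x a `face_set`
#' @param ... unused
#' @export
as_tibble.face_set <- function(x, ...) {
  tibble::tibble(face = seq_along(x$area),
                 v1 = x$faces[, 1], v2 = x$faces[, 2], v3 = x$faces[, 3],
                 x = x$center[, 1], y = x$center[, 2], z = x$center[, 3],
                 nx = x$normal[, 1], ny = x$normal[, 2], nz = x$normal[, 3],
                 area = x$area, plus_tet = x$plus_tet, minus_tet = x$minus_tet,
                 is_boundary = x$is_boundary)
}

# face-neighbor tets of each tet (via inner faces); list of integer vectors
tet_neighbors <- function(fs) {
  nb <- vector("list", fs$n_tets)
  inner <- which(!fs$is_boundary)
  for (f in inner) {
    p <- fs$plus_tet[f]; m <- fs$minus_tet[f]
    nb[[p]] <- c(nb[[p]], m)
    nb[[m]] <- c(nb[[m]], p)
  }
  nb
}

# the 4 faces adjacent to each tet, with the sign convention: +1 if the tet
# is the plus tet of the face (face normal points away from the tet)
tet_face_index <- function(fs) {
  nt <- fs$n_tets
  idx <- matrix(0L, nt, 4L)
  sgn <- matrix(0, nt, 4L)
  fill <- integer(nt)
  for (f in seq_along(fs$area)) {
    p <- fs$plus_tet[f]
    fill[p] <- fill[p] + 1L
    idx[p, fill[p]] <- f; sgn[p, fill[p]] <- 1
    m <- fs$minus_tet[f]
    if (!is.na(m)) {
      fill[m] <- fill[m] + 1L
      idx[m, fill[m]] <- f; sgn[m, fill[m]] <- -1
    }
  }
  list(face = idx, sign = sgn)
}

# ---- surfaces, STL and external meshes -------------------------------------

#' Triangulated surface mesh
#'
#' @param vertices n-by-3 matrix in meters
#' @param triangles m-by-3 matrix of 1-based vertex indices
#' @return object of class `surface_mesh`
#' @export
surface_mesh <- function(vertices, triangles) {
  V <- unname(as.matrix(vertices)); storage.mode(V) <- "double"
  F3 <- unname(as.matrix(triangles)); storage.mode(F3) <- "integer"
  if (ncol(V) != 3L || ncol(F3) != 3L) rlang::abort("vertices must be n x 3, triangles m x 3")
  structure(list(vertices = V, triangles = F3), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

#' Boundary surface of a tetrahedral mesh
#' @param mesh a [tet_mesh()]
#' @return a [surface_mesh()] with outward-oriented triangles
#' @export
as_surface <- function(mesh) {
  fs <- build_faces(mesh)
  bidx <- which(fs$is_boundary)
  tri <- fs$faces[bidx, , drop = FALSE]
  # orient triangles so that the right-hand normal matches the outward normal
  e1 <- fs$vertices[tri[, 2], ] - fs$vertices[tri[, 1], ]
  e2 <- fs$vertices[tri[, 3], ] - fs$vertices[tri[, 1], ]
  nr <- cross_rows(e1, e2)
  flip <- rowSums(nr * fs$normal[bidx, , drop = FALSE]) < 0
  tri[flip, ] <- tri[flip, c(1, 3, 2)]
  used <- sort(unique(as.vector(tri)))
  remap <- integer(nrow(fs$vertices)); remap[used] <- seq_along(used)
  surface_mesh(fs$vertices[used, , drop = FALSE], matrix(remap[tri], ncol = 3L))
}

surface_open_edges <- function(surface) {
  tri <- surface$triangles
  ed <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  ekey <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  tab <- table(ekey)
  names(tab)[tab != 2L]
}

#' Check that a surface is watertight
#'
#' A closed orientable triangle surface has every edge shared by exactly two
#' triangles. Returns `TRUE` invisibly, or aborts with a diagnostic listing
#' the open edges.
#'
#' @param surface a [surface_mesh()]
#' @export
check_watertight <- function(surface) {
  open <- surface_open_edges(surface)
  if (length(open) > 0L)
    rlang::abort(paste0("surface is not watertight: ", length(open),
                        " open edge(s), e.g. vertex pairs ",
                        paste(utils::head(open, 5L), collapse = "; ")),
                 class = "coremag_open_surface")
  invisible(TRUE)
}

#' Import an STL surface
#'
#' Reads binary or ASCII STL. Duplicate facet vertices are merged with a
#' relative tolerance of 1e-6 of the bounding-box diagonal. STL files are
#' conventionally in millimeters; coordinates are multiplied by `scale`
#' (default `1e-3`, mm to m). The surface is checked for watertightness; a
#' non-watertight file aborts with a list of open edges.
#'
#' @param path STL file path
#' @param scale unit conversion factor applied to coordinates (default mm -> m)
#' @param check abort if the surface is not watertight (default `TRUE`)
#' @return a [surface_mesh()]
#' @export
import_stl <- function(path, scale = 1e-3, check = TRUE) {
  if (!file.exists(path)) rlang::abort(sprintf("STL file not found: %s", path))
  sz <- file.size(path)
  con <- file(path, "rb"); on.exit(close(con))
  header <- readBin(con, "raw", 80L)
  is_binary <- FALSE
  if (sz >= 84) {
    ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (!is.na(ntri) && ntri > 0 && sz == 84 + 50 * as.numeric(ntri)) is_binary <- TRUE
  }
  if (is_binary) {
    raw <- readBin(con, "raw", 50L * ntri)
    m <- matrix(raw, nrow = 50L)
    coords <- readBin(as.vector(m[1:48, ]), "numeric", size = 4L, n = 12L * ntri,
                      endian = "little")
    coords <- matrix(coords, ncol = 12L, byrow = TRUE)[, 4:12, drop = FALSE]
  } else {
    txt <- readLines(path, warn = FALSE)
    vlines <- grep("^\\s*vertex", txt, value = TRUE)
    if (length(vlines) == 0L || length(vlines) %% 3L != 0L)
      rlang::abort("unreadable STL: no vertex records found")
    nums <- t(vapply(strsplit(trimws(vlines), "\\s+"),
                     function(p) as.numeric(p[2:4]), numeric(3)))
    ntri <- nrow(nums) / 3L
    coords <- cbind(nums[seq(1, by = 3, length.out = ntri), , drop = FALSE],
                    nums[seq(2, by = 3, length.out = ntri), , drop = FALSE],
                    nums[seq(3, by = 3, length.out = ntri), , drop = FALSE])
  }
  pts <- rbind(coords[, 1:3, drop = FALSE], coords[, 4:6, drop = FALSE],
               coords[, 7:9, drop = FALSE]) * scale
  diag_len <- sqrt(sum((apply(pts, 2, max) - apply(pts, 2, min))^2))
  tol <- max(diag_len, 1e-30) * 1e-6
  key <- paste(round(pts[, 1] / tol), round(pts[, 2] / tol), round(pts[, 3] / tol))
  uid <- match(key, unique(key))
  V <- pts[!duplicated(key), , drop = FALSE]
  ntri <- nrow(coords)
  tri <- cbind(uid[seq_len(ntri)], uid[ntri + seq_len(ntri)], uid[2L * ntri + seq_len(ntri)])
  keep <- tri[, 1] != tri[, 2] & tri[, 2] != tri[, 3] & tri[, 1] != tri[, 3]
  surf <- surface_mesh(V, tri[keep, , drop = FALSE])
  if (check) check_watertight(surf)
  surf
}

#' Write a surface to ASCII STL
#'
#' @param surface a [surface_mesh()]
#' @param path output file
#' @param scale unit conversion applied on write (default m -> mm)
#' @export
write_stl <- function(surface, path, scale = 1e3) {
  V <- surface$vertices * scale
  tri <- surface$triangles
  con <- file(path, "w"); on.exit(close(con))
  writeLines("solid coremag", con)
  for (i in seq_len(nrow(tri))) {
    a <- V[tri[i, 1], ]; b <- V[tri[i, 2], ]; c3 <- V[tri[i, 3], ]
    n <- c((b[2] - a[2]) * (c3[3] - a[3]) - (b[3] - a[3]) * (c3[2] - a[2]),
           (b[3] - a[3]) * (c3[1] - a[1]) - (b[1] - a[1]) * (c3[3] - a[3]),
           (b[1] - a[1]) * (c3[2] - a[2]) - (b[2] - a[2]) * (c3[1] - a[1]))
    nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
    writeLines(c(sprintf("  facet normal %g %g %g", n[1], n[2], n[3]),
                 "    outer loop",
                 sprintf("      vertex %g %g %g", a[1], a[2], a[3]),
                 sprintf("      vertex %g %g %g", b[1], b[2], b[3]),
                 sprintf("      vertex %g %g %g", c3[1], c3[2], c3[3]),
                 "    endloop", "  endfacet"), con)
  }
  writeLines("endsolid coremag", con)
  invisible(path)
}

#' Fill a watertight surface with tetrahedra
#'
#' Voxel-based tetrahedralization: a structured grid of target cell size `h`
#' covers the bounding box, cells whose centers fall inside the closed
#' surface (ray casting) are kept, and each kept cell is split into 6 tets.
#' The result is a staircase approximation whose volume converges to the
#' enclosed volume as `h` shrinks; it is intended for quick imports of CAD
#' shapes, not for boundary-accurate solves.
#'
#' @param surface a watertight [surface_mesh()]
#' @param h target cell edge length in m
#' @return a [tet_mesh()]
#' @export
tetrahedralize_surface <- function(surface, h) {
  check_watertight(surface)
  V <- surface$vertices
  lo <- apply(V, 2, min); hi <- apply(V, 2, max)
  n <- pmax(1L, ceiling((hi - lo) / h))
  xs <- seq(lo[1], hi[1], length.out = n[1] + 1L)
  ys <- seq(lo[2], hi[2], length.out = n[2] + 1L)
  zs <- seq(lo[3], hi[3], length.out = n[3] + 1L)
  cc <- as.matrix(expand.grid(x = (xs[-1] + xs[-length(xs)]) / 2,
                              y = (ys[-1] + ys[-length(ys)]) / 2,
                              z = (zs[-1] + zs[-length(zs)]) / 2))
  Ftri <- surface$triangles - 1L
  storage.mode(Ftri) <- "integer"
  inside <- cpp_points_in_surface(V, Ftri, cc)
  if (!any(inside)) rlang::abort("no grid cell centers fall inside the surface; reduce `h`")
  structured_hex_mesh(n, lo, hi, keep_cell = function(cx, cy, cz) inside)
}

#' Read an external tetrahedral mesh (.node / .ele pair)
#'
#' TetGen-style plain-text format: the `.node` file holds `n 3 ...` then one
#' vertex per line (`id x y z`); the `.ele` file holds `m 4 ...` then one tet
#' per line (`id v1 v2 v3 v4`). Both 0- and 1-based ids are accepted.
#'
#' @param node_path,ele_path file paths
#' @param scale unit conversion factor applied to coordinates
#' @return a [tet_mesh()]
#' @export
read_tet_mesh <- function(node_path, ele_path, scale = 1) {
  nh <- scan(node_path, nmax = 4, quiet = TRUE)
  nodes <- matrix(scan(node_path, skip = 1, quiet = TRUE), ncol = nh[2] + 1 + (nh[3] %||% 0),
                  byrow = TRUE)
  eh <- scan(ele_path, nmax = 3, quiet = TRUE)
  eles <- matrix(scan(ele_path, skip = 1, quiet = TRUE), ncol = eh[2] + 1, byrow = TRUE)
  ids <- nodes[, 1]
  offset <- 1L - min(ids)
  T4 <- eles[, 2:5, drop = FALSE] + offset
  tet_mesh(nodes[order(ids), 2:4, drop = FALSE] * scale, T4)
}

# ---- VTK export -------------------------------------------------------------

#' Write a mesh (with optional cell data) to a legacy ASCII VTK file
#'
#' @param x a [tet_mesh()] or [surface_mesh()]
#' @param path output `.vtk` file
#' @param cell_data named list of per-cell numeric vectors or 3-column
#'   matrices (written as SCALARS / VECTORS)
#' @export
write_vtk <- function(x, path, cell_data = list()) {
  if (inherits(x, "tet_mesh")) {
    cells <- x$tets; ctype <- 10L
  } else if (inherits(x, "surface_mesh")) {
    cells <- x$triangles; ctype <- 5L
  } else rlang::abort("`x` must be a tet_mesh or surface_mesh")
  V <- x$vertices
  nc <- nrow(cells); npc <- ncol(cells)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "coremag export", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(V))), con)
  utils::write.table(V, con, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("CELLS %d %d", nc, nc * (npc + 1L)), con)
  utils::write.table(cbind(npc, cells - 1L), con, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("CELL_TYPES %d", nc), con)
  writeLines(as.character(rep(ctype, nc)), con)
  if (length(cell_data) > 0L) {
    writeLines(sprintf("CELL_DATA %d", nc), con)
    for (nm in names(cell_data)) {
      v <- cell_data[[nm]]
      if (is.matrix(v) && ncol(v) == 3L) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
        writeLines(as.character(v), con)
      }
    }
  }
  invisible(path)
}
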