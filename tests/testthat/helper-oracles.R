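# Shared fixtures and independent oracles used across the suite.

MU0_TEST <- 4e-7 * pi

# brute-force field integral of a unit-density triangle by barycentric
# subdivision (independent of the analytic kernel path)
tri_field_quadrature <- function(tri, p, k = 200L) {
  v1 <- tri[1, ]; v2 <- tri[2, ]; v3 <- tri[3, ]
  e1 <- v2 - v1; e2 <- v3 - v1
  nr <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  area <- sqrt(sum(nr^2)) / 2
  g <- c(0, 0, 0); cnt <- 0L
  for (i in 0:(k - 1L)) for (j in 0:(k - 1L - i)) {
    for (b in list(c(i + 1 / 3, j + 1 / 3),
                   if (i + j < k - 1L) c(i + 2 / 3, j + 2 / 3))) {
      if (is.null(b)) next
      l1 <- b[1] / k; l2 <- b[2] / k
      pt <- (1 - l1 - l2) * v1 + l1 * v2 + l2 * v3
      d <- p - pt
      g <- g + d / sum(d^2)^1.5
      cnt <- cnt + 1L
    }
  }
  g * area / cnt
}

# ring-structured triangulation of a flat disc in the z = 0 plane
# (n_az wedges x n_r rings; well-shaped triangles, unlike a pure fan)
disc_face_set <- function(radius, n_az = 64L, n_r = 8L) {
  th <- 2 * pi * (seq_len(n_az) - 1L) / n_az
  V <- rbind(c(0, 0, 0))
  ring_start <- integer(n_r)
  for (i in seq_len(n_r)) {
    ring_start[i] <- nrow(V)
    V <- rbind(V, cbind(radius * i / n_r * cos(th), radius * i / n_r * sin(th), 0))
  }
  nxt <- function(k) (k %% n_az) + 1L
  tri <- NULL
  for (k in seq_len(n_az))  # innermost fan
    tri <- rbind(tri, c(1L, ring_start[1] + k, ring_start[1] + nxt(k)))
  for (i in seq_len(n_r - 1L)) {
    a <- ring_start[i]; b <- ring_start[i + 1L]
    for (k in seq_len(n_az)) {
      tri <- rbind(tri, c(a + k, b + k, b + nxt(k)),
                   c(a + k, b + nxt(k), a + nxt(k)))
    }
  }
  e1 <- V[tri[, 2], ] - V[tri[, 1], ]
  e2 <- V[tri[, 3], ] - V[tri[, 1], ]
  nr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area <- sqrt(rowSums(nr^2)) / 2
  nf <- nrow(tri)
  structure(list(faces = tri, normal = nr / (2 * area), area = area,
                 center = (V[tri[, 1], ] + V[tri[, 2], ] + V[tri[, 3], ]) / 3,
                 plus_tet = rep(NA_integer_, nf), minus_tet = rep(NA_integer_, nf),
                 is_boundary = rep(TRUE, nf), vertices = V, n_tets = 0L),
            class = "face_set")
}

# two tets sharing the face (1,2,3); the second apex is placed so the two
# centroids are separated along the shared-face normal
two_tet_mesh <- function() {
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0.4, 0.4, -1.5))
  tet_mesh(V, rbind(c(1, 2, 3, 4), c(1, 2, 3, 5)))
}

small_ball_solution <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      coil <- helmholtz_pair(0.1, n_segments = 64L, I0 = 100)
      ball <- ball_mesh(10e-3, n = 8L)
      cache <<- list(coil = coil, ball = ball,
                     sol = solve_linear_core(ball, mu_r = 3, coil))
    }
    cache
  }
})

applied_H0 <- function(coil) {
  f <- coil_fields(coil, c(0, 0, 0))
  sqrt(f$Hx^2 + f$Hy^2 + f$Hz^2)
}

rotation_xyz <- function(ax, ay, az) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  Ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  Rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}
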