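# Post-solve physics of the coil + core combination. The solution stores the
# core magnetization M and the face charges; any downstream field (secondary
# vector potential, induced electric field, exterior H) is evaluated from
# those without re-solving, and the whole assembly may be rigidly moved or
# rotated first.

#' Per-tet magnetization of a solution
#'
#' `M = (mu_r - 1) * H_total` per tet (A/m).
#'
#' @param solution a `coremag_solution` with an interior (tet mesh) solve
#' @return tibble with tet centroids, `Mx, My, Mz` and `M_mag` (A/m)
#' @export
magnetization <- function(solution) {
  if (is.null(solution$M))
    rlang::abort("solution has no interior magnetization (boundary-only solve)")
  M <- solution$M
  cen <- solution$mesh$centroid
  tibble::tibble(tet = seq_len(nrow(M)),
                 x = cen[, 1], y = cen[, 2], z = cen[, 3],
                 Mx = M[, 1], My = M[, 2], Mz = M[, 3],
                 M_mag = row_norms(M), mu_r = solution$mu_r)
}

#' Core energy and inductance correction
#'
#' The extra magnetic energy stored by the magnetized core is
#' `U_s = 1/2 * sum_t V_t * M_t . B^p(r_t)` with `B^p` the free-space coil
#' flux density at the tet centroid; the inductance correction is
#' `L_s = 2 U_s / I0^2`, added to the free-space Neumann inductance `L_p`.
#'
#' @param solution a `coremag_solution` with magnetization
#' @return list with `U_s` (J), `L_s` (H) and, when `L_p` is available,
#'   `L_total = L_p + L_s` (H)
#' @export
core_energy_and_inductance <- function(solution) {
  if (is.null(solution$M)) rlang::abort("solution has no interior magnetization")
  if (solution$I0 == 0)
    rlang::abort("inductance correction is undefined at zero terminal current")
  Bp <- coil_AB(solution$coil, solution$mesh$centroid)$B
  U_s <- 0.5 * sum(solution$mesh$volume * rowSums(solution$M * Bp))
  L_s <- 2 * U_s / solution$I0^2
  list(U_s = U_s, L_s = L_s,
       L_total = if (!is.na(solution$L_p)) solution$L_p + L_s else NA_real_)
}

solution_tet_vertices <- function(solution) {
  V <- solution$mesh$vertices; T4 <- solution$mesh$tets
  cbind(V[T4[, 1], ], V[T4[, 2], ], V[T4[, 3], ], V[T4[, 4], ])
}

#' Secondary vector potential of the magnetized core
#'
#' `A^s(r) = (mu0/4pi) * sum_t V_t * M_t x (r - r_t) / |r - r_t|^3` by the
#' centroid rule; observation points within `eta` tet-radii of a centroid
#' use one level of red refinement (8 children) of that tet instead.
#'
#' @param solution a `coremag_solution` with magnetization
#' @param points n-by-3 observation points (m)
#' @param eta near-field radius multiplier
#' @return n-by-3 matrix of A^s in V s/m
#' @export
secondary_vector_potential <- function(solution, points, eta = 3) {
  if (is.null(solution$M)) rlang::abort("solution has no interior magnetization")
  pts <- as_point_matrix(points)
  MU0 / (4 * pi) * cpp_As_from_M(solution_tet_vertices(solution),
                                 solution$mesh$volume, solution$M, pts, eta)
}

#' Total induced electric field of the coil + core
#'
#' `E = -(dI/dt) * [A^p(r) + A^s(r)] / I0`, the primary (incident) TMS
#' electric field of the coil with its magnetic core. The stored
#' magnetization is reused, so `dIdt` can be changed at will without
#' re-solving the core.
#'
#' @param solution a `coremag_solution`
#' @param points n-by-3 observation points (m)
#' @param dIdt current change rate in A/s
#' @return tibble with the points and `Ex, Ey, Ez` in V/m
#' @export
total_E <- function(solution, points, dIdt) {
  pts <- as_point_matrix(points)
  Ap <- coil_AB(solution$coil, pts)$A
  As <- if (!is.null(solution$M)) secondary_vector_potential(solution, pts)
        else matrix(0, nrow(pts), 3)
  E <- -dIdt / solution$I0 * (Ap + As)
  tibble::tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                 Ex = E[, 1], Ey = E[, 2], Ez = E[, 3])
}

#' Secondary magnetic field outside the core
#'
#' Evaluated from the stored face charges via the single-layer integral;
#' valid anywhere, with near-face analytic integration.
#'
#' @inheritParams total_E
#' @return tibble with the points and `Hx, Hy, Hz` in A/m
#' @export
secondary_H_outside <- function(solution, points) {
  pts <- as_point_matrix(points)
  H <- single_layer_H(solution$faces, solution$rho, pts)
  tibble::tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                 Hx = H[, 1], Hy = H[, 2], Hz = H[, 3])
}

#' Rigidly move or rotate a solved coil + core assembly
#'
#' The coil-core combination is solved once; afterwards the whole assembly
#' may be moved or rotated without recomputing the magnetization. Points,
#' normals and vector quantities transform covariantly.
#'
#' @param solution a `coremag_solution`
#' @param rotation 3x3 rotation matrix
#' @param translation length-3 translation (m)
#' @return the transformed `coremag_solution`
#' @export
transform_solution <- function(solution, rotation = diag(3), translation = c(0, 0, 0)) {
  Rt <- t(rotation)
  tr_pts <- function(p) sweep(p %*% Rt, 2, translation, `+`)
  tr_vec <- function(v) v %*% Rt
  solution$coil <- transform_coil(solution$coil, rotation, translation)
  if (!is.null(solution$mesh)) {
    solution$mesh$vertices <- tr_pts(solution$mesh$vertices)
    solution$mesh$centroid <- tr_pts(solution$mesh$centroid)
  }
  solution$faces$vertices <- tr_pts(solution$faces$vertices)
  solution$faces$center <- tr_pts(solution$faces$center)
  solution$faces$normal <- tr_vec(solution$faces$normal)
  if (!is.null(solution$M)) solution$M <- tr_vec(solution$M)
  if (!is.null(solution$H_total)) solution$H_total <- tr_vec(solution$H_total)
  solution
}

# ---- broom-style accessors --------------------------------------------------

#' Tidy a coil + core solution
#'
#' One row per tet with the local permeability, total field and
#' magnetization magnitudes.
#'
#' @param x a `coremag_solution`
#' @param ... unused
#' @return a tibble
#' @export
tidy.coremag_solution <- function(x, ...) {
  if (is.null(x$mesh)) {
    return(tibble::tibble(face = seq_along(x$rho), rho = x$rho,
                          area = x$faces$area))
  }
  cen <- x$mesh$centroid
  vol <- x$mesh$volume
  mu <- x$mu_r
  hm <- row_norms(x$H_total)
  mm <- row_norms(x$M)
  tibble::tibble(tet = seq_len(nrow(cen)),
                 x = cen[, 1], y = cen[, 2], z = cen[, 3],
                 volume = vol, mu_r = mu, H_mag = hm, M_mag = mm)
}

#' One-row summary of a coil + core solution
#'
#' @param x a `coremag_solution`
#' @param ... unused
#' @return a one-row tibble with inductances (H), mean core permeability,
#'   iteration count and final convergence deviations
#' @export
glance.coremag_solution <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  tibble::tibble(kind = x$kind, n_faces = length(x$rho),
                 n_tets = if (!is.null(x$mesh)) nrow(x$mesh$tets) else NA_integer_,
                 I0 = x$I0, L_p = x$L_p, L_s = x$L_s,
                 L_total = if (!is.na(x$L_p)) x$L_p + x$L_s else NA_real_,
                 mean_mu_r = if (!is.null(x$mu_r)) mean(x$mu_r) else NA_real_,
                 iterations = last$iteration, e1 = last$e1, e2 = last$e2,
                 converged = x$converged)
}

#' Convergence plot of a nonlinear solve
#'
#' Plots the per-iteration relative deviations e1 (charges) and e2
#' (permeabilities) on a log scale.
#'
#' @param object a `coremag_solution` from [solve_nonlinear_core()]
#' @param ... unused
#' @export
autoplot.coremag_convergence <- function(object, ...) {
  df <- tibble::tibble(
    iteration = rep(object$log$iteration, 2),
    deviation = c(object$log$e1, object$log$e2),
    measure = rep(c("e1 (charge density)", "e2 (permeability)"),
                  each = nrow(object$log)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$deviation,
                                   color = .data$measure)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "nonlinear iteration", y = "relative deviation",
                  color = NULL, title = "Successive-substitution convergence")
}
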