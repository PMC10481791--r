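# Surface magnetic-charge integral equation: the charge density rho_s (units
# T) on mesh faces satisfies the Fredholm second-kind ("Phillips-type")
# equation
#
#   rho(r)/2 - K(r) n(r) . (1/4pi) int (r - r') / |r - r'|^3 rho(r') dS'
#     = K(r) n(r) . B^p(r)
#
# with the permeability contrast K = (mu+ - mu-) / (mu+ + mu-) across each
# face. The secondary field anywhere is the single-layer gradient
#   H^s(r) = (1 / 4pi mu0) int rho(r') (r - r') / |r - r'|^3 dS'.

# Build a face_set directly from a closed triangulated surface (boundary-only
# solves): all faces are boundary faces with outward normals.
surface_face_set <- function(surface) {
  check_watertight(surface)
  V <- surface$vertices; tri <- surface$triangles
  e1 <- V[tri[, 2], ] - V[tri[, 1], ]
  e2 <- V[tri[, 3], ] - V[tri[, 1], ]
  nr <- cross_rows(e1, e2)
  area <- row_norms(nr) / 2
  normal <- nr / (2 * area)
  center <- (V[tri[, 1], ] + V[tri[, 2], ] + V[tri[, 3], ]) / 3
  # orient outward: the signed enclosed volume sum must be positive
  vol <- sum(rowSums(center * normal) * area) / 3
  if (vol < 0) normal <- -normal
  structure(list(faces = unname(tri), normal = normal, area = area, center = center,
                 plus_tet = rep(NA_integer_, nrow(tri)),
                 minus_tet = rep(NA_integer_, nrow(tri)),
                 is_boundary = rep(TRUE, nrow(tri)), vertices = V, n_tets = 0L),
            class = "face_set")
}

face_subset <- function(fs, idx) {
  structure(list(faces = fs$faces[idx, , drop = FALSE],
                 normal = fs$normal[idx, , drop = FALSE],
                 area = fs$area[idx],
                 center = fs$center[idx, , drop = FALSE],
                 plus_tet = fs$plus_tet[idx], minus_tet = fs$minus_tet[idx],
                 is_boundary = fs$is_boundary[idx], vertices = fs$vertices,
                 n_tets = fs$n_tets),
            class = "face_set")
}

faces_F0 <- function(fs) {
  f <- fs$faces - 1L
  storage.mode(f) <- "integer"
  f
}

#' Precompute the dense single-layer influence operator
#'
#' Assembles the dense matrix `G` with `G[i, j] = (1/4pi) n_i . g_j(c_i)`,
#' where `g_j` is the field integral of a unit charge density on face `j`,
#' evaluated at face centers. Faces within `eta` face-radii use the analytic
#' constant-density triangle integral; the self entry is the principal value
#' (zero normal component); farther faces use the centroid rule. The matrix
#' is contrast-independent, so it is assembled once per mesh and reused
#' across all linear solves and nonlinear iterations.
#'
#' @param faces a [build_faces()] face set (or one built from a surface)
#' @param eta near-field radius multiplier
#' @return an object of class `bem_operator`
#' @export
bem_operator <- function(faces, eta = 3) {
  stopifnot(inherits(faces, "face_set"))
  G <- cpp_G_matrix(faces$vertices, faces_F0(faces), faces$center,
                    faces$normal, faces$area, eta)
  structure(list(G = G, faces = faces, eta = eta), class = "bem_operator")
}

#' @export
print.bem_operator <- function(x, ...) {
  cat(sprintf("<bem_operator> dense %d x %d single-layer operator (eta = %g)\n",
              nrow(x$G), ncol(x$G), x$eta))
  invisible(x)
}

#' Apply the second-kind charge operator
#'
#' Returns the left-hand side `rho/2 - K * (G rho)` of the charge equation
#' evaluated at all face centers. With `K = 0` everywhere the operator is
#' exactly `rho/2`; the self-face contribution enters only through the
#' principal-value `rho/2` term.
#'
#' @param op a [bem_operator()]
#' @param K per-face permeability contrast in `[-1, 1]`
#' @param rho per-face charge density (T)
#' @return per-face operator values
#' @export
apply_operator <- function(op, K, rho) {
  if (length(K) != ncol(op$G) || length(rho) != ncol(op$G))
    rlang::abort("`K` and `rho` must have one value per face")
  if (any(abs(K) > 1 + 1e-12)) rlang::abort("contrasts must satisfy |K| <= 1")
  rho / 2 - K * as.numeric(op$G %*% rho)
}

#' Solve the charge equation with GMRES
#'
#' @param op a [bem_operator()]
#' @param K per-face contrasts
#' @param rhs right-hand side `K * n . B^p` at face centers (T)
#' @param tol relative GMRES residual tolerance
#' @param max_iter maximum GMRES iterations
#' @param x0 optional warm start
#' @return list with `rho` (charge density, T), `iterations`, `residuals`
#' @export
solve_charges <- function(op, K, rhs, tol = 1e-8, max_iter = 300L, x0 = NULL) {
  if (!all(is.finite(rhs))) rlang::abort("`rhs` must be finite")
  if (tol <= 0) rlang::abort("`tol` must be positive")
  sol <- gmres_solve(function(v) v / 2 - K * as.numeric(op$G %*% v),
                     rhs, tol = tol, max_iter = max_iter, x0 = x0)
  if (!sol$converged)
    rlang::abort(paste0("GMRES did not reach tol = ", tol, " in ", max_iter,
                        " iterations (last residual ",
                        signif(utils::tail(sol$residuals, 1), 3), ")"),
                 class = "coremag_gmres_failure",
                 residuals = sol$residuals)
  list(rho = sol$x, iterations = sol$iterations, residuals = sol$residuals)
}

#' Secondary magnetic field of face charges
#'
#' Single-layer field `H^s(r) = (1/4pi mu0) sum_f int_f rho_f (r - r')/|r - r'|^3 dS'`
#' at arbitrary points; faces near an observation point use the analytic
#' triangle integral (principal value on the face plane itself).
#'
#' @param faces a `face_set`
#' @param rho per-face charge density (T)
#' @param points n-by-3 observation points (m)
#' @param eta near-field radius multiplier
#' @return n-by-3 matrix of H^s in A/m
#' @export
single_layer_H <- function(faces, rho, points, eta = 3) {
  pts <- as_point_matrix(points)
  if (length(rho) != length(faces$area)) rlang::abort("`rho` must have one value per face")
  cpp_single_layer_H(faces$vertices, faces_F0(faces), faces$center, faces$area,
                     as.numeric(rho), pts, eta) / MU0
}

#' Solve a linear (constant-permeability) core in a coil field
#'
#' The charge equation is solved on the boundary faces with the uniform
#' contrast `K = (mu - mu0)/(mu + mu0)`; the secondary field then gives the
#' total interior field and the magnetization `M = (mu_r - 1) H` per tet.
#'
#' Two interior-magnetization routes are used. For moderate permeability the
#' direct constitutive evaluation `M = (mu_r - 1)(H^p + H^s)` at tet
#' centroids is accurate; for strongly permeable cores it is a difference of
#' nearly cancelling fields whose discretization error is amplified by
#' `mu_r - 1`. Above `mu_switch` the magnetization is instead reconstructed
#' from the boundary charges alone: inside a linear core M is curl- and
#' divergence-free with exact boundary flux `n . M = rho / mu0`, so it is
#' obtained from an auxiliary interior Neumann solve on the same operator
#' (the subtraction-style correction for `mu >> mu0`).
#'
#' @param core a [tet_mesh()] (full interior solution) or a closed
#'   [surface_mesh()] (charges and exterior fields only)
#' @param mu_r constant relative permeability, `>= 1`
#' @param coil a [filament_coil()]
#' @param tol,max_iter GMRES controls
#' @param compute_inductance also compute the free-space coil inductance
#'   `L_p` (Neumann sum) and the core correction `L_s` (requires a tet mesh)
#' @param op optional precomputed [bem_operator()] on the boundary faces
#' @param mu_switch permeability above which the charge-based interior
#'   reconstruction replaces the direct constitutive evaluation
#' @return a `coremag_solution` object; see [glance.coremag_solution()]
#' @export
solve_linear_core <- function(core, mu_r, coil, tol = 1e-8, max_iter = 300L,
                              compute_inductance = TRUE, op = NULL,
                              mu_switch = 8) {
  if (mu_r < 1) rlang::abort("`mu_r` must be >= 1")
  if (inherits(core, "tet_mesh")) {
    mesh <- core
    fs_all <- build_faces(mesh)
    bidx <- which(fs_all$is_boundary)
    faces <- face_subset(fs_all, bidx)
  } else if (inherits(core, "surface_mesh")) {
    mesh <- NULL
    faces <- surface_face_set(core)
  } else rlang::abort("`core` must be a tet_mesh or a surface_mesh")
  if (mu_r > mu_switch)
    rlang::inform(sprintf(
      "mu_r = %g > %g: interior magnetization reconstructed from boundary charges (high-contrast correction)",
      mu_r, mu_switch))
  K <- rep((mu_r - 1) / (mu_r + 1), length(faces$area))  # (mu - mu0)/(mu + mu0)
  Bp <- coil_AB(coil, faces$center)$B
  rhs <- K * rowSums(faces$normal * Bp)
  op <- op %||% bem_operator(faces)
  sol <- if (mu_r == 1) list(rho = numeric(length(K)), iterations = 0L, residuals = numeric(0))
         else solve_charges(op, K, rhs, tol = tol, max_iter = max_iter)
  rho <- sol$rho
  M <- NULL; mu_r_tet <- NULL; H_total <- NULL; L_s <- NA_real_
  if (!is.null(mesh)) {
    Hp <- coil_AB(coil, mesh$centroid)$B / MU0
    Hs <- single_layer_H(faces, rho, mesh$centroid)
    H_total <- Hp + Hs
    mu_r_tet <- rep(mu_r, nrow(mesh$tets))
    if (mu_r == 1) {
      M <- matrix(0, nrow(mesh$tets), 3)
      L_s <- 0
    } else if (mu_r <= mu_switch) {
      M <- (mu_r - 1) * H_total
    } else {
      hr <- harmonic_reconstruction(op, faces, rho, mesh$centroid)
      M <- hr$M
      # boundary-only energy functional: more accurate than the volume sum
      # when many tets touch the surface
      if (coil$I0 != 0)
        L_s <- 2 * surface_core_energy(faces, hr$sigma, coil) / coil$I0^2
    }
  }
  L_p <- if (compute_inductance) self_inductance(coil, check = FALSE) else NA_real_
  out <- new_coremag_solution(
    coil = coil, mesh = mesh, faces = faces, rho = rho, mu_r = mu_r_tet,
    H_total = H_total, M = M, curve = NULL, L_p = L_p, L_s_override = L_s,
    log = tibble::tibble(iteration = 1L, e1 = NA_real_, e2 = NA_real_,
                         gmres_iterations = sol$iterations,
                         mean_mu_r = mu_r, min_mu_r = mu_r, max_mu_r = mu_r),
    converged = TRUE, kind = "linear")
  out
}

# Interior magnetization of a LINEAR core reconstructed from the boundary
# charges. Inside a constant-permeability core the magnetization is both
# curl-free (H is curl-free, M = (mu_r - 1) H) and divergence-free, with the
# exact boundary flux n . M = rho / mu0. It is therefore the gradient field
# of an interior harmonic potential and is recovered by solving the interior
# Neumann problem with an auxiliary single-layer density sigma on the same
# faces: (G - I/2) sigma = rho (any nullspace component produces zero
# interior field). This avoids the cancellation M = (mu_r - 1)(H^p + H^s)
# that amplifies discretization error by mu_r for strongly permeable cores
# (the direct difference of two nearly opposite O(H^p) fields).
harmonic_reconstruction <- function(op, faces, rho, points) {
  sol <- gmres_solve(function(v) as.numeric(op$G %*% v) - v / 2, rho,
                     tol = 1e-10, max_iter = 300L)
  # single_layer_H carries a 1/mu0; with the T-valued density sigma solving
  # (G - I/2) sigma = rho this yields exactly the A/m magnetization field
  list(M = single_layer_H(faces, sol$x, points), sigma = sol$x)
}

#' Single-layer scalar potential of face charges
#'
#' `phi(r) = (1/4pi mu0) sum_f int_f rho_f / |r - r'| dS'` (amperes for a
#' T-valued density); continuous across the faces, with analytic near-face
#' integrals. The magnetization potential of a linear core: `M = -grad phi`.
#'
#' @inheritParams single_layer_H
#' @return potential values at the points
#' @export
single_layer_potential <- function(faces, rho, points, eta = 3) {
  pts <- as_point_matrix(points)
  cpp_single_layer_potential(faces$vertices, faces_F0(faces), faces$center,
                             faces$area, as.numeric(rho), pts, eta) / MU0
}

# Core energy of a LINEAR core evaluated purely on the boundary surface:
# with M = -grad(phi) divergence-free and div B^p = 0,
#   U_s = 1/2 int_V M . B^p dV = -1/2 oint_S phi (B^p . n) dS.
# Avoids the near-boundary error of volume evaluation on coarse meshes.
surface_core_energy <- function(faces, sigma, coil) {
  phi <- single_layer_potential(faces, sigma, faces$center)
  Bn <- rowSums(faces$normal * coil_AB(coil, faces$center)$B)
  -0.5 * sum(phi * Bn * faces$area)
}

new_coremag_solution <- function(coil, mesh, faces, rho, mu_r, H_total, M,
                                 curve, L_p, log, converged, kind,
                                 L_s_override = NA_real_) {
  sol <- structure(list(coil = coil, mesh = mesh, faces = faces, rho = rho,
                        mu_r = mu_r, H_total = H_total, M = M, curve = curve,
                        L_p = L_p, L_s = L_s_override, I0 = coil$I0, log = log,
                        converged = converged, kind = kind),
                   class = "coremag_solution")
  if (is.na(sol$L_s) && !is.null(M) && coil$I0 != 0) {
    en <- core_energy_and_inductance(sol)
    sol$L_s <- en$L_s
  }
  sol
}

#' @export
print.coremag_solution <- function(x, ...) {
  cat(sprintf("<coremag_solution> %s core solve, %d faces%s\n", x$kind,
              length(x$rho),
              if (!is.null(x$mesh)) sprintf(", %d tets", nrow(x$mesh$tets)) else ""))
  if (!is.na(x$L_p))
    cat(sprintf("  L_p = %.4g H, L_s = %.4g H, L = %.4g H\n",
                x$L_p, x$L_s, x$L_p + x$L_s))
  if (!is.null(x$mu_r))
    cat(sprintf("  mean core mu_r = %.4g (min %.4g, max %.4g)\n",
                mean(x$mu_r), min(x$mu_r), max(x$mu_r)))
  invisible(x)
}
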