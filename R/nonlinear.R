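# Nonlinear core solver: successive substitution over the B-H curve, with
# the charge equation applied to ALL faces (inner and boundary) of the
# tetrahedral core mesh. Permeability is constant per tet; every face
# carries the differential contrast K = (mu+ - mu-)/(mu+ + mu-) of its two
# adjacent tets (mu- = mu0 on the boundary).

#' Initialize the nonlinear core state
#'
#' Assigns each tet the permeability of the free-space coil field at its
#' centroid, `mu_r = mu_r(|H^p|)`, with zero charges and zero secondary
#' field (the charge density is zero only at this first step).
#'
#' @param mesh a [tet_mesh()]
#' @param faces the [build_faces()] face set of `mesh`
#' @param curve a [bh_curve()]
#' @param coil a [filament_coil()]
#' @return an object of class `core_state`
#' @export
initialize_core_state <- function(mesh, faces, curve, coil) {
  Hp <- coil_AB(coil, mesh$centroid)$B / MU0
  mu_r <- relative_permeability(curve, row_norms(Hp))
  structure(list(mesh = mesh, faces = faces, curve = curve, coil = coil,
                 H_p = Hp, H_s = matrix(0, nrow(Hp), 3),
                 mu_r = mu_r, rho = numeric(length(faces$area)),
                 iteration = 0L),
            class = "core_state")
}

#' @export
print.core_state <- function(x, ...) {
  cat(sprintf("<core_state> iteration %d: mu_r in [%.4g, %.4g], mean %.4g\n",
              x$iteration, min(x$mu_r), max(x$mu_r), mean(x$mu_r)))
  invisible(x)
}

#' Secondary field per tet from the current charges
#'
#' By default the single-layer field of all face charges is evaluated at tet
#' centroids. With stabilizer weight `beta > 0`, the centroid value is
#' blended with the average of the four field values just inside the tet's
#' four faces (principal value plus the `-/+ rho/(2 mu0)` jump on the inner
#' side), a face-based average that damps the iteration for steep curves:
#' `H_s <- (1 - beta) * centroid + beta * face_average`.
#'
#' @param state a [initialize_core_state()] state
#' @param faces the face set
#' @param beta stabilizer weight in `[0, 1]`
#' @return n_tet-by-3 matrix of H^s (A/m)
#' @export
update_secondary_field <- function(state, faces, beta = 0) {
  if (beta < 0 || beta > 1) rlang::abort("`beta` must be in [0, 1]")
  Hs <- single_layer_H(faces, state$rho, state$mesh$centroid)
  if (beta > 0) {
    tfi <- tet_face_index(faces)
    Hface <- single_layer_H(faces, state$rho, faces$center)  # principal values
    nt <- nrow(state$mesh$centroid)
    Havg <- matrix(0, nt, 3)
    for (k in 1:4) {
      f <- tfi$face[, k]
      s <- tfi$sign[, k]   # +1 when the tet is the plus tet (normal points away)
      Hin <- Hface[f, , drop = FALSE] - (s * state$rho[f] / (2 * MU0)) * faces$normal[f, , drop = FALSE]
      Havg <- Havg + Hin / 4
    }
    Hs <- (1 - beta) * Hs + beta * Havg
  }
  Hs
}

#' Neighbor smoothing of the per-tet permeability
#'
#' `mu[t] <- alpha * mu[t] + (1 - alpha)/4 * sum(mu[neighbors])`; tets with
#' fewer than four face-neighbors keep the missing weight themselves, so a
#' uniform field is a fixed point for any alpha.
#'
#' @param mu_r per-tet relative permeability
#' @param neighbors list of face-neighbor tet indices per tet (see
#'   [build_faces()])
#' @param alpha retained weight, `0 < alpha <= 1` (1 = no smoothing)
#' @return smoothed per-tet permeability
#' @export
smooth_permeability <- function(mu_r, neighbors, alpha) {
  if (alpha <= 0 || alpha > 1) rlang::abort("`alpha` must satisfy 0 < alpha <= 1")
  if (alpha == 1) return(mu_r)
  out <- numeric(length(mu_r))
  w <- (1 - alpha) / 4
  for (t in seq_along(mu_r)) {
    nb <- neighbors[[t]]
    k <- length(nb)
    out[t] <- (alpha + (4 - k) * w) * mu_r[t] + w * sum(mu_r[nb])
  }
  out
}

#' Update the per-tet permeability from the B-H curve
#'
#' Evaluates the raw curve value `mu_r(|H^p + H^s|)` per tet, then applies
#' the neighbor smoothing of [smooth_permeability()].
#'
#' @inheritParams update_secondary_field
#' @param curve a [bh_curve()]
#' @param alpha smoothing weight (1 = raw curve values)
#' @param neighbors optional precomputed neighbor list
#' @return per-tet relative permeability
#' @export
update_permeability <- function(state, curve, alpha = 1, neighbors = NULL) {
  raw <- relative_permeability(curve, row_norms(state$H_p + state$H_s))
  if (alpha == 1) return(raw)
  neighbors <- neighbors %||% tet_neighbors(state$faces)
  smooth_permeability(raw, neighbors, alpha)
}

#' Per-face differential permeability contrasts
#'
#' `K = (mu+ - mu-)/(mu+ + mu-)` with `mu+` and `mu-` the permeabilities of
#' the plus/minus adjacent tets; boundary faces see `mu- = mu0`. Relative
#' permeabilities are used directly since the `mu0` factors cancel.
#'
#' @param state a `core_state` (or any object with a `mu_r` per-tet vector)
#' @param faces the face set
#' @return per-face contrast vector in `[-1, 1]`
#' @export
face_contrasts <- function(state, faces) {
  mu <- state$mu_r
  mu_plus <- mu[faces$plus_tet]
  mu_minus <- ifelse(faces$is_boundary, 1, mu[ifelse(is.na(faces$minus_tet), 1L,
                                                     faces$minus_tet)])
  (mu_plus - mu_minus) / (mu_plus + mu_minus)
}

#' Solve a nonlinear core by successive substitution
#'
#' Iterates: secondary field from the current charges, permeability update
#' from the B-H curve (with optional neighbor smoothing), differential face
#' contrasts, and a GMRES solve of the charge equation on all faces (right-
#' hand side `K * n . B^p` at every face center). Convergence is declared
#' when the relative deviations
#' `e1 = ||rho_n - rho_(n-1)|| / ||rho_n||` and
#' `e2 = ||mu_n - mu_(n-1)|| / ||mu_n||`
#' both drop below their tolerances.
#'
#' If `e1` or `e2` grows for five consecutive iterations the run is declared
#' divergent; with `auto_stabilize = TRUE` (default) the solve is retried
#' once with the face-averaging stabilizer (`beta = 0.25`) before failing
#' with advice to reduce `alpha` or raise `beta`.
#'
#' @param mesh a [tet_mesh()] core
#' @param curve a [bh_curve()]
#' @param coil a [filament_coil()] (its `I0` sets the drive strength)
#' @param alpha permeability smoothing weight (1 = none)
#' @param beta face-averaging stabilizer weight in `[0, 1]`
#' @param tol_e1,tol_e2 convergence tolerances on e1 and e2
#' @param max_iter maximum nonlinear iterations
#' @param gmres_tol,gmres_max GMRES controls for each linear solve
#' @param mu_switch permeability above which the final interior field of a
#'   tet is reconstructed from its face jump conditions rather than by
#'   direct centroid evaluation (high-contrast correction)
#' @param compute_inductance also compute `L_p` and the core correction `L_s`
#' @param auto_stabilize retry once with `beta = 0.25` on detected divergence
#' @param verbose print one line per iteration
#' @return a `coremag_solution` with the converged state and a per-iteration
#'   convergence log (`$log`: iteration, e1, e2, GMRES iterations, mu_r
#'   summaries), also of class `coremag_convergence` for [autoplot()]
#' @export
solve_nonlinear_core <- function(mesh, curve, coil, alpha = 0.7, beta = 0,
                                 tol_e1 = 1e-3, tol_e2 = 5e-3, max_iter = 30L,
                                 gmres_tol = 1e-8, gmres_max = 300L,
                                 mu_switch = 8,
                                 compute_inductance = TRUE,
                                 auto_stabilize = TRUE, verbose = FALSE) {
  faces <- build_faces(mesh)
  op <- bem_operator(faces)
  Hmats <- cpp_H_matrices(faces$vertices, faces_F0(faces), faces$center,
                          faces$area, mesh$centroid, op$eta)
  Bn <- rowSums(faces$normal * coil_AB(coil, faces$center)$B)
  neighbors <- tet_neighbors(faces)
  run <- function(beta_use) {
    nonlinear_iterate(mesh, faces, curve, coil, op, Hmats, Bn, neighbors,
                      alpha, beta_use, tol_e1, tol_e2, max_iter,
                      gmres_tol, gmres_max, mu_switch, verbose)
  }
  res <- if (auto_stabilize && beta == 0) {
    tryCatch(run(0), coremag_divergence = function(e) {
      rlang::inform("divergence detected; retrying with face-averaging stabilizer beta = 0.25")
      run(0.25)
    })
  } else run(beta)
  L_s <- NA_real_
  if (min(res$mu_r) > mu_switch && max(res$mu_r) / min(res$mu_r) < 1.05 &&
      coil$I0 != 0) {
    # the whole core sits on the flat small-signal part of the curve: the
    # state is effectively a linear core, so use the charge-based interior
    # reconstruction and the boundary energy functional (accurate at any mu)
    bidx <- which(faces$is_boundary)
    bfaces <- face_subset(faces, bidx)
    bop <- bem_operator(bfaces, eta = op$eta)
    hr <- harmonic_reconstruction(bop, bfaces, res$rho[bidx], mesh$centroid)
    res$M <- hr$M
    L_s <- 2 * surface_core_energy(bfaces, hr$sigma, coil) / coil$I0^2
  }
  L_p <- if (compute_inductance) self_inductance(coil, check = FALSE) else NA_real_
  sol <- new_coremag_solution(coil = coil, mesh = mesh, faces = faces,
                              rho = res$rho, mu_r = res$mu_r,
                              H_total = res$H_total, M = res$M, curve = curve,
                              L_p = L_p, log = res$log, converged = res$converged,
                              kind = "nonlinear", L_s_override = L_s)
  class(sol) <- c("coremag_solution", "coremag_convergence")
  sol
}

nonlinear_iterate <- function(mesh, faces, curve, coil, op, Hmats, Bn, neighbors,
                              alpha, beta, tol_e1, tol_e2, max_iter,
                              gmres_tol, gmres_max, mu_switch, verbose) {
  nt <- nrow(mesh$tets); nf <- length(faces$area)
  Hp <- coil_AB(coil, mesh$centroid)$B / MU0
  state <- structure(list(mesh = mesh, faces = faces, curve = curve, coil = coil,
                          H_p = Hp, H_s = matrix(0, nt, 3),
                          mu_r = relative_permeability(curve, row_norms(Hp)),
                          rho = numeric(nf), iteration = 0L),
                     class = "core_state")
  tfi <- if (beta > 0) tet_face_index(faces) else NULL
  mu_prev <- state$mu_r
  rho_prev <- state$rho
  log_rows <- vector("list", max_iter)
  converged <- FALSE
  bad_e1 <- 0L; bad_e2 <- 0L
  e1_prev <- Inf; e2_prev <- Inf
  for (it in seq_len(max_iter)) {
    # (b) secondary field from current charges
    if (it == 1L) {
      state$H_s <- matrix(0, nt, 3)
    } else {
      Hs <- cbind(Hmats$Hx %*% state$rho, Hmats$Hy %*% state$rho,
                  Hmats$Hz %*% state$rho) / MU0
      if (beta > 0) {
        Hface <- single_layer_H(faces, state$rho, faces$center)
        Havg <- matrix(0, nt, 3)
        for (k in 1:4) {
          f <- tfi$face[, k]; s <- tfi$sign[, k]
          Havg <- Havg + (Hface[f, , drop = FALSE] -
                          (s * state$rho[f] / (2 * MU0)) * faces$normal[f, , drop = FALSE]) / 4
        }
        Hs <- (1 - beta) * Hs + beta * Havg
      }
      state$H_s <- Hs
    }
    # (c) permeability from the curve, smoothed
    raw <- relative_permeability(curve, row_norms(state$H_p + state$H_s))
    state$mu_r <- if (alpha < 1) smooth_permeability(raw, neighbors, alpha) else raw
    # (d) contrasts, (e) charge solve on all faces
    K <- face_contrasts(state, faces)
    rhs <- K * Bn
    sol <- solve_charges(op, K, rhs, tol = gmres_tol, max_iter = gmres_max,
                         x0 = if (it > 1L) state$rho else NULL)
    state$rho <- sol$rho
    state$iteration <- it
    nr <- sqrt(sum(state$rho^2)); nm <- sqrt(sum(state$mu_r^2))
    e1 <- if (nr > 0) sqrt(sum((state$rho - rho_prev)^2)) / nr else 0
    e2 <- if (nm > 0) sqrt(sum((state$mu_r - mu_prev)^2)) / nm else 0
    log_rows[[it]] <- tibble::tibble(
      iteration = it, e1 = e1, e2 = e2, gmres_iterations = sol$iterations,
      mean_mu_r = mean(state$mu_r), min_mu_r = min(state$mu_r),
      max_mu_r = max(state$mu_r))
    if (verbose)
      message(sprintf("iter %2d: e1 = %.3e, e2 = %.3e, gmres = %d, mean mu_r = %.4g",
                      it, e1, e2, sol$iterations, mean(state$mu_r)))
    rho_prev <- state$rho; mu_prev <- state$mu_r
    if (it >= 2L && e1 <= tol_e1 && e2 <= tol_e2) { converged <- TRUE; break }
    bad_e1 <- if (e1 > e1_prev) bad_e1 + 1L else 0L
    bad_e2 <- if (e2 > e2_prev) bad_e2 + 1L else 0L
    e1_prev <- e1; e2_prev <- e2
    if (bad_e1 >= 5L || bad_e2 >= 5L)
      rlang::abort(paste("nonlinear iteration diverging (e1/e2 increased for 5",
                         "consecutive steps); reduce `alpha` or increase the",
                         "face-averaging stabilizer `beta`"),
                   class = c("coremag_divergence", "coremag_nonconvergence"),
                   log = do.call(rbind, log_rows[seq_len(it)]))
  }
  log <- do.call(rbind, log_rows[!vapply(log_rows, is.null, TRUE)])
  # consistent final fields for the converged permeability/charges
  state$H_s <- cbind(Hmats$Hx %*% state$rho, Hmats$Hy %*% state$rho,
                     Hmats$Hz %*% state$rho) / MU0
  H_total <- state$H_p + state$H_s
  # high-permeability tets: the direct interior field is a difference of
  # nearly cancelling terms whose error is amplified by mu_r; reconstruct it
  # from the per-face jump conditions instead (normal field continuity
  # mu n.H_in = mu_other n.H_other, evaluated from the uncancelled outside)
  hi <- which(state$mu_r > mu_switch)
  if (length(hi) > 0L) {
    Hrec <- jump_interior_H(faces, state$rho, state$mu_r, coil)
    H_total[hi, ] <- Hrec[hi, , drop = FALSE]
  }
  # curve-consistent magnetization: chi(|H|) H is bounded by the material's
  # saturation ceiling for any H, unlike (mu_iter - 1) H with mismatched
  # iterate permeabilities
  M <- (relative_permeability(curve, row_norms(H_total)) - 1) * H_total
  list(rho = state$rho, mu_r = state$mu_r, H_total = H_total, M = M,
       log = log, converged = converged)
}

# Per-tet total field reconstructed from the normal components just inside
# the tet's four faces. The field on the far side of each face is evaluated
# without cancellation (principal value plus half-jump); the exact interface
# condition mu_t n.H_t = mu_other n.H_other then scales it down into the
# tet, and the four normal projections determine H by least squares.
jump_interior_H <- function(faces, rho, mu_r, coil) {
  Hpv <- single_layer_H(faces, rho, faces$center) +
    coil_AB(coil, faces$center)$B / MU0
  hn_pv <- rowSums(faces$normal * Hpv)
  tfi <- tet_face_index(faces)
  nt <- length(mu_r)
  H <- matrix(0, nt, 3)
  for (t in seq_len(nt)) {
    f <- tfi$face[t, ]
    s <- tfi$sign[t, ]
    other <- ifelse(s > 0, faces$minus_tet[f], faces$plus_tet[f])
    mu_other <- ifelse(is.na(other), 1, mu_r[pmax(other, 1L, na.rm = TRUE)])
    hn_other <- hn_pv[f] + s * rho[f] / (2 * MU0)
    d <- (mu_other / mu_r[t]) * hn_other
    N <- faces$normal[f, , drop = FALSE]
    H[t, ] <- solve(crossprod(N), crossprod(N, d))
  }
  H
}
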