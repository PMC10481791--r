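# Successive substitution on all faces of the core mesh.

# nearly field-independent froelich curve (mu_r0 = 5): reduces to a linear core
constant_curve <- function(mu_r0 = 5) {
  bh_curve("froelich", a1 = 1 / (MU0_TEST * (mu_r0 - 1)), a2 = 1e-12)
}

test_that("state initialization follows the free-space coil field", {
  cfg <- make_fixture("loop_cylinder")
  mesh <- config_core(cfg)
  faces <- build_faces(mesh)
  curve <- preset_material(1)
  coil_off <- config_coil(cfg); coil_off$I0 <- 0
  st0 <- initialize_core_state(mesh, faces, curve, coil_off)
  expect_equal(st0$mu_r, rep(initial_permeability(curve), nrow(mesh$tets)))
  expect_true(all(st0$rho == 0) && all(st0$H_s == 0))
  # a strong drive saturates: everywhere strictly below the small-signal value
  coil_hot <- config_coil(cfg); coil_hot$I0 <- 20e3
  st1 <- initialize_core_state(mesh, faces, curve, coil_hot)
  expect_true(all(st1$mu_r < initial_permeability(curve)))
  # rho = 0 implies a vanishing secondary field
  expect_true(all(update_secondary_field(st1, faces) == 0))
})

test_that("permeability smoothing is a proper local average", {
  cfg <- make_fixture("loop_cylinder")
  mesh <- config_core(cfg)
  faces <- build_faces(mesh)
  nb <- coremag:::tet_neighbors(faces)
  uniform <- rep(42, nrow(mesh$tets))
  for (alpha in c(0.3, 0.7, 1)) {
    expect_equal(smooth_permeability(uniform, nb, alpha), uniform)
  }
  # a single spike is strictly contracted toward its neighbors
  patt <- rep(100, nrow(mesh$tets))
  spike <- which.max(lengths(nb))
  patt[spike] <- 200
  sm <- smooth_permeability(patt, nb, alpha = 0.5)
  expect_lt(max(sm) - min(sm), max(patt) - min(patt))
  expect_equal(sm[spike], 0.5 * 200 + 0.5 * 100)
  expect_error(smooth_permeability(patt, nb, alpha = 0), "alpha")
})

test_that("face contrasts follow the differential permeability convention", {
  two <- two_tet_mesh()
  fs <- build_faces(two)
  st <- list(mu_r = c(1000, 1000))
  K <- face_contrasts(st, fs)
  inner <- which(!fs$is_boundary)
  expect_equal(K[inner], 0)                       # equal neighbors
  expect_equal(K[fs$is_boundary][1], 999 / 1001)  # boundary sees mu0
  st2 <- list(mu_r = c(10, 4))
  expect_equal(face_contrasts(st2, fs)[inner], (10 - 4) / (10 + 4))
})

test_that("a single charged face obeys the rho/mu0 jump relation", {
  fs <- disc_face_set(0.1, n_az = 8L, n_r = 1L)
  one <- coremag:::face_subset(fs, 1L)
  rho <- 3e-3
  eps <- 1e-9
  p_in <- one$center[1, ] - eps * one$normal[1, ]
  p_out <- one$center[1, ] + eps * one$normal[1, ]
  Hin <- single_layer_H(one, rho, p_in)
  Hout <- single_layer_H(one, rho, p_out)
  jump <- as.numeric(Hout - Hin)
  expect_equal(sum(jump * one$normal[1, ]), rho / MU0_TEST, tolerance = 1e-6)
})

test_that("a field-independent curve reproduces the linear boundary solve", {
  cfg <- make_fixture("loop_cylinder")
  mesh <- config_core(cfg)
  coil <- config_coil(cfg)
  curve <- constant_curve(5)
  nl <- solve_nonlinear_core(mesh, curve, coil, alpha = 1,
                             compute_inductance = FALSE)
  expect_true(nl$converged)
  expect_lte(max(nl$log$iteration), 2L)
  lin <- solve_linear_core(mesh, mu_r = initial_permeability(curve), coil = coil,
                           compute_inductance = FALSE)
  b <- which(nl$faces$is_boundary)
  # inner faces carry (essentially) no charge; boundary matches the linear solve
  expect_lt(max(abs(nl$rho[-b])), 1e-6 * max(abs(nl$rho[b])))
  expect_lt(sqrt(sum((nl$rho[b] - lin$rho)^2)) / sqrt(sum(lin$rho^2)), 1e-6)
  # identical consecutive states drive both deviations to zero
  expect_lt(nl$log$e1[nrow(nl$log)], 1e-6)
})

test_that("the weak-field nonlinear solution matches the small-signal linear core", {
  cfg <- make_fixture("loop_cylinder")
  mesh <- config_core(cfg)
  coil <- config_coil(cfg); coil$I0 <- 1e-3
  curve <- preset_material(1)
  nl <- solve_nonlinear_core(mesh, curve, coil, compute_inductance = FALSE)
  lin <- suppressMessages(
    solve_linear_core(mesh, mu_r = initial_permeability(curve), coil = coil,
                      compute_inductance = FALSE))
  b <- which(nl$faces$is_boundary)
  expect_lt(sqrt(sum((nl$rho[b] - lin$rho)^2)) / sqrt(sum(lin$rho^2)), 0.01)
  expect_lt(abs(mean(nl$mu_r) / initial_permeability(curve) - 1), 0.01)
})

test_that("saturation reduces the average permeability monotonically with current", {
  cfg <- make_fixture("loop_cylinder")
  mesh <- config_core(cfg)
  curve <- preset_material(1)
  mu_means <- vapply(c(1e-3, 100, 20e3), function(I0) {
    coil <- config_coil(cfg); coil$I0 <- I0
    mean(solve_nonlinear_core(mesh, curve, coil,
                              compute_inductance = FALSE)$mu_r)
  }, numeric(1))
  expect_true(all(diff(mu_means) < 0))
  expect_true(all(mu_means <= initial_permeability(curve)))
  expect_true(all(mu_means >= 1))
})

test_that("the solution is invariant under plus/minus relabeling of tets", {
  cfg <- make_fixture("loop_cylinder")
  mesh <- config_core(cfg)
  coil <- config_coil(cfg)
  curve <- preset_material(1)
  sol1 <- solve_nonlinear_core(mesh, curve, coil, compute_inductance = FALSE)
  # reversing the tet order flips every plus/minus assignment (and normals)
  perm <- rev(seq_len(nrow(mesh$tets)))
  mesh2 <- tet_mesh(mesh$vertices, mesh$tets[perm, ])
  sol2 <- solve_nonlinear_core(mesh2, curve, coil, compute_inductance = FALSE)
  expect_equal(sol2$mu_r[order(perm)], sol1$mu_r, tolerance = 1e-6)
  expect_equal(sum(abs(sol2$rho) * sol2$faces$area),
               sum(abs(sol1$rho) * sol1$faces$area), tolerance = 1e-6)
})

test_that("the face-averaging stabilizer is a convex blend", {
  cfg <- make_fixture("loop_cylinder")
  mesh <- config_core(cfg)
  faces <- build_faces(mesh)
  coil <- config_coil(cfg)
  st <- initialize_core_state(mesh, faces, preset_material(1), coil)
  set.seed(11)
  st$rho <- rnorm(length(faces$area), sd = 1e-4)
  h0 <- update_secondary_field(st, faces, beta = 0)
  h1 <- update_secondary_field(st, faces, beta = 1)
  h05 <- update_secondary_field(st, faces, beta = 0.5)
  expect_equal(h05, 0.5 * h0 + 0.5 * h1, tolerance = 1e-12)
  expect_error(update_secondary_field(st, faces, beta = 2), "beta")
})
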