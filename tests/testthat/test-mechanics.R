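# Constitutive model, element kernels, solver, principal stresses, feedback.

test_that("Green-Lagrange strain matches closed forms", {
  expect_equal(strain(diag(3)), matrix(0, 3, 3))
  eps <- strain(diag(c(1.1, 1)))
  expect_equal(eps[1L, 1L], (1.1^2 - 1) / 2)
  expect_equal(eps[2L, 2L], 0)
  shear <- strain(matrix(c(1, 0, 0.2, 1), 2, 2)) # F = [[1, .2], [0, 1]]
  expect_equal(shear, matrix(c(0, 0.1, 0.1, 0.02), 2, 2))
  expect_error(strain(matrix(c(1, 0, 0, -1), 2, 2)), "determinant")
  expect_error(strain(matrix(c(1, NA, 0, 1), 2, 2)), "finite")
})

test_that("SVK stress is the strain-energy gradient (finite differences)", {
  mat <- material_params()
  set.seed(42)
  for (rep in 1:5) {
    a <- rnorm(3, sd = 0.02)
    eps <- matrix(c(a[1L], a[3L], a[3L], a[2L]), 2, 2)
    S <- svk_energy(eps, mat)$S
    h <- 1e-6
    for (ij in list(c(1, 1), c(2, 2))) {
      dE <- matrix(0, 2, 2); dE[ij[1L], ij[2L]] <- h
      fd <- (svk_energy(eps + dE, mat)$W - svk_energy(eps - dE, mat)$W) / (2 * h)
      expect_equal(fd, S[ij[1L], ij[2L]], tolerance = 1e-6)
    }
    # off-diagonal: symmetric perturbation carries both E12 and E21
    dE <- matrix(c(0, h, h, 0), 2, 2)
    fd <- (svk_energy(eps + dE, mat)$W - svk_energy(eps - dE, mat)$W) / (2 * h)
    expect_equal(fd, 2 * S[1L, 2L], tolerance = 1e-6)
  }
  # equibiaxial closed form: S = (2 lambda + 2 mu) e * I
  lp <- pavemech:::lame_plane_stress(mat$E_matrix, mat$nu_matrix)
  e <- 0.01
  S <- svk_energy(diag(c(e, e)), mat)$S
  expect_equal(S, (2 * lp$lambda + 2 * lp$mu) * e * diag(2))
  expect_equal(svk_energy(matrix(0, 2, 2), mat)$W, 0)
})

test_that("fiber term vanishes orthogonally and calibrates the stiffness ratio", {
  mat <- material_params(fiber_ratio = 5)
  # strain orthogonal to the fiber: zero fiber energy
  eps <- diag(c(0, 0.03))
  expect_equal(fiber_energy(eps, c(1, 0), mat)$W, 0)
  # fiber_ratio = 1 reduces exactly to the isotropic model
  expect_equal(fiber_zeta(material_params(fiber_ratio = 1)), 0)
  # finite-difference tangent of W_total at zero strain -> Voigt D matrix;
  # uniaxial (laterally free) stiffness along/across the fiber ratio = 5
  a <- c(1, 0)
  W <- function(e1, e2, g) {
    eps <- matrix(c(e1, g / 2, g / 2, e2), 2, 2)
    svk_energy(eps, mat)$W + fiber_energy(eps, a, mat)$W
  }
  h <- 1e-5
  D11 <- (W(h, 0, 0) - 2 * W(0, 0, 0) + W(-h, 0, 0)) / h^2
  D22 <- (W(0, h, 0) - 2 * W(0, 0, 0) + W(0, -h, 0)) / h^2
  D12 <- (W(h, h, 0) - W(h, -h, 0) - W(-h, h, 0) + W(-h, -h, 0)) / (4 * h^2)
  E_along <- D11 - D12^2 / D22
  E_cross <- D22 - D12^2 / D11
  expect_equal(E_along / E_cross, 5, tolerance = 1e-5)
  expect_warning(fiber_energy(eps, c(2, 0), mat), "normaliz")
})

test_that("assembled internal force is the gradient of the energy", {
  mesh <- fx_two_cell_mesh()
  mat <- material_params()
  fib <- matrix(rep(c(1, 0.3, 0), each = nrow(mesh$triangles)),
                ncol = 3L)
  cache <- pavemech:::build_fem_cache(mesh, mat, fiber = fib)
  set.seed(7)
  X <- mesh$vertices + matrix(rnorm(length(mesh$vertices), sd = 0.05),
                              ncol = 3L)
  pel <- rep(0.2, nrow(mesh$triangles))
  a <- pavemech:::assemble_system(cache, X, pel, NULL, TRUE)
  h <- 1e-6
  idx <- sample(length(X), 25L)
  for (k in idx) {
    Xp <- X; Xp[k] <- Xp[k] + h
    Xm <- X; Xm[k] <- Xm[k] - h
    ep <- pavemech:::assemble_system(cache, Xp, pel, NULL, FALSE)$energy
    em <- pavemech:::assemble_system(cache, Xm, pel, NULL, FALSE)$energy
    # dof layout is row-major over vertices
    v <- (k - 1L) %% nrow(X) + 1L
    c3 <- (k - 1L) %/% nrow(X) + 1L
    expect_equal(a$grad[3L * (v - 1L) + c3], (ep - em) / (2 * h),
                 tolerance = 1e-4)
  }
  # Hessian column check at a few dofs
  H <- Matrix::sparseMatrix(i = a$hi + 1L, j = a$hj + 1L, x = a$hx,
                            dims = c(length(X), length(X)))
  for (k in sample(length(X), 5L)) {
    v <- (k - 1L) %% nrow(X) + 1L
    c3 <- (k - 1L) %/% nrow(X) + 1L
    dof <- 3L * (v - 1L) + c3
    Xp <- X; Xp[k] <- Xp[k] + h
    Xm <- X; Xm[k] <- Xm[k] - h
    gp <- pavemech:::assemble_system(cache, Xp, pel, NULL, FALSE)$grad
    gm <- pavemech:::assemble_system(cache, Xm, pel, NULL, FALSE)$grad
    expect_equal(as.numeric(H[, dof]), (gp - gm) / (2 * h), tolerance = 1e-3)
  }
})

test_that("loads and constraints follow the template conventions", {
  mesh <- fx_two_cell_mesh()
  mat <- material_params() # 1% expansion
  loads <- apply_loads_and_bcs(mesh, mat)
  # outer vertices prescribed radially about the centroid
  out_v <- which(mesh$outer)[1L]
  cen <- loads$centroid
  dofs <- 3L * (out_v - 1L) + 1:2
  i1 <- match(dofs[1L], loads$fixed_idx); i2 <- match(dofs[2L], loads$fixed_idx)
  expect_equal(loads$fixed_val[i1],
               cen[1L] + 1.01 * (mesh$vertices[out_v, 1L] - cen[1L]))
  expect_equal(loads$fixed_val[i2],
               cen[2L] + 1.01 * (mesh$vertices[out_v, 2L] - cen[2L]))
  # every cell-boundary vertex carries a z constraint
  zb <- which(mesh$z_fixed)
  expect_true(all((3L * (zb - 1L) + 3L) %in% loads$fixed_idx))
  # an outer vertex at (100, 0) expanded 1% about the origin -> (101, 0)
  expect_equal(0 + 1.01 * (100 - 0), 101)
  # no loads -> zero displacement in 0 iterations
  mat0 <- material_params(turgor_P = 0, boundary_expansion = 0,
                          fiber_ratio = 1)
  d0 <- solve_equilibrium(mesh, mat0)
  expect_true(d0$converged)
  expect_equal(max(abs(d0$X - mesh$vertices)), 0)
})

test_that("pressurized sphere carries isotropic Laplace stress", {
  mat <- material_params(fiber_ratio = 1)
  m <- make_sphere_mesh(20, 2)
  d <- solve_equilibrium(m, mat)
  s <- principal_stress(d, m, mat)
  expect_true(all((s$sigma1 - s$sigma2) / s$sigma1 < 0.05))
  expect_true(all(abs(rowSums(s$dir1 * s$dir2)) < 1e-8)) # d1 perpendicular d2
  # equibiaxial state flags many degenerate elements
  expect_gt(sum(s$degenerate), 0)
  expect_error(principal_stress(
    structure(list(converged = FALSE), class = "fem_displacements"), m, mat),
    "not converged")
})

test_that("rigid rotation of the template rotates stress directions with it", {
  mesh <- fx_two_cell_mesh()
  mat <- material_params(fiber_ratio = 1)
  d1 <- solve_equilibrium(mesh, mat)
  s1 <- principal_stress(d1, mesh, mat)
  th <- 37 * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  mesh2 <- mesh
  mesh2$vertices <- mesh$vertices %*% t(R)
  d2 <- solve_equilibrium(mesh2, mat)
  s2 <- principal_stress(d2, mesh2, mat)
  expect_equal(s2$sigma1, s1$sigma1, tolerance = 1e-5)
  expect_equal(s2$sigma2, s1$sigma2, tolerance = 1e-5)
  keep <- !s1$degenerate & !s2$degenerate &
    (s1$sigma1 - s1$sigma2) > 0.05 * abs(s1$sigma1)
  rot_dir <- s1$dir1[keep, , drop = FALSE] %*% t(R)
  cosang <- abs(rowSums(rot_dir * s2$dir1[keep, , drop = FALSE]))
  expect_gt(stats::median(cosang), 0.999)
})

test_that("stress direction pattern is robust to 0.5-2x parameter changes", {
  fx <- fx_jigsaw_template()
  base <- fx$stress
  keep0 <- !base$degenerate
  ang <- function(s) atan2(s$dir1[, 2L], s$dir1[, 1L]) * 180 / pi
  for (mat2 in list(material_params(E_matrix = 20, fiber_ratio = 1),
                    material_params(turgor_P = 0.4, fiber_ratio = 1),
                    material_params(wall_thickness = 0.5, fiber_ratio = 1))) {
    d <- solve_equilibrium(fx$mesh, mat2)
    s <- principal_stress(d, fx$mesh, mat2)
    keep <- keep0 & !s$degenerate
    dtheta <- axial_angle_diff(ang(base)[keep], ang(s)[keep])
    expect_lt(stats::median(dtheta), 15)
  }
})

test_that("feedback alignment is a no-op without anisotropy and stable with it", {
  mesh <- fx_two_cell_mesh()
  mat1 <- material_params(fiber_ratio = 1)
  fb <- feedback_align(mesh, mat1, n_steps = 3)
  # fiber_ratio 1: solve is independent of fibers, directions identical
  expect_gt(stats::median(fb$cosine), 0.999)
  expect_equal(fb$iterations, 1L)
})
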