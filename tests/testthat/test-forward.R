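single_tet_mesh <- function(mu_a = 0.01, mus = 1, ri = 1.4) {
  nodes <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10))
  mesh <- structure(list(nodes = nodes, elems = matrix(1:4, 1),
                         node_label = rep(1L, 4), elem_label = 1L,
                         element_volumes = 1000 / 6,
                         voxel_pitch = c(10, 10, 10), meta = list()),
                    class = "tetra_mesh")
  mesh$surface <- cetanirs:::.extract_surface(mesh)
  assign_uniform_properties(mesh, mu_a, mus, ri)
}

test_that("single-tetrahedron system matches hand-computed element integrals", {
  mu_a <- 0.01; mus <- 1; ri <- 1.4
  mesh <- single_tet_mesh(mu_a, mus, ri)
  K <- as.matrix(assemble_system(mesh)$K)
  kap <- 1 / (3 * (mu_a + mus)); V <- 1000 / 6
  # closed-form P1 gradients for the right tet with legs 10 mm
  G <- rbind(c(-0.1, -0.1, -0.1), c(0.1, 0, 0), c(0, 0.1, 0), c(0, 0, 0.1))
  S <- kap * V * G %*% t(G)
  gam <- 1 / (2 * boundary_factor(ri))
  areas <- c(50, 50, 50, sqrt(3) / 2 * 100)    # faces opp. nodes 4,3,2... all
  # node 1 belongs to the three right faces; nodes 2-4 to two right faces +
  # the slanted face
  bnd <- c(3 * 50, 2 * 50 + areas[4], 2 * 50 + areas[4], 2 * 50 + areas[4]) *
    gam / 3
  expected <- S + diag(mu_a * V / 4 + bnd)
  expect_equal(K, expected, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(K, t(K))
})

test_that("absorption changes touch only the diagonal (lumped mass)", {
  mesh <- fix_bench()$mesh
  sys1 <- assemble_system(mesh)
  mesh2 <- mesh
  mesh2$node_props$mu_a <- 2 * mesh$node_props$mu_a
  mesh2$node_props$kappa <- mesh$node_props$kappa  # isolate the mass term
  sys2 <- assemble_system(mesh2)
  D <- sys2$K - sys1$K
  expect_equal(Matrix::nnzero(D - Matrix::Diagonal(nrow(mesh$nodes),
                                                   Matrix::diag(D))), 0)
  expect_equal(Matrix::diag(D), mesh$node_props$mu_a * sys1$vlump)
  bad <- mesh; bad$node_props$mu_a[5] <- -1
  expect_error(assemble_system(bad), "non-positive")
})

test_that("fluence is positive and decays monotonically along the surface", {
  s <- fix_slab()
  expect_true(all(s$fwd0$phi > 0))
  expect_true(all(s$fwd0$amplitudes > 0))
  src1 <- s$opt[s$opt$role == "source", ][1, ]
  pts <- cbind(src1$x + seq(30, 120, by = 10), 80, src1$z)
  sys <- s$fwd0$system
  vals <- interpolate_field(sys, s$fwd0$phi[, as.character(src1$id)], pts)
  expect_true(all(diff(vals[, 1]) < 0))
})

test_that("interpolation reproduces nodal values and linear fields", {
  s <- fix_bench()
  sys <- s$fwd$system
  mesh <- s$mesh
  lin <- 2 + 0.3 * mesh$nodes[, 1] - 0.1 * mesh$nodes[, 2] +
    0.05 * mesh$nodes[, 3]
  ids <- c(10, 101, 555)
  at_nodes <- interpolate_field(sys, lin, mesh$nodes[ids, ])
  expect_equal(at_nodes[, 1], lin[ids], tolerance = 1e-9)
  set.seed(10)
  pts <- cbind(runif(10, 10, 70), runif(10, 10, 50), runif(10, 10, 70))
  vals <- interpolate_field(sys, lin, pts)
  expect_equal(vals[, 1],
               2 + 0.3 * pts[, 1] - 0.1 * pts[, 2] + 0.05 * pts[, 3],
               tolerance = 1e-9)
})

test_that("adjoint reciprocity: swapping load and measurement functional", {
  s <- fix_bench()
  sys <- s$fwd$system
  src <- s$opt[s$opt$role == "source", ][1, ]
  det <- s$opt[s$opt$role == "detector", ][1, ]
  b_src <- cetanirs:::.point_load(sys,
                                  as.vector(cetanirs:::source_positions(
                                    s$mesh, src)))
  e_det <- cetanirs:::.point_load(sys, unlist(det[, c("x", "y", "z")]))
  a1 <- sum(e_det * as.vector(Matrix::solve(sys$factor, b_src)))
  a2 <- sum(b_src * as.vector(Matrix::solve(sys$factor, e_det)))
  expect_lt(abs(a1 / a2 - 1), 1e-3)
})

test_that("Jacobian entries are non-positive and match finite differences", {
  s <- fix_bench()
  J <- compute_jacobian(s$fwd)
  expect_true(all(J <= 0))
  amp0 <- s$fwd$amplitudes[1]
  d <- 1e-4
  # sample nodes whose sensitivity is resolvable against round-off
  resolvable <- which(abs(J[1, ]) * d / amp0 > 1e-9)
  set.seed(11)
  for (n in sample(resolvable, 6)) {
    m2 <- s$mesh
    m2$node_props$mu_a[n] <- m2$node_props$mu_a[n] + d
    fwd2 <- solve_forward(assemble_system(m2), s$opt, s$ch)
    fd <- fwd2$amplitudes[1] - amp0
    expect_rel_equal(J[1, n] * d, fd, 0.01)
  }
})

test_that("Jacobian row sums predict a global absorption increase", {
  s <- fix_bench()
  J <- compute_jacobian(s$fwd)
  d <- 1e-5
  m2 <- s$mesh
  m2$node_props$mu_a <- m2$node_props$mu_a + d
  m2$node_props$kappa <- m2$node_props$kappa  # scattering-only kappa kept
  fwd2 <- solve_forward(assemble_system(m2), s$opt, s$ch)
  drop_resolve <- fwd2$amplitudes - s$fwd$amplitudes
  drop_pred <- as.vector(J %*% rep(d, ncol(J)))
  expect_rel_equal(drop_pred, drop_resolve, 0.02)
})

test_that("wavelength re-assignment leaves the geometry bit-identical", {
  p <- fix_phantom()
  lams <- c(600, 850, 1100, 1700)
  h0 <- c(sum(p$mesh$nodes), sum(as.numeric(p$mesh$elems)))
  for (lam in lams) {
    m <- assign_properties(p$mesh, lam, fix_basis(), fix_compositions())
    expect_identical(c(sum(m$nodes), sum(as.numeric(m$elems))), h0)
    expect_identical(m$elems, p$mesh$elems)
  }
})

test_that("TS at a fixed channel is stable under mesh refinement", {
  ts_at <- function(h) {
    vol <- labeled_box(c(140, 70, 100), h, label_fun = function(x, y, z)
      ifelse(y > 50, 3L, ifelse(y > 35, 4L, 1L)))
    mesh <- assign_properties(mesh_labeled_volume(vol), 850,
                              fix_basis(), fix_compositions())
    opt <- surface_optodes(mesh, rbind(c(40, 70, 50), c(100, 70, 50)))
    ch <- build_channels(opt, 50, 70)
    fwd0 <- solve_forward(assemble_system(mesh), opt, ch)
    mesh_a <- activate_region(mesh, "brain", 1.1, fix_basis(),
                              fix_compositions())
    fwd_a <- solve_forward(assemble_system(mesh_a), opt, ch)
    ts_index(fwd0$amplitudes, fwd_a$amplitudes)[1]
  }
  t1 <- ts_at(3.5)
  t2 <- ts_at(3.5 / 2^(1 / 3))  # element volume halved
  expect_rel_equal(t2, t1, 0.02)
})
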