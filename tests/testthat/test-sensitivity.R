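test_that("activation changes only the target tissue's absorption", {
  p <- fix_phantom()
  m1 <- activate_region(p$mesh, "brain", 1.0, fix_basis(),
                        fix_compositions())
  expect_equal(m1$node_props, p$mesh$node_props)
  m2 <- activate_region(p$mesh, "brain", 1.1, fix_basis(),
                        fix_compositions())
  sel <- p$mesh$node_label == 1L
  expect_true(all(m2$node_props$mu_a[sel] > p$mesh$node_props$mu_a[sel]))
  expect_equal(m2$node_props$mu_a[!sel], p$mesh$node_props$mu_a[!sel])
  expect_equal(m2$node_props$mu_s_prime, p$mesh$node_props$mu_s_prime)
  m3 <- activate_region(p$mesh, "muscle", 1.1, fix_basis(),
                        fix_compositions())
  sel4 <- p$mesh$node_label == 4L
  expect_true(all(m3$node_props$mu_a[sel4] > p$mesh$node_props$mu_a[sel4]))
  expect_equal(m3$node_props$mu_a[!sel4], p$mesh$node_props$mu_a[!sel4])
  expect_error(activate_region(p$mesh, "kidney", 1.1), "unknown tissue")
})

test_that("brain activation raises brain mu_a at every hemoglobin-absorbing wavelength", {
  b <- fix_basis(); comps <- fix_compositions()
  vol <- labeled_box(40, 8, label = 1L)
  mesh <- mesh_labeled_volume(vol)
  for (lam in seq(600, 1700, by = 100)) {
    m0 <- assign_properties(mesh, lam, b, comps)
    m1 <- activate_region(m0, "brain", 1.1, b, comps)
    if (basis_mu_a(b, "HbO", lam) > 0)
      expect_gt(m1$node_props$mu_a[1], m0$node_props$mu_a[1])
  }
})

test_that("TS index obeys its log identities and equals the two-solve log ratio", {
  expect_equal(ts_index(c(1, 2), c(1, 2)), c(0, 0))
  expect_equal(ts_index(10 * c(3, 5), c(3, 5)), c(1, 1))
  expect_error(ts_index(c(1, -1), c(1, 1)), "positive")
  s <- fix_slab(); fa <- fix_slab_active()
  ts <- ts_index(s$fwd0$amplitudes, fa$amplitudes)
  expect_equal(ts, log10(s$fwd0$amplitudes) - log10(fa$amplitudes))
  expect_true(all(ts >= 0))
})

test_that("TS increases strictly with the activation multiplier", {
  s <- fix_bench()
  ts <- vapply(c(1.05, 1.1, 1.2), function(mult) {
    ma <- activate_region(s$mesh, "brain", mult, fix_basis(),
                          fix_compositions())
    fa <- solve_forward(assemble_system(ma), s$opt, s$ch)
    ts_index(s$fwd$amplitudes, fa$amplitudes)[1]
  }, numeric(1))
  expect_true(all(diff(ts) > 0))
  expect_true(all(ts > 0))
})

test_that("TS agrees with the first-order Jacobian prediction at 1% activation", {
  s <- fix_bench()
  J <- compute_jacobian(s$fwd)
  ma <- activate_region(s$mesh, "brain", 1.01, fix_basis(),
                        fix_compositions())
  fa <- solve_forward(assemble_system(ma), s$opt, s$ch)
  ts <- ts_index(s$fwd$amplitudes, fa$amplitudes)
  dmu <- ma$node_props$mu_a - s$mesh$node_props$mu_a
  pred <- -as.vector(J %*% dmu) / (log(10) * s$fwd$amplitudes)
  expect_rel_equal(pred, ts, 0.10)
})

test_that("Jacobian depth metric is normalized, scale-invariant, monotone with separation", {
  s <- fix_slab()
  J <- fix_slab_jacobian()
  dm <- jacobian_depth_metric(J, s$mesh, "brain")
  expect_true(all(dm >= 0 & dm <= 1))
  expect_equal(jacobian_depth_metric(100 * J, s$mesh, "brain"), dm)
  means <- tapply(dm, s$ch$bin, mean)
  expect_true(all(diff(means) > 0))
  # all-target mesh: metric is exactly 1
  one <- s$mesh; one$node_label[] <- 1L
  expect_equal(unname(jacobian_depth_metric(J[1:3, ], one, "brain")),
               rep(1, 3))
  expect_error(jacobian_depth_metric(J, s$mesh, "bone"), "absent")
})

test_that("flatfield reconstruction solves the toy identity-like problem", {
  # 1 nonzero per row: channels see exactly one node each
  J <- matrix(0, 3, 6)
  J[1, 2] <- -4; J[2, 4] <- -2; J[3, 5] <- -1
  mu_a <- rep(0.01, 6); mu_a[4] <- 0.05   # perturbation concentrated there
  ff <- flatfield_reconstruct(J, mu_a, lambda_reg = 1e-8)
  # closed-form small-matrix oracle
  dmu <- 0.01 * mu_a
  dphi <- J %*% dmu
  L <- colSums(J^2) + 1e-2 * max(colSums(J^2))
  Jh <- sweep(J, 2, L, "/")
  M <- rowSums(Jh^2) + 1e-2 * max(rowSums(Jh^2))
  Jt <- Jh / M
  x <- solve(tcrossprod(Jt) + 1e-8 * diag(3), dphi / M)
  oracle <- as.vector(crossprod(Jt, x)) / L
  expect_equal(ff$dmu_rec, oracle)
  expect_equal(ff$node_of_max, which.max(oracle))
  # seen nodes dominate unseen ones; the perturbed seen node wins
  expect_equal(which.max(ff$dmu_rec[c(2, 4, 5)]), 2L)
})

test_that("flatfield output is linear in the flatfield percentage", {
  J <- fix_slab_jacobian()[1:10, ]
  mu_a <- fix_slab()$mesh$node_props$mu_a
  f1 <- flatfield_reconstruct(J, mu_a, flat_frac = 0.01)
  f2 <- flatfield_reconstruct(J, mu_a, flat_frac = 0.03)
  expect_equal(f2$dmu_rec, 3 * f1$dmu_rec)
})

test_that("flatfield peak depth grows from the 60-70 to the 110-120 mm bin", {
  s <- fix_slab()
  J <- fix_slab_jacobian()
  g <- attr(s$ch, "groups")
  mu_a <- s$mesh$node_props$mu_a
  f2 <- flatfield_reconstruct(J[g[[2]], , drop = FALSE], mu_a, s$mesh)
  f7 <- flatfield_reconstruct(J[g[[7]], , drop = FALSE], mu_a, s$mesh)
  expect_gte(f7$depth_of_max, f2$depth_of_max)
  expect_gt(f2$depth_of_max, 0)
})

test_that("large-detector power reduces to mean fluence times area", {
  s <- fix_bench()
  det <- s$opt[s$opt$role == "detector", ][1, ]
  ctr <- unlist(det[, c("x", "y", "z")])
  const <- rep(3.5, nrow(s$mesh$nodes))
  fake <- s$fwd; fake$phi <- matrix(const, ncol = 1,
                                    dimnames = list(NULL, "1"))
  P <- large_detector_power(fake, 1, ctr)
  expect_equal(as.numeric(P), attr(P, "area") * 3.5, tolerance = 1e-9)
  expect_equal(attr(P, "area"), 100)
  P1 <- large_detector_power(fake, 1, ctr, grid_n = 1)
  expect_equal(as.numeric(P1), attr(P1, "area") * 3.5, tolerance = 1e-9)
})

test_that("large-detector power matches quadrature of an analytic half-space field", {
  # analytic diffusion field sampled on a fine slab mesh
  vol <- labeled_box(c(120, 40, 80), 2, label = 1L)
  mesh <- assign_uniform_properties(mesh_labeled_volume(vol), 0.005, 0.5)
  kap <- 1 / (3 * 0.505); mueff <- sqrt(0.005 / kap)
  srcpos <- c(10, 40, 40)
  fieldfun <- function(p) {
    r <- sqrt(colSums((t(p) - srcpos)^2))
    exp(-mueff * r) / (4 * pi * kap * pmax(r, 1))
  }
  phi <- fieldfun(mesh$nodes)
  sys <- assemble_system(mesh)
  fwd <- structure(list(phi = matrix(phi, ncol = 1,
                                     dimnames = list(NULL, "1")),
                        system = sys), class = "forward_result")
  ctr <- c(70, 40, 40)   # 60 mm from the source on the top surface
  P <- large_detector_power(fwd, 1, ctr)
  # independent fine midpoint quadrature of the analytic field over the
  # 10 x 10 mm patch
  f <- function(u, v) fieldfun(cbind(ctr[1] + u, 40, ctr[3] + v))
  n <- 801; mid <- seq(-5 + 5 / n, 5 - 5 / n, length.out = n)
  oracle <- mean(outer(mid, mid, function(u, v) f(u, v))) * 100
  expect_rel_equal(as.numeric(P), oracle, 0.01)
})

test_that("detector power metrics follow their definitions", {
  m <- detector_power_metrics(1e-10, 0.9999e-10)
  expect_equal(m$delta_P, 1e-14, tolerance = 1e-6)
  expect_equal(m$P_max, 1e-10)
  expect_equal(m$dynamic_range, 1e4, tolerance = 1e-6)
  expect_equal(m$delta_over_pmax, 1e-4, tolerance = 1e-6)
  mz <- detector_power_metrics(2e-10, 2e-10)
  expect_true(mz$flagged)
  expect_equal(mz$dynamic_range, Inf)
  # common rescaling: only delta_P scales
  m2 <- detector_power_metrics(5e-10, 5 * 0.9999e-10)
  expect_equal(m2$dynamic_range, m$dynamic_range, tolerance = 1e-9)
  expect_equal(m2$delta_P, 5 * m$delta_P, tolerance = 1e-9)
  expect_error(detector_power_metrics(-1, 1), "positive")
})
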