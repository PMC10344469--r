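# Shared fixtures, built once per test run. Everything is generated in code;
# sizes are chosen so the whole suite stays desk-scale.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fix[[name]])) assign(name, build(), envir = .fix)
  get(name, envir = .fix)
}

fix_basis <- function() fixture("basis", spectral_basis)

fix_compositions <- function() fixture("compositions", tissue_compositions)

# layered slab: 20 mm blubber over 20 mm muscle over brain, optodes in a
# line on the top (y = 80) surface -> channels spanning 50-120 mm
fix_slab <- function() fixture("slab", function() {
  vol <- labeled_box(c(240, 80, 80), 4, label_fun = function(x, y, z)
    ifelse(y > 60, 3L, ifelse(y > 40, 4L, 1L)))
  mesh <- assign_properties(mesh_labeled_volume(vol), 850,
                            fix_basis(), fix_compositions())
  opt <- surface_optodes(mesh, cbind(seq(20, 220, by = 10), 80, 40))
  ch <- bin_channels(build_channels(opt, 50, 120))
  fwd0 <- solve_forward(assemble_system(mesh), opt, ch)
  list(vol = vol, mesh = mesh, opt = opt, ch = ch, fwd0 = fwd0)
})

fix_slab_active <- function() fixture("slab_active", function() {
  s <- fix_slab()
  mesh_a <- activate_region(s$mesh, "brain", 1.1, fix_basis(),
                            fix_compositions())
  solve_forward(assemble_system(mesh_a), s$opt, s$ch)
})

fix_slab_jacobian <- function() fixture("slab_J", function() {
  compute_jacobian(fix_slab()$fwd0)
})

# small dolphin-head phantom at 850 nm with sliced optode rings
fix_phantom <- function() fixture("phantom", function() {
  vol <- generate_phantom(phantom_config(), voxel_size = 10, seed = 1)
  mesh <- assign_properties(mesh_labeled_volume(vol), 850,
                            fix_basis(), fix_compositions())
  opt <- place_optodes(mesh, n_slices = 7, per_slice = 13, exclusion = 10)
  ch <- bin_channels(build_channels(opt, 50, 120))
  list(vol = vol, mesh = mesh, opt = opt, ch = ch)
})

fix_phantom_forward <- function() fixture("phantom_fwd", function() {
  p <- fix_phantom()
  solve_forward(assemble_system(p$mesh), p$opt, p$ch)
})

# homogeneous two-optode bench on a small box (fast Jacobian/TS checks)
fix_bench <- function() fixture("bench", function() {
  vol <- labeled_box(c(80, 60, 80), 4, label_fun = function(x, y, z)
    ifelse(y > 40, 3L, ifelse(y > 30, 4L, 1L)))
  mesh <- assign_properties(mesh_labeled_volume(vol), 850,
                            fix_basis(), fix_compositions())
  opt <- surface_optodes(mesh, rbind(c(20, 60, 40), c(68, 60, 40)))
  ch <- build_channels(opt, 10, 100)
  fwd <- solve_forward(assemble_system(mesh), opt, ch)
  list(mesh = mesh, opt = opt, ch = ch, fwd = fwd)
})

expect_rel_equal <- function(object, expected, tol) {
  expect_true(all(abs(object / expected - 1) <= tol),
              label = sprintf("max rel dev %.3g <= %.3g",
                              max(abs(object / expected - 1)), tol))
}
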