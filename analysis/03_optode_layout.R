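#!/usr/bin/env Rscript
# Stage 3: optode placement and channel construction.
#
# Places optode rings on equidistant body slices (alternating sources and
# detectors, 10 mm exclusion), builds all 50-120 mm source-detector channels
# for the adult and juvenile meshes, and bins them by separation.

suppressPackageStartupMessages(library(cetanirs))
dir.create("results", showWarnings = FALSE)

vol <- generate_phantom(phantom_config(), voxel_size = 6, seed = 1)
mesh_adult <- mesh_labeled_volume(vol)

for (model in c("adult", "juvenile")) {
  mesh <- if (model == "adult") mesh_adult else scale_mesh(mesh_adult, 0.75)
  opt <- place_optodes(mesh, n_slices = 11, per_slice = 21, exclusion = 10)
  ch <- bin_channels(build_channels(opt, 50, 120))
  message(sprintf(
    "%s: %d optodes (%d sources / %d detectors), %d channels in 50-120 mm",
    model, nrow(opt), sum(opt$role == "source"),
    sum(opt$role == "detector"), nrow(ch)))
  print(table(bin = ch$bin))
  write_layout_csv(opt, ch, file.path("results", paste0("03_layout_", model)))
}
message("wrote results/03_layout_{adult,juvenile}/{optodes,channels}.csv")
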