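#!/usr/bin/env Rscript
# Study geometry: the five-layer head slab, the high-density checkerboard
# optode array, the cumulative nearest-neighbor channel sets, and the
# evaluation region of interest. Writes the geometry tables other steps
# and readers refer to.

library(fdhddot)

outdir <- "results/geometry"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

cfg <- sweep_config()
ph <- build_layered_slab(cfg$phantom$layer_thicknesses,
                         cfg$phantom$lateral_extent,
                         cfg$phantom$depth_extent,
                         cfg$phantom$voxel_size)
print(ph)

arr <- place_checkerboard_array(cfg$array$pitch, cfg$array$n_rows,
                                cfg$array$n_cols, ph)
print(arr)
write_optodes_tsv(arr, file.path(outdir, "optodes.tsv"))

ch3 <- enumerate_channels(arr, 3)
ch4 <- enumerate_channels(arr, 4)
write_channels_tsv(ch4, file.path(outdir, "channels_nn4.tsv"))
cat("channel counts: NN3 =", nrow(ch3), ", NN4 =", nrow(ch4), "\n")
cat("mean separations per class (mm):\n")
print(round(tapply(ch4$sep_mm, ch4$nn, mean), 2))

message("computing summed baseline intensity for the ROI definition ...")
sens <- summed_baseline_intensity(ph, arr, cfg$wavelengths)
mask <- define_roi(ph, arr, cfg$roi$lateral_margin, cfg$roi$sensitivity_floor, sens)
roi <- roi_index(ph, mask)
cat("ROI:", roi$n, "voxels; depth range",
    min(roi$depth), "-", max(roi$depth), "mm",
    "(sensitivity floor", cfg$roi$sensitivity_floor, ")\n")

tissue_rows <- data.frame(
  tissue = ph$tissues,
  z_layers = as.vector(table(factor(ph$layer_labels, levels = 1:5))),
  roi_voxels = as.vector(table(factor(roi$label, levels = 1:5)))
)
write.csv(tissue_rows, file.path(outdir, "tissue_summary.csv"), row.names = FALSE)
write.csv(data.frame(n_roi = roi$n, max_depth_mm = max(roi$depth),
                     brain_voxels = sum(roi$brain)),
          file.path(outdir, "roi_summary.csv"), row.names = FALSE)

# volumes as NIfTI for visual inspection, when the reader is available
if (requireNamespace("RNifti", quietly = TRUE)) {
  h <- ph$h
  RNifti::writeNifti(RNifti::asNifti(ph$labels + 0, pixdim = c(h, h, h)),
                     file.path(outdir, "labels.nii"))
  RNifti::writeNifti(RNifti::asNifti(mask + 0, pixdim = c(h, h, h)),
                     file.path(outdir, "roi_mask.nii"))
}
cat("geometry tables written to", outdir, "\n")
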