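#' Run the full D-OCT viability pipeline on one cross-section
#'
#' Chains frame normalization, per-pixel Welch spectral mapping, spheroid
#' masking, viability splitting at the fmean threshold, edge-artifact
#' correction and pseudo-color rendering.
#'
#' @param stack A [doct_stack()].
#' @param params A [welch_params()].
#' @param colormap A [colormap_spec()].
#' @param threshold fmean segmentation threshold, Hz (default 10.5).
#' @param smooth,n_chunks Passed to [compute_dynamics_maps()].
#' @param edge_correction,rim_width,reassign Passed to
#'   [segment_cross_section()].
#' @return Object of class `doct_result`: list with `maps` (`doct_maps`),
#'   `segmentation` (`doct_segmentation`), `rgb` (masked pseudo-color array)
#'   and `viability`.
#' @export
doct_process <- function(stack, params = welch_params(),
                         colormap = colormap_spec(), threshold = 10.5,
                         smooth = TRUE, n_chunks = 1,
                         edge_correction = TRUE, rim_width = 5,
                         reassign = "viable") {
  maps <- compute_dynamics_maps(stack, params = params, smooth = smooth,
                                n_chunks = n_chunks)
  seg <- segment_cross_section(maps, threshold = threshold,
                               edge_correction = edge_correction,
                               rim_width = rim_width, reassign = reassign)
  rgb <- render_pseudocolor(maps, colormap, mask = seg$spheroid)
  structure(list(maps = maps, segmentation = seg, rgb = rgb,
                 viability = seg$viability),
            class = "doct_result")
}

#' @export
print.doct_result <- function(x, ...) {
  print(x$maps)
  print(x$segmentation)
  invisible(x)
}

#' Write the outputs of a processed cross-section to a directory
#'
#' Saves the three dynamics maps as 32-bit TIFFs with scale sidecars, the
#' masks as 8-bit PNGs, the pseudo-color composite as PNG, a labeled overlay
#' TIFF (0 background / 1 viable / 2 necrotic / 3 edge artifact), and a CSV
#' with per-map summaries, pixel counts and the viability fraction.
#'
#' @param result A `doct_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_result <- function(result, dir) {
  stopifnot(inherits(result, "doct_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_map(result$maps$fmean, file.path(dir, "fmean.tif"))
  write_map(result$maps$fstd, file.path(dir, "fstd.tif"))
  write_map(result$maps$std, file.path(dir, "std.tif"))
  seg <- result$segmentation
  write_mask(seg$spheroid, file.path(dir, "mask_spheroid.png"))
  write_mask(seg$viable, file.path(dir, "mask_viable.png"))
  write_mask(seg$necrotic, file.path(dir, "mask_necrotic.png"))
  write_mask(seg$edge_artifact, file.path(dir, "mask_edge_artifact.png"))
  write_rgb(result$rgb, file.path(dir, "pseudocolor.png"))
  lab <- segmentation_labels(seg)
  tiff::writeTIFF(lab / 3, file.path(dir, "labels.tif"),
                  bits.per.sample = 8L, compression = "none")
  summ <- data.frame(
    quantity = c("fmean_min", "fmean_mean", "fmean_max",
                 "fstd_min", "fstd_mean", "fstd_max",
                 "std_min", "std_mean", "std_max",
                 "n_spheroid", "n_viable", "n_necrotic", "n_edge_artifact",
                 "threshold_hz", "viability"),
    value = c(min(result$maps$fmean), mean(result$maps$fmean),
              max(result$maps$fmean),
              min(result$maps$fstd), mean(result$maps$fstd),
              max(result$maps$fstd),
              min(result$maps$std), mean(result$maps$std),
              max(result$maps$std),
              sum(seg$spheroid), sum(seg$viable), sum(seg$necrotic),
              sum(seg$edge_artifact), seg$threshold, seg$viability))
  write.csv(summ, file.path(dir, "summary.csv"), row.names = FALSE)
  invisible(dir)
}
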