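#' Average mean frequency over a mask
#'
#' Arithmetic mean of the fmean raster over the pixels of a (non-empty)
#' mask — the per-cross-section summary used for depth profiles and
#' longitudinal monitoring.
#'
#' @param fmean_map Mean-frequency raster, Hz.
#' @param mask Logical raster of the same shape.
#' @return Mean frequency in Hz.
#' @export
mean_fmean_over_mask <- function(fmean_map, mask) {
  stopifnot(all(dim(fmean_map) == dim(mask)))
  mask <- mask != 0
  if (!any(mask)) stop("empty mask")
  mean(fmean_map[mask])
}

#' Depth profile of class-wise mean frequency through a spheroid volume
#'
#' For a y-ordered sequence of cross-section maps and segmentations, computes
#' the average fmean per slice over the whole spheroid and over the viable
#' and necrotic classes separately. Depth is measured from the first slice
#' where the spheroid mask is non-empty, in steps of `meta$y_spacing`.
#' Classes with an empty mask on a slice contribute no row for that depth.
#'
#' @param volume_maps List of `doct_maps`, ordered along y.
#' @param volume_masks List of `doct_segmentation` of equal length.
#' @param meta An [acquisition_meta()] (supplies `y_spacing`).
#' @return Data frame of class `doct_depth_profile` with columns
#'   `depth_um`, `class` ("total", "viable", "necrotic"), `mean_fmean` (Hz)
#'   and `n_pixels`.
#' @export
depth_profile <- function(volume_maps, volume_masks, meta) {
  stopifnot(inherits(meta, "doct_meta"))
  if (length(volume_maps) != length(volume_masks))
    stop(sprintf("length mismatch: %d maps vs %d segmentations",
                 length(volume_maps), length(volume_masks)))
  nonempty <- vapply(volume_masks, function(s) sum(s$spheroid) > 0, logical(1))
  if (!any(nonempty)) stop("no slice contains a spheroid")
  first <- which(nonempty)[1]
  rows <- list()
  for (i in which(nonempty)) {
    depth <- (i - first) * meta$y_spacing
    mp <- volume_maps[[i]]; sg <- volume_masks[[i]]
    for (cls in c("total", "viable", "necrotic")) {
      msk <- switch(cls, total = sg$spheroid, viable = sg$viable,
                    necrotic = sg$necrotic)
      n <- sum(msk != 0)
      if (n == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        depth_um = depth, class = cls,
        mean_fmean = mean_fmean_over_mask(mp$fmean, msk),
        n_pixels = n, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("doct_depth_profile", class(out))
  out
}

#' Tidy longitudinal table of per-sample viability records
#'
#' Collects one record per (sample, day) — central-cross-section mean fmean
#' and viability — into a tidy time-series table sorted by sample then day.
#' Duplicate (sample, day) pairs are an error.
#'
#' @param records Data frame with columns `sample_id`, `day`,
#'   `mean_fmean_center`, `viability`, or a list of such single-row records.
#' @param csv Optional path; when given the table is also written as CSV.
#' @return Sorted data frame of class `doct_longitudinal`.
#' @export
longitudinal_table <- function(records, csv = NULL) {
  if (!is.data.frame(records))
    records <- do.call(rbind, lapply(records, as.data.frame))
  need <- c("sample_id", "day", "mean_fmean_center", "viability")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0)
    stop(sprintf("missing record fields: %s", paste(miss, collapse = ", ")))
  if (any(records$day < 0)) stop("day must be non-negative")
  key <- paste(records$sample_id, records$day)
  if (anyDuplicated(key))
    stop(sprintf("duplicate (sample, day) record: %s", key[duplicated(key)][1]))
  out <- records[order(records$sample_id, records$day), need]
  rownames(out) <- NULL
  if (!is.null(csv)) write.csv(out, csv, row.names = FALSE)
  class(out) <- c("doct_longitudinal", class(out))
  out
}

#' Mean and 95% confidence band across replicate depth profiles
#'
#' Combines depth profiles from replicate volumes into a per-depth,
#' per-class mean with a normal-approximation 95% band
#' (mean +/- 1.96 SE across replicates).
#'
#' @param profiles List of `doct_depth_profile` data frames.
#' @return Data frame with columns `depth_um`, `class`, `mean_fmean`,
#'   `lo95`, `hi95`, `n_replicates`.
#' @export
profile_confidence_band <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  all <- do.call(rbind, lapply(profiles, as.data.frame))
  agg <- split(all, list(all$depth_um, all$class), drop = TRUE)
  rows <- lapply(agg, function(g) {
    n <- nrow(g)
    m <- mean(g$mean_fmean)
    se <- if (n > 1) stats::sd(g$mean_fmean) / sqrt(n) else 0
    data.frame(depth_um = g$depth_um[1], class = g$class[1],
               mean_fmean = m, lo95 = m - 1.96 * se, hi95 = m + 1.96 * se,
               n_replicates = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$class, out$depth_um), ]
  rownames(out) <- NULL
  out
}
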