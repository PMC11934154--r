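#' 8-connected component labeling of a binary mask
#'
#' Labels connected regions of a binary raster using 8-connectivity (edge or
#' corner adjacency), the standard convention for blob masks.
#'
#' @param mask Logical or 0/1 matrix.
#' @return Integer matrix of the same shape; 0 = background, components
#'   numbered from 1 in decreasing size order.
#' @export
label_components <- function(mask) {
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  out <- matrix(0L, nr, nc)
  if (length(idx) == 0) return(out)
  vid <- integer(nr * nc)
  vid[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% nr) + 1L
  c_ <- ((idx - 1L) %/% nr) + 1L
  edges <- integer(0)
  # neighbors E, S, SE, NE relative to each pixel cover all 8-adjacencies
  for (d in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- r + d[1]; c2 <- c_ + d[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- (c2[ok] - 1L) * nr + r2[ok]
    has <- mask[j]
    from <- vid[idx[ok][has]]
    to <- vid[j[has]]
    if (length(from)) edges <- c(edges, rbind(from, to))
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  memb <- igraph::components(g)$membership
  # renumber components largest-first for a stable, size-ordered labeling
  sz <- sort(table(memb), decreasing = TRUE)
  relab <- integer(length(sz))
  relab[as.integer(names(sz))] <- seq_along(sz)
  out[idx] <- relab[memb]
  out
}

.fill_holes <- function(mask) {
  img <- EBImage::fillHull(EBImage::Image(mask * 1))
  EBImage::imageData(img) != 0
}

#' Segment the spheroid from a reference intensity image
#'
#' Thresholds the temporal-mean intensity (or STD) raster, keeps the largest
#' connected component above `min_area`, and optionally fills interior holes.
#' The result is the total-tissue mask against which viability is computed.
#'
#' @param reference_image 2D raster, typically the temporal mean intensity.
#' @param strategy "otsu" (automatic) or "absolute" (use `threshold`).
#' @param threshold Absolute intensity threshold when `strategy = "absolute"`.
#' @param fill_holes Fill enclosed holes in the mask? Default TRUE.
#' @param min_area Discard components smaller than this many pixels.
#' @return Logical matrix.
#' @export
spheroid_mask <- function(reference_image, strategy = c("otsu", "absolute"),
                          threshold = NULL, fill_holes = TRUE, min_area = 16) {
  strategy <- match.arg(strategy)
  stopifnot(is.matrix(reference_image))
  if (strategy == "otsu") {
    lo <- min(reference_image); hi <- max(reference_image)
    if (hi <= lo) stop("no spheroid found: constant reference image")
    scaled <- (reference_image - lo) / (hi - lo)
    thr01 <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
    bin <- scaled > thr01
  } else {
    if (is.null(threshold)) stop("absolute strategy requires `threshold`")
    bin <- reference_image > threshold
  }
  lab <- label_components(bin)
  if (max(lab) == 0) stop("no spheroid found")
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  if (length(keep) == 0) stop("no spheroid found: all components below min_area")
  mask <- lab == keep[which.max(sizes[keep])]  # largest surviving component
  if (fill_holes) mask <- .fill_holes(mask)
  mask
}

#' Midpoint segmentation threshold between viability classes
#'
#' Given the upper limit of the mean-frequency band of highly viable tissue
#' and the lower limit of the necrotic band, returns their arithmetic mean —
#' e.g. (9.5, 11.5) Hz gives the 10.5 Hz operating threshold.
#'
#' @param viable_upper Upper fmean limit of viable tissue, Hz.
#' @param necrotic_lower Lower fmean limit of necrotic tissue, Hz.
#' @return Threshold in Hz.
#' @export
segmentation_threshold <- function(viable_upper, necrotic_lower) {
  if (!(viable_upper < necrotic_lower))
    stop("viable_upper must be below necrotic_lower")
  (viable_upper + necrotic_lower) / 2
}

#' Split the spheroid into viable and necrotic masks by fmean
#'
#' Viable pixels have `fmean < threshold`, necrotic pixels
#' `fmean >= threshold` (ties go to necrotic); both are intersected with the
#' spheroid mask.
#'
#' @param fmean_map Mean-frequency raster, Hz.
#' @param spheroid Logical spheroid mask, same shape.
#' @param threshold Frequency threshold in Hz (default 10.5).
#' @return List with logical matrices `viable` and `necrotic`.
#' @export
split_by_viability <- function(fmean_map, spheroid, threshold = 10.5) {
  stopifnot(all(dim(fmean_map) == dim(spheroid)))
  spheroid <- spheroid != 0
  list(viable = spheroid & (fmean_map < threshold),
       necrotic = spheroid & (fmean_map >= threshold))
}

#' Reclassify the specular edge-ring artifact
#'
#' The refractive-index step at the spheroid/medium interface produces
#' spurious broadband (high-fmean) signal in a thin rim, which the fmean
#' threshold misclassifies as necrotic. This operation finds
#' necrotic-labeled 8-connected components that touch the spheroid boundary
#' and lie entirely within `rim_width` pixels (Euclidean distance) of it,
#' marks them as edge artifact, and removes them from the necrotic mask.
#' Interior necrotic components are untouched. Depending on `reassign`, the
#' rim pixels join the viable mask (the tissue there is in fact highly
#' viable) or are excluded from both classes.
#'
#' @param necrotic_mask Logical necrotic mask.
#' @param spheroid_mask Logical spheroid mask, same shape.
#' @param rim_width Rim depth in pixels (default 5).
#' @param reassign "viable" (default) or "exclude".
#' @param viable_mask Logical viable mask; required when
#'   `reassign = "viable"`.
#' @return List with logical matrices `necrotic`, `edge_artifact` and
#'   (updated) `viable` (NULL if no viable mask was supplied).
#' @export
remove_edge_artifact <- function(necrotic_mask, spheroid_mask, rim_width = 5,
                                 reassign = c("viable", "exclude"),
                                 viable_mask = NULL) {
  reassign <- match.arg(reassign)
  stopifnot(all(dim(necrotic_mask) == dim(spheroid_mask)))
  necrotic_mask <- necrotic_mask != 0
  spheroid_mask <- spheroid_mask != 0
  if (reassign == "viable" && is.null(viable_mask))
    stop("reassign = \"viable\" requires `viable_mask`")
  # distance of each interior pixel to the nearest background pixel:
  # boundary pixels have distance 1
  d <- EBImage::imageData(EBImage::distmap(EBImage::Image(spheroid_mask * 1)))
  lab <- label_components(necrotic_mask)
  edge <- matrix(FALSE, nrow(necrotic_mask), ncol(necrotic_mask))
  if (max(lab) > 0) {
    for (l in seq_len(max(lab))) {
      comp <- lab == l
      dc <- d[comp]
      if (any(dc <= 1) && all(dc <= rim_width)) edge <- edge | comp
    }
  }
  necrotic <- necrotic_mask & !edge
  viable <- viable_mask
  if (!is.null(viable)) {
    viable <- viable != 0
    if (reassign == "viable") viable <- viable | edge
  }
  list(necrotic = necrotic, edge_artifact = edge, viable = viable)
}

#' Viability of a segmented cross-section
#'
#' The fraction of spheroid pixels classified viable:
#' `|viable| / |spheroid|`.
#'
#' @param result A `doct_segmentation` object (see
#'   [segment_cross_section()]), or a list with logical `viable` and
#'   `spheroid` masks.
#' @return Fraction in `[0, 1]`.
#' @export
viability <- function(result) {
  sph <- result$spheroid
  via <- result$viable
  stopifnot(!is.null(sph), !is.null(via))
  n_sph <- sum(sph != 0)
  if (n_sph == 0) stop("empty spheroid mask")
  sum(via != 0) / n_sph
}

#' Full viability segmentation of one cross-section
#'
#' Convenience wrapper chaining [spheroid_mask()] on the temporal-mean
#' intensity, [split_by_viability()] at `threshold`, and (optionally)
#' [remove_edge_artifact()].
#'
#' @param maps A `doct_maps` object from [compute_dynamics_maps()].
#' @param reference_image Raster for the spheroid mask; defaults to the
#'   temporal-mean intensity if given, else the STD map is used.
#' @param threshold fmean threshold in Hz (default 10.5).
#' @param mask_strategy Passed to [spheroid_mask()].
#' @param mask_threshold Absolute threshold for `strategy = "absolute"`.
#' @param min_area Minimum component area for the spheroid mask.
#' @param edge_correction Apply [remove_edge_artifact()]? Default TRUE.
#' @param rim_width Rim depth in pixels for the edge correction.
#' @param reassign "viable" or "exclude" for edge-artifact pixels.
#' @return Object of class `doct_segmentation`: list with logical masks
#'   `spheroid`, `viable`, `necrotic`, `edge_artifact`, the `threshold`, and
#'   the `viability` fraction.
#' @export
segment_cross_section <- function(maps, reference_image = NULL,
                                  threshold = 10.5,
                                  mask_strategy = "otsu",
                                  mask_threshold = NULL, min_area = 16,
                                  edge_correction = TRUE, rim_width = 5,
                                  reassign = "viable") {
  stopifnot(inherits(maps, "doct_maps"))
  if (is.null(reference_image)) reference_image <- maps$std
  sph <- spheroid_mask(reference_image, strategy = mask_strategy,
                       threshold = mask_threshold, min_area = min_area)
  cls <- split_by_viability(maps$fmean, sph, threshold)
  edge <- matrix(FALSE, nrow(sph), ncol(sph))
  if (edge_correction) {
    fix <- remove_edge_artifact(cls$necrotic, sph, rim_width = rim_width,
                                reassign = reassign,
                                viable_mask = cls$viable)
    cls$necrotic <- fix$necrotic
    if (!is.null(fix$viable)) cls$viable <- fix$viable
    edge <- fix$edge_artifact
  }
  res <- structure(list(spheroid = sph, viable = cls$viable,
                        necrotic = cls$necrotic, edge_artifact = edge,
                        threshold = threshold, viability = NA_real_),
                   class = "doct_segmentation")
  res$viability <- viability(res)
  res
}

#' @export
print.doct_segmentation <- function(x, ...) {
  cat(sprintf("D-OCT segmentation (threshold %.2f Hz)\n", x$threshold))
  cat(sprintf("  spheroid %d px | viable %d px | necrotic %d px | edge %d px\n",
              sum(x$spheroid), sum(x$viable), sum(x$necrotic),
              sum(x$edge_artifact)))
  cat(sprintf("  viability = %.3f\n", x$viability))
  invisible(x)
}

#' Labeled overlay raster of a segmentation
#'
#' @param result A `doct_segmentation`.
#' @return Integer matrix: 0 background, 1 viable, 2 necrotic,
#'   3 edge artifact.
#' @export
segmentation_labels <- function(result) {
  lab <- matrix(0L, nrow(result$spheroid), ncol(result$spheroid))
  lab[result$viable] <- 1L
  lab[result$necrotic] <- 2L
  lab[result$edge_artifact] <- 3L
  lab
}
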