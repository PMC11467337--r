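#' Construct a refractive-index tomogram
#'
#' A tomogram is the unit of analysis: a 3D voxel grid of refractive-index
#' (RI) values together with its physical voxel spacing and the RI of the
#' surrounding medium. Axes are ordered (x, y, z) with z the optical axis.
#'
#' @param ri 3D numeric array of refractive-index values.
#' @param voxel_spacing Numeric length-3, voxel pitch in micrometres
#'   (lateral x, lateral y, axial z).
#' @param medium_ri RI of the immersion medium (default 1.337,
#'   phosphate-buffered saline).
#' @return An object of class `tomogram`.
#' @export
tomogram <- function(ri, voxel_spacing = c(0.156, 0.156, 0.312),
                     medium_ri = 1.337) {
  stopifnot(is.array(ri), length(dim(ri)) == 3)
  if (!all(is.finite(ri))) stop("tomogram contains non-finite RI values")
  if (any(dim(ri) <= 0)) stop("tomogram grid dimensions must be positive")
  voxel_spacing <- as.numeric(voxel_spacing)
  stopifnot(length(voxel_spacing) == 3, all(voxel_spacing > 0))
  structure(
    list(ri = ri, voxel_spacing = voxel_spacing, medium_ri = medium_ri),
    class = "tomogram"
  )
}

#' @export
print.tomogram <- function(x, ...) {
  d <- dim(x$ri)
  cat(sprintf(
    "<tomogram> %d x %d x %d voxels, spacing %.3f x %.3f x %.3f um, medium RI %.4f\n",
    d[1], d[2], d[3], x$voxel_spacing[1], x$voxel_spacing[2],
    x$voxel_spacing[3], x$medium_ri))
  cat(sprintf("  RI range [%.4f, %.4f]\n", min(x$ri), max(x$ri)))
  invisible(x)
}

#' @export
dim.tomogram <- function(x) dim(x$ri)

#' Construct a segmentation mask
#'
#' Voxel label map over background / cytoplasm / nucleoplasm / nucleolus /
#' lipid. The nucleus is the union of nucleoplasm and nucleolus.
#'
#' @param labels 3D integer array with values in 0:4
#'   (0 background, 1 cytoplasm, 2 nucleoplasm, 3 nucleolus, 4 lipid).
#' @param provenance `"ground_truth"` or `"rule_based"`.
#' @return An object of class `seg_mask`.
#' @export
seg_mask <- function(labels, provenance = c("ground_truth", "rule_based")) {
  provenance <- match.arg(provenance)
  stopifnot(is.array(labels), length(dim(labels)) == 3)
  if (!all(labels %in% 0:4)) stop("mask labels must be integers in 0:4")
  structure(
    list(labels = array(as.integer(labels), dim(labels)),
         provenance = provenance),
    class = "seg_mask"
  )
}

#' @export
print.seg_mask <- function(x, ...) {
  d <- dim(x$labels)
  counts <- tabulate(x$labels + 1L, nbins = 5L)
  cat(sprintf("<seg_mask> %d x %d x %d (%s)\n", d[1], d[2], d[3],
              x$provenance))
  cat(sprintf("  %s: %d voxels\n", names(LABELS), counts), sep = "")
  invisible(x)
}

# region voxel selector; nucleus = nucleoplasm | nucleolus, cell = all labels
region_mask <- function(mask, region) {
  lab <- mask$labels
  switch(region,
    cell        = lab != 0L,  # whole cell, lipid droplets included
    nucleus     = lab == 2L | lab == 3L,
    nucleoplasm = lab == 2L,
    nucleolus   = lab == 3L,
    cytoplasm   = lab == 1L,
    lipid       = lab == 4L,
    stop("unknown region: ", region)
  )
}

REGIONS <- c("cell", "nucleus", "nucleoplasm", "nucleolus", "cytoplasm")
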