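# redox: voxelwise mitochondrial redox ratio (NADH/FAD).

#' Voxelwise redox ratio NADH/FAD
#'
#' Computes `rr = nadh / fad` voxel by voxel. Voxels with `fad <= eps` are
#' flagged undefined (`NA`) and excluded from the mean; both channels should
#' be flat-field corrected first ([flat_field_correct()]). The tissue mask
#' defaults to voxels with signal in either channel. Higher ratios indicate
#' a more reduced mitochondrial state.
#'
#' @param nadh,fad [vmi_volume()] objects of identical shape.
#' @param tissue Optional [vmi_mask()]; the mean is taken over defined
#'   tissue voxels only.
#' @param eps Small positive FAD floor below which the ratio is undefined
#'   (default 1 intensity count).
#' @param fad_contaminated Set `TRUE` for FITC-injected lungs, where the FAD
#'   channel also collects FITC: the output is then labelled
#'   `"NADH/(FAD+FITC)"` since it is no longer a pure redox ratio.
#' @return An object of class `vmi_redox`: `rr` (3D array, `NA` where
#'   undefined), `tissue_mask`, `mean_rr`, `label`.
#' @export
redox_ratio <- function(nadh, fad, tissue = NULL, eps = 1,
                        fad_contaminated = FALSE) {
  stopifnot(inherits(nadh, "vmi_volume"), inherits(fad, "vmi_volume"))
  if (!identical(dim(nadh$voxels), dim(fad$voxels)))
    stop("NADH and FAD shapes differ", call. = FALSE)
  if (!is.numeric(eps) || eps <= 0) stop("eps must be > 0", call. = FALSE)
  d <- dim(nadh$voxels)
  if (is.null(tissue)) {
    tissue <- vmi_mask(nadh$voxels > 0 | fad$voxels > 0, nadh$spacing,
                       nadh$channel)
  } else {
    stopifnot(inherits(tissue, "vmi_mask"))
    if (!identical(dim(tissue$voxels), d))
      stop("tissue mask shape differs", call. = FALSE)
  }
  defined <- fad$voxels > eps
  rr <- array(NA_real_, d)
  rr[defined] <- nadh$voxels[defined] / fad$voxels[defined]
  sel <- defined & tissue$voxels
  mean_rr <- if (any(sel)) mean(rr[sel]) else NA_real_
  structure(list(rr = rr, tissue_mask = tissue, mean_rr = mean_rr,
                 label = if (fad_contaminated) "NADH/(FAD+FITC)"
                         else "NADH/FAD"),
            class = "vmi_redox")
}

#' @export
print.vmi_redox <- function(x, ...) {
  cat(sprintf("<vmi_redox> %s  mean RR over tissue = %.4f (%d defined voxels)\n",
              x$label, x$mean_rr,
              sum(!is.na(x$rr) & x$tissue_mask$voxels)))
  invisible(x)
}
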