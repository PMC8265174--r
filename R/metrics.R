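# metrics: Dice overlap and Murray's-law branching analysis.

#' Dice overlap coefficient between two masks
#'
#' `Dice = 2 |A intersect B| / (|A| + |B|)`. If both masks are empty the
#' coefficient is defined as 0 (with a warning), since the ratio is 0/0.
#'
#' @param a,b [vmi_mask()] objects of identical shape.
#' @return An object of class `vmi_dice`: list with `dice`, `size_a`,
#'   `size_b`, `intersection`.
#' @examples
#' m1 <- vmi_mask(array(c(TRUE, TRUE, FALSE, FALSE), c(1, 2, 2)), c(1, 1, 1))
#' m2 <- vmi_mask(array(c(TRUE, FALSE, TRUE, FALSE), c(1, 2, 2)), c(1, 1, 1))
#' dice(m1, m2)$dice  # 2*1/(2+2) = 0.5
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "vmi_mask"), inherits(b, "vmi_mask"))
  if (!identical(dim(a$voxels), dim(b$voxels)))
    stop("mask shapes differ", call. = FALSE)
  na <- sum(a$voxels)
  nb <- sum(b$voxels)
  ni <- sum(a$voxels & b$voxels)
  d <- if (na + nb > 0) {
    2 * ni / (na + nb)
  } else {
    warning("both masks are empty; Dice defined as 0", call. = FALSE)
    0
  }
  structure(list(dice = d, size_a = na, size_b = nb, intersection = ni),
            class = "vmi_dice")
}

#' @export
print.vmi_dice <- function(x, ...) {
  cat(sprintf("Dice = %.4f  (|A| = %d, |B| = %d, |A ∩ B| = %d)\n",
              x$dice, x$size_a, x$size_b, x$intersection))
  invisible(x)
}

#' Per-depth cubed-diameter sums for Murray's-law analysis
#'
#' For each depth `k` with depth `k + 1` present in the tree, sums the cubed
#' diameters of the depth-`k` branches (the parents) and of the
#' depth-`(k+1)` branches (the daughters). Terminal branches at depth `k`
#' have no daughters at depth `k + 1` yet still contribute to the parent
#' sum, biasing it upward; `exclude_terminal_parents = TRUE` omits them to
#' quantify that bias (the default `FALSE` mirrors the uncorrected
#' depth-based bookkeeping).
#'
#' @param tree A `vmi_tree` (from [build_tree()] or [generate_tree()]).
#' @param exclude_terminal_parents Omit branches with no children from the
#'   parent-side sums.
#' @return A data frame with columns `depth`, `parent_cubed_sum`,
#'   `daughter_cubed_sum` (um^3), ordered by depth.
#' @export
murray_depth_sums <- function(tree, exclude_terminal_parents = FALSE) {
  br <- branch_table(tree)
  depths <- sort(unique(br$depth))
  if (length(depths) < 2L)
    stop("Murray analysis needs a tree with at least 2 depths", call. = FALSE)
  ks <- depths[(depths + 1L) %in% depths]
  rows <- lapply(ks, function(k) {
    par <- br[br$depth == k, ]
    if (exclude_terminal_parents) par <- par[!par$is_terminal, ]
    dau <- br[br$depth == k + 1L, ]
    data.frame(depth = k,
               parent_cubed_sum = sum(par$mean_diameter_um^3),
               daughter_cubed_sum = sum(dau$mean_diameter_um^3))
  })
  do.call(rbind, rows)
}

#' Fit the Murray's-law identity
#'
#' Ordinary least-squares regression of the daughter cubed-diameter sums on
#' the parent cubed-diameter sums. A vasculature obeying Murray's law gives
#' a significantly linear relation close to the identity line (slope 1,
#' intercept 0).
#'
#' @param depth_rows Data frame from [murray_depth_sums()] (>= 2 rows).
#' @param exclude_terminal_parents Stored in the result for provenance.
#' @return An object of class `vmi_murray`: `depth_rows`, `slope`,
#'   `intercept` (um^3), `r_squared`, `exclude_terminal_parents`.
#' @export
murray_fit <- function(depth_rows, exclude_terminal_parents = FALSE) {
  if (!is.data.frame(depth_rows) || nrow(depth_rows) < 2L)
    stop("need at least 2 depth rows to fit", call. = FALSE)
  x <- depth_rows$parent_cubed_sum
  y <- depth_rows$daughter_cubed_sum
  if (stats::sd(x) <= 1e-9 * mean(abs(x)))
    stop("zero variance in parent sums; fit undefined. Note: an ideal ",
         "Murray tree whose terminals all sit at the deepest level ",
         "conserves the cubed-diameter sum at every depth, so all points ",
         "coincide; depth variation requires terminals at varying depths",
         call. = FALSE)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  ss_res <- sum((y - (intercept + slope * x))^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  r2 <- min(max(r2, 0), 1)
  structure(list(depth_rows = depth_rows, slope = slope,
                 intercept = intercept, r_squared = r2,
                 exclude_terminal_parents = isTRUE(exclude_terminal_parents)),
            class = "vmi_murray")
}

#' @export
print.vmi_murray <- function(x, ...) {
  cat(sprintf(
    "Murray's-law fit over %d depth pairs: slope = %.4f, intercept = %.4g um^3, r^2 = %.5f\n",
    nrow(x$depth_rows), x$slope, x$intercept, x$r_squared))
  cat("  (identity line slope 1, intercept 0 = perfect compliance)\n")
  invisible(x)
}

#' Vascular volume fraction
#'
#' Fraction of tissue occupied by segmented vessels: true-voxel count of
#' `mask` divided by the tissue voxel count (or the total grid if no tissue
#' mask is given). A simple vascular-density biomarker.
#'
#' @param mask A [vmi_mask()] of vessels.
#' @param tissue Optional [vmi_mask()] of the tissue envelope.
#' @return A fraction in `[0, 1]`.
#' @export
vascular_volume_fraction <- function(mask, tissue = NULL) {
  stopifnot(inherits(mask, "vmi_mask"))
  if (is.null(tissue)) return(mean(mask$voxels))
  stopifnot(inherits(tissue, "vmi_mask"))
  if (!identical(dim(mask$voxels), dim(tissue$voxels)))
    stop("mask shapes differ", call. = FALSE)
  nt <- sum(tissue$voxels)
  if (nt == 0) stop("empty tissue mask", call. = FALSE)
  sum(mask$voxels & tissue$voxels) / nt
}
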