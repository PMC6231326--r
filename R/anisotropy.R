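# Multiscale nematic-tensor anisotropy of fibrous textures.
#
# Orientation convention: angles are measured from the column (x) axis
# toward increasing row (y), modulo pi (nematic symmetry). The fiber
# direction at a pixel is the 90-degree rotation of the local intensity
# gradient, so for gradient (gx, gy):
#   cos 2theta = (gy^2 - gx^2) / (gx^2 + gy^2)
#   sin 2theta = -2 gx gy     / (gx^2 + gy^2)
# The mean nematic tensor of a region is [[c, s], [s, -c]]/2 with c, s
# the weighted means of cos 2theta, sin 2theta; its eigenvalue
# difference sqrt(c^2 + s^2) is the anisotropy (0 isotropic, 1 aligned).

#' Per-pixel fiber orientations from intensity gradients
#'
#' Computes, for every interior pixel, the local fiber orientation (the
#' 90-degree rotation of the central-difference intensity gradient) on
#' the doubled circle, together with a contribution weight. Border
#' pixels, zero-gradient pixels, and pixels outside `mask` carry weight
#' zero.
#'
#' @param image Numeric intensity matrix, at least 3x3.
#' @param mask Optional label/binary matrix of the same shape; pixels
#'   where `mask == 0` are excluded (weight 0).
#' @param weighting `"grad2"` (default) weights each orientation sample
#'   by its squared gradient magnitude, so strong edges dominate and
#'   near-flat pixels contribute negligibly; `"unit"` gives every
#'   nonzero-gradient pixel weight 1.
#' @return An object of class `mq_orientations`: list with matrices
#'   `cos2t`, `sin2t`, `weight` (all zero where weight is zero) and the
#'   image dimensions.
#' @examples
#' img <- 100 + 50 * sin(2 * pi * matrix(1:64, 64, 64) / 8) # horizontal stripes
#' o <- local_orientations(img)
#' all(o$cos2t[o$weight > 0] == 1) # fibers horizontal (theta = 0)
#' @export
local_orientations <- function(image, mask = NULL,
                               weighting = c("grad2", "unit")) {
  weighting <- match.arg(weighting)
  .check_image(image)
  h <- nrow(image); w <- ncol(image)
  if (h < 3 || w < 3) stop("image must be at least 3x3")
  if (!is.null(mask)) .check_mask(mask, image)

  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  gx[, 2:(w - 1)] <- (image[, 3:w] - image[, 1:(w - 2)]) / 2
  gy[2:(h - 1), ] <- (image[3:h, ] - image[1:(h - 2), ]) / 2
  g2 <- gx^2 + gy^2

  valid <- matrix(FALSE, h, w)
  valid[2:(h - 1), 2:(w - 1)] <- TRUE
  valid <- valid & (g2 > 0)
  if (!is.null(mask)) valid <- valid & (mask > 0)

  cos2t <- sin2t <- weight <- matrix(0, h, w)
  cos2t[valid] <- (gy[valid]^2 - gx[valid]^2) / g2[valid]
  sin2t[valid] <- (-2 * gx[valid] * gy[valid]) / g2[valid]
  weight[valid] <- if (weighting == "grad2") g2[valid] else 1

  structure(
    list(cos2t = cos2t, sin2t = sin2t, weight = weight,
         height = h, width = w, weighting = weighting),
    class = "mq_orientations"
  )
}

#' Mean nematic tensor of a rectangular patch
#'
#' @param samples An `mq_orientations` object from [local_orientations()].
#' @param rows,cols Integer index ranges delimiting the patch.
#' @return List of class `mq_nematic_tensor`: `c` and `s` (weighted means
#'   of cos 2theta and sin 2theta), `w_total` (total weight), and
#'   `n_pixels` (count of contributing pixels). A zero-weight patch has
#'   `c = s = 0`.
#' @export
patch_tensor <- function(samples, rows, cols) {
  stopifnot(inherits(samples, "mq_orientations"))
  if (length(rows) == 0 || length(cols) == 0) stop("empty patch region")
  if (min(rows) < 1 || max(rows) > samples$height ||
      min(cols) < 1 || max(cols) > samples$width) {
    stop("patch out of bounds")
  }
  w <- samples$weight[rows, cols, drop = FALSE]
  tw <- sum(w)
  n <- sum(w > 0)
  if (tw == 0) {
    tens <- list(c = 0, s = 0, w_total = 0, n_pixels = 0L)
  } else {
    tens <- list(
      c = sum(samples$cos2t[rows, cols] * w) / tw,
      s = sum(samples$sin2t[rows, cols] * w) / tw,
      w_total = tw, n_pixels = as.integer(n)
    )
  }
  structure(tens, class = "mq_nematic_tensor")
}

#' Anisotropy score of a nematic tensor
#'
#' The eigenvalue difference of the traceless tensor
#' `[[c, s], [s, -c]]/2`, which is `sqrt(c^2 + s^2)`: 0 for isotropic
#' orientation content, 1 for perfect alignment. Identical to the
#' circular resultant length of the weighted doubled angles.
#'
#' @param t An `mq_nematic_tensor` (or list with `c`, `s`, `w_total`).
#' @return Score in `[0, 1]`; 0 when `w_total` is 0.
#' @export
patch_anisotropy <- function(t) {
  if (is.null(t$w_total) || t$w_total == 0) return(0)
  min(sqrt(t$c^2 + t$s^2), 1)
}

#' Grid sizes for the multiscale patch decomposition
#'
#' Candidate grid sizes are the powers `{2^i} U {3^i}` for
#' `i = 0, 1, 2, ...` (so 1, 2, 3, 4, 8, 9, 16, 27, ...), deduplicated
#' and sorted; a size N is kept only while the floor-divided patch sides
#' `floor(height/N)` and `floor(width/N)` are both at least
#' `min_patch_px`. With `scale_set = "multiples"` the alternative
#' collection `{2i} U {3i}` for `i >= 1` is used instead.
#'
#' @param height,width Image dimensions in px.
#' @param min_patch_px Minimum patch side (default 10).
#' @param scale_set `"powers"` (default) or `"multiples"`.
#' @return List of class `mq_scale_plan` with `grid_sizes` and
#'   `min_patch_px`.
#' @examples
#' build_scale_plan(241, 261)$grid_sizes # 1 2 3 4 8 9 16
#' @export
build_scale_plan <- function(height, width, min_patch_px = 10,
                             scale_set = c("powers", "multiples")) {
  scale_set <- match.arg(scale_set)
  stopifnot(min_patch_px >= 2)
  if (height < min_patch_px || width < min_patch_px) {
    stop("image smaller than min_patch_px (", min_patch_px, ") in a dimension")
  }
  nmax <- min(height, width)
  cand <- if (scale_set == "powers") {
    sort(unique(c(2^(0:floor(log2(nmax))), 3^(0:floor(log(nmax, 3))))))
  } else {
    sort(unique(c(seq(2, nmax, by = 2), seq(3, nmax, by = 3))))
  }
  keep <- floor(height / cand) >= min_patch_px &
          floor(width / cand) >= min_patch_px
  grid_sizes <- cand[keep]
  if (scale_set == "powers") stopifnot(grid_sizes[1] == 1)
  structure(list(grid_sizes = grid_sizes, min_patch_px = min_patch_px),
            class = "mq_scale_plan")
}

# patch boundaries for an N-way split of extent len: equal floor(len/N)
# sides, with the last patch absorbing the remainder so patches tile the
# image exactly.
.patch_breaks <- function(len, n) {
  side <- floor(len / n)
  starts <- side * (0:(n - 1)) + 1
  ends <- c(side * (1:(n - 1)), len)
  cbind(starts, ends)
}

#' Multiscale nematic anisotropy of an image
#'
#' For each grid size N in the scale plan the image is split into N x N
#' non-overlapping patches (the last patch row/column absorbs any
#' remainder). Every patch with at least `min_valid_pixels` weighted
#' orientation samples is scored by its nematic-tensor anisotropy. Each
#' pixel's anisotropy value is the mean score of all processed patches
#' containing it across scales; the global score is the mean over all
#' pixels with at least one processed patch (and inside `mask`, if
#' given). Patches below `min_valid_pixels` are skipped, not
#' zero-scored, so flat background does not dilute the score.
#'
#' @inheritParams local_orientations
#' @param plan An `mq_scale_plan`; defaults to
#'   `build_scale_plan(nrow(image), ncol(image), min_patch_px)`.
#' @param min_valid_pixels Minimum weighted samples per scored patch
#'   (default 100).
#' @param min_patch_px Minimum patch side used when `plan` is NULL.
#' @return Object of class `mq_anisotropy`: `pixel_map` (matrix in
#'   `[0,1]`, NA outside evaluated pixels), `patch_scores` (data.frame
#'   with scale, row, col, score, n_valid_pixels), `global_score`, and
#'   `scales_used`.
#' @examples
#' img <- 100 + 50 * sin(2 * pi * matrix(1:128, 128, 128) / 8)
#' multiscale_anisotropy(img)$global_score # 1: perfectly parallel stripes
#' @export
multiscale_anisotropy <- function(image, mask = NULL, plan = NULL,
                                  min_valid_pixels = 100,
                                  min_patch_px = 10,
                                  weighting = c("grad2", "unit")) {
  weighting <- match.arg(weighting)
  .check_image(image)
  h <- nrow(image); w <- ncol(image)
  if (is.null(plan)) plan <- build_scale_plan(h, w, min_patch_px)
  stopifnot(inherits(plan, "mq_scale_plan"))

  o <- local_orientations(image, mask, weighting)
  ssum <- matrix(0, h, w)
  scnt <- matrix(0L, h, w)
  ps <- list()

  for (N in plan$grid_sizes) {
    rb <- .patch_breaks(h, N)
    cb <- .patch_breaks(w, N)
    for (i in seq_len(N)) {
      rr <- rb[i, 1]:rb[i, 2]
      for (j in seq_len(N)) {
        cc <- cb[j, 1]:cb[j, 2]
        wp <- o$weight[rr, cc]
        nv <- sum(wp > 0)
        if (nv < min_valid_pixels) next
        tw <- sum(wp)
        cm <- sum(o$cos2t[rr, cc] * wp) / tw
        sm <- sum(o$sin2t[rr, cc] * wp) / tw
        sc <- min(sqrt(cm^2 + sm^2), 1)
        ssum[rr, cc] <- ssum[rr, cc] + sc
        scnt[rr, cc] <- scnt[rr, cc] + 1L
        ps[[length(ps) + 1L]] <- c(N, i, j, sc, nv)
      }
    }
  }

  if (length(ps) == 0) stop("no quantifiable texture")
  evaluated <- scnt > 0
  if (!is.null(mask)) evaluated <- evaluated & (mask > 0)
  if (!any(evaluated)) stop("no quantifiable texture")

  pixel_map <- matrix(NA_real_, h, w)
  pixel_map[evaluated] <- ssum[evaluated] / scnt[evaluated]
  patch_scores <- as.data.frame(do.call(rbind, ps))
  names(patch_scores) <- c("scale", "row", "col", "score", "n_valid_pixels")

  vals <- pixel_map[evaluated]
  # mean of a constant vector is that constant (exact, no accumulation)
  global_score <- if (all(vals == vals[1])) vals[1] else mean(vals)

  structure(
    list(pixel_map = pixel_map,
         patch_scores = patch_scores,
         global_score = global_score,
         scales_used = sort(unique(patch_scores$scale))),
    class = "mq_anisotropy"
  )
}

#' Whole-image anisotropy (global nematic order parameter)
#'
#' Single-patch anisotropy of the entire image: the resultant length of
#' all weighted pixel orientations on the doubled circle. This is the
#' estimator of the global order parameter `|mean exp(2i theta)|` of the
#' underlying fiber angles; unlike the multiscale score it carries no
#' contribution from purely local (patch-level) order.
#'
#' @inheritParams local_orientations
#' @return Score in `[0, 1]`.
#' @export
whole_image_anisotropy <- function(image, mask = NULL,
                                   weighting = c("grad2", "unit")) {
  o <- local_orientations(image, mask, match.arg(weighting))
  patch_anisotropy(patch_tensor(o, seq_len(o$height), seq_len(o$width)))
}
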