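# Nuclear/cytosolic marker quantification: nucleus segmentation from the
# DNA (Hoechst) channel, QC filtering of mitotic/aberrant/border nuclei,
# perinuclear-ring cytosol ROI, per-cell ratio readouts, and categorical
# localization classes.

.as_ebi <- function(m) EBImage::Image(m)
.as_mat <- function(x) {
  m <- EBImage::imageData(x)
  dim(m) <- dim(m)[1:2]
  m
}

#' Segment nuclei from a DNA-stain channel
#'
#' Detection runs on a Gaussian-smoothed copy of the image: global Otsu
#' threshold, hole filling, and a watershed split on the distance
#' transform to separate touching nuclei. Each detected object is then
#' refined on the raw image by keeping pixels above half of the object's
#' median raw intensity; this restores the true boundary of bright
#' (e.g. mitotic) nuclei, which a single global threshold would
#' over-grow, and preserves object shape for the roundness QC. Objects
#' below `min_area` are dropped and labels are renumbered in raster
#' order of their centroids.
#'
#' @param hoechst Numeric intensity matrix (DNA channel); must not be
#'   constant.
#' @param min_area Minimum nuclear area in px^2 (default 100).
#' @param smoothing_sigma Gaussian sigma in px for detection (default 2).
#' @param refine If TRUE (default), apply the per-object half-median
#'   refinement on the raw image.
#' @return Integer label matrix (0 background). A field with no
#'   detectable nuclei returns an all-zero mask with a warning.
#' @export
segment_nuclei <- function(hoechst, min_area = 100, smoothing_sigma = 2,
                           refine = TRUE) {
  .check_image(hoechst, "hoechst")
  rng <- range(hoechst)
  if (rng[1] == rng[2]) stop("constant image: no threshold exists")
  h <- nrow(hoechst); w <- ncol(hoechst)

  sm <- .as_mat(EBImage::gblur(.as_ebi(hoechst / rng[2]), sigma = smoothing_sigma))
  thr <- EBImage::otsu(.as_ebi(sm), range = range(sm), levels = 256)
  bw <- sm > thr
  if (!any(bw)) {
    warning("no nuclei found")
    return(matrix(0L, h, w))
  }
  bw <- .as_mat(EBImage::fillHull(.as_ebi(bw))) > 0
  lab <- .as_mat(EBImage::watershed(EBImage::distmap(.as_ebi(bw)),
                                    tolerance = 1, ext = 1))
  storage.mode(lab) <- "integer"

  if (refine) {
    out <- matrix(0L, h, w)
    brush <- EBImage::makeBrush(2 * ceiling(smoothing_sigma) + 1, "disc")
    for (k in .labels_of(lab)) {
      inobj <- lab == k
      # search in a dilated zone (detection can clip thin/elongated
      # shapes near high-curvature borders) but never inside other
      # detected objects
      zone <- .as_mat(EBImage::dilate(.as_ebi(inobj * 1L), brush)) > 0
      zone <- zone & (inobj | lab == 0)
      cut <- 0.5 * median(hoechst[inobj])
      keep <- zone & (hoechst > cut)
      if (!any(keep)) next
      # largest connected component, holes refilled
      cc <- .as_mat(EBImage::bwlabel(.as_ebi(keep * 1L)))
      tab <- tabulate(cc[cc > 0])
      big <- which.max(tab)
      comp <- .as_mat(EBImage::fillHull(.as_ebi((cc == big) * 1L))) > 0
      out[comp] <- k
    }
    lab <- out
  }

  areas <- tabulate(lab[lab > 0])
  drop <- which(areas > 0 & areas < min_area)
  if (length(drop) > 0) lab[lab %in% drop] <- 0L

  .relabel_raster(lab)
}

# renumber labels 1..n in raster-scan order of object centroids
.relabel_raster <- function(lab) {
  labs <- .labels_of(lab)
  if (length(labs) == 0) {
    warning("no nuclei found")
    return(lab)
  }
  rows <- row(lab)[lab > 0]; cols <- col(lab)[lab > 0]; vals <- lab[lab > 0]
  cy <- tapply(rows, vals, mean); cx <- tapply(cols, vals, mean)
  ord <- order(round(cy), cx)
  newid <- integer(max(labs))
  newid[as.integer(names(cy))[ord]] <- seq_along(ord)
  out <- lab
  out[lab > 0] <- newid[lab[lab > 0]]
  out
}

# 8-connected contour chain length per object (unit + sqrt(2) steps)
.chain_perimeters <- function(lab) {
  oc <- EBImage::ocontour(.as_ebi(lab))
  p <- vapply(oc, function(pts) {
    if (nrow(pts) < 2) return(4)  # lone pixel: unit square boundary
    q <- rbind(pts, pts[1, , drop = FALSE])
    sum(sqrt(rowSums(diff(q)^2)))
  }, 0)
  setNames(p, names(oc))
}

#' QC-filter segmented nuclei
#'
#' Flags each nucleus that should be excluded from quantification:
#' `mitotic_intensity` (mean DNA-stain above `mitotic_factor` times the
#' population median), `aberrant_roundness` (4*pi*A/P^2 below
#' `min_roundness`, perimeter from the 8-connected border contour chain
#' length), `area_out_of_range`, and `border` (any pixel on the outermost
#' row or column).
#'
#' @param mask Integer label matrix from [segment_nuclei()].
#' @param hoechst DNA-channel intensity matrix, same shape.
#' @param cfg An [mq_config()] object (the `nc_quant` group is used).
#' @return data.frame with one row per nucleus: `label`, `area`,
#'   `perimeter`, `roundness`, `mean_hoechst`, `touches_border`,
#'   `qc_pass`, and `qc_reasons` (semicolon-joined flags, empty when
#'   passing).
#' @export
qc_filter <- function(mask, hoechst, cfg = mq_config()) {
  .check_mask(mask, hoechst)
  p <- cfg$nc_quant
  labs <- .labels_of(mask)
  if (length(labs) == 0) {
    return(data.frame(label = integer(), area = numeric(),
                      perimeter = numeric(), roundness = numeric(),
                      mean_hoechst = numeric(), touches_border = logical(),
                      qc_pass = logical(), qc_reasons = character()))
  }
  h <- nrow(mask); w <- ncol(mask)
  vals <- mask[mask > 0]
  area <- tabulate(vals)[labs]
  mh <- as.numeric(tapply(hoechst[mask > 0], vals, mean)[as.character(labs)])
  perim <- .chain_perimeters(mask)[as.character(labs)]
  roundness <- 4 * pi * area / perim^2
  edge <- c(mask[1, ], mask[h, ], mask[, 1], mask[, w])
  touches <- labs %in% edge[edge > 0]
  med <- median(mh)

  reasons <- vapply(seq_along(labs), function(i) {
    r <- character(0)
    if (mh[i] > p$mitotic_factor * med) r <- c(r, "mitotic_intensity")
    if (roundness[i] < p$min_roundness) r <- c(r, "aberrant_roundness")
    if (area[i] < p$min_area || area[i] > p$max_area) r <- c(r, "area_out_of_range")
    if (touches[i]) r <- c(r, "border")
    paste(r, collapse = ";")
  }, "")

  data.frame(label = labs, area = as.numeric(area),
             perimeter = as.numeric(perim), roundness = as.numeric(roundness),
             mean_hoechst = mh, touches_border = touches,
             qc_pass = reasons == "", qc_reasons = reasons,
             stringsAsFactors = FALSE)
}

#' Perinuclear cytosolic ring ROI
#'
#' For each nucleus, the ring is the set of background pixels within
#' `width_px` (Euclidean distance) of that nucleus, excluding all
#' nuclei; where the dilations of neighboring nuclei overlap, each pixel
#' is assigned to its nearest nucleus, so rings are disjoint by
#' construction.
#'
#' @param mask Integer nuclear label matrix.
#' @param width_px Ring width in px (default 4).
#' @return Integer label matrix of rings, labels matching the nuclei.
#' @export
perinuclear_ring <- function(mask, width_px = 4) {
  .check_mask(mask)
  if (width_px < 1) stop("width_px must be >= 1")
  if (length(.labels_of(mask)) == 0) return(matrix(0L, nrow(mask), ncol(mask)))
  bgdist <- .as_mat(EBImage::distmap(.as_ebi((mask == 0) * 1L)))
  # the growth zone must contain the seeds themselves; nuclei pixels are
  # cleared from the result afterwards
  zone <- (mask > 0) | (bgdist <= width_px)
  vor <- EBImage::propagate(.as_ebi(mask * 0), seeds = .as_ebi(mask),
                            mask = .as_ebi(zone * 1L))
  ring <- .as_mat(vor)
  storage.mode(ring) <- "integer"
  ring[mask > 0] <- 0L
  ring
}

#' Grow whole-cell regions from nuclear seeds
#'
#' Seeded Voronoi-style growth from the nuclei over a cell-area support
#' (Otsu threshold of the Gaussian-smoothed marker channel), capped at
#' `max_grow_px` from the nuclear border. Returns one whole-cell label
#' per nucleus for total-intensity measurements; regions of neighboring
#' cells partition the support without overlap.
#'
#' @param mask Integer nuclear label matrix.
#' @param marker Marker-channel intensity matrix, same shape.
#' @param max_grow_px Growth cap in px (default 40).
#' @param smoothing_sigma Gaussian sigma for the support threshold.
#' @return Integer label matrix of whole-cell regions (each contains its
#'   nucleus).
#' @export
grow_cell_region <- function(mask, marker, max_grow_px = 40,
                             smoothing_sigma = 2) {
  .check_image(marker, "marker")
  .check_mask(mask, marker)
  if (length(.labels_of(mask)) == 0) return(matrix(0L, nrow(mask), ncol(mask)))
  rng <- range(marker)
  support <- if (rng[1] == rng[2]) {
    matrix(FALSE, nrow(marker), ncol(marker))
  } else {
    sm <- .as_mat(EBImage::gblur(.as_ebi(marker / rng[2]), sigma = smoothing_sigma))
    sm > EBImage::otsu(.as_ebi(sm), range = range(sm), levels = 256)
  }
  bgdist <- .as_mat(EBImage::distmap(.as_ebi((mask == 0) * 1L)))
  zone <- (support | mask > 0) & (bgdist <= max_grow_px)
  cells <- EBImage::propagate(.as_ebi(mask * 0), seeds = .as_ebi(mask),
                              mask = .as_ebi(zone * 1L))
  cells <- .as_mat(cells)
  storage.mode(cells) <- "integer"
  cells[mask > 0] <- mask[mask > 0]
  cells
}

#' Classify nucleocytoplasmic distribution
#'
#' @param nc_ratio Positive nuclear-to-cytosolic ratio(s).
#' @param delta Class half-band (default 0.2): `"N"` (predominantly
#'   nuclear) if ratio > 1 + delta, `"C"` (predominantly cytosolic) if
#'   ratio < 1/(1 + delta), `"NC"` (even) otherwise.
#' @return Character vector of classes.
#' @export
classify_distribution <- function(nc_ratio, delta = 0.2) {
  stopifnot(delta > 0)
  if (any(!is.na(nc_ratio) & nc_ratio <= 0)) stop("nc_ratio must be positive")
  ifelse(is.na(nc_ratio), NA_character_,
         ifelse(nc_ratio > 1 + delta, "N",
                ifelse(nc_ratio < 1 / (1 + delta), "C", "NC")))
}

#' Per-cell marker measurements and localization classes
#'
#' Measures the marker channel over the nucleus, the perinuclear ring,
#' and the whole-cell region of every QC-passing nucleus. The primary
#' readout is `nc_ratio = nuclear_mean / ring_mean`; the complementary
#' fraction readout is `nuclear_to_total` (summed nuclear marker over
#' summed whole-cell marker). Cells whose ring mean is zero get an NA
#' ratio and class and are excluded from ratio summaries.
#'
#' @param marker Marker-channel intensity matrix.
#' @param nuclei,rings,cells Label matrices from [segment_nuclei()],
#'   [perinuclear_ring()], [grow_cell_region()].
#' @param records QC data.frame from [qc_filter()].
#' @param delta Localization class half-band (default 0.2).
#' @return data.frame with one row per QC-passing cell: `label`,
#'   `nuclear_mean`, `ring_mean`, `total_mean`, `nc_ratio`,
#'   `nuclear_to_total`, `loc_class`.
#' @export
measure_cells <- function(marker, nuclei, rings, cells, records,
                          delta = 0.2) {
  .check_image(marker, "marker")
  .check_mask(nuclei, marker, "nuclei")
  .check_mask(rings, marker, "rings")
  .check_mask(cells, marker, "cells")
  keep <- records$label[records$qc_pass]
  if (length(keep) == 0) {
    return(data.frame(label = integer(), nuclear_mean = numeric(),
                      ring_mean = numeric(), total_mean = numeric(),
                      nc_ratio = numeric(), nuclear_to_total = numeric(),
                      loc_class = character(), stringsAsFactors = FALSE))
  }
  if (!all(keep %in% .labels_of(rings))) {
    stop("label present in nuclei but absent in rings: internal inconsistency")
  }
  nuc_mean <- tapply(marker[nuclei > 0], nuclei[nuclei > 0], mean)
  nuc_sum <- tapply(marker[nuclei > 0], nuclei[nuclei > 0], sum)
  ring_mean <- tapply(marker[rings > 0], rings[rings > 0], mean)
  cell_mean <- tapply(marker[cells > 0], cells[cells > 0], mean)
  cell_sum <- tapply(marker[cells > 0], cells[cells > 0], sum)
  k <- as.character(keep)
  nm <- as.numeric(nuc_mean[k]); rm_ <- as.numeric(ring_mean[k])
  ratio <- ifelse(rm_ > 0, nm / rm_, NA_real_)
  data.frame(
    label = keep,
    nuclear_mean = nm,
    ring_mean = rm_,
    total_mean = as.numeric(cell_mean[k]),
    nc_ratio = ratio,
    nuclear_to_total = as.numeric(nuc_sum[k] / cell_sum[k]),
    loc_class = classify_distribution(ratio, delta),
    stringsAsFactors = FALSE
  )
}

#' Percentage of cells per localization class
#'
#' @param measurements data.frame from [measure_cells()] (or anything
#'   with a `loc_class` column).
#' @return Named numeric vector of percentages for N, C, and NC; sums to
#'   100.
#' @export
summarize_fractions <- function(measurements) {
  cls <- measurements$loc_class
  cls <- cls[!is.na(cls)]
  if (length(cls) == 0) stop("no classified cells")
  counts <- c(N = sum(cls == "N"), C = sum(cls == "C"), NC = sum(cls == "NC"))
  100 * counts / sum(counts)
}

#' Full nuclear/cytosolic quantification pipeline
#'
#' Convenience wrapper running segmentation, QC, ring and cell-region
#' construction, and per-cell measurement in one call.
#'
#' @param hoechst DNA-channel intensity matrix.
#' @param marker Marker-channel intensity matrix, same shape.
#' @param cfg An [mq_config()] object.
#' @param nuclei Optional externally supplied nuclear label matrix; when
#'   given, segmentation is skipped.
#' @return List with `nuclei`, `rings`, `cells` (label matrices),
#'   `records` (QC table), `cells_df` (per-cell measurements), and
#'   `fractions` (percentages per class, NULL when no cell classified).
#' @export
quantify_nc <- function(hoechst, marker, cfg = mq_config(), nuclei = NULL) {
  p <- cfg$nc_quant
  if (is.null(nuclei)) {
    nuclei <- segment_nuclei(hoechst, min_area = p$min_area,
                             smoothing_sigma = p$smoothing_sigma)
  } else {
    .check_mask(nuclei, hoechst, "nuclei")
  }
  records <- qc_filter(nuclei, hoechst, cfg)
  rings <- perinuclear_ring(nuclei, p$ring_width)
  cells <- grow_cell_region(nuclei, marker, p$max_grow_px, p$smoothing_sigma)
  cells_df <- measure_cells(marker, nuclei, rings, cells, records, p$delta)
  fr <- if (any(!is.na(cells_df$loc_class))) summarize_fractions(cells_df) else NULL
  list(nuclei = nuclei, rings = rings, cells = cells,
       records = records, cells_df = cells_df, fractions = fr)
}
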