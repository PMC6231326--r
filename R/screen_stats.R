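# Screen Z-scoring and hit calling, genotype specificity, exact Fisher
# enrichment, dual-luciferase normalization, and collagen gel
# contraction indices.

.check_screen_table <- function(table) {
  req <- c("plate", "well", "sirna", "genotype", "replicate", "is_control", "value")
  miss <- setdiff(req, names(table))
  if (length(miss) > 0) stop("screen table missing column(s): ", paste(miss, collapse = ", "))
  key <- paste(table$genotype, table$plate, table$well, table$replicate)
  if (anyDuplicated(key)) stop("duplicate (plate, well, replicate) rows in screen table")
  if (!all(is.finite(table$value))) stop("non-finite well values")
  invisible(table)
}

#' Z-score an siRNA screen against non-targeting control wells
#'
#' For every plate and replicate (and genotype, when several are
#' present), the control mean and sample standard deviation (n - 1) are
#' computed from the non-targeting control wells; each siRNA's
#' per-replicate value x is the mean of its wells on that plate and
#' replicate, and its Z-score is `(x - control mean) / control SD`. The
#' mean Z across replicates is the hit statistic: a hit requires
#' `|mean Z| > threshold` strictly.
#'
#' @param table data.frame with columns `plate`, `well`, `sirna`,
#'   `genotype`, `replicate`, `is_control` (logical), `value`.
#' @param threshold Absolute mean-Z hit threshold (default 2.5, strict).
#' @param pooled If TRUE, controls are pooled across plates within each
#'   replicate instead of per plate.
#' @return data.frame with one row per (sirna, genotype): `mean_z`,
#'   `n_replicates`, `is_hit`, `direction` (`"up"`, `"down"`, `"none"`).
#'   The per-replicate Z values are attached as attribute
#'   `"replicate_z"` (long data.frame).
#' @export
zscore_screen <- function(table, threshold = 2.5, pooled = FALSE) {
  .check_screen_table(table)
  table$plate_norm <- if (pooled) "pooled" else as.character(table$plate)

  ctrl <- table[table$is_control, ]
  if (nrow(ctrl) == 0) stop("no control wells in screen table")
  grp <- interaction(ctrl$genotype, ctrl$plate_norm, ctrl$replicate, drop = TRUE)
  if (any(tabulate(grp) < 2)) {
    stop("every plate x replicate needs >= 2 control wells")
  }
  cstat <- do.call(rbind, lapply(split(ctrl, grp), function(d) {
    data.frame(genotype = d$genotype[1], plate_norm = d$plate_norm[1],
               replicate = d$replicate[1],
               ctrl_mean = mean(d$value), ctrl_sd = sd(d$value))
  }))
  if (any(cstat$ctrl_sd == 0)) stop("degenerate plate: control SD is zero")

  samp <- table[!table$is_control, ]
  if (nrow(samp) == 0) stop("no siRNA wells in screen table")
  sgrp <- interaction(samp$genotype, samp$plate_norm, samp$replicate,
                      samp$sirna, drop = TRUE)
  xs <- do.call(rbind, lapply(split(samp, sgrp), function(d) {
    data.frame(sirna = d$sirna[1], genotype = d$genotype[1],
               plate_norm = d$plate_norm[1], replicate = d$replicate[1],
               x = mean(d$value))
  }))
  xs <- merge(xs, cstat, by = c("genotype", "plate_norm", "replicate"))
  xs$z <- (xs$x - xs$ctrl_mean) / xs$ctrl_sd

  res <- do.call(rbind, lapply(
    split(xs, interaction(xs$sirna, xs$genotype, drop = TRUE)),
    function(d) {
      mz <- mean(d$z)
      data.frame(sirna = d$sirna[1], genotype = d$genotype[1],
                 mean_z = mz, n_replicates = length(unique(d$replicate)),
                 is_hit = abs(mz) > threshold,
                 direction = if (abs(mz) > threshold) {
                   if (mz > 0) "up" else "down"
                 } else "none",
                 stringsAsFactors = FALSE)
    }))
  rownames(res) <- NULL
  attr(res, "replicate_z") <- xs[, c("sirna", "genotype", "plate_norm",
                                     "replicate", "z")]
  attr(res, "threshold") <- threshold
  res
}

#' Partition screen hits by genotype specificity
#'
#' A gene is genotype-specific when it is a hit in one genotype and not
#' in the other (optionally also requiring the other genotype's |mean Z|
#' to stay below `margin`); `shared` requires a hit in both genotypes
#' with the same direction.
#'
#' @param wt,ko data.frames from [zscore_screen()] for the two
#'   genotypes; must cover the same siRNA set.
#' @param threshold Absolute mean-Z hit threshold (strict).
#' @param margin Optional |Z| bound on the other genotype for a specific
#'   call (default `Inf`).
#' @return data.frame with `sirna`, `mean_z_wt`, `mean_z_ko`, and
#'   `specificity` in `{"WT-specific", "KO-specific", "shared", "none"}`.
#' @export
genotype_specific_hits <- function(wt, ko, threshold = 2.5, margin = Inf) {
  if (!setequal(wt$sirna, ko$sirna)) stop("mismatched siRNA sets between genotypes")
  m <- merge(wt[, c("sirna", "mean_z")], ko[, c("sirna", "mean_z")],
             by = "sirna", suffixes = c("_wt", "_ko"))
  hit_wt <- abs(m$mean_z_wt) > threshold
  hit_ko <- abs(m$mean_z_ko) > threshold
  spec <- rep("none", nrow(m))
  spec[hit_wt & !hit_ko & abs(m$mean_z_ko) < margin] <- "WT-specific"
  spec[hit_ko & !hit_wt & abs(m$mean_z_wt) < margin] <- "KO-specific"
  spec[hit_wt & hit_ko & sign(m$mean_z_wt) == sign(m$mean_z_ko)] <- "shared"
  m$specificity <- spec
  m
}

#' Exact Fisher enrichment of a 2x2 table
#'
#' Exact hypergeometric test computed from log-binomial coefficients.
#' The table counts are `a` (in-set and selected), `b` (in-set, not
#' selected), `c` (out-of-set, selected), `d` (neither). The `greater`
#' alternative (default, enrichment) is the probability of an overlap at
#' least `a` under fixed margins. The odds ratio is the sample odds
#' ratio `(a d)/(b c)`, NA when the denominator is zero.
#'
#' @param a,b,c,d Non-negative integer counts.
#' @param alternative `"greater"` (default), `"less"`, or `"two_sided"`.
#' @return List with `odds_ratio` and `p_value`.
#' @examples
#' fisher_enrichment(3, 1, 1, 3)$p_value # 17/70
#' @export
fisher_enrichment <- function(a, b, c, d,
                              alternative = c("greater", "less", "two_sided")) {
  alternative <- match.arg(alternative)
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-9)) {
    stop("counts must be non-negative integers")
  }
  if (sum(counts) < 1) stop("grand total must be >= 1")
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  xs <- lo:hi
  logp <- lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)
  p <- exp(logp)
  p_value <- switch(
    alternative,
    greater   = sum(p[xs >= a]),
    less      = sum(p[xs <= a]),
    two_sided = sum(p[p <= p[xs == a] * (1 + 1e-7)])
  )
  or <- if (b * c == 0) {
    if (a * d == 0) NA_real_ else Inf
  } else {
    (a * d) / (b * c)
  }
  list(odds_ratio = or, p_value = min(p_value, 1))
}

#' Normalize dual-luciferase activities
#'
#' Per-sample firefly/secreted-luciferase ratios, expressed as fold
#' change over the mean ratio of a reference condition (controls for
#' transfection efficiency differences between samples).
#'
#' @param firefly,metluc Numeric activity vectors, same length;
#'   `metluc` must be strictly positive.
#' @param condition Character/factor vector of condition labels.
#' @param reference_condition Condition whose mean ratio defines fold
#'   change 1.
#' @return Numeric vector of normalized activities.
#' @export
normalize_luciferase <- function(firefly, metluc, condition,
                                 reference_condition) {
  stopifnot(length(firefly) == length(metluc),
            length(condition) == length(firefly))
  if (any(metluc <= 0)) stop("metluc activities must be > 0")
  ref <- condition == reference_condition
  if (!any(ref)) stop("empty reference group: ", reference_condition)
  ratio <- firefly / metluc
  ratio / mean(ratio[ref])
}

#' Collagen gel contraction fold change
#'
#' Contraction index of a gel is its fractional area loss
#' `(A0 - A) / A0` relative to the initial (well) area A0; the readout
#' is the fold change of the condition's index over the control's.
#'
#' @param condition_mask,control_mask Binary/label matrices containing
#'   exactly one foreground gel object each.
#' @param well_mask Optional binary matrix defining the initial gel area
#'   A0; defaults to the full image frame.
#' @return List with `fold_change`, `index_condition`, `index_control`.
#' @export
gel_contraction <- function(condition_mask, control_mask, well_mask = NULL) {
  area_of <- function(mask, what) {
    .check_mask(mask, name = what)
    cc <- .as_mat(EBImage::bwlabel(.as_ebi((mask > 0) * 1L)))
    nobj <- max(cc)
    if (nobj == 0) stop(what, ": no gel object found")
    if (nobj > 1) stop(what, ": multiple (", nobj, ") gel objects found")
    sum(mask > 0)
  }
  a_cond <- area_of(condition_mask, "condition_mask")
  a_ctrl <- area_of(control_mask, "control_mask")
  a0 <- if (is.null(well_mask)) {
    length(condition_mask)
  } else {
    sum(well_mask > 0)
  }
  if (a_cond > a0 || a_ctrl > a0) stop("gel area exceeds initial area A0")
  idx_cond <- (a0 - a_cond) / a0
  idx_ctrl <- (a0 - a_ctrl) / a0
  if (idx_ctrl == 0) stop("control gel shows no contraction; fold change undefined")
  list(fold_change = idx_cond / idx_ctrl,
       index_condition = idx_cond, index_control = idx_ctrl)
}
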