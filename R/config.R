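#' Default analysis configuration
#'
#' Central registry of every tunable threshold in the package, grouped by
#' pipeline stage. Values can be overridden by passing nested lists;
#' unknown keys are rejected so typos cannot silently fall back to
#' defaults.
#'
#' @param anisotropy,nc_quant,screen Named lists of overrides for the
#'   corresponding parameter group (see Details).
#'
#' @details
#' `anisotropy`:
#' \describe{
#'   \item{min_patch_px}{Minimum side of a patch in pixels (default 10).}
#'   \item{min_valid_pixels}{Minimum number of weighted orientation
#'     samples for a patch to be scored (default 100, i.e. a full
#'     10x10 patch).}
#'   \item{weighting}{`"grad2"` (gradient-magnitude-squared weights,
#'     default) or `"unit"` (weight 1 per nonzero-gradient pixel).}
#'   \item{scale_set}{`"powers"` (grid sizes 2^i and 3^i, default) or
#'     `"multiples"` (2i and 3i, i >= 1).}
#' }
#' `nc_quant`:
#' \describe{
#'   \item{smoothing_sigma}{Gaussian sigma in px for nucleus detection
#'     (default 2).}
#'   \item{min_area,max_area}{Accepted nuclear area range in px^2
#'     (defaults 100, 2000).}
#'   \item{mitotic_factor}{A nucleus whose mean Hoechst exceeds
#'     `mitotic_factor` times the population median is flagged mitotic
#'     (default 2).}
#'   \item{min_roundness}{Nuclei with 4*pi*A/P^2 below this are flagged
#'     aberrant (default 0.65).}
#'   \item{ring_width}{Width in px of the perinuclear cytosolic ring
#'     (default 4).}
#'   \item{max_grow_px}{Cap in px on cytosol growth from the nucleus
#'     (default 40).}
#'   \item{delta}{Localization class half-band: N if ratio > 1 + delta,
#'     C if ratio < 1/(1 + delta), else NC (default 0.2).}
#' }
#' `screen`:
#' \describe{
#'   \item{threshold}{Absolute mean-Z hit threshold, strict inequality
#'     (default 2.5).}
#'   \item{pooled}{If TRUE, controls are pooled across plates within a
#'     replicate; default FALSE (per-plate normalization).}
#'   \item{specificity_margin}{Optional |Z| bound the other genotype must
#'     stay under for a genotype-specific call (default `Inf`, i.e.
#'     "not a hit" suffices).}
#' }
#'
#' @return A named list of parameter groups with class `mq_config`.
#' @examples
#' cfg <- mq_config(nc_quant = list(ring_width = 6))
#' cfg$nc_quant$ring_width
#' @export
mq_config <- function(anisotropy = list(), nc_quant = list(), screen = list()) {
  defaults <- list(
    anisotropy = list(
      min_patch_px     = 10,
      min_valid_pixels = 100,
      weighting        = "grad2",
      scale_set        = "powers"
    ),
    nc_quant = list(
      smoothing_sigma = 2,
      min_area        = 100,
      max_area        = 2000,
      mitotic_factor  = 2,
      min_roundness   = 0.65,
      ring_width      = 4,
      max_grow_px     = 40,
      delta           = 0.2
    ),
    screen = list(
      threshold          = 2.5,
      pooled             = FALSE,
      specificity_margin = Inf
    )
  )
  user <- list(anisotropy = anisotropy, nc_quant = nc_quant, screen = screen)
  cfg <- defaults
  for (grp in names(defaults)) {
    over <- user[[grp]]
    if (!is.list(over)) stop("config group '", grp, "' must be a list")
    bad <- setdiff(names(over), names(defaults[[grp]]))
    if (length(bad) > 0) {
      stop("unknown config key(s) in '", grp, "': ", paste(bad, collapse = ", "))
    }
    cfg[[grp]][names(over)] <- over
  }
  .validate_config(cfg)
  structure(cfg, class = "mq_config")
}

.validate_config <- function(cfg) {
  a <- cfg$anisotropy
  stopifnot(a$min_patch_px >= 2, a$min_valid_pixels >= 1)
  if (!a$weighting %in% c("grad2", "unit")) {
    stop("anisotropy$weighting must be 'grad2' or 'unit'")
  }
  if (!a$scale_set %in% c("powers", "multiples")) {
    stop("anisotropy$scale_set must be 'powers' or 'multiples'")
  }
  n <- cfg$nc_quant
  stopifnot(
    n$smoothing_sigma > 0, n$min_area >= 1, n$max_area > n$min_area,
    n$mitotic_factor > 1, n$min_roundness > 0, n$min_roundness <= 1.1,
    n$ring_width >= 1, n$max_grow_px >= 1, n$delta > 0
  )
  s <- cfg$screen
  stopifnot(s$threshold > 0, is.logical(s$pooled), s$specificity_margin > 0)
  invisible(cfg)
}
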