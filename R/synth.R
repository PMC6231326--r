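# Synthetic ground-truth generators for every pipeline stage: fibrous
# textures with a controlled orientation distribution, multicell fields
# with a planted nuclear:cytosolic marker ratio and QC categories, and
# screen plates with planted hit effects. Every generator is a pure
# function of its arguments including the seed.

#' Sample from the von Mises distribution
#'
#' Best-Fisher rejection sampler; `kappa = 0` reduces to the uniform
#' distribution on the circle.
#'
#' @param n Number of draws.
#' @param mu Mean direction in radians.
#' @param kappa Concentration, >= 0.
#' @return Numeric vector of angles in `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu, kappa) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (kappa < 1e-12) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- n - length(out)
    z <- cos(pi * runif(m))
    f <- (1 + r * z) / (r + z)
    cq <- kappa * (r - f)
    u2 <- runif(m)
    ok <- (cq * (2 - cq) - u2 > 0) | (log(cq / u2) + 1 - cq >= 0)
    th <- sign(runif(sum(ok)) - 0.5) * acos(pmin(pmax(f[ok], -1), 1))
    out <- c(out, mu + th)
  }
  out[seq_len(n)] %% (2 * pi)
}

#' Generate a synthetic fibrous texture with known orientation order
#'
#' Renders `n_fibers` straight line segments as Gaussian-profile ridges.
#' Fiber angles theta are drawn on the doubled circle,
#' `2 theta ~ von Mises(2 mu, kappa)`, matching the nematic symmetry of
#' the anisotropy score; `kappa = 0` gives isotropic fibers. The planted
#' ground truth is the empirical order parameter
#' `|mean_k exp(2i theta_k)|` of the sampled angles.
#'
#' Angles are measured from the column (x) axis toward increasing row,
#' the same convention as [local_orientations()]. Fiber centers are
#' uniform over the field; lengths are uniform between 25% and 75% of
#' the shorter image side. By default the background is dark
#' (noise-free), emulating a well-stained cytoskeletal channel; additive
#' Gaussian noise is available via `noise_sd`.
#'
#' @param height,width Image size in px (defaults 512).
#' @param n_fibers Number of fibers (default 300).
#' @param mu Mean orientation in radians, modulo pi (default pi/4).
#' @param kappa von Mises concentration on the doubled angle (default 2).
#' @param fiber_width Gaussian ridge sigma in px (default 2).
#' @param intensity Ridge peak intensity, a.u. (default 100).
#' @param noise_sd Additive Gaussian noise SD, a.u. (default 0); negative
#'   results are clipped at zero.
#' @param seed Integer seed; the generator is deterministic per seed.
#' @return List with `image` (matrix), `angles` (fiber angles in
#'   `[0, pi)`), and `truth` (empirical order parameter).
#' @export
generate_fibers <- function(height = 512, width = 512, n_fibers = 300,
                            mu = pi / 4, kappa = 2, fiber_width = 2,
                            intensity = 100, noise_sd = 0, seed = 1) {
  stopifnot(height >= 8, width >= 8, n_fibers >= 1, kappa >= 0,
            fiber_width > 0, intensity > 0, noise_sd >= 0)
  withr::with_seed(seed, {
    theta <- (rvonmises(n_fibers, 2 * mu, kappa) / 2) %% pi
    len <- runif(n_fibers, 0.25, 0.75) * min(height, width)
    cx <- runif(n_fibers, 1, width)
    cy <- runif(n_fibers, 1, height)
    img <- matrix(0, height, width)
    pad <- 3 * fiber_width
    for (k in seq_len(n_fibers)) {
      dx <- cos(theta[k]); dy <- sin(theta[k]); L <- len[k] / 2
      ys <- cy[k] + c(-dy, dy) * L
      xs <- cx[k] + c(-dx, dx) * L
      rlo <- max(1, floor(min(ys) - pad)); rhi <- min(height, ceiling(max(ys) + pad))
      clo <- max(1, floor(min(xs) - pad)); chi <- min(width, ceiling(max(xs) + pad))
      if (rlo > rhi || clo > chi) next
      rr <- rlo:rhi; cc <- clo:chi
      X <- matrix(cc, length(rr), length(cc), byrow = TRUE)
      Y <- matrix(rr, length(rr), length(cc))
      t <- pmin(pmax((X - cx[k]) * dx + (Y - cy[k]) * dy, -L), L)
      d2 <- (X - (cx[k] + t * dx))^2 + (Y - (cy[k] + t * dy))^2
      img[rr, cc] <- img[rr, cc] + intensity * exp(-d2 / (2 * fiber_width^2))
    }
    if (noise_sd > 0) {
      img <- pmax(img + rnorm(length(img), 0, noise_sd), 0)
    }
    list(image = img,
         angles = theta,
         truth = Mod(mean(exp(2i * theta))))
  })
}

#' Generate a synthetic multicell field with planted N:C ratio
#'
#' Places `n_cells` non-overlapping cells (nuclear disk of radius
#' `nucleus_radius` inside a cytoplasmic disk of radius
#' `cytoplasm_radius`) by rejection sampling. The DNA channel carries
#' nucleus-only signal; the marker channel carries `marker_base` in the
#' cytoplasm and `nc_ratio_true * marker_base` in the nucleus, both
#' under multiplicative lognormal noise with coefficient of variation
#' `noise_cv` (mean 1, so planted ratios are unbiased).
#'
#' QC categories are planted by fraction: `border` cells are centered
#' half a nuclear radius from an image edge (their nuclei are clipped by
#' the frame), `mitotic` nuclei carry 2.5x DNA-stain intensity, and
#' `aberrant` nuclei are 3:1 ellipses of equal area at a random
#' orientation. Remaining cells are `normal`.
#'
#' @param height,width Field size in px (defaults 800).
#' @param n_cells Number of cells (default 50).
#' @param nucleus_radius,cytoplasm_radius Disk radii in px (defaults 12
#'   and 24; cytoplasm must exceed nucleus).
#' @param nc_ratio_true Planted nuclear:cytosolic marker ratio
#'   (default 2).
#' @param marker_base Cytoplasmic marker intensity, a.u. (default 100).
#' @param noise_cv Lognormal noise CV (default 0.1).
#' @param frac_border,frac_mitotic,frac_aberrant Planted QC-category
#'   fractions; must sum to <= 1 (defaults 0).
#' @param hoechst_base Nuclear DNA-stain intensity, a.u. (default 100).
#' @param mitotic_factor Intensity multiplier for mitotic nuclei
#'   (default 2.5).
#' @param seed Integer seed.
#' @return List with `hoechst`, `marker` (matrices), and `truth`
#'   (data.frame: `cell`, `row`, `col`, `category`, `nc_ratio_true`).
#' @export
generate_cell_field <- function(height = 800, width = 800, n_cells = 50,
                                nucleus_radius = 12, cytoplasm_radius = 24,
                                nc_ratio_true = 2, marker_base = 100,
                                noise_cv = 0.1,
                                frac_border = 0, frac_mitotic = 0,
                                frac_aberrant = 0,
                                hoechst_base = 100, mitotic_factor = 2.5,
                                seed = 1) {
  stopifnot(cytoplasm_radius > nucleus_radius, n_cells >= 1,
            nc_ratio_true > 0, marker_base > 0, noise_cv >= 0,
            frac_border >= 0, frac_mitotic >= 0, frac_aberrant >= 0,
            frac_border + frac_mitotic + frac_aberrant <= 1)
  nb <- round(frac_border * n_cells)
  nm <- round(frac_mitotic * n_cells)
  na_ <- round(frac_aberrant * n_cells)
  category <- c(rep("border", nb), rep("mitotic", nm), rep("aberrant", na_),
                rep("normal", n_cells - nb - nm - na_))

  withr::with_seed(seed, {
    cr <- cytoplasm_radius; nr <- nucleus_radius
    cent <- matrix(NA_real_, n_cells, 2)
    attempts <- 0L
    for (k in seq_len(n_cells)) {
      repeat {
        attempts <- attempts + 1L
        if (attempts > 10000L) stop("packing failure: could not place ", n_cells, " cells")
        p <- if (category[k] == "border") {
          side <- sample(4, 1); d <- nr / 2
          switch(side,
                 c(d, runif(1, cr, width - cr)),
                 c(height - d, runif(1, cr, width - cr)),
                 c(runif(1, cr, height - cr), d),
                 c(runif(1, cr, height - cr), width - d))
        } else {
          c(runif(1, cr + 2, height - cr - 2), runif(1, cr + 2, width - cr - 2))
        }
        placed <- cent[seq_len(k - 1), , drop = FALSE]
        if (k == 1 ||
            min(sqrt((placed[, 1] - p[1])^2 + (placed[, 2] - p[2])^2)) > 2 * cr + 4) break
      }
      cent[k, ] <- p
    }

    R <- matrix(seq_len(height), height, width)
    C <- matrix(seq_len(width), height, width, byrow = TRUE)
    hoechst <- matrix(0, height, width)
    marker <- matrix(0, height, width)
    for (k in seq_len(n_cells)) {
      cy <- cent[k, 1]; cx <- cent[k, 2]
      d2 <- (R - cy)^2 + (C - cx)^2
      nuc <- if (category[k] == "aberrant") {
        ang <- runif(1, 0, pi)
        a <- nr * sqrt(3); b <- nr / sqrt(3)
        u <- (C - cx) * cos(ang) + (R - cy) * sin(ang)
        v <- -(C - cx) * sin(ang) + (R - cy) * cos(ang)
        (u / a)^2 + (v / b)^2 <= 1
      } else {
        d2 <= nr^2
      }
      cyt <- d2 <= cr^2 & !nuc
      hf <- if (category[k] == "mitotic") mitotic_factor else 1
      hoechst[nuc] <- hoechst_base * hf
      marker[nuc] <- nc_ratio_true * marker_base
      marker[cyt] <- marker_base
    }
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      noisify <- function(m) {
        i <- m > 0
        m[i] <- m[i] * rlnorm(sum(i), meanlog = -sdlog^2 / 2, sdlog = sdlog)
        m
      }
      hoechst <- noisify(hoechst)
      marker <- noisify(marker)
    }
    list(hoechst = hoechst, marker = marker,
         truth = data.frame(cell = seq_len(n_cells),
                            row = cent[, 1], col = cent[, 2],
                            category = category,
                            nc_ratio_true = nc_ratio_true,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate an siRNA screen plate layout with planted effects
#'
#' Control wells are drawn from `Normal(control_mean, control_sd)`;
#' wells of an siRNA with planted effect e are drawn from
#' `Normal(control_mean + e * control_sd, control_sd)`, independently
#' across replicates. Control wells are split between two non-targeting
#' control identities, as in arrayed screens run with two independent
#' non-targeting pools.
#'
#' @param n_sirnas Number of siRNAs (default 89).
#' @param n_control_wells Control wells per replicate (default 28: with
#'   89 siRNAs at 4 wells each occupying 356 wells of a 384-well plate,
#'   the 28 remaining wells carry the two non-targeting control pools;
#'   must be >= 2).
#' @param wells_per_sirna Wells per siRNA per replicate (default 4).
#' @param n_replicates Number of replicates (default 3).
#' @param control_mean,control_sd Control well distribution (defaults 1
#'   and 0.1).
#' @param planted_effects Named numeric vector mapping siRNA ids (see
#'   Details) to effects in control-SD units; unnamed siRNAs get 0.
#' @param genotype Genotype label stored in the table (default `"WT"`).
#' @param seed Integer seed.
#' @details siRNA ids are `"siRNA_001"` ... zero-padded; control ids are
#'   `"NTC_1"` and `"NTC_2"`.
#' @return data.frame in screen-table format (`plate`, `well`, `sirna`,
#'   `genotype`, `replicate`, `is_control`, `value`) with attribute
#'   `"planted_effects"`.
#' @export
simulate_screen <- function(n_sirnas = 89, n_control_wells = 28,
                            wells_per_sirna = 4, n_replicates = 3,
                            control_mean = 1, control_sd = 0.1,
                            planted_effects = NULL, genotype = "WT",
                            seed = 1) {
  stopifnot(n_sirnas >= 1, n_control_wells >= 2, wells_per_sirna >= 1,
            n_replicates >= 1, control_sd > 0)
  ids <- sprintf("siRNA_%03d", seq_len(n_sirnas))
  eff <- setNames(rep(0, n_sirnas), ids)
  if (!is.null(planted_effects)) {
    bad <- setdiff(names(planted_effects), ids)
    if (length(bad) > 0) stop("unknown siRNA id(s) in planted_effects: ",
                              paste(bad, collapse = ", "))
    eff[names(planted_effects)] <- planted_effects
  }
  ctrl_ids <- rep(c("NTC_1", "NTC_2"), length.out = n_control_wells)

  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_replicates), function(rep_i) {
      ctrl <- data.frame(
        plate = "P1",
        well = sprintf("C%02d", seq_len(n_control_wells)),
        sirna = ctrl_ids, genotype = genotype, replicate = rep_i,
        is_control = TRUE,
        value = rnorm(n_control_wells, control_mean, control_sd),
        stringsAsFactors = FALSE
      )
      samp <- data.frame(
        plate = "P1",
        well = sprintf("W%04d", seq_len(n_sirnas * wells_per_sirna)),
        sirna = rep(ids, each = wells_per_sirna),
        genotype = genotype, replicate = rep_i, is_control = FALSE,
        value = rnorm(n_sirnas * wells_per_sirna,
                      control_mean + rep(eff, each = wells_per_sirna) * control_sd,
                      control_sd),
        stringsAsFactors = FALSE
      )
      rbind(ctrl, samp)
    })
    out <- do.call(rbind, rows)
    attr(out, "planted_effects") <- eff
    out
  })
}
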