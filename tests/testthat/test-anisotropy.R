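test_that("orientation samples follow the rotated-gradient convention", {
  # horizontal stripes: gradient vertical, fibers horizontal (theta = 0)
  o <- local_orientations(stripe_image(64, axis = "row"))
  expect_true(all(o$cos2t[o$weight > 0] == 1))

  # constant image: no gradient anywhere
  o0 <- local_orientations(matrix(5, 32, 32))
  expect_true(all(o0$weight == 0))

  # 45-degree stripes: sin 2theta = -1 for theta = 3pi/4 (mod pi)
  r <- matrix(seq_len(64), 64, 64); cc <- t(r)
  o45 <- local_orientations(100 + 50 * sin(2 * pi * (r + cc) / 8))
  s <- o45$sin2t[o45$weight > 0]
  expect_true(all(abs(abs(s) - 1) < 1e-9))
  expect_lt(abs(mean(o45$cos2t[o45$weight > 0])), 1e-9)

  expect_error(local_orientations(matrix(1, 2, 5)), "3x3")
  expect_error(local_orientations(matrix(1, 8, 8), mask = matrix(1L, 4, 4)),
               "shape")
})

test_that("patch tensors cancel under symmetric orientation content", {
  mk_orient <- function(theta, w = rep(1, length(theta))) {
    n <- length(theta)
    structure(list(cos2t = matrix(cos(2 * theta), 1), sin2t = matrix(sin(2 * theta), 1),
                   weight = matrix(w, 1), height = 1L, width = n,
                   weighting = "unit"), class = "mq_orientations")
  }
  t1 <- patch_tensor(mk_orient(rep(0, 8)), 1, 1:8)
  expect_equal(c(t1$c, t1$s), c(1, 0))
  expect_equal(patch_anisotropy(t1), 1)

  t2 <- patch_tensor(mk_orient(rep(c(0, pi / 2), 4)), 1, 1:8)
  expect_equal(c(t2$c, t2$s), c(0, 0))

  t3 <- patch_tensor(mk_orient(c(0, pi / 4, pi / 2, 3 * pi / 4)), 1, 1:4)
  expect_equal(patch_anisotropy(t3), 0)

  t0 <- patch_tensor(mk_orient(rep(0, 4), w = rep(0, 4)), 1, 1:4)
  expect_equal(c(t0$c, t0$s, t0$w_total), c(0, 0, 0))
  expect_equal(patch_anisotropy(t0), 0)
  expect_error(patch_tensor(mk_orient(0), 1, integer(0)), "empty patch")
})

test_that("tensor anisotropy equals the circular resultant length", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(2:40, 1)
    theta <- runif(n, 0, pi)
    w <- runif(n)
    o <- structure(list(cos2t = matrix(cos(2 * theta), 1),
                        sin2t = matrix(sin(2 * theta), 1),
                        weight = matrix(w, 1), height = 1L, width = n,
                        weighting = "unit"), class = "mq_orientations")
    got <- patch_anisotropy(patch_tensor(o, 1, seq_len(n)))
    expect_equal(got, resultant_length(theta, w), tolerance = 1e-12)
  }
})

test_that("von Mises orientation sets recover the Bessel-ratio order parameter", {
  # E |mean exp(2i theta)| -> I1(kappa)/I0(kappa) for 2theta ~ vM(., kappa)
  set.seed(7)
  theta <- rvonmises(200000, 0, 2) / 2
  expected <- besselI(2, 1) / besselI(2, 0)  # 0.6978
  expect_equal(resultant_length(theta), expected, tolerance = 0.01)
  o <- structure(list(cos2t = matrix(cos(2 * theta), 1),
                      sin2t = matrix(sin(2 * theta), 1),
                      weight = matrix(1, 1, length(theta)),
                      height = 1L, width = length(theta),
                      weighting = "unit"), class = "mq_orientations")
  expect_equal(patch_anisotropy(patch_tensor(o, 1, seq_along(theta))),
               resultant_length(theta), tolerance = 1e-12)
})

test_that("scale plans apply the floor rule over powers of 2 and 3", {
  # exhaustive candidate enumeration oracle
  plan_oracle <- function(h, w, minp) {
    cand <- sort(unique(c(2^(0:20), 3^(0:15))))
    cand[vapply(cand, function(n) floor(h / n) >= minp && floor(w / n) >= minp, TRUE)]
  }
  for (dims in list(c(241, 261), c(512, 512), c(100, 37), c(10, 10))) {
    expect_identical(build_scale_plan(dims[1], dims[2])$grid_sizes,
                     plan_oracle(dims[1], dims[2], 10))
  }
  expect_identical(build_scale_plan(10, 10)$grid_sizes, 1)
  expect_error(build_scale_plan(9, 200), "smaller than min_patch_px")
  # the alternative multiples reading starts at N = 2
  expect_identical(build_scale_plan(100, 100, scale_set = "multiples")$grid_sizes[1:4],
                   c(2, 3, 4, 6))
})

test_that("multiscale score is exact for stationary textures and errors on flat ones", {
  img <- stripe_image(128, axis = "row")
  res <- multiscale_anisotropy(img)
  expect_gte(res$global_score, 0.95)
  expect_true(all(res$patch_scores$score >= 0 & res$patch_scores$score <= 1))
  expect_true(all(res$pixel_map[!is.na(res$pixel_map)] >= 0))
  # global score is the mean of the defined pixel map entries
  expect_equal(res$global_score, mean(res$pixel_map, na.rm = TRUE),
               tolerance = 1e-12)
  expect_error(multiscale_anisotropy(matrix(3, 64, 64)), "no quantifiable texture")
})

test_that("single-scale run equals the whole-image patch score exactly", {
  g <- generate_fibers(height = 128, width = 128, n_fibers = 40, kappa = 2,
                       seed = 11)
  plan1 <- structure(list(grid_sizes = 1, min_patch_px = 10),
                     class = "mq_scale_plan")
  ms <- multiscale_anisotropy(g$image, plan = plan1)
  expect_identical(ms$global_score, whole_image_anisotropy(g$image))
})

test_that("scores are invariant to intensity scaling and transposition", {
  g <- generate_fibers(height = 160, width = 160, n_fibers = 60, kappa = 1,
                       seed = 5)
  s1 <- multiscale_anisotropy(g$image)$global_score
  expect_lt(abs(multiscale_anisotropy(g$image * 10)$global_score - s1), 1e-9)
  expect_lt(abs(multiscale_anisotropy(t(g$image))$global_score - s1), 1e-9)
})

test_that("pixels outside the mask never influence patch tensors", {
  g <- generate_fibers(height = 96, width = 96, n_fibers = 30, kappa = 4,
                       seed = 9)
  plan1 <- structure(list(grid_sizes = 1, min_patch_px = 10),
                     class = "mq_scale_plan")
  mask <- matrix(0L, 96, 96); mask[21:69, 26:79] <- 1L
  r1 <- multiscale_anisotropy(g$image, mask = mask, plan = plan1)
  # poison everything strictly outside the mask's 1-px gradient halo:
  # the masked computation must be bit-identical
  halo <- matrix(0L, 96, 96); halo[20:70, 25:80] <- 1L
  img2 <- g$image
  set.seed(1)
  img2[halo == 0] <- 1e6 * runif(sum(halo == 0))
  r2 <- multiscale_anisotropy(img2, mask = mask, plan = plan1)
  expect_identical(r2$global_score, r1$global_score)
  # and the pixel map is only defined inside the mask
  expect_true(all(is.na(r1$pixel_map[mask == 0])))
})

test_that("degenerate masks raise the no-texture error", {
  g <- generate_fibers(height = 64, width = 64, n_fibers = 20, seed = 2)
  tiny <- matrix(0L, 64, 64); tiny[30:32, 30:32] <- 1L  # < 100 px
  expect_error(multiscale_anisotropy(g$image, mask = tiny),
               "no quantifiable texture")
})
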