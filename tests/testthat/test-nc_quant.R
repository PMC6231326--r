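test_that("a single bright disk segments to one nucleus of the right area", {
  img <- matrix(0, 120, 120)
  img[disk_mask(120, 60, 60, 15) > 0] <- 200
  img <- img + 1  # faint offset so the image is not binary
  lab <- segment_nuclei(img)
  expect_equal(length(unique(lab[lab > 0])), 1)
  expect_lt(abs(sum(lab > 0) - pi * 15^2) / (pi * 15^2), 0.10)

  two <- matrix(0, 120, 120)
  two[disk_mask(120, 40, 40, 12) > 0] <- 150
  two[disk_mask(120, 85, 85, 12) > 0] <- 150
  lab2 <- segment_nuclei(two + 1)
  expect_equal(length(unique(lab2[lab2 > 0])), 2)

  expect_error(segment_nuclei(matrix(0, 50, 50)), "constant image")
})

test_that("labels are renumbered in raster order of centroids", {
  img <- matrix(0, 100, 100)
  img[disk_mask(100, 80, 20, 10) > 0] <- 100   # lower-left
  img[disk_mask(100, 20, 80, 10) > 0] <- 100   # upper-right
  lab <- segment_nuclei(img + 1)
  cy <- tapply(row(lab)[lab > 0], lab[lab > 0], mean)
  expect_lt(cy[["1"]], cy[["2"]])
})

test_that("QC flags border, mitotic, and aberrant nuclei", {
  f <- generate_cell_field(n_cells = 30, frac_border = 0.2, frac_mitotic = 0.2,
                           frac_aberrant = 0.2, seed = 4)
  nuc <- segment_nuclei(f$hoechst)
  rec <- qc_filter(nuc, f$hoechst)
  expect_true(all(rec$qc_pass == (rec$qc_reasons == "")))
  expect_true(all(rec$roundness > 0 & rec$roundness <= 1.1))

  truth_cat <- f$truth$category[match_truth(nuc, f$truth)]
  expect_true(all(grepl("border", rec$qc_reasons[truth_cat == "border"])))
  expect_true(all(grepl("mitotic", rec$qc_reasons[truth_cat == "mitotic"])))
  # circular interior nuclei at median intensity pass
  expect_true(all(rec$qc_pass[truth_cat == "normal"]))

  expect_equal(nrow(qc_filter(matrix(0L, 10, 10), matrix(1, 10, 10))), 0)
})

test_that("perinuclear rings are disjoint annuli of the expected area", {
  mask <- disk_mask(100, 50, 50, 10)
  ring <- perinuclear_ring(mask, width_px = 4)
  expect_true(all(ring[mask > 0] == 0))        # never overlaps the nucleus
  a_expect <- pi * (14^2 - 10^2)
  expect_lt(abs(sum(ring > 0) - a_expect) / a_expect, 0.12)
  expect_error(perinuclear_ring(mask, width_px = 0), ">= 1")

  # two nearby nuclei: rings disjoint, split by nearest-nucleus distance
  m2 <- disk_mask(120, 60, 40, 10)
  m2[disk_mask(120, 60, 65, 10) > 0] <- 2L
  r2 <- perinuclear_ring(m2, 4)
  expect_true(all(r2[m2 > 0] == 0))
  expect_setequal(unique(r2[r2 > 0]), c(1L, 2L))
  # each ring pixel is nearer its own nucleus than the other
  d1 <- sqrt((row(m2) - 60)^2 + (col(m2) - 40)^2)
  d2 <- sqrt((row(m2) - 60)^2 + (col(m2) - 65)^2)
  expect_true(all(d1[r2 == 1] <= d2[r2 == 1] + 1.5))
  expect_true(all(d2[r2 == 2] <= d1[r2 == 2] + 1.5))
})

test_that("cell regions contain their nucleus and partition the support", {
  f <- generate_cell_field(n_cells = 12, height = 400, width = 400, seed = 3)
  nuc <- segment_nuclei(f$hoechst)
  cells <- grow_cell_region(nuc, f$marker)
  expect_true(all(cells[nuc > 0] == nuc[nuc > 0]))
  # no overlap is possible in a single label matrix; check every nucleus
  # got a region at least as large as itself
  an <- table(nuc[nuc > 0]); ac <- table(cells[cells > 0])
  expect_true(all(ac[names(an)] >= an))

  # marker zero outside nuclei: nothing to grow into
  mk0 <- matrix(0, 400, 400); mk0[nuc > 0] <- 50
  cells0 <- grow_cell_region(nuc, mk0)
  outside <- cells0 > 0 & nuc == 0
  expect_lt(sum(outside) / sum(nuc > 0), 0.25)
})

test_that("ratio arithmetic and localization classes follow the band rule", {
  expect_identical(classify_distribution(2.0), "N")
  expect_identical(classify_distribution(1.0), "NC")
  expect_identical(classify_distribution(0.5), "C")
  expect_identical(classify_distribution(c(1.2, 1 / 1.2)), c("NC", "NC"))
  expect_error(classify_distribution(-1), "positive")

  # hand-built geometry: nucleus at 200, ring at 100 -> ratio 2
  nuc <- disk_mask(80, 40, 40, 10)
  ring <- perinuclear_ring(nuc, 4)
  cells <- grow_cell_region(nuc, matrix(100, 80, 80) + nuc * 100)
  marker <- matrix(100, 80, 80); marker[nuc > 0] <- 200
  rec <- data.frame(label = 1L, qc_pass = TRUE)
  m <- measure_cells(marker, nuc, ring, cells, rec)
  expect_equal(m$nc_ratio, 2.0)
  expect_identical(m$loc_class, "N")

  # uniform marker: ratio 1, nuclear_to_total = area fraction
  mu <- matrix(100, 80, 80)
  cells_u <- nuc; cells_u[ring > 0] <- 1L
  m2 <- measure_cells(mu, nuc, ring, cells_u, rec)
  expect_equal(m2$nc_ratio, 1.0)
  expect_equal(m2$nuclear_to_total, sum(nuc > 0) / sum(cells_u > 0))
  expect_identical(m2$loc_class, "NC")

  # zero ring signal: undefined ratio, excluded from classes
  mz <- matrix(0, 80, 80); mz[nuc > 0] <- 50
  m3 <- measure_cells(mz, nuc, ring, cells_u, rec)
  expect_true(is.na(m3$nc_ratio))
  expect_true(is.na(m3$loc_class))
})

test_that("summarize_fractions sums to 100 and errors on empty input", {
  df <- data.frame(loc_class = c("N", "N", "C", "NC"))
  fr <- summarize_fractions(df)
  expect_equal(unname(fr), c(50, 25, 25))
  expect_equal(sum(fr), 100, tolerance = 1e-9)
  expect_equal(unname(summarize_fractions(data.frame(loc_class = rep("N", 3)))),
               c(100, 0, 0))
  expect_error(summarize_fractions(data.frame(loc_class = character())),
               "no classified cells")
})

test_that("planted N:C ratios are recovered end to end", {
  f <- generate_cell_field(n_cells = 20, height = 520, width = 520,
                           nc_ratio_true = 2, seed = 8)
  res <- quantify_nc(f$hoechst, f$marker)
  med <- median(res$cells_df$nc_ratio, na.rm = TRUE)
  expect_lt(abs(med - 2) / 2, 0.1)
  expect_true(all(res$cells_df$nuclear_to_total >= 0 &
                  res$cells_df$nuclear_to_total <= 1))
})
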