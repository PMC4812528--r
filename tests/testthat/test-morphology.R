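disk_image <- function(dim, centers, r) {
  img <- matrix(0, dim, dim)
  for (i in seq_len(nrow(centers)))
    img <- pathrisk:::paint_disk(img, centers[i, 1], centers[i, 2], r)
  img
}

test_that("cell-area segmentation recovers simple geometries", {
  # one disk covering ~25% of the field
  dimn <- 128
  r <- sqrt(0.25 * dimn^2 / pi)
  img <- disk_image(dimn, cbind(64, 64), r)
  seg <- segment_cell_area(img)
  expect_equal(seg$cell_area_fraction, 0.25, tolerance = 0.02)
  # blank and saturated images
  expect_equal(segment_cell_area(matrix(0, 32, 32))$cell_area_fraction, 0)
  expect_equal(segment_cell_area(matrix(7, 32, 32))$cell_area_fraction, 0)
})

test_that("nuclei counting separates touching disks and ignores specks", {
  set.seed(51)
  centers <- as.matrix(expand.grid(seq(20, 140, 40), seq(20, 140, 40)))[1:12, ]
  img <- disk_image(160, centers, 7)
  res <- count_nuclei(img)
  expect_equal(res$count, 12)
  expect_equal(nrow(res$centers), 12)

  # two disks overlapping by ~30% of the radius are split by watershed
  img2 <- disk_image(96, rbind(c(40, 48), c(40 + 1.7 * 8, 48)), 8)
  expect_equal(count_nuclei(img2)$count, 2)

  # blank field
  expect_equal(count_nuclei(matrix(0, 32, 32))$count, 0)
})

test_that("cell-size metric arithmetic and degenerate cases", {
  expect_equal(cell_size_metric(0.40, 10), 4.0)
  expect_equal(cell_size_metric(0.40, 5), 8.0)
  expect_equal(cell_size_metric(0, 7), 0)
  expect_warning(v <- cell_size_metric(0.4, 0), "no nuclei")
  expect_true(is.na(v))
  # linear in area fraction at fixed count
  expect_equal(cell_size_metric(0.2, 4), 2 * cell_size_metric(0.1, 4))
})

test_that("shortest inter-nucleus distances follow the pairwise enumeration", {
  centers <- rbind(c(0, 0), c(3, 4), c(6, 8))
  expect_equal(nearest_nucleus_distances(centers), c(5, 5, 10))
  expect_length(nearest_nucleus_distances(rbind(c(0, 0), c(1, 1))), 1)
  expect_warning(d <- nearest_nucleus_distances(rbind(c(0, 0))), "fewer than 2")
  expect_length(d, 0)
  expect_equal(nearest_nucleus_distances(rbind(c(2, 2), c(2, 2), c(9, 9)))[1],
               0)
})

test_that("stain fractions handle full, empty, and partial coverage", {
  mask <- disk_image(96, cbind(48, 48), 30)
  expect_equal(stain_fraction(mask, mask), 1.0)
  expect_equal(stain_fraction(matrix(0, 96, 96), mask), 0.0)
  expect_warning(v <- stain_fraction(mask, matrix(0, 96, 96)), "empty")
  expect_true(is.na(v))
  # stain on a known 30% subset of the cell region
  idx <- which(mask == 1)
  stain <- matrix(0, 96, 96)
  stain[idx[seq_len(round(0.3 * length(idx)))]] <- 1
  expect_equal(stain_fraction(stain, mask), 0.30, tolerance = 0.03)
})

test_that("group comparison matches the closed-form Welch t-test", {
  m <- data.frame(group = rep(c("a", "b"), each = 3),
                  metric = c(1, 2, 3, 4, 5, 6))
  res <- compare_groups(m, "metric")
  ref <- t.test(1:3, 4:6)
  expect_equal(res$p, ref$p.value)
  expect_equal(res$t, unname(ref$statistic))

  # identical groups -> high P; far-separated -> tiny P
  m2 <- data.frame(group = rep(c("a", "b"), each = 10),
                   metric = rep(seq(0, 1, length.out = 10), 2))
  expect_gt(compare_groups(m2, "metric")$p, 0.9)
  m3 <- data.frame(group = rep(c("a", "b"), each = 10),
                   metric = c(rnorm(10, 0, 0.5), rnorm(10, 10, 0.5)))
  expect_lt(compare_groups(m3, "metric")$p, 0.001)
})

test_that("full-field quantification is consistent on a synthetic field", {
  sim <- simulate_fluorescence_field(simulation_config(),
                                     "dispersed_large", seed = 52,
                                     noise_sd = 0)
  q <- quantify_field(sim$field)
  expect_equal(q$n_nuclei, sim$truth$n_nuclei)
  expect_lt(abs(q$cell_area_fraction - sim$truth$cell_area_fraction), 0.01)
  expect_equal(q$actin_fraction, sim$truth$actin_fraction, tolerance = 0.05)
})

test_that("fields round-trip through image files", {
  sim <- simulate_fluorescence_field(simulation_config(), "clustered_small",
                                     seed = 61, noise_sd = 0)
  d <- withr::local_tempdir()
  paths <- file.path(d, c("actin.png", "adhesion.png", "nuclei.png"))
  EBImage::writeImage(EBImage::Image(sim$field$actin), paths[1])
  EBImage::writeImage(EBImage::Image(sim$field$adhesion), paths[2])
  EBImage::writeImage(EBImage::Image(sim$field$nuclei), paths[3])
  f <- read_fluorescence_field(paths[1], paths[2], paths[3], group = "control")
  q1 <- quantify_field(f)
  q2 <- quantify_field(sim$field)
  expect_equal(q1$n_nuclei, q2$n_nuclei)
  expect_lt(abs(q1$cell_area_fraction - q2$cell_area_fraction), 0.005)
})
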