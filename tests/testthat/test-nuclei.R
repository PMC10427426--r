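# Stain deconvolution, nuclei segmentation stand-in, dedup and per-patch
# summaries.

test_that("background pixels unmix to zero optical density", {
  basis <- stain_basis(I0 = 255)
  px <- array(rep(255 - 1, 3), c(1, 1, 3))  # I0 - eps exactly
  od <- deconvolve(px, basis)
  expect_equal(od$h[1, 1], 0, tolerance = 1e-12)
  expect_equal(od$dab[1, 1], 0, tolerance = 1e-12)
})

test_that("forward mixing then unmixing recovers stain amounts", {
  basis <- stain_basis()
  h <- matrix(runif(64, 0, 1.2), 8)
  d <- matrix(runif(64, 0, 1.2), 8)
  px <- stain_mix(h, d, basis)
  od <- deconvolve(px, basis)
  expect_lt(max(abs(od$h - h)), 1e-6)
  expect_lt(max(abs(od$dab - d)), 1e-6)
})

test_that("pure DAB pixels clip hematoxylin to zero", {
  basis <- stain_basis()
  px <- stain_mix(matrix(0, 2, 2), matrix(0.8, 2, 2), basis)
  od <- deconvolve(px, basis)
  expect_lt(max(od$h), 1e-8)
  expect_true(all(od$dab > 0.7))
  expect_error(stain_basis(hematoxylin = c(1, 0, 0), dab = c(0.999, 0.04, 0)),
               "collinear-basis")
})

# draw discs of a given OD onto a blank map
planted_discs <- function(n_side, centers, radius, od_value, size = 200) {
  m <- matrix(0, size, size)
  for (i in seq_len(nrow(centers))) {
    ys <- pmax(1, floor(centers[i, 2] - radius)):
      pmin(size, ceiling(centers[i, 2] + radius))
    xs <- pmax(1, floor(centers[i, 1] - radius)):
      pmin(size, ceiling(centers[i, 1] + radius))
    disc <- outer(ys - centers[i, 2], rep(1, length(xs)))^2 +
      outer(rep(1, length(ys)), xs - centers[i, 1])^2 <= radius^2
    m[ys, xs][disc] <- od_value
  }
  m
}

test_that("planted non-touching discs are each segmented once", {
  centers <- as.matrix(expand.grid(x = seq(20, 180, by = 40),
                                   y = seq(20, 180, by = 40)))
  m <- planted_discs(5, centers, radius = 5, od_value = 0.9)
  nuc <- segment_nuclei(m + matrix(rnorm(length(m), 0, 0.01), nrow(m)))
  expect_equal(nrow(nuc), 25L)
  # centroids within 2 px of planted centres (0-based truth)
  d <- sapply(seq_len(nrow(nuc)), function(i)
    min(sqrt((centers[, 1] - 1 - nuc$centroid_x[i])^2 +
               (centers[, 2] - 1 - nuc$centroid_y[i])^2)))
  expect_lt(max(d), 2)
})

test_that("touching discs are split by the watershed", {
  centers <- rbind(c(60, 60), c(60 + 1.5 * 8, 60))  # 1.5 radii apart
  m <- planted_discs(2, centers, radius = 8, od_value = 0.9, size = 120)
  nuc <- segment_nuclei(m)
  expect_equal(nrow(nuc), 2L)
})

test_that("a blank map yields no nuclei", {
  expect_equal(nrow(segment_nuclei(matrix(0, 80, 80))), 0L)
})

test_that("dedup drops centroids strictly within 20 px", {
  two <- function(dist) data.frame(
    centroid_x = c(10, 10 + dist), centroid_y = c(10, 10),
    area = c(50, 40), perimeter = c(25, 22), circularity = c(0.9, 0.9),
    dab_tile_mean = c(0.1, 0.1))
  expect_equal(nrow(dedup_nuclei(two(19))), 1L)
  expect_equal(nrow(dedup_nuclei(two(20))), 2L)
  empty <- two(19)[0, ]
  expect_equal(nrow(dedup_nuclei(empty)), 0L)
})

test_that("dedup keeps the larger nucleus and is idempotent", {
  set.seed(31)
  nuc <- data.frame(centroid_x = runif(60, 0, 150),
                    centroid_y = runif(60, 0, 150),
                    area = sample(20:80, 60, TRUE),
                    perimeter = runif(60, 15, 35),
                    circularity = runif(60, 0.5, 1),
                    dab_tile_mean = runif(60))
  once <- dedup_nuclei(nuc)
  twice <- dedup_nuclei(once)
  expect_equal(twice, once)
  # the largest nucleus always survives
  expect_true(max(nuc$area) %in% once$area)
})

test_that("nuclei are assigned to patches by half-open footprint", {
  patches <- data.frame(patch_id = 1:4,
                        x0 = c(0, 64, 0, 64), y0 = c(0, 0, 64, 64))
  nuc <- data.frame(centroid_x = c(10, 64, 63.9, 70),
                    centroid_y = c(10, 10, 70, 64),
                    area = c(50, 60, 40, 30),
                    perimeter = rep(25, 4), circularity = rep(0.9, 4),
                    dab_tile_mean = c(0.2, 0.4, 0.1, 0.3))
  s <- summarize_patches(nuc, patches)
  expect_equal(s$nuclei_count, c(1L, 1L, 1L, 1L))
  # boundary x = 64 belongs to the patch with x0 = 64
  expect_equal(s$mean_dab_tile[2], 0.4)
  expect_equal(s$mean_area[1], 50)
})

test_that("every kept nucleus lands in exactly one patch", {
  set.seed(8)
  patches <- expand.grid(x0 = seq(0, 192, 64), y0 = seq(0, 192, 64))
  patches$patch_id <- seq_len(nrow(patches))
  nuc <- data.frame(centroid_x = runif(120, 0, 255.9),
                    centroid_y = runif(120, 0, 255.9),
                    area = sample(20:60, 120, TRUE),
                    perimeter = runif(120, 15, 30),
                    circularity = runif(120, 0.5, 1),
                    dab_tile_mean = runif(120))
  kept <- dedup_nuclei(nuc)
  s <- summarize_patches(kept, patches)
  expect_equal(sum(s$nuclei_count), nrow(kept))
  expect_true(all(is.na(s$mean_area[s$nuclei_count == 0])))
})

test_that("DAB tile intensity tracks the planted concentration", {
  centers <- as.matrix(expand.grid(x = seq(30, 170, by = 70),
                                   y = seq(30, 170, by = 70)))
  h <- planted_discs(3, centers, radius = 6, od_value = 0.9)
  lvls <- c(0.1, 0.4, 0.8)
  means <- vapply(lvls, function(lv) {
    dab <- matrix(lv, 200, 200)
    nuc <- segment_nuclei(h, od_dab = dab)
    mean(nuc$dab_tile_mean)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  expect_equal(means, lvls, tolerance = 1e-6)
})
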