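test_that("voxelwise labeling follows the tissue intervals and the mask", {
  hu <- matrix(55, 10, 10)
  expect_true(all(label_image(hu, matrix(1, 10, 10)) == "muscle"))
  expect_true(all(label_image(hu, matrix(0, 10, 10)) == "background"))
  expect_error(label_image(hu, matrix(1, 5, 5)), "shapes differ")
  # out-of-window voxels fall out of the labeling even inside the mask
  hu[1, 1] <- -1000
  lab <- label_image(hu, matrix(1, 10, 10))
  expect_equal(lab[1, 1], "background")
  # labels agree with classify_hu on a noisy phantom
  ph <- generate_phantom(phantom_spec(noise_sd = 8, blend_width = 0, seed = 2))
  lab2 <- label_image(ph$hu, ph$mask)
  sel <- lab2 != "background"
  expect_equal(lab2[sel], as.character(classify_hu(ph$hu[sel])))
})

test_that("phantom labels match the generating geometry away from the blend", {
  spec <- phantom_spec(size = 64, r_core = 18, r_outer = 28, blend_width = 2,
                       noise_sd = 3, seed = 4)
  ph <- generate_phantom(spec)
  lab <- label_image(ph$hu, ph$mask)
  n <- spec$size; ctr <- (n + 1) / 2
  dist <- sqrt(outer((1:n - ctr)^2, (1:n - ctr)^2, `+`))
  interior <- dist < spec$r_core - 3
  ring <- dist > spec$r_core + 3 & dist < spec$r_outer - 1
  expect_true(mean(lab[interior] == "muscle") > 0.99)
  expect_true(mean(lab[ring] == "fat") > 0.99)
})

test_that("a straight interface yields a 2x width boundary band", {
  hu <- make_interface_image(10, 10, left = 5)
  lab <- label_image(hu, matrix(1, 10, 10))
  bm <- boundary_mask(lab, width = 2)
  marked_cols <- which(apply(bm, 2, any))
  expect_equal(marked_cols, 4:7)
  expect_true(all(bm[, 4:7]))
  # all-muscle image has no boundary
  expect_false(any(boundary_mask(matrix("muscle", 8, 8), width = 2)))
  expect_error(boundary_mask(lab, width = 0), ">= 1")
})

test_that("boundary detection matches a brute-force pairwise oracle", {
  ph <- generate_phantom(phantom_spec(size = 64, blend_width = 0,
                                      noise_sd = 0, seed = 1))
  lab <- ph$labels
  for (width in c(1, 2)) {
    bm <- boundary_mask(lab, width = width)
    oracle <- matrix(FALSE, nrow(lab), ncol(lab))
    fat <- which(lab == "fat", arr.ind = TRUE)
    mus <- which(lab == "muscle", arr.ind = TRUE)
    cheb <- function(a, b)  # min Chebyshev distance from each row of a to set b
      apply(a, 1, function(p)
        min(pmax(abs(b[, 1] - p[1]), abs(b[, 2] - p[2]))))
    oracle[fat[cheb(fat, mus) <= width, , drop = FALSE]] <- TRUE
    oracle[mus[cheb(mus, fat) <= width, , drop = FALSE]] <- TRUE
    expect_identical(bm, oracle)
  }
})

test_that("connective and background pixels are never in the boundary", {
  ph <- generate_phantom(phantom_spec(blend_width = 3, noise_sd = 5, seed = 8))
  lab <- label_image(ph$hu, ph$mask)
  bm <- boundary_mask(lab, width = 2)
  expect_false(any(bm[lab == "connective"]))
  expect_false(any(bm[lab == "background"]))
})

test_that("boundary pixels move to the nearer tissue mean in HU space", {
  # 1x6 strip: two fat pixels, two muscle pixels, two boundary pixels
  hu <- matrix(c(-80, -80, -100, 30, 55, 55), 1, 6)
  lab <- matrix(c("fat", "fat", "fat", "muscle", "muscle", "muscle"), 1, 6)
  bnd <- matrix(c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE), 1, 6)
  res <- pve_correct(hu, lab, boundary = bnd)
  # fat mean -80, muscle mean 55: -100 -> fat bin, 30 -> muscle bin
  fat_bin <- trimodr:::hu_bin_index(-80)
  mus_bin <- trimodr:::hu_bin_index(55)
  expect_equal(res$histogram$counts[fat_bin], 3)
  expect_equal(res$histogram$counts[mus_bin], 3)
  expect_equal(res$histogram$counts[trimodr:::hu_bin_index(-100)], 0)
  expect_equal(res$histogram$counts[trimodr:::hu_bin_index(30)], 0)
  expect_equal(res$report$n_to_fat, 1)
  expect_equal(res$report$n_to_muscle, 1)
  expect_equal(res$report$fat_mean_hu, -80)
  expect_equal(res$report$muscle_mean_hu, 55)
})

test_that("an empty boundary leaves the histogram unchanged", {
  ph <- generate_phantom(phantom_spec(blend_width = 0, noise_sd = 4, seed = 3))
  res <- pve_correct(ph$hu, ph$labels,
                     boundary = matrix(FALSE, nrow(ph$hu), ncol(ph$hu)))
  expect_equal(res$histogram$counts, res$uncorrected$counts)
  expect_equal(res$report$n_moved, 0)
})

test_that("correction conserves counts and replays per-pixel on a blended phantom", {
  ph <- generate_phantom(phantom_spec(size = 64, blend_width = 2,
                                      noise_sd = 3, seed = 12))
  res <- pve_correct(ph$hu, ph$labels, width = 2)
  expect_equal(sum(res$histogram$counts), sum(res$uncorrected$counts))
  expect_gt(res$report$n_moved, 0)

  # per-pixel replay oracle
  bnd <- boundary_mask(ph$labels, 2)
  fm <- mean(ph$hu[ph$labels == "fat" & !bnd])
  mm <- mean(ph$hu[ph$labels == "muscle" & !bnd])
  replay <- ph$hu[ph$labels != "background"]
  replay <- replay[replay >= -200 & replay <= 200]
  counts <- build_histogram(replay)$counts
  for (v in ph$hu[bnd]) {
    if (v < -200 || v > 200) next
    counts[trimodr:::hu_bin_index(v)] <- counts[trimodr:::hu_bin_index(v)] - 1
    dest <- if (abs(v - fm) <= abs(v - mm)) fm else mm
    counts[trimodr:::hu_bin_index(dest)] <- counts[trimodr:::hu_bin_index(dest)] + 1
  }
  expect_equal(res$histogram$counts, counts)

  # the connective-interval counts drop: blended pixels leave the center
  tissue <- bin_tissue()
  expect_lt(sum(res$histogram$counts[tissue == "connective"]),
            sum(res$uncorrected$counts[tissue == "connective"]))
})

test_that("correction fails cleanly when a tissue mean is undefined", {
  hu <- matrix(c(-80, -80, 55, 55), 1, 4)
  lab <- matrix(c("fat", "fat", "muscle", "muscle"), 1, 4)
  bnd <- matrix(c(TRUE, TRUE, FALSE, FALSE), 1, 4)  # no fat outside boundary
  expect_error(pve_correct(hu, lab, boundary = bnd), "undefined")
})
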