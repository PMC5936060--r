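# Grayscale conversion, inversion, rasterization and embryo scoring.

test_that("grayscale conversion is the unweighted channel mean, rounded half-to-even", {
  px <- array(c(10, 20, 30), dim = c(1, 1, 3))
  expect_identical(to_grayscale_8bit(px)[1, 1], 20L)
  expect_identical(to_grayscale_8bit(array(255, c(1, 1, 3)))[1, 1], 255L)
  set.seed(5)
  img <- array(sample(0:255, 16 * 16 * 3, replace = TRUE), c(16, 16, 3))
  g <- to_grayscale_8bit(img)
  # brute-force per-pixel loop oracle
  for (i in 1:16) for (j in 1:16)
    expect_identical(g[i, j], as.integer(round(mean(img[i, j, ]))))
  expect_error(to_grayscale_8bit(matrix(numeric(0), 0, 0)), "empty")
})

test_that("inversion is the involution v -> 255 - v", {
  img <- matrix(c(0L, 128L, 255L, 7L), 2, 2)
  expect_identical(invert(img), 255L - img)
  expect_identical(invert(invert(img)), img)
  expect_true(all(invert(matrix(128L, 3, 3)) == 127L))
})

test_that("inversion commutes with grayscale conversion up to 1 intensity unit", {
  set.seed(6)
  img <- array(sample(0:255, 12 * 12 * 3, replace = TRUE), c(12, 12, 3))
  a <- invert(to_grayscale_8bit(img))
  b <- to_grayscale_8bit(255 - img)
  expect_true(all(abs(a - b) <= 1L))
})

test_that("rasterization matches the even-odd per-pixel oracle", {
  rect <- rbind(c(0, 0), c(5, 0), c(5, 4), c(0, 4))
  expect_identical(sum(rasterize(rect, 10, 10)), 20L)
  tri <- rbind(c(0, 0), c(10, 0), c(0, 10))
  m <- rasterize(tri, 12, 12)
  n_oracle <- sum(vapply(0:11, function(y) sum(vapply(0:11, function(x)
    oracle_point_in_polygon(x + 0.5, y + 0.5, tri), logical(1))), integer(1)))
  expect_identical(sum(m), n_oracle)
  expect_error(rasterize(rbind(c(50, 50), c(60, 50), c(55, 60)), 10, 10),
               "degenerate")
})

test_that("ROI means equal the masked-pixel loop oracle exactly", {
  set.seed(8)
  for (i in 1:10) {
    img <- random_gray_image(24, 24)
    v <- random_polygon(24, 24)
    expect_identical(mean_intensity(img, v), oracle_mean_intensity(img, v))
  }
  # uniform image: any ROI gives the constant
  expect_identical(mean_intensity(matrix(50L, 20, 20), random_polygon(20, 20)),
                   50)
})

test_that("embryo scoring subtracts background and flags negatives", {
  img <- matrix(26L, 40, 40)
  img[25:34, 6:35] <- 80L                      # "stained" band
  sig <- rbind(c(10, 26), c(30, 26), c(30, 32), c(10, 32))
  bg <- translate_roi(sig, 0, -20)
  m <- score_embryo(img, sig, bg, "e1")
  expect_equal(m$signal_mean, 80)
  expect_equal(m$background_mean, 26)
  expect_equal(m$score, 54)
  expect_false(m$negative_flag)
  # swapped ROIs: negative score, flagged, retained
  m2 <- score_embryo(img, bg, sig, "e1")
  expect_equal(m2$score, -54)
  expect_true(m2$negative_flag)
  # identical regions score zero
  m3 <- score_embryo(img, sig, sig, "e1")
  expect_equal(m3$score, 0)
  # unequal areas rejected
  big <- rbind(c(5, 5), c(35, 5), c(35, 20), c(5, 20))
  expect_error(score_embryo(img, sig, big), "unequal")
})

test_that("scores cancel uniform shifts and flip sign under inversion", {
  set.seed(9)
  img <- matrix(sample(60:180, 50 * 50, replace = TRUE), 50, 50)
  sig <- rbind(c(5, 5), c(20, 5), c(20, 15), c(5, 15))
  bg <- translate_roi(sig, 22, 25)
  s0 <- score_embryo(img, sig, bg)$score
  expect_equal(score_embryo(img + 30L, sig, bg)$score, s0)  # shift cancels
  expect_equal(score_embryo(invert(img), sig, bg)$score, -s0)  # antisymmetry
  # monotonicity: brightening pixels strictly inside the signal ROI
  img2 <- img
  mask <- rasterize(sig, 50, 50)
  img2[mask] <- pmin(img2[mask] + 10L, 255L)
  expect_gt(score_embryo(img2, sig, bg)$score, s0)
})

test_that("batch conversion inverts and grayscales every image, skipping non-images", {
  tmp <- withr::local_tempdir()
  ind <- file.path(tmp, "in"); outd <- file.path(tmp, "out")
  dir.create(ind)
  set.seed(10)
  imgs <- list()
  for (i in 1:2) {
    imgs[[i]] <- array(sample(0:255, 8 * 8 * 3, replace = TRUE), c(8, 8, 3))
    write_image(imgs[[i]], file.path(ind, sprintf("e%d.png", i)))
  }
  writeLines("not an image", file.path(ind, "notes.txt"))
  expect_warning(n <- batch_convert(ind, outd), "skipping")
  expect_equal(as.integer(n), 2L)
  for (i in 1:2)
    expect_identical(read_image(file.path(outd, sprintf("e%d.png", i))),
                     invert(to_grayscale_8bit(imgs[[i]])))
  # empty directory converts nothing
  empt <- file.path(tmp, "empty"); dir.create(empt)
  expect_equal(as.integer(batch_convert(empt, file.path(tmp, "out2"))), 0L)
})

test_that("image and ROI files round-trip through PNG/TIFF and JSON", {
  tmp <- withr::local_tempdir()
  set.seed(12)
  gray <- random_gray_image(9, 7)
  for (ext in c("png", "tiff")) {
    f <- file.path(tmp, paste0("img.", ext))
    write_image(gray, f)
    expect_identical(read_image(f), gray)
  }
  rois <- list(list(embryo_id = "e1",
                    signal = rbind(c(1, 2), c(5, 2), c(5, 6)),
                    background = rbind(c(1, 10), c(5, 10), c(5, 14))))
  f <- file.path(tmp, "rois.json")
  write_roi_json(rois, f)
  back <- read_roi_json(f)
  expect_identical(back[[1]]$embryo_id, "e1")
  expect_equal(back[[1]]$signal, rois[[1]]$signal)
  expect_equal(back[[1]]$background, rois[[1]]$background)
})
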