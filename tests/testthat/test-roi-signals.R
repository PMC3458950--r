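test_that("spherical masks match brute-force voxel enumeration", {
  affine <- diag(c(3, 3, 3, 1))  # 3 mm isotropic grid, origin at voxel (1,1,1)
  shape <- c(30, 30, 30)
  spec <- roi_spec("test", c(45, 45, 45), 7.5)
  mask <- build_spherical_mask(spec, affine, shape)

  # oracle: exhaustive distance check over the full grid
  grid <- as.matrix(expand.grid(i = 0:29, j = 0:29, k = 0:29))
  mm <- grid * 3
  inside <- rowSums(sweep(mm, 2, spec$center)^2) <= 7.5^2
  expect_equal(nrow(mask), sum(inside))
  key <- function(m) sort(paste(m[, 1], m[, 2], m[, 3]))
  expect_identical(key(mask), key(grid[inside, , drop = FALSE] + 1L))

  # degenerate sphere: radius 0.1 mm centred exactly on a voxel centre
  tiny <- build_spherical_mask(roi_spec("pt", c(9, 9, 9), 0.1), affine, shape)
  expect_equal(nrow(tiny), 1L)
  expect_equal(as.integer(tiny), c(4L, 4L, 4L))
})

test_that("masks respect the affine and stay inside the bounding box", {
  # PCC-like spec on a 3 mm MNI-style affine with a translated origin
  affine <- rbind(c(-3, 0, 0, 90), c(0, 3, 0, -126), c(0, 0, 3, -72),
                  c(0, 0, 0, 1))
  spec <- roi_spec("pcc", c(-5, -49, 40), 7.5)
  mask <- build_spherical_mask(spec, affine, c(61, 73, 61))
  expect_gt(nrow(mask), 0)
  mm <- (mask - 1L) %*% t(affine[1:3, 1:3]) +
    matrix(affine[1:3, 4], nrow(mask), 3, byrow = TRUE)
  expect_true(all(abs(sweep(mm, 2, spec$center)) <= 7.5 + 1e-9))

  # centre far outside the field of view
  expect_error(
    build_spherical_mask(roi_spec("out", c(1e4, 0, 0), 7.5), affine,
                         c(61, 73, 61)),
    "outside"
  )
})

test_that("mean-signal extraction averages mask voxels per volume", {
  dims <- c(4, 4, 4, 40)
  vol <- array(5, dims)
  mask <- cbind(i = c(1L, 2L), j = c(1L, 1L), k = c(1L, 1L))
  s <- extract_mean_signal(vol, mask, dt = 2)
  expect_true(all(s$values == 5))
  expect_equal(length(s$values), 40)

  # two voxels with known series -> elementwise mean
  vol[1, 1, 1, ] <- seq(1, 79, by = 2)
  vol[2, 1, 1, ] <- seq(3, 81, by = 2)
  s2 <- extract_mean_signal(vol, mask, dt = 2)
  expect_equal(s2$values, seq(2, 80, by = 2))

  # single voxel -> verbatim series; scaling commutes with extraction
  one <- extract_mean_signal(vol, mask[1, , drop = FALSE], dt = 2)
  expect_equal(one$values, vol[1, 1, 1, ])
  s3 <- extract_mean_signal(vol * 2.5, mask, dt = 2)
  expect_equal(s3$values, s2$values * 2.5)

  bad <- cbind(i = 9L, j = 1L, k = 1L)
  expect_error(extract_mean_signal(vol, bad), "outside")
})

test_that("z-normalisation yields exact zero mean / unit variance and is idempotent", {
  z <- znormalize(c(1, 2, 3, rep(c(1, 2, 3), 10)))
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(mean(z^2), 1, tolerance = 1e-12)
  expect_equal(znormalize(z), z, tolerance = 1e-9)
  expect_error(znormalize(rep(2, 50)), "constant")

  s <- roi_series("s1", "pcc", sin(1:60), 2)
  zn <- znormalize(s)
  expect_s3_class(zn, "roi_series")
  expect_lt(abs(mean(zn$values)), 1e-12)
})

test_that("series TSV round-trips and NIfTI extraction matches manual masking", {
  series <- list(
    pcc = roi_series("s1", "pcc", rnorm(50), 2),
    dacc = roi_series("s1", "dacc", rnorm(50), 2)
  )
  path <- tempfile(fileext = ".tsv")
  write_series_tsv(series, path)
  back <- read_series_tsv(path, dt = 2, subject_id = "s1")
  expect_named(back, c("pcc", "dacc"))
  expect_equal(back$pcc$values, series$pcc$values, tolerance = 1e-12)

  # small synthetic 4D NIfTI: extraction through the file equals manual means
  set.seed(7)
  arr <- array(rnorm(12 * 12 * 12 * 35), c(12, 12, 12, 35))
  img <- RNifti::asNifti(arr, reference = NULL)
  img <- RNifti::`pixdim<-`(img, c(3, 3, 3, 2))
  nii <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, nii)
  affine <- structure(RNifti::xform(RNifti::readNifti(nii)), class = NULL)
  rois <- list(r1 = roi_spec("r1", as.numeric(affine %*% c(5, 5, 5, 1))[1:3], 4))
  got <- extract_roi_signals(nii, rois, normalize = FALSE)
  mask <- build_spherical_mask(rois$r1, affine, dim(arr)[1:3])
  manual <- sapply(seq_len(35), function(t) {
    mean(arr[cbind(mask, t)])
  })
  expect_equal(got$r1$values, manual, tolerance = 1e-6)
})
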