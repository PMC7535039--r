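test_that("phantom geometry honors the configuration", {
  cfg <- small_phantom_config(n_subjects = 3)
  ph <- generate_phantom(cfg, 1)
  expect_identical(dim(ph$volume$data), cfg$shape)
  expect_equal(ph$volume$spacing, c(0.7, 0.7, 5))
  # GTVr strictly inside GTV, fraction within 10% of target
  expect_true(all(ph$gtv$data[ph$gtvr$data == 1L] == 1L))
  frac <- mask_count(ph$gtvr) / mask_count(ph$gtv)
  expect_lt(abs(frac - cfg$recurrent_fraction), 0.1 * cfg$recurrent_fraction)
  # isodose covers the configured fraction of GTVr
  expect_equal(overlap_fraction(ph$gtvr, ph$isodose95),
               cfg$infield_overlap, tolerance = 2 / mask_count(ph$gtvr))
  # intensities within scanner range, clipping below 0.1%
  expect_true(all(ph$volume$data >= 0 & ph$volume$data <= 4095))
  clipped <- mean(ph$volume$data %in% c(0, 4095))
  expect_lt(clipped, 0.001)
})

test_that("full isodose coverage yields overlap exactly 1", {
  cfg <- small_phantom_config(infield_overlap = 1.0)
  ph <- generate_phantom(cfg, 1)
  expect_equal(overlap_fraction(ph$gtvr, ph$isodose95), 1.0)
})

test_that("generation is deterministic given (seed, subject_index)", {
  cfg <- small_phantom_config(seed = 7)
  a <- generate_phantom(cfg, 2)
  b <- generate_phantom(cfg, 2)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$gtvr$data, b$gtvr$data)
  c1 <- generate_phantom(cfg, 3)
  expect_false(identical(a$volume$data, c1$volume$data))
})

test_that("null configuration produces no habitat mean difference", {
  cfg <- small_phantom_config(
    n_subjects = 20, seed = 5, intensity_shift = 0,
    correlation_length_rec = 1.0, correlation_length_nonrec = 1.0,
    noise_sd = 10
  )
  d <- sapply(1:20, function(i) {
    ph <- generate_phantom(cfg, i)
    pair <- make_habitats(ph$gtv, ph$gtvr, ph$subject_id)
    mean(ph$volume$data[pair$recurrent$data == 1L]) -
      mean(ph$volume$data[pair$nonrecurrent$data == 1L])
  })
  # no detectable systematic habitat difference (a true shift of even half
  # the noise SD would drive this p-value below 1e-5 at n = 20)
  expect_gt(t.test(d)$p.value, 0.001)
  expect_lt(abs(mean(d)), sd(d))
})

test_that("the configured intensity shift is recovered from habitat means", {
  cfg <- small_phantom_config(
    n_subjects = 20, seed = 9, intensity_shift = 50,
    correlation_length_rec = 1.0, correlation_length_nonrec = 1.0,
    noise_sd = 10
  )
  d <- sapply(1:20, function(i) {
    ph <- generate_phantom(cfg, i)
    pair <- make_habitats(ph$gtv, ph$gtvr, ph$subject_id)
    mean(ph$volume$data[pair$recurrent$data == 1L]) -
      mean(ph$volume$data[pair$nonrecurrent$data == 1L])
  })
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - 50), 3 * se)
})

test_that("habitat mean separation is monotone in the intensity shift", {
  seps <- sapply(c(0, 25, 50), function(shift) {
    cfg <- small_phantom_config(
      n_subjects = 6, seed = 3, intensity_shift = shift,
      correlation_length_rec = 1.0, correlation_length_nonrec = 1.0,
      noise_sd = 10
    )
    mean(sapply(1:6, function(i) {
      ph <- generate_phantom(cfg, i)
      pair <- make_habitats(ph$gtv, ph$gtvr, ph$subject_id)
      mean(ph$volume$data[pair$recurrent$data == 1L]) -
        mean(ph$volume$data[pair$nonrecurrent$data == 1L])
    }))
  })
  expect_true(all(diff(seps) > 0))
})

test_that("cohort writing produces files, manifest, and reproducible bytes", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg <- small_phantom_config(n_subjects = 2, seed = 21)
  man <- generate_cohort(cfg, dir1)
  expect_equal(nrow(man), 2)
  expect_true(all(file.exists(man$volume, man$gtv, man$gtvr, man$isodose95)))
  # manifest voxel counts agree with a re-read of the written masks
  v <- read_volume(man$volume[1])
  g <- read_mask(man$gtv[1], v, role = "GTV")
  expect_equal(mask_count(g), man$n_gtv[1])

  man2 <- generate_cohort(cfg, dir2)
  expect_identical(
    unname(tools::md5sum(man$volume)),
    unname(tools::md5sum(man2$volume))
  )

  # empty cohort: manifest only
  dir3 <- withr::local_tempdir()
  man0 <- generate_cohort(small_phantom_config(n_subjects = 0), dir3)
  expect_equal(nrow(man0), 0)
  expect_identical(list.files(dir3), "manifest.csv")
})
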