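spec128 <- phantom_spec(image_size = 128)

test_that("rendering is deterministic under a fixed seed", {
  for (plane in c("axial1", "axial2", "coronal")) {
    a <- render_slice(spec128, plane, seed = 7)
    b <- render_slice(spec128, plane, seed = 7)
    expect_identical(a, b)
    c <- render_slice(spec128, plane, seed = 8)
    expect_false(identical(a$image$hu, c$image$hu))
  }
})

test_that("noiseless rendering gives exact tissue means", {
  spec <- phantom_spec(image_size = 128, noise_sd = 0)
  sl <- render_slice(spec, "axial1", seed = 3)
  expect_equal(mean(sl$image$hu[sl$masks$eyeball]), 5)
  expect_equal(mean(sl$image$hu[sl$masks$optic_nerve]), 35)
  expect_equal(mean(sl$image$hu[sl$masks$MRM]), 50)
})

test_that("pixel values stay inside the CT range in every plane", {
  spec <- phantom_spec(image_size = 128, noise_sd = 400)  # forces clipping
  for (plane in c("axial1", "axial2", "coronal")) {
    sl <- render_slice(spec, plane, seed = 5)
    expect_true(min(sl$image$hu) >= -1024)
    expect_true(max(sl$image$hu) <= 3071)
    expect_type(sl$image$hu[1], "integer")
  }
})

test_that("unknown plane tags and invalid specs are rejected", {
  expect_error(render_slice(spec128, "sagittal", 1), "plane")
  expect_error(phantom_spec(image_size = 100), "divisible")
  expect_error(phantom_spec(image_size = 32), "divisible|64")
  expect_error(phantom_spec(enlargement_factor = 0.5), "enlargement")
  expect_error(phantom_spec(noise_sd = -1), "noise")
})

test_that("each plane carries its tissue inventory with disjoint masks", {
  inventory <- list(axial1 = c("eyeball", "optic_nerve", "MRM", "LRM"),
                    axial2 = "lacrimal_gland",
                    coronal = c("optic_nerve", "MRM", "LRM", "SRM", "IRM"))
  for (plane in names(inventory)) {
    for (seed in 1:3) {
      sl <- render_slice(spec128, plane, seed)
      expect_setequal(names(sl$masks), inventory[[plane]])
      expect_true(all(vapply(sl$masks, sum, numeric(1)) > 0))
      overlap <- Reduce(`+`, lapply(sl$masks, function(m) m + 0L))
      expect_true(max(overlap) <= 1L)
    }
  }
})

test_that("muscle enlargement never shrinks the muscle masks", {
  factors <- c(1, 1.3, 1.7, 2.2)
  for (plane in c("axial1", "coronal")) {
    areas <- sapply(factors, function(f) {
      spec <- phantom_spec(image_size = 128, enlargement_factor = f)
      sl <- render_slice(spec, plane, seed = 9)
      sum(sl$masks$MRM) + sum(sl$masks$LRM)
    })
    expect_true(all(diff(areas) >= 0))
    expect_gt(areas[4], areas[1])  # enlargement is actually visible
  }
})

test_that("generated datasets round-trip losslessly and reproducibly", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  man <- generate_dataset(5, spec128, "axial1", d1, seed = 40)
  # 4 tissues per axial1 slice -> 20 manifest rows, 5 unique slices
  expect_equal(nrow(man), 20L)
  expect_equal(length(unique(man$id)), 5L)
  expect_setequal(unique(man$tissue), c("eyeball", "optic_nerve", "MRM",
                                        "LRM"))
  expect_true(all(file.exists(file.path(d1, man$image_path))))
  expect_true(all(file.exists(file.path(d1, man$mask_path))))
  # per-item seeds: item i rendered with seed + i
  sl3 <- render_slice(spec128, "axial1", seed = 43)
  row3 <- man[man$id == "axial1_0003" & man$tissue == "eyeball", ]
  expect_equal(row3$seed, 43)
  expect_identical(read_ct_image(file.path(d1, row3$image_path)),
                   sl3$image$hu)
  expect_identical(read_mask(file.path(d1, row3$mask_path)),
                   unclass(sl3$masks$eyeball))
  # identical second run, file by file
  generate_dataset(5, spec128, "axial1", d2, seed = 40)
  for (f in c(man$image_path, man$mask_path)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
})

test_that("simulate() draws independent reproducible slices", {
  sls <- simulate(spec128, nsim = 3, seed = 60, plane = "coronal")
  expect_length(sls, 3)
  expect_identical(sls[[2]], render_slice(spec128, "coronal", seed = 62))
})
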