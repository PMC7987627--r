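test_that("dose conversion to percent of prescription scales linearly and round-trips", {
  d <- data.frame(dose = 47.25, volume = 1)
  expect_equal(dvh_to_relative(d, 47.25)$dose, 100)

  d <- data.frame(dose = c(0, 23.625, 47.25), volume = c(1, .6, .1))
  expect_equal(dvh_to_relative(d, 47.25)$dose, c(0, 50, 100))

  set.seed(101)
  for (i in 1:20) {
    dvh <- rand_dvh()
    rel <- dvh_to_relative(dvh, 42)
    back <- rel
    back$dose <- back$dose * 42 / 100
    expect_equal(back$dose, dvh$dose, tolerance = 1e-12)
  }
  expect_error(dvh_to_relative(d, 0), class = "dosegain_error_invalid_argument")
  expect_error(dvh_to_relative(d, -5), class = "dosegain_error_invalid_argument")
})

test_that("differential volumes decompose the curve and conserve total volume", {
  expect_equal(differential_volumes(data.frame(dose = 10, volume = 2)),
               tibble::tibble(dose = 10, dvol = 2))

  dv <- differential_volumes(data.frame(dose = c(0, 10, 20),
                                        volume = c(1, 0.5, 0)))
  expect_equal(dv$dvol, c(0.5, 0.5, 0))

  set.seed(42)
  for (i in 1:25) {
    dvh <- rand_dvh(n_points = sample(3:80, 1), v0 = runif(1, 0.5, 500))
    dv <- differential_volumes(dvh)
    expect_equal(sum(dv$dvol), dvh$volume[1], tolerance = 1e-9)
    expect_true(all(dv$dvol >= 0))
  }

  expect_error(as_dvh(data.frame(dose = c(0, 10), volume = c(0.5, 1))),
               class = "dosegain_error_invalid_dvh")
})

test_that("DVH canonicalization merges duplicates and repairs truncated exports", {
  # duplicated dose keeps the smaller cumulative volume (step-function value)
  dvh <- as_dvh(data.frame(dose = c(0, 10, 10, 20), volume = c(1, .8, .6, .2)))
  expect_equal(dvh$dose, c(0, 10, 20))
  expect_equal(dvh$volume, c(1, .6, .2))

  # truncated export: curve starts below V0 -> (0, V0) prepended
  dvh <- as_dvh(data.frame(dose = c(5, 10), volume = c(.7, .2)), total_volume = 1)
  expect_equal(dvh$dose[1], 0)
  expect_equal(dvh$volume[1], 1)

  expect_error(as_dvh(data.frame(dose = c(-1, 2), volume = c(1, 0))),
               class = "dosegain_error_invalid_dvh")
})

test_that("MADD matches the voxel-level brute-force oracle within one grid width", {
  # exact on a step-function DVH built from the voxels themselves
  set.seed(7)
  for (i in 1:10) {
    vox <- c(runif(500, 0, 40), rnorm(500, 100, 4))
    vox <- vox[vox >= 0]
    a <- runif(1, 0, 110)
    dvh <- dvh_from_voxels_exact(vox)
    expect_equal(madd(dvh, a), voxel_madd_oracle(vox, a), tolerance = 1e-12)
  }

  # on a 0.1-wide grid the strip sum is within one grid width of the oracle
  set.seed(8)
  grid_width <- 0.1
  for (i in 1:10) {
    vox <- c(rexp(6000, 1), rnorm(4000, runif(1, 90, 105), runif(1, 2, 6)))
    vox <- pmax(vox, 0)
    a <- sample(c(0, 100, runif(1, 0, 110)), 1)
    dvh <- dvh_from_doses(vox, grid_width)
    expect_lt(abs(madd(dvh, a) - voxel_madd_oracle(vox, a)), grid_width)
  }
})

test_that("MADD obeys the zero law, scale equivariance and the translation bound", {
  # all volume exactly at the reference dose -> perfect plan, MADD 0
  expect_equal(madd(data.frame(dose = 42, volume = 3), 42), 0)
  # half volume at 10%, half at 30%, reference 0 -> mean dose 20%
  expect_equal(madd(data.frame(dose = c(10, 30), volume = c(1, .5)), 0), 20)

  set.seed(9)
  for (i in 1:20) {
    dvh <- rand_dvh(v0 = runif(1, 0.5, 100))
    a1 <- runif(1, 0, 120)
    a2 <- runif(1, 0, 120)
    k <- runif(1, 0.1, 5)
    m1 <- madd(dvh, a1)
    expect_gte(m1, 0)
    # scaling doses and reference by k scales the MADD by k
    scaled <- dvh
    scaled$dose <- scaled$dose * k
    expect_equal(madd(scaled, a1 * k), k * m1, tolerance = 1e-9)
    # moving the reference by |a1 - a2| moves the MADD by at most that much
    expect_lte(abs(m1 - madd(dvh, a2)), abs(a1 - a2) + 1e-12)
    # volumes in mL or as fractions give the identical MADD
    frac <- dvh
    frac$volume <- frac$volume / frac$volume[1]
    expect_equal(madd(frac, a1), m1, tolerance = 1e-12)
  }

  expect_error(madd(data.frame(dose = c(0, 10), volume = c(0, 0)), 0),
               class = "dosegain_error_degenerate_structure")
  expect_error(madd(data.frame(dose = 10, volume = 1), -1),
               class = "dosegain_error_invalid_argument")
})

test_that("cohort DVH CSV round-trips with unit metadata and Gy conversion", {
  set.seed(12)
  tab <- tibble::tibble(
    patient_id = rep(c("P1", "P2"), each = 6),
    setup = rep(rep(c("prone", "supine"), each = 3), 2),
    structure = "heart",
    dose = rep(c(0, 10, 20), 4),
    volume = rep(c(1, .4, .1), 4)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_dvh(tab, path, dose_unit = "percent")
  expect_equal(as.data.frame(read_dvh(path)), as.data.frame(tab))

  gy <- tab
  gy$dose <- gy$dose * 47.25 / 100
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_dvh(gy, path2, dose_unit = "Gy")
  expect_error(read_dvh(path2), class = "dosegain_error_unit")
  back <- read_dvh(path2, prescribed_dose = 47.25)
  expect_equal(back$dose, tab$dose, tolerance = 1e-12)
})

test_that("planning-system text exports parse into structure curves", {
  lines <- c(
    "Patient: anonymous", "",
    "Structure: heart",
    "Dose [%]   Ratio of Total Structure Volume [%]",
    "0          100.0",
    "10         42.5",
    "25         5.0", "",
    "Structure: lung_left",
    "Dose [%]   Volume [cm3]",
    "0          1500.0",
    "15         300.0"
  )
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(lines, path)
  out <- read_dvh_export(path, patient_id = "P9", setup = "prone")
  expect_setequal(unique(out$structure), c("heart", "lung_left"))
  heart <- out[out$structure == "heart", ]
  expect_equal(heart$volume, c(1, .425, .05))   # percent volumes -> fractions
  lung <- out[out$structure == "lung_left", ]
  expect_equal(lung$volume, c(1500, 300))       # absolute volumes kept
  expect_equal(madd(heart, 0), 10 * (.425 - .05) + 25 * .05)
})
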