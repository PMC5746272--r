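# Shape family: generation, selection, interpolation, Omega detection, IO.

test_that("stand-in family spans 80 depths with the constructed force curve", {
  fam <- stand_in_family()
  expect_length(fam$shapes, 80)
  expect_equal(fam$depths, 10 * seq(0.1, 8, by = 0.1))
  expect_equal(diff(fam$depths), rep(1, 79))
  expect_equal(max(fam$forces), 725)
  f0 <- actinME:::family_force_curve(0, membrane_params())
  expect_equal(f0, 0)
  # single maximum, then decreasing on the deep branch
  imax <- which.max(fam$forces)
  expect_true(all(diff(fam$forces[imax:80]) < 0))
})

test_that("shape selection is nearest-depth with piecewise-linear force", {
  fam <- stand_in_family()
  sel <- select_shape(fam, 1.4)
  expect_equal(sel$shape$y_I, 1)
  expect_equal(sel$f_in, 0.6 * fam$forces[1] + 0.4 * fam$forces[2])
  node <- select_shape(fam, 3)
  expect_equal(node$shape$y_I, 3)
  expect_equal(node$f_in, fam$forces[3])
  flat <- select_shape(fam, 0)
  expect_equal(flat$f_in, 0)
  expect_false(is_omega(flat$shape))
  expect_warning(out <- select_shape(fam, 200), "clamped")
  expect_equal(out$shape$y_I, 80)
  # continuity and piecewise linearity across the whole family
  ys <- seq(0, 80, by = 0.25)
  fs <- vapply(ys, function(y) select_shape(fam, y)$f_in, 0)
  expect_true(all(abs(diff(fs, differences = 2))[seq(2, 318, by = 4) - 1] <
                    1e-8))
})

test_that("Omega detection finds overhangs and is monotone along the family", {
  fam <- stand_in_family()
  flags <- vapply(fam$shapes, is_omega, logical(1))
  expect_true(all(diff(flags) >= 0))
  expect_equal(fam$depths[which(flags)[1]], membrane_params()$d_omega)
  # hand-built overhang: 25 nm bulb over a 10 nm neck
  pr <- actinME:::omega_profile(60, 10, 25, 100)
  sh <- membrane_shape(actinME:::arclength(pr$r, pr$y), pr$r, pr$y, 60, 10)
  expect_true(is_omega(sh))
  # monotone-radius dome
  dm <- actinME:::dome_profile(20, 10, 100)
  expect_false(is_omega(membrane_shape(actinME:::arclength(dm$r, dm$y),
                                       dm$r, dm$y, 20, 5)))
})

test_that("family files round-trip, reorder, and reject missing levels", {
  fam <- stand_in_family()
  path <- tempfile(fileext = ".txt")
  write_shape_family(fam, path)
  back <- load_shape_family(path)
  expect_equal(back$depths, fam$depths)
  expect_equal(back$forces, fam$forces)
  expect_equal(back$shapes[[40]]$samples, fam$shapes[[40]]$samples)

  # drop one shape -> rejected
  lines <- readLines(path)
  hdr <- which(startsWith(lines, "SHAPE "))
  trunc <- c(lines[1:3], sub("80", "79", lines[4]),
             lines[5:(hdr[80] - 1)])
  path2 <- tempfile(fileext = ".txt")
  writeLines(trunc, path2)
  expect_error(load_shape_family(path2), "80 depth levels")
})

test_that("forbidden zone: flat membrane, Omega pocket, and empty overlap", {
  lat <- lattice_spec("cylindrical", nr = 40L, ny = 70L, y_lo = -5L)
  flat <- forbidden_zone_mask(flat_shape(), lat)
  y <- (seq_len(70) - 1 - 5) * LATTICE_DELTA
  expect_equal(unname(flat), outer(rep(TRUE, 40), y < 0, FUN = "&"))

  fam <- stand_in_family()
  sh <- fam$shapes[[60]]     # 60 nm: Omega shape
  m <- forbidden_zone_mask(sh, lat)
  # a column through the neck region has two disjoint forbidden bands
  col <- m[10, ]
  runs <- rle(col)
  expect_equal(sum(runs$values), 2)
  # cytoplasmic pocket between flare and bulb is allowed: spot checks
  y_of <- function(j) (j - 1 - 5) * LATTICE_DELTA
  pocket_rows <- which(y_of(seq_len(70)) > 10 & y_of(seq_len(70)) < 25)
  expect_false(any(m[10, pocket_rows]))
  # far outside everything: no overlap
  expect_false(any(m[, y_of(seq_len(70)) > 65]))
})

test_that("region update reads ring and tip heights off the shape", {
  geom <- region_geometry()
  g0 <- update_regions(geom, flat_shape())
  expect_equal(c(g0$yL, g0$yS), c(0, 0))
  fam <- stand_in_family()
  sh <- select_shape(fam, 54)$shape
  g1 <- update_regions(geom, sh)
  expect_equal(g1$yS - g1$yL, 54, tolerance = 1e-6)
  expect_equal(update_regions(g1, sh), g1)   # idempotent
  # translation with the plateau offset
  g2 <- update_regions(geom, sh, offset = -7)
  expect_equal(g2$yL, g1$yL - 7)
  expect_equal(g2$yS, g1$yS - 7)
})
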