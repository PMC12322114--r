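geom4 <- grid_geometry(2, 2, x0 = 0, y0 = 2000, dx = 1000)  # 100 ha cells

share2 <- function(s1, s2) {
  crop_stack(list(LMAIZ = matrix(s1, 2, 2), PARI = matrix(s2, 2, 2)),
             geom4, kind = "share", units = "fraction")
}

test_that("cell weights above 100% are capped before deriving growing area", {
  w <- grid_create(matrix(c(120, 50, 80, 0), 2, 2), dx = 1000,
                   units = "percent")
  out <- crop_growing_area(w, share2(0.4, 0.1))
  expect_equal(out$uaa, matrix(c(100, 50, 80, 0), 2, 2))
  expect_equal(out$ga$layers$LMAIZ[2, 1], 50 * 0.4)   # 20 ha
  expect_equal(out$ga$layers$PARI[2, 2], 0)
  expect_error(crop_growing_area(
    grid_create(matrix(-1, 2, 2), dx = 1000), share2(0.4, 0.1)), "negative")
})

test_that("crop equipped area is share times total and bounded by it", {
  taei <- grid_create(matrix(c(50, 40, 0, 10), 2, 2), dx = 1000)
  st <- crop_aei(share2(0.5, 0.3), taei)
  expect_equal(st$layers$LMAIZ[1, 1], 25)
  expect_equal(st$layers$PARI[1, 1], 15)
  expect_true(all(stack_total(st) <= taei$values + 1e-12))
  expect_true(all(st$layers$LMAIZ[2, 1] == 0 | taei$values[2, 1] != 0))
})

test_that("zonal sums match brute-force masked sums", {
  set.seed(6)
  vals <- list(LMAIZ = matrix(runif(16), 4, 4), PARI = matrix(runif(16), 4, 4))
  gm <- grid_geometry(4, 4, dx = 1000)
  st <- crop_stack(vals, gm)
  idx <- matrix(c(rep(1L, 8), rep(2L, 8)), 4, 4)
  idx[4, 4] <- NA  # a cell outside all regions
  rr <- region_raster(idx, c("A", "B", "EMPTY"), gm)
  zs <- zonal_sum(st, rr)
  for (cc in names(vals)) {
    expect_equal(zs$total_ha[zs$region_id == "A" & zs$crop_code == cc],
                 sum(vals[[cc]][!is.na(idx) & idx == 1]), tolerance = 1e-12)
    expect_equal(zs$total_ha[zs$region_id == "B" & zs$crop_code == cc],
                 sum(vals[[cc]][!is.na(idx) & idx == 2]), tolerance = 1e-12)
    expect_equal(zs$total_ha[zs$region_id == "EMPTY" & zs$crop_code == cc], 0)
  }
  # single-region world: zonal sum equals the grid sum
  rr1 <- region_raster(matrix(1L, 4, 4), "A", gm)
  z1 <- zonal_sum(st, rr1)
  expect_equal(z1$total_ha[z1$crop_code == "LMAIZ"], sum(vals$LMAIZ))
})

test_that("calibration coefficients follow the target/equipped ratio", {
  tg <- data.frame(region_id = "A", crop_code = c("LMAIZ", "PARI", "CERE"),
                   year = 2010, aai_ha = c(250, 0, 1200))
  ae <- data.frame(region_id = "A", crop_code = c("LMAIZ", "PARI", "CERE"),
                   year = 2010, total_ha = c(1000, 500, 1000))
  cal <- suppressWarnings(calibration(tg, ae))
  expect_equal(cal$coeff_pct[cal$crop_code == "LMAIZ"], 25)
  expect_equal(cal$coeff_pct[cal$crop_code == "PARI"], 0)
  # coefficients above 100% are not clipped (but do warn)
  expect_equal(cal$coeff_pct[cal$crop_code == "CERE"], 120)
  expect_warning(calibration(tg, ae), "100")
  # zero equipped area with positive target: flagged, coefficient 0
  calf <- calibration(
    data.frame(region_id = "A", crop_code = "OLIVGR", year = 2010,
               aai_ha = 10),
    data.frame(region_id = "A", crop_code = "OLIVGR", year = 2010,
               total_ha = 0))
  expect_true(calf$flagged)
  expect_equal(calf$coeff_pct, 0)
  expect_error(calibration(
    data.frame(region_id = "A", crop_code = "X", year = 2010, aai_ha = -1),
    ae), "negative")
})

test_that("allocation conserves regional targets exactly", {
  b <- small_world(seed = 23, years = 2010:2011, n_crops = 4)
  res <- run_build(b)
  for (ys in names(res$aai)) {
    zs <- zonal_sum(res$aai_uncapped[[ys]], b$region_raster)
    zs$year <- as.integer(ys)
    m <- merge(zs, res$targets, by = c("region_id", "crop_code", "year"))
    expect_lt(max_rel_err(m$total_ha, m$aai_ha), 1e-9)
  }
  # scaling all targets by lambda scales every cell by lambda (monotonicity)
  ys <- "2010"
  cal <- res$calibration[res$calibration$year == 2010, ]
  cal2 <- cal; cal2$coeff_pct <- cal2$coeff_pct * 0.5
  aei_stack <- crop_aei(b$crop_share_grids, res$taei)
  a1 <- allocate_aai(aei_stack, cal, b$region_raster)
  a2 <- allocate_aai(aei_stack, cal2, b$region_raster)
  for (cc in names(a1$layers))
    expect_equal(a2$layers[[cc]], a1$layers[[cc]] * 0.5, tolerance = 1e-12)
})

test_that("allocation refuses cells in regions without coefficients", {
  gm <- grid_geometry(2, 2, dx = 1000)
  st <- crop_stack(list(LMAIZ = matrix(1, 2, 2)), gm, year = 2010)
  rr <- region_raster(matrix(c(1L, 1L, 2L, 2L), 2, 2), c("A", "B"), gm)
  cal <- data.frame(region_id = "A", crop_code = "LMAIZ", year = 2010,
                    coeff_pct = 50, flagged = FALSE)
  expect_error(allocate_aai(st, cal, rr), "B")
})

test_that("the capacity cap scales crops proportionally to exactly the cap", {
  gm <- grid_geometry(1, 2, x0 = 0, y0 = 1000, dx = 1000)
  st <- crop_stack(list(LMAIZ = matrix(c(60, 30), 1, 2),
                        PARI = matrix(c(80, 40), 1, 2)), gm)
  out <- apply_cell_cap(st, cap_ha = 100)
  expect_equal(out$stack$layers$LMAIZ[1, 1], 100 * 60 / 140)
  expect_equal(out$stack$layers$PARI[1, 1], 100 * 80 / 140)
  expect_equal(stack_total(out$stack)[1, 1], 100, tolerance = 1e-12)
  # between-crop ratios preserved: 80/60 = 4/3 before and after
  expect_equal(out$stack$layers$PARI[1, 1] / out$stack$layers$LMAIZ[1, 1],
               4 / 3, tolerance = 1e-12)
  # under-cap cell untouched
  expect_equal(out$stack$layers$LMAIZ[1, 2], 30)
  expect_equal(out$stack$layers$PARI[1, 2], 40)
  expect_equal(sum(out$triggered), 1L)
  expect_error(apply_cell_cap(st, cap_ha = 0), "positive")
})

test_that("rainfed derivation clamps and satisfies the exact identity", {
  gm <- grid_geometry(1, 3, x0 = 0, y0 = 1000, dx = 1000)
  ga <- crop_stack(list(LMAIZ = matrix(c(10, 3, 5), 1, 3)), gm,
                   kind = "growing_area")
  aai <- crop_stack(list(LMAIZ = matrix(c(4, 4, 0), 1, 3)), gm)
  out <- derive_rainfed(ga, aai)
  expect_equal(out$rainfed$layers$LMAIZ[1, ], c(6, 0, 5))
  expect_equal(out$aai$layers$LMAIZ[1, ], c(4, 3, 0))
  expect_equal(out$diagnostics$clamped_ha, 1)
  expect_equal(out$diagnostics$n_cells, 1L)
  # identity holds exactly everywhere
  expect_identical(out$aai$layers$LMAIZ + out$rainfed$layers$LMAIZ,
                   ga$layers$LMAIZ)
})
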