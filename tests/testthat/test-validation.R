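pts_df <- function(...) {
  d <- data.frame(...)
  if (is.null(d$lu2)) d$lu2 <- ""
  d
}

test_that("survey classification filters land use then applies WM codes", {
  p <- pts_df(x = 1:4, y = 1:4, lu1 = c("U111", "U111", "U370", "U112"),
              wm = c(4L, 5L, 1L, 2L))
  out <- classify_survey_points(p)
  expect_equal(nrow(out), 3)                   # non-agricultural point dropped
  expect_equal(out$irrigated, c(TRUE, FALSE, FALSE))  # wm4 yes, wm5/wm2 no
  # potential irrigation counts only behind the flag
  out2 <- classify_survey_points(p, include_potential = TRUE)
  expect_equal(out2$irrigated, c(TRUE, FALSE, TRUE))
  # secondary land use can qualify a point
  p2 <- pts_df(x = 1, y = 1, lu1 = "U370", lu2 = "U112", wm = 1L)
  expect_equal(nrow(classify_survey_points(p2)), 1)
  expect_error(classify_survey_points(pts_df(x = 1, y = 1, lu1 = "U111",
                                             wm = 7L)), "7")
})

test_that("point-side block percentages are simple irrigated ratios", {
  gm <- grid_geometry(40, 40, x0 = 0, y0 = 40000, dx = 1000)
  # 20 points in one 40-km block, 5 irrigated
  p <- pts_df(x = seq(500, by = 1000, length.out = 20), y = 500,
              lu1 = "U111", wm = c(rep(1L, 5), rep(5L, 15)))
  a <- block_irrigated_percentage_points(classify_survey_points(p), gm, 40)
  expect_equal(a$ip, 25)
  expect_equal(a$n_points, 20L)
  # zero irrigated of 7
  p0 <- pts_df(x = rep(500, 7), y = 500, lu1 = "U111", wm = 5L)
  expect_equal(block_irrigated_percentage_points(
    classify_survey_points(p0), gm, 40)$ip, 0)
  # points outside the grid are dropped
  pout <- pts_df(x = -5000, y = 500, lu1 = "U111", wm = 1L)
  expect_equal(nrow(block_irrigated_percentage_points(
    classify_survey_points(pout), gm, 40)), 0)
})

test_that("raster-side block percentages divide by covered block area", {
  # full 40-km block of 1-km cells holding 4000 ha -> 2.5%
  gm <- grid_geometry(40, 40, x0 = 0, y0 = 40000, dx = 1000)
  g <- grid_create(matrix(4000 / 1600, 40, 40), x0 = 0, y0 = 40000,
                   dx = 1000)
  out <- block_irrigated_percentage_raster(g, 40)
  expect_equal(out$ip, 2.5)
  # zero area -> 0%
  expect_equal(block_irrigated_percentage_raster(
    grid_create(matrix(0, 40, 40), x0 = 0, y0 = 40000, dx = 1000), 40)$ip, 0)
  # checkerboard half-full at the 100-ha cap -> 50%
  cb <- matrix(0, 8, 8); cb[(row(cb) + col(cb)) %% 2 == 0] <- 100
  out_cb <- block_irrigated_percentage_raster(
    grid_create(cb, x0 = 0, y0 = 8000, dx = 1000), 8)
  expect_equal(out_cb$ip, 50)
  # partial edge blocks use the actually covered area
  g2 <- grid_create(matrix(10, 6, 6), x0 = 0, y0 = 6000, dx = 1000)
  out2 <- block_irrigated_percentage_raster(g2, 4)
  # corner block covers 2x2 cells = 400 ha holding 40 ha -> 10% everywhere
  expect_true(all(abs(out2$ip - 10) < 1e-12))
  expect_error(block_irrigated_percentage_raster(g2, 2.5), "multiple")
})

test_that("the paired filter applies the inclusive minimum on both sides", {
  a <- data.frame(block_id = c("b1", "b2", "b3", "b4"),
                  ip = c(0.2, 0.3, 0, 5))
  b <- data.frame(block_id = c("b1", "b2", "b3", "b4"),
                  ip = c(5, 0.3, 0, 4))
  out <- paired_filter(a, b, min_ip_pct = 0.3)
  expect_equal(out$block_id, c("b2", "b4"))  # 0.2% excluded, 0.3% retained
  # blocks missing on one side never pair
  out2 <- paired_filter(a[1:2, ], b[3:4, ])
  expect_equal(nrow(out2), 0)
})

test_that("agreement statistics match hand-computed sums on a fixed table", {
  pairs <- data.frame(
    ip_a = c(1.2, 3.5, 2.2, 7.9, 4.4, 6.1, 0.8, 5.3),
    ip_b = c(0.9, 2.8, 2.5, 6.2, 3.9, 5.5, 1.1, 4.0))
  st <- agreement_stats(pairs, crop_code = "LMAIZ")
  # independent textbook sum-formula computation
  a <- pairs$ip_a; b <- pairs$ip_b; n <- 8
  sxy <- sum(a * b) - sum(a) * sum(b) / n
  sxx <- sum(a^2) - sum(a)^2 / n
  syy <- sum(b^2) - sum(b)^2 / n
  r <- sxy / sqrt(sxx * syy)
  slope <- sxy / sxx
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  expect_equal(st$pearson_r, r, tolerance = 1e-12)
  expect_equal(st$slope, slope, tolerance = 1e-12)
  expect_equal(st$p_value, p, tolerance = 1e-12)
  expect_equal(st$stars, "***")
  expect_equal(st$n_blocks, 8L)
})

test_that("agreement statistics handle degenerate inputs", {
  prop <- data.frame(ip_a = 1:10, ip_b = 2 * (1:10))
  st <- agreement_stats(prop)
  expect_equal(st$pearson_r, 1, tolerance = 1e-12)
  expect_equal(st$slope, 2, tolerance = 1e-12)
  flat <- data.frame(ip_a = 1:5, ip_b = rep(3, 5))
  stf <- agreement_stats(flat)
  expect_true(stf$flagged)
  expect_true(is.na(stf$pearson_r))
  expect_error(agreement_stats(prop[1:2, ]), "at least 3")
})

test_that("classification mappings have the published structure", {
  dg <- reclass_map("dgpcm")
  expect_equal(nrow(dg), 28)                       # 28 source crop classes
  expect_equal(length(unique(dg$target_code)), 16) # 16 output classes
  expect_equal(sum(dg$target_code == "OTHER"), 8)  # 8 classes merged
  expect_true(all(dg$target_code %in% crop_catalog()$crop_code))
  agg <- reclass_map("aggregated12")
  expect_equal(length(unique(agg$target_code)), 12)
  expect_true(all(reclass_map("lucas")$target_code %in%
                    crop_catalog()$crop_code))
})

test_that("reclassification merges areas additively and conserves totals", {
  areas <- data.frame(crop_code = c("SWHE", "BARL", "LMAIZ", "SOYA"),
                      area_ha = c(2, 3, 7, 1))
  out <- reclassify(reclass_map("dgpcm"), areas)
  expect_equal(out$area_ha[out$crop_code == "CERE"], 5)
  expect_equal(out$area_ha[out$crop_code == "OTHER"], 1)
  expect_equal(sum(out$area_ha), sum(areas$area_ha))
  expect_error(reclassify(reclass_map("dgpcm"),
                          data.frame(crop_code = "NOPE", area_ha = 1)),
               "NOPE")
  # non-area tables just get re-keyed
  pts <- data.frame(crop_code = c("B16", "B11"), x = 1:2)
  out2 <- reclassify(reclass_map("lucas"), pts)
  expect_equal(out2$crop_code, c("LMAIZ", "CERE"))
})

test_that("dense surveys of a uniform-fraction world agree with the product", {
  # regions aligned with comparison blocks; every cell surveyed once
  cfg <- world_config(grid_height = 64, grid_width = 64, n_nuts1 = 4,
                      nuts2_per_nuts1 = 4, n_crops = 2, years = 2010,
                      ratio = 1, aei_fixed = 80, weight_fixed = 100,
                      seed = 21)
  b <- make_world(cfg)
  res <- run_build(b)
  pts <- make_survey_points(b, 4096, 2010, seed = 22)
  v <- run_validate(res, pts, block_km = 16, min_ip_pct = 0.3)
  expect_true(all(v$pearson_r > 0.9))
  # irrigated percentages on both sides live in [0, 100]
  gm <- b$target_geom
  pa <- block_irrigated_percentage_points(
    classify_survey_points(pts), gm, 16)
  pb <- block_irrigated_percentage_raster(
    grid_create(stack_total(res$aai[["2010"]]), x0 = gm$x0, y0 = gm$y0,
                dx = gm$dx), 16)
  expect_true(all(pa$ip >= 0 & pa$ip <= 100))
  expect_true(all(pb$ip >= 0 & pb$ip <= 100))
})
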