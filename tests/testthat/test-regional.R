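regions2 <- data.frame(
  region_id = c("P1", "P1A", "P1B"),
  parent_id = c(NA, "P1", "P1"),
  level = c("NUTS1", "NUTS2", "NUTS2"))

test_that("region shares are proportional to reference crop sums", {
  ref <- data.frame(region_id = c("P1A", "P1B"), crop_code = "LMAIZ",
                    aai_ha = c(30, 70))
  sh <- compute_region_shares(ref, regions2)
  expect_equal(sh$share_pct[match(c("P1A", "P1B"), sh$region_id)], c(30, 70))
  expect_false(any(sh$flagged))
})

test_that("missing or zero reference data falls back to an even split", {
  regions4 <- data.frame(
    region_id = c("P1", paste0("P1", LETTERS[1:4])),
    parent_id = c(NA, rep("P1", 4)), level = c("NUTS1", rep("NUTS2", 4)))
  # no reference rows at all
  sh <- compute_region_shares(
    data.frame(region_id = character(0), crop_code = character(0),
               aai_ha = numeric(0)), regions4)
  expect_equal(sh$share_pct, rep(25, 4))
  expect_true(all(sh$flagged))
  # all-zero reference rows
  ref0 <- data.frame(region_id = c("P1A", "P1B"), crop_code = "LMAIZ",
                     aai_ha = c(0, 0))
  sh0 <- compute_region_shares(ref0, regions2)
  expect_equal(sh0$share_pct, rep(100 / 2, 2))
  expect_true(all(sh0$flagged))
  expect_error(compute_region_shares(
    data.frame(region_id = "P1A", crop_code = "LMAIZ", aai_ha = -1),
    regions2), "negative")
})

test_that("NUTS1 totals disaggregate conservatively and NUTS2 pass through", {
  sh <- data.frame(region_id = c("P1A", "P1B"), parent_id = "P1",
                   share_pct = c(30, 70), flagged = FALSE)
  ser <- data.frame(region_id = "P1", year = 2010, taai_ha = 100)
  out <- disaggregate_total_aai(ser, sh, regions2)
  expect_equal(out$taai_ha[match(c("P1A", "P1B"), out$region_id)], c(30, 70))
  # zero parent propagates zeros
  out0 <- disaggregate_total_aai(
    data.frame(region_id = "P1", year = 2011, taai_ha = 0), sh, regions2)
  expect_equal(out0$taai_ha, c(0, 0))
  # even split conserves a non-round total exactly
  regions4 <- data.frame(
    region_id = c("P1", paste0("P1", LETTERS[1:4])),
    parent_id = c(NA, rep("P1", 4)), level = c("NUTS1", rep("NUTS2", 4)))
  sh4 <- data.frame(region_id = paste0("P1", LETTERS[1:4]), parent_id = "P1",
                    share_pct = rep(25, 4), flagged = TRUE)
  o4 <- disaggregate_total_aai(
    data.frame(region_id = "P1", year = 2010, taai_ha = 123.4), sh4, regions4)
  expect_equal(o4$taai_ha, rep(30.85, 4))
  expect_equal(sum(o4$taai_ha), 123.4, tolerance = 1e-12)
  # NUTS2 rows pass through untouched
  mix <- rbind(ser, data.frame(region_id = "P1A", year = 2012, taai_ha = 5))
  om <- disaggregate_total_aai(mix, sh, regions2)
  expect_equal(om$taai_ha[om$region_id == "P1A" & om$year == 2012], 5)
})

test_that("crop proportions close to 100 and flag zero-sum regions", {
  ref <- data.frame(region_id = "P1A", crop_code = c("LMAIZ", "PARI"),
                    aai_ha = c(40, 60))
  pr <- compute_crop_proportions(ref)
  expect_equal(pr$share_pct, c(40, 60))
  # single crop takes everything
  pr1 <- compute_crop_proportions(
    data.frame(region_id = "X", crop_code = "OLIVGR", aai_ha = 5))
  expect_equal(pr1$share_pct, 100)
  # 16 equal crops -> 6.25 each
  pr16 <- compute_crop_proportions(
    data.frame(region_id = "X", crop_code = crop_catalog()$crop_code,
               aai_ha = 1))
  expect_equal(pr16$share_pct, rep(6.25, 16))
  expect_equal(sum(pr16$share_pct), 100)
  # duplicates refused
  expect_error(compute_crop_proportions(
    data.frame(region_id = "X", crop_code = c("PARI", "PARI"),
               aai_ha = c(1, 2))), "duplicate")
  # zero-sum region flagged with zero shares
  pr0 <- compute_crop_proportions(
    data.frame(region_id = "X", crop_code = c("PARI", "LMAIZ"),
               aai_ha = c(0, 0)))
  expect_true(all(pr0$flagged))
  expect_equal(pr0$share_pct, c(0, 0))
})

test_that("annual crop targets conserve the regional total", {
  shares <- data.frame(region_id = "P1A",
                       crop_code = c("LMAIZ", "PARI", "CERE"),
                       share_pct = c(50, 30, 20), flagged = FALSE)
  ser <- data.frame(region_id = "P1A", year = c(2010, 2015),
                    taai_ha = c(10, 80))
  out <- crop_aai_series(ser, shares)
  expect_equal(sort(out$aai_ha[out$year == 2010]), c(2, 3, 5))
  expect_equal(sum(out$aai_ha[out$year == 2015]), 80, tolerance = 1e-12)
  expect_equal(out$aai_ha[out$year == 2015 & out$crop_code == "LMAIZ"], 40)
  # zero total -> zero crops
  o0 <- crop_aai_series(data.frame(region_id = "P1A", year = 2011,
                                   taai_ha = 0), shares)
  expect_true(all(o0$aai_ha == 0))
  # flagged region reports unallocated mass instead of inventing a crop
  fl <- data.frame(region_id = "P1B", crop_code = "LMAIZ", share_pct = 0,
                   flagged = TRUE)
  of <- crop_aai_series(data.frame(region_id = "P1B", year = 2010,
                                   taai_ha = 7), fl)
  expect_true(all(of$aai_ha == 0))
  un <- attr(of, "unallocated")
  expect_equal(un$unallocated_ha, 7)
  # region missing from shares is an error
  expect_error(crop_aai_series(data.frame(region_id = "ZZ", year = 2010,
                                          taai_ha = 1), shares), "missing")
})

test_that("proportions are time-invariant: equal totals give equal vectors", {
  b <- small_world(seed = 13, years = 2010:2012, n_crops = 5)
  sh <- compute_region_shares(b$crop_aai_ref, b$region_table)
  ser <- disaggregate_total_aai(b$aai_series, sh, b$region_table)
  pr <- compute_crop_proportions(b$crop_aai_ref)
  # force two years to the same totals; crop vectors must be identical
  ser2 <- ser[ser$year %in% 2010:2011, ]
  ser2$taai_ha[ser2$year == 2011] <- ser2$taai_ha[ser2$year == 2010]
  out <- crop_aai_series(ser2, pr)
  a <- out[out$year == 2010, c("region_id", "crop_code", "aai_ha")]
  b2 <- out[out$year == 2011, c("region_id", "crop_code", "aai_ha")]
  m <- merge(a, b2, by = c("region_id", "crop_code"))
  expect_equal(m$aai_ha.x, m$aai_ha.y, tolerance = 1e-12)
})
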