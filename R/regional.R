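# Regional disaggregation of annual irrigated-area totals.
#
# Annual total irrigated area (AAI) is reported per region, at NUTS2
# level except where only the NUTS1 total exists. Crop-specific AAI is
# reported once, for the 2010 reference year. Two fixed proportion sets
# carry the totals down: the NUTS2-within-NUTS1 split (from reference
# crop sums) and the per-crop split within each NUTS2. Both are assumed
# constant over the mapped years. Conservation is exact by construction:
# children always sum to the parent, crops to the regional total.
#
# Table layouts (data.frames):
#   regions:   region_id, parent_id (NA for NUTS1), level ("NUTS1"/"NUTS2")
#   aai series: region_id, year, taai_ha
#   crop reference: region_id, crop_code, aai_ha  (reference year, NUTS2)

check_region_table <- function(regions) {
  stopifnot(all(c("region_id", "parent_id", "level") %in% names(regions)))
  if (anyDuplicated(regions$region_id))
    stop("duplicate region identifiers in region table")
  n2 <- regions[regions$level == "NUTS2", ]
  if (any(is.na(n2$parent_id)))
    stop("NUTS2 region without a parent: ",
         paste(n2$region_id[is.na(n2$parent_id)], collapse = ", "))
  bad <- !n2$parent_id %in% regions$region_id[regions$level == "NUTS1"]
  if (any(bad))
    stop("NUTS2 region with unknown parent: ",
         paste(n2$region_id[bad], collapse = ", "))
  invisible(regions)
}

#' NUTS2-within-NUTS1 shares of total irrigated area
#'
#' For every NUTS1 unit, splits 100% across its NUTS2 children in
#' proportion to their reference-year crop-summed irrigated area. Where a
#' parent's crop sum is zero, or none of its children appear in the
#' reference table, the parent total is split evenly across its N
#' children (each gets 100/N) and the children are flagged.
#'
#' @param ref reference crop table (`region_id`, `crop_code`, `aai_ha`),
#'   NUTS2 level.
#' @param regions region table (`region_id`, `parent_id`, `level`).
#' @return data.frame `region_id`, `parent_id`, `share_pct`, `flagged`;
#'   shares within one parent sum to 100.
#' @export
compute_region_shares <- function(ref, regions) {
  check_region_table(regions)
  if (any(ref$aai_ha < 0)) stop("negative reference irrigated area")
  n2 <- regions[regions$level == "NUTS2", c("region_id", "parent_id")]
  sums <- tapply(ref$aai_ha, ref$region_id, sum)
  n2$crop_sum <- as.numeric(sums[n2$region_id])
  n2$has_data <- !is.na(n2$crop_sum)
  n2$crop_sum[is.na(n2$crop_sum)] <- 0
  out <- do.call(rbind, lapply(split(n2, n2$parent_id), function(ch) {
    tot <- sum(ch$crop_sum)
    if (tot > 0) {
      data.frame(region_id = ch$region_id, parent_id = ch$parent_id,
                 share_pct = 100 * ch$crop_sum / tot, flagged = FALSE)
    } else {
      # zero crop sum or no data at all: even split, flagged
      data.frame(region_id = ch$region_id, parent_id = ch$parent_id,
                 share_pct = rep(100 / nrow(ch), nrow(ch)), flagged = TRUE)
    }
  }))
  rownames(out) <- NULL
  out
}

#' Disaggregate annual NUTS1 totals to NUTS2
#'
#' Series rows reported at NUTS1 level are split across the children using
#' the fixed reference-year shares; rows already at NUTS2 level pass
#' through unchanged. Per year, the children of each parent sum exactly to
#' the parent total.
#'
#' @param series annual totals (`region_id`, `year`, `taai_ha`), mixed
#'   NUTS1/NUTS2 level.
#' @param shares output of [compute_region_shares()].
#' @param regions region table.
#' @return NUTS2-level series (`region_id`, `year`, `taai_ha`).
#' @export
disaggregate_total_aai <- function(series, shares, regions) {
  check_region_table(regions)
  if (any(series$taai_ha < 0)) stop("negative total irrigated area in series")
  lvl <- setNames(regions$level, regions$region_id)
  if (any(!series$region_id %in% regions$region_id))
    stop("series region not in region table: ",
         paste(setdiff(series$region_id, regions$region_id), collapse = ", "))
  is1 <- lvl[series$region_id] == "NUTS1"
  pass <- series[!is1, c("region_id", "year", "taai_ha")]
  top <- series[is1, ]
  split_rows <- do.call(rbind, lapply(seq_len(nrow(top)), function(k) {
    ch <- shares[shares$parent_id == top$region_id[k], ]
    if (nrow(ch) == 0)
      stop("no NUTS2 shares for NUTS1 region ", top$region_id[k],
           " (year ", top$year[k], ")")
    data.frame(region_id = ch$region_id, year = top$year[k],
               taai_ha = ch$share_pct / 100 * top$taai_ha[k])
  }))
  out <- rbind(pass, split_rows)
  rownames(out) <- NULL
  out[order(out$region_id, out$year), ]
}

#' Per-crop proportions of the reference-year irrigated area
#'
#' Within each region, each crop's share of the summed crop-specific
#' irrigated area (the crop sum is used as the total, not any separately
#' reported figure, so the shares always close to 100%). Regions whose
#' crop sum is zero get all-zero shares and are flagged.
#'
#' @param ref reference crop table (`region_id`, `crop_code`, `aai_ha`).
#' @return data.frame `region_id`, `crop_code`, `share_pct`, `flagged`.
#' @export
compute_crop_proportions <- function(ref) {
  if (any(ref$aai_ha < 0)) stop("negative reference irrigated area")
  if (anyDuplicated(ref[c("region_id", "crop_code")]))
    stop("duplicate (region, crop) rows in crop reference table")
  out <- do.call(rbind, lapply(split(ref, ref$region_id), function(r) {
    tot <- sum(r$aai_ha)
    data.frame(region_id = r$region_id, crop_code = r$crop_code,
               share_pct = if (tot > 0) 100 * r$aai_ha / tot else 0,
               flagged = tot <= 0)
  }))
  rownames(out) <- NULL
  out
}

#' Annual crop-specific irrigated-area targets
#'
#' Applies the fixed reference-year crop proportions to every year of the
#' NUTS2 total series: `aai(crop, year) = share/100 * total(year)`. For
#' non-flagged regions, crops sum exactly to the regional total. For
#' flagged regions (all-zero crop shares but possibly positive totals)
#' all crops are 0 and the unallocated total is reported in the
#' `unallocated` attribute (data.frame `region_id`, `year`,
#' `unallocated_ha`) rather than forced into an arbitrary crop.
#'
#' @param nuts2_series NUTS2 totals (`region_id`, `year`, `taai_ha`).
#' @param crop_shares output of [compute_crop_proportions()].
#' @return data.frame `region_id`, `crop_code`, `year`, `aai_ha` with
#'   attribute `unallocated`.
#' @export
crop_aai_series <- function(nuts2_series, crop_shares) {
  miss <- setdiff(nuts2_series$region_id, crop_shares$region_id)
  if (length(miss))
    stop("series region missing from crop shares: ",
         paste(miss, collapse = ", "))
  out <- merge(nuts2_series, crop_shares, by = "region_id")
  out$aai_ha <- out$share_pct / 100 * out$taai_ha
  unalloc <- out[out$flagged & out$taai_ha > 0,
                 c("region_id", "year", "taai_ha")]
  unalloc <- unique(unalloc)
  names(unalloc)[3] <- "unallocated_ha"
  rownames(unalloc) <- NULL
  res <- out[order(out$region_id, out$crop_code, out$year),
             c("region_id", "crop_code", "year", "aai_ha")]
  rownames(res) <- NULL
  attr(res, "unallocated") <- unalloc
  res
}
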