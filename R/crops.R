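# Crop catalogs and classification mappings.
#
# The output catalog holds 16 crop classes keyed by Eurostat/DGPCM-style
# codes. Source products use finer (28-class crop-type map, LUCAS survey
# codes) or coarser (12-class aggregation used for cross-product
# comparison) schemes; total mappings between them are provided so areas
# and survey points can be re-keyed with exact area conservation.

#' The 16-class output crop catalog
#'
#' @return data.frame `crop_code`, `crop_name`.
#' @export
crop_catalog <- function() {
  data.frame(
    crop_code = c("CERE", "LMAIZ", "PARI", "PULS", "POTA", "SUGB", "SUNF",
                  "LRAPE", "TEXT", "GRAS", "TOMA_OVEG", "APPL_OFRU", "CITR",
                  "OLIVGR", "VINY", "OTHER"),
    crop_name = c("Other cereals (excl. maize and rice)", "Maize", "Rice",
                  "Pulses", "Potato", "Sugar beet", "Sunflower",
                  "Rape and turnip rape", "Textile crops", "Grassland",
                  "Fresh vegetable, melon, strawberry - open field",
                  "Fruit and berry", "Citrus", "Olive", "Vineyards",
                  "Other crops"))
}

#' Crop classification mappings
#'
#' Total source-to-target mappings between crop schemes:
#' \describe{
#'   \item{`dgpcm`}{the 28-class crop-type-map scheme to the 16 output
#'     classes: the six non-maize, non-rice cereals merge into `CERE`
#'     and eight minor classes (root crops, soya, tobacco, other
#'     industrial crops, flowers, forage plants, nurseries, other
#'     permanent crops) merge into `OTHER`; the rest map one-to-one.}
#'   \item{`lucas`}{survey crop codes (B/E series) to the 16 output
#'     classes.}
#'   \item{`aggregated12`}{the 16 output classes to the 12-class scheme
#'     used when comparing against coarser global products: the five
#'     horticultural/permanent classes merge into `VEGFRU`, textile
#'     crops map to `COTT`.}
#' }
#'
#' @param scheme one of `"dgpcm"`, `"lucas"`, `"aggregated12"`.
#' @return data.frame `source_code`, `target_code` with attribute
#'   `scheme`.
#' @export
reclass_map <- function(scheme = c("dgpcm", "lucas", "aggregated12")) {
  scheme <- match.arg(scheme)
  m <- switch(scheme,
    dgpcm = c(
      SWHE = "CERE", DWHE = "CERE", BARL = "CERE", RYEM = "CERE",
      OATS = "CERE", OCER = "CERE",
      LMAIZ = "LMAIZ", PARI = "PARI", PULS = "PULS", POTA = "POTA",
      SUGB = "SUGB", SUNF = "SUNF", LRAPE = "LRAPE", TEXT = "TEXT",
      GRAS = "GRAS", TOMA_OVEG = "TOMA_OVEG", APPL_OFRU = "APPL_OFRU",
      CITR = "CITR", OLIVGR = "OLIVGR", VINY = "VINY",
      ROOF = "OTHER", SOYA = "OTHER", TOBA = "OTHER", OIND = "OTHER",
      FLOW = "OTHER", OFAR = "OTHER", NURS = "OTHER", OCRO = "OTHER"),
    lucas = c(
      B11 = "CERE", B12 = "CERE", B13 = "CERE", B14 = "CERE",
      B15 = "CERE", B18 = "CERE", B19 = "CERE",
      B16 = "LMAIZ", B17 = "PARI", B41 = "PULS", B21 = "POTA",
      B22 = "SUGB", B31 = "SUNF", B32 = "LRAPE",
      B34 = "TEXT", B35 = "TEXT",
      E10 = "GRAS", E20 = "GRAS", E30 = "GRAS",
      B42 = "TOMA_OVEG", B43 = "TOMA_OVEG", B45 = "TOMA_OVEG",
      B71 = "APPL_OFRU", B72 = "APPL_OFRU", B73 = "APPL_OFRU",
      B74 = "APPL_OFRU", B75 = "APPL_OFRU",
      B76 = "CITR", B77 = "CITR", B81 = "OLIVGR", B82 = "VINY",
      B23 = "OTHER", B33 = "OTHER", B36 = "OTHER", B37 = "OTHER",
      B44 = "OTHER", B51 = "OTHER", B52 = "OTHER", B53 = "OTHER",
      B54 = "OTHER", B55 = "OTHER", B83 = "OTHER", B84 = "OTHER"),
    aggregated12 = c(
      CERE = "CERE", LMAIZ = "LMAIZ", PARI = "PARI", PULS = "PULS",
      POTA = "POTA", SUGB = "SUGB", SUNF = "SUNF", LRAPE = "LRAPE",
      TEXT = "COTT", GRAS = "GRAS",
      TOMA_OVEG = "VEGFRU", APPL_OFRU = "VEGFRU", CITR = "VEGFRU",
      OLIVGR = "VEGFRU", VINY = "VEGFRU",
      OTHER = "OTHER"))
  out <- data.frame(source_code = names(m), target_code = unname(m))
  attr(out, "scheme") <- scheme
  out
}

#' Re-key crop-coded areas or points under a classification mapping
#'
#' For an area table (has an `area_ha` column), areas of source classes
#' mapping to the same target are summed, conserving total area exactly.
#' For any other table, the `crop_code` column is simply replaced.
#' Unmapped source codes are an error naming the code.
#'
#' @param map a [reclass_map()] data.frame.
#' @param x data.frame with a `crop_code` column (and optionally
#'   `area_ha`).
#' @return re-keyed data.frame; attribute `n_targets` counts distinct
#'   target codes present.
#' @export
reclassify <- function(map, x) {
  lut <- setNames(map$target_code, map$source_code)
  unknown <- setdiff(unique(x$crop_code), names(lut))
  if (length(unknown))
    stop("crop code(s) not in ", attr(map, "scheme") %||% "reclass",
         " map: ", paste(unknown, collapse = ", "))
  x$crop_code <- unname(lut[x$crop_code])
  if ("area_ha" %in% names(x)) {
    keys <- setdiff(names(x), "area_ha")
    x <- stats::aggregate(x["area_ha"], x[keys], sum)
  }
  attr(x, "n_targets") <- length(unique(x$crop_code))
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
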