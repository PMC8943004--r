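#' Biome codes, barrier/hospitable categories and record-level assignment
#'
#' Terrestrial biome codes follow the WWF Terrestrial Ecoregions numbering
#' (1-14). Barriers — biomes offering little or no refuelling opportunity to
#' a crepuscular aerial insectivore — default to Deserts & Xeric Shrublands
#' (13), Mediterranean Forests, Woodlands & Scrub (12) and Tropical &
#' Subtropical Moist Broadleaf Forests (1, a soft barrier); the remaining
#' semi-open biomes are hospitable. The map is an editable data.frame so the
#' soft-barrier judgement can be revisited.
#'
#' @name biome
NULL

#' Default biome code table with barrier/hospitable categories
#'
#' @return data.frame with columns code, name, category.
#' @export
biome_code_table <- function() {
  data.frame(
    code = 1:14,
    name = c(
      "Tropical & Subtropical Moist Broadleaf Forests",
      "Tropical & Subtropical Dry Broadleaf Forests",
      "Tropical & Subtropical Coniferous Forests",
      "Temperate Broadleaf & Mixed Forests",
      "Temperate Conifer Forests",
      "Boreal Forests/Taiga",
      "Tropical & Subtropical Grasslands, Savannas & Shrublands",
      "Temperate Grasslands, Savannas & Shrublands",
      "Flooded Grasslands & Savannas",
      "Montane Grasslands & Shrublands",
      "Tundra",
      "Mediterranean Forests, Woodlands & Scrub",
      "Deserts & Xeric Shrublands",
      "Mangroves"
    ),
    category = c("barrier", "hospitable", "hospitable", "hospitable",
                 "hospitable", "hospitable", "hospitable", "hospitable",
                 "hospitable", "hospitable", "hospitable", "barrier",
                 "barrier", "hospitable")
  )
}

#' Map a biome code to its category
#'
#' @param code integer biome code(s).
#' @param map data.frame with columns code and category; rows with category
#'   "excluded" propagate exclusion downstream.
#' @return character vector of categories.
#' @export
categorize_biome <- function(code, map = biome_code_table()) {
  ok <- is.na(code) | code %in% map$code
  if (!all(ok)) {
    stop("biome code(s) not in category map: ",
         paste(unique(code[!ok]), collapse = ", "))
  }
  map$category[match(code, map$code)]
}

#' Drop records in singleton biomes
#'
#' Position estimates whose biome occurs fewer than `min_count` times within
#' a grouping (flyway or individual) are excluded from analysis: a single
#' visit to a biome supports no within-biome comparison.
#'
#' @param records data.frame with a `biome_code` column.
#' @param group optional grouping vector (default: one group).
#' @param min_count minimum occurrences to keep a biome (default 2).
#' @return `records` with rare-biome rows removed.
#' @export
exclude_singleton_biomes <- function(records, group = NULL, min_count = 2) {
  if (is.null(group)) group <- rep(1L, nrow(records))
  key <- paste(group, records$biome_code)
  counts <- table(key)
  keep <- is.na(records$biome_code) | counts[key] >= min_count
  records[keep, , drop = FALSE]
}

#' Assign biomes to position estimates
#'
#' GPS fixes are assigned by point sampling (the cell containing the fix);
#' geolocation estimates, whose positional error is large, by the zonal
#' majority within their 97.5% credible-interval box.
#'
#' @param positions data.frame with lon, lat and (for method "zonal")
#'   lon_lo, lon_hi, lat_lo, lat_hi CI bounds.
#' @param biome_raster categorical `ascii_grid` of biome codes.
#' @param method "point" or "zonal".
#' @param map category map, see [categorize_biome()].
#' @return `positions` with biome_code, biome_category, majority_fraction
#'   and tie_flag columns added.
#' @export
assign_biomes <- function(positions, biome_raster, method = c("point", "zonal"),
                          map = biome_code_table()) {
  method <- match.arg(method)
  n <- nrow(positions)
  code <- rep(NA_real_, n); frac <- rep(NA_real_, n); tie <- rep(FALSE, n)
  if (method == "point") {
    code <- sample_point(biome_raster, positions$lon, positions$lat)
    frac <- rep(1, n)
  } else {
    for (i in seq_len(n)) {
      z <- zonal_majority(biome_raster, positions$lon_lo[i], positions$lon_hi[i],
                          positions$lat_lo[i], positions$lat_hi[i])
      code[i] <- z$majority; frac[i] <- z$fraction; tie[i] <- z$tie
    }
  }
  positions$biome_code <- code
  positions$biome_category <- categorize_biome(code, map)
  positions$majority_fraction <- frac
  positions$tie_flag <- tie
  positions
}
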