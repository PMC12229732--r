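# Canonical column schema for regional agronomic record tables.
#
# Numeric soil/weather/production measurements plus categorical crop, season
# and soil-type labels and decimal-degree coordinates. Header matching is
# case-insensitive and alias-aware so files using "Lat"/"Long"/"Crops" load
# without renaming.

agri_numeric_columns <- function() {
  c("ph", "ec", "n", "p", "k", "temperature", "rainfall",
    "area", "production", "yield", "latitude", "longitude")
}

agri_categorical_columns <- function() {
  c("crop", "season", "soil")
}

agri_all_columns <- function() {
  c("ph", "ec", "n", "p", "k", "latitude", "longitude", "crop", "season",
    "temperature", "rainfall", "area", "production", "yield", "soil")
}

#' Default detection feature set
#'
#' The ten numeric agronomic measurements used by the non-spatial detectors.
#' Latitude and longitude are deliberately excluded: they are routed only to
#' the spatially aware methods, and categorical columns never enter distance
#' computations.
#'
#' @return Character vector of canonical feature names.
#' @export
agri_feature_names <- function() {
  c("n", "p", "k", "ph", "ec", "temperature", "rainfall",
    "area", "production", "yield")
}

# Known label vocabularies (season per the regional cropping calendar; soil
# types and crops as they appear in the study region).
agri_vocabularies <- function() {
  list(
    season = c("Kharif", "Rabi", "Summer"),
    soil = c("Sandy", "Loam", "Clay", "Clay loam", "Red", "Black", "Alluvial"),
    crop = c("Jowar", "Maize", "Paddy", "Cowpea", "Groundnut", "Ragi", "Sunflower")
  )
}

# header alias -> canonical name (keys lower-case, stripped of non-alnum)
agri_header_aliases <- function() {
  c(
    "ph" = "ph", "ec" = "ec", "n" = "n", "p" = "p", "k" = "k",
    "nitrogen" = "n", "phosphorus" = "p", "potassium" = "k",
    "lat" = "latitude", "latitude" = "latitude",
    "long" = "longitude", "lon" = "longitude", "longitude" = "longitude",
    "crop" = "crop", "crops" = "crop",
    "season" = "season", "soil" = "soil", "soiltype" = "soil",
    "temperature" = "temperature", "temp" = "temperature",
    "rainfall" = "rainfall", "rain" = "rainfall",
    "area" = "area", "production" = "production", "yield" = "yield"
  )
}

normalize_header <- function(x) {
  key <- gsub("[^a-z0-9]", "", tolower(x))
  aliases <- agri_header_aliases()
  out <- unname(aliases[key])
  ifelse(is.na(out), make.names(tolower(x)), out)
}
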