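## Bundled reference data: monthly climate tables, fitted crop-parameter
## sets and actual farm yields for the three Yunnan potato cropping
## seasons (spring, autumn, early spring).

.pg_extdata <- function(file) {
  path <- system.file("extdata", file, package = "potatogap")
  if (path == "") stop_pg("bundled data file '%s' not found", file)
  path
}

#' Bundled monthly climate table for one cropping season
#'
#' Monthly mean maximum/minimum temperature, monthly rainfall total,
#' monthly mean daily solar radiation and sunshine hours recorded by
#' on-site weather stations over three Yunnan potato cropping seasons:
#' spring (Mar-Sep), autumn (Aug-Dec) and early spring (Jan-May).
#'
#' @param season `"spring"`, `"autumn"` or `"early_spring"`.
#' @return a [monthly_climate()] object.
#' @export
#' @examples
#' season_summary(load_climate("spring"))
load_climate <- function(season = c("spring", "autumn", "early_spring")) {
  season <- match.arg(season)
  df <- read.csv(.pg_extdata(sprintf("climate_%s.csv", season)),
                 stringsAsFactors = FALSE)
  monthly_climate(season, df)
}

#' Bundled crop-parameter sets for three cultivars in three seasons
#'
#' The fitted model-parameter table for cultivars Yunshu 401, Yunshu 505
#' and Cooperation 88 in the spring, autumn and early-spring seasons:
#' canopy parameters (`wmax`, `tm`, `te`), partition parameters (`a_max`,
#' `tu`, `b`), radiation-use efficiency (`rue`, g/MJ), the potential
#' yield reported for each run (`reported_yield`, t/ha) and the observed
#' phenology (`emergence_day`, `maturity_day`, days after sowing).
#'
#' @return a `data.frame`, one row per season-genotype combination.
#' @seealso [crop_parameter_set()] to turn one row into a
#'   [crop_parameters()] object.
#' @export
load_parameter_sets <- function() {
  read.csv(.pg_extdata("parameter_sets.csv"), stringsAsFactors = FALSE)
}

#' Crop parameters for one bundled cultivar-season combination
#'
#' @param genotype `"Yunshu 401"`, `"Yunshu 505"` or `"Cooperation 88"`.
#' @param season `"spring"`, `"autumn"` or `"early_spring"`.
#' @param dry_matter_fraction,base_temperature passed to
#'   [crop_parameters()].
#' @return a [crop_parameters()] object with attributes `genotype`,
#'   `season`, `emergence_day`, `maturity_day` and `reported_yield`.
#' @export
#' @examples
#' crop_parameter_set("Yunshu 505", "spring")
crop_parameter_set <- function(genotype, season,
                               dry_matter_fraction = 0.20,
                               base_temperature = 2) {
  tab <- load_parameter_sets()
  row <- tab[tab$genotype == genotype & tab$season == season, , drop = FALSE]
  if (nrow(row) != 1L)
    stop_pg("no bundled parameter set for genotype '%s' in season '%s'",
            genotype, season)
  p <- crop_parameters(
    canopy = canopy_parameters(row$wmax, row$tm, row$te),
    partition = partition_parameters(row$a_max, row$tu, row$b),
    rue = row$rue,
    dry_matter_fraction = dry_matter_fraction,
    base_temperature = base_temperature)
  attr(p, "genotype") <- genotype
  attr(p, "season") <- season
  attr(p, "emergence_day") <- row$emergence_day
  attr(p, "maturity_day") <- row$maturity_day
  attr(p, "reported_yield") <- row$reported_yield
  p
}

#' Bundled season-by-genotype yield records
#'
#' The reported potential yields of the nine bundled cultivar-season runs
#' joined with the season-level actual farm yields (spring 19.6, autumn
#' 15.27, early spring 20.72 t/ha), ready for [gap_report()].
#'
#' @return a [season_yield_records()] table.
#' @export
#' @examples
#' gap_report(reference_yield_records())
reference_yield_records <- function() {
  tab <- load_parameter_sets()
  act <- read.csv(.pg_extdata("actual_yields.csv"), stringsAsFactors = FALSE)
  actual <- act$actual_yield[match(tab$season, act$season)]
  season_yield_records(tab$season, tab$genotype, tab$reported_yield, actual)
}

#' Write / read a crop-parameter set as JSON
#'
#' Serializes the seven-parameter vector with keys `wmax`, `tm`, `te`,
#' `a_max`, `tu`, `b`, `rue` plus `dry_matter_fraction` and
#' `base_temperature`; thermal-time units (degree C d) are recorded in a
#' `units` header field.
#'
#' @param params a [crop_parameters()] object.
#' @param path file path to write to / read from.
#' @return `write_parameters_json()` returns `path` invisibly;
#'   `read_parameters_json()` returns a [crop_parameters()] object.
#' @export
write_parameters_json <- function(params, path) {
  if (!inherits(params, "crop_parameters"))
    stop_pg("'params' must be a crop_parameters object")
  obj <- list(units = "thermal time in degree C d; rue in g/MJ",
              wmax = params$canopy$wmax, tm = params$canopy$tm,
              te = params$canopy$te, a_max = params$partition$a_max,
              tu = params$partition$tu, b = params$partition$b,
              rue = params$rue,
              dry_matter_fraction = params$dry_matter_fraction,
              base_temperature = params$base_temperature)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_parameters_json
#' @export
read_parameters_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  crop_parameters(
    canopy = canopy_parameters(obj$wmax, obj$tm, obj$te),
    partition = partition_parameters(obj$a_max, obj$tu, obj$b),
    rue = obj$rue,
    dry_matter_fraction = obj$dry_matter_fraction %||% 0.20,
    base_temperature = obj$base_temperature %||% 2)
}
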