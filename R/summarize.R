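#' Per-species change-percentage table
#'
#' Turns per-species areas (km^2) into the study's summary rows: the
#' percentage of the distribution removed by land-cover correction, and —
#' relative to the current LCC-corrected area — loss and gain percentages per
#' future scenario, nationally and within protected areas. Gain percentages
#' can exceed 100 (a small current range can more than double). Species with
#' zero current LCC-corrected area are flagged (`valid = FALSE`) and excluded
#' from aggregates.
#'
#' @param areas data.frame with one row per species and columns:
#'   `species`, `area_current_nolcc`, `area_current_lcc`,
#'   `area_current_nolcc_pa`, `area_current_lcc_pa`, and per scenario `s`
#'   in `scenarios`: `loss_<s>_nat`, `gain_<s>_nat`, `loss_<s>_pa`,
#'   `gain_<s>_pa` (areas, km^2).
#' @param scenarios future scenario ids (default `c("rcp45", "rcp85")`).
#' @return data.frame of percentage rows (class `species_change_table`).
#' @export
build_species_table <- function(areas, scenarios = c("rcp45", "rcp85")) {
  pct <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)
  out <- data.frame(
    species = areas$species,
    area_current_nolcc = areas$area_current_nolcc,
    area_current_lcc = areas$area_current_lcc,
    area_current_lcc_pa = areas$area_current_lcc_pa,
    reduced_pct_national = pct(areas$area_current_nolcc - areas$area_current_lcc,
                               areas$area_current_nolcc),
    reduced_pct_pa = pct(areas$area_current_nolcc_pa - areas$area_current_lcc_pa,
                         areas$area_current_nolcc_pa),
    valid = areas$area_current_lcc > 0
  )
  for (s in scenarios) {
    out[[paste0("loss_", s, "_nat")]] <- pct(areas[[paste0("loss_", s, "_nat")]],
                                             areas$area_current_lcc)
    out[[paste0("gain_", s, "_nat")]] <- pct(areas[[paste0("gain_", s, "_nat")]],
                                             areas$area_current_lcc)
    out[[paste0("loss_", s, "_pa")]] <- pct(areas[[paste0("loss_", s, "_pa")]],
                                            areas$area_current_lcc_pa)
    out[[paste0("gain_", s, "_pa")]] <- pct(areas[[paste0("gain_", s, "_pa")]],
                                            areas$area_current_lcc_pa)
  }
  class(out) <- c("species_change_table", "data.frame")
  out
}

#' Summary statistics for one table column
#'
#' Median (midpoint of central order statistics for even n), 25th/75th
#' percentiles by the linear-interpolation convention (type 7), mean, and
#' standard deviation (n - 1 denominator), over valid rows.
#'
#' @param rows data.frame (e.g. [build_species_table()] output or the
#'   packaged study table).
#' @param column column name.
#' @return list with `median`, `q25`, `q75`, `mean`, `sd`, `n`.
#' @export
column_summary <- function(rows, column) {
  x <- rows[[column]]
  if (is.null(x)) stop("no such column: ", column)
  if (!is.null(rows$valid)) x <- x[rows$valid]
  x <- x[!is.na(x)]
  if (length(x) < 2) stop("need at least 2 valid values in ", column)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(median = q[2], q25 = q[1], q75 = q[3],
       mean = mean(x), sd = stats::sd(x), n = length(x))
}

#' Paired contrast between two columns
#'
#' Mean difference (b - a) with a two-sided paired t-test (n - 1 degrees of
#' freedom), as used to compare scenario severities across species.
#'
#' @param rows data.frame.
#' @param column_a,column_b paired column names (difference is b - a).
#' @return list with `mean_diff`, `t`, `p`, `df`, `n`.
#' @export
paired_contrast <- function(rows, column_a, column_b) {
  a <- rows[[column_a]]; b <- rows[[column_b]]
  if (is.null(a) || is.null(b)) stop("unknown column name")
  if (!is.null(rows$valid)) { a <- a[rows$valid]; b <- b[rows$valid] }
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2) stop("need at least 2 paired values")
  d <- b - a
  if (stats::sd(d) == 0) {
    return(list(mean_diff = mean(d), t = NA_real_,
                p = if (all(d == 0)) 1 else NA_real_,
                df = length(d) - 1, n = length(d)))
  }
  tt <- stats::t.test(b, a, paired = TRUE)
  list(mean_diff = mean(d), t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), n = length(d))
}

#' The study's per-species results table (packaged fixture)
#'
#' The printed 19-species table of current LCC-corrected areas, LCC reduction
#' percentages and per-scenario loss/gain percentages (national and within
#' protected areas), as shipped with the package for reproducing the
#' cross-species aggregates.
#'
#' @return data.frame with 19 rows.
#' @export
load_table2_fixture <- function() {
  path <- system.file("extdata", "table2_dipterocarps.csv",
                      package = "dipterocarpSDM")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
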