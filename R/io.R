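#' Required plot-table columns (internal dictionary)
#'
#' Column dictionary of the plot-level trial table: identifiers (`trial`,
#' `block`, `treatment`, `trial_type`, `site_id`, `plot_id`), doses
#' (`dose_N`, `dose_P`, `dose_K`, kg ha-1 elemental), soil covariates
#' (`sand`, `silt`, `clay` percent, `c_pct`, `ph`, `p_m3`, `k_m3`, `ca_m3`,
#' `mg_m3`, `al_m3` mg kg-1, soil-type memberships `mem_*`), management
#' (`density`, `season_length`, `planting_date`, `harvest_date`,
#' `maturity_class`) and targets (`yield` Mg ha-1, `frac_S`, `frac_M`,
#' `frac_L`, `sg`).
#'
#' @return Character vector of required column names.
#' @export
trial_table_columns <- function() {
  c("trial", "block", "treatment", "trial_type", "site_id", "plot_id",
    "dose_N", "dose_P", "dose_K",
    "sand", "silt", "clay", "c_pct", "ph",
    "p_m3", "k_m3", "ca_m3", "mg_m3", "al_m3",
    "mem_loamy_gleyed", "mem_sandy_gleyed", "mem_podzolized",
    "density", "season_length", "planting_date", "harvest_date",
    "maturity_class",
    "yield", "frac_S", "frac_M", "frac_L", "sg")
}

#' Read a plot-level trial table, optionally mapping an external dialect
#'
#' Reads a CSV of plot records and renames columns from an external dialect
#' (e.g. a published supplementary table) to the internal dictionary of
#' [trial_table_columns()] via `column_map`. Dates are parsed as ISO-8601.
#' Missing optional columns are tolerated; missing required columns raise
#' an error naming them.
#'
#' @param path CSV file path.
#' @param column_map Named character vector mapping internal names (the
#'   names) to the file's column names (the values); unmapped columns are
#'   kept as-is.
#' @param required Columns that must be present after mapping (default:
#'   the full dictionary).
#' @return Data frame in the internal dialect.
#' @export
read_trial_table <- function(path, column_map = NULL,
                             required = trial_table_columns()) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    missing_src <- setdiff(unname(column_map), names(tab))
    if (length(missing_src)) {
      stop("column_map refers to absent column(s): ",
           paste(missing_src, collapse = ", "))
    }
    idx <- match(unname(column_map), names(tab))
    names(tab)[idx] <- names(column_map)
  }
  absent <- setdiff(required, names(tab))
  if (length(absent)) {
    stop("trial table lacks required column(s): ",
         paste(absent, collapse = ", "))
  }
  for (cl in intersect(c("planting_date", "harvest_date"), names(tab))) {
    tab[[cl]] <- as.Date(tab[[cl]])
  }
  tab
}
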