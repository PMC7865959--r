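#' Measurement-table input and output
#'
#' CSV schemas for the two measurement tables. All files use micrometre
#' units exclusively (lengths um, areas um^2, volumes um^3), comma
#' separators, '.' decimals, UTF-8 and a mandatory header.
#'
#' Profile tables (2D): `spine_id`, `micrograph_id`, `head_area_um2`,
#' `psd_length_um`, `sal_length_um`, `excluded`; optional positional
#' columns `center_x_um`, `center_y_um`, `radius_um` are preserved.
#'
#' Spine tables (3D): `spine_id`, `volume_um3`, `sas_um2`, `on_shaft`,
#' `x`, `y`, `z`. Coordinates may be empty for density-only workflows that
#' never section or count the table geometrically.
#'
#' @name table_io
#' @keywords internal
NULL

.require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop("'", path, "' is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

.row_errors <- function(bad, what) {
  if (any(bad, na.rm = TRUE)) {
    rows <- which(bad)
    stop(what, " in row(s): ",
         paste(utils::head(rows, 20), collapse = ", "),
         if (length(rows) > 20) " ..." else "", call. = FALSE)
  }
}

.check_numeric_col <- function(df, col, path, positive = TRUE,
                               allow_na = FALSE) {
  v <- df[[col]]
  # a column that is entirely empty is read as logical NA; treat as numeric
  if (is.logical(v) && all(is.na(v))) v <- as.numeric(v)
  if (!is.numeric(v)) {
    stop("'", path, "' column ", col, " is not numeric", call. = FALSE)
  }
  if (!allow_na) .row_errors(is.na(v), paste0("missing ", col))
  if (positive) .row_errors(!is.na(v) & v <= 0, paste0("non-positive ", col))
  v
}

#' Read a 2D profile measurement table
#'
#' @param path CSV file path.
#' @return Validated `data.frame` of profiles. Rows violating the
#'   measurement invariants (non-positive sizes, PSD longer than SAL) abort
#'   the read with the offending row indices.
#' @export
read_profile_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("'", path, "' contains no data rows", call. = FALSE)
  .require_columns(df, c("spine_id", "micrograph_id", "head_area_um2",
                         "psd_length_um", "sal_length_um", "excluded"), path)
  .check_numeric_col(df, "head_area_um2", path)
  .check_numeric_col(df, "psd_length_um", path)
  .check_numeric_col(df, "sal_length_um", path)
  df$excluded <- as.logical(df$excluded)
  .row_errors(is.na(df$excluded), "invalid 'excluded' flag")
  .row_errors(df$psd_length_um > df$sal_length_um,
              "PSD length exceeds SAL")
  df
}

#' Write a 2D profile measurement table
#'
#' @param profiles Profile `data.frame` (or a `"micrograph_set"`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(profiles, path) {
  if (inherits(profiles, "micrograph_set")) profiles <- profiles$profiles
  core <- c("spine_id", "micrograph_id", "head_area_um2", "psd_length_um",
            "sal_length_um", "excluded")
  extra <- intersect(c("center_x_um", "center_y_um", "radius_um"),
                     names(profiles))
  utils::write.csv(profiles[, c(core, extra), drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a 3D reconstructed-spine measurement table
#'
#' Head radii are derived from volumes under the sphere model on read. The
#' spherical-cap bound `sas_um2 <= 4 pi r^2` is enforced for spine-head
#' rows; shaft rows (`on_shaft` true) may have empty volumes. Missing
#' coordinates are accepted (density-only workflows) but any geometric
#' operation on the table will then refuse to run.
#'
#' @param path CSV file path.
#' @return Validated spine table (class `"spine_table"`).
#' @export
read_spine_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("'", path, "' contains no data rows", call. = FALSE)
  .require_columns(df, c("spine_id", "volume_um3", "sas_um2", "on_shaft",
                         "x", "y", "z"), path)
  df$on_shaft <- as.logical(df$on_shaft)
  .row_errors(is.na(df$on_shaft), "invalid 'on_shaft' flag")
  .check_numeric_col(df, "sas_um2", path)
  v <- .check_numeric_col(df, "volume_um3", path, allow_na = TRUE)
  .row_errors(!df$on_shaft & is.na(v), "missing volume for spine-head row")
  for (cc in c("x", "y", "z")) {
    df[[cc]] <- .check_numeric_col(df, cc, path, positive = FALSE,
                                   allow_na = TRUE)
  }
  out <- data.frame(
    spine_id = df$spine_id,
    x = df$x, y = df$y, z = df$z,
    head_volume_um3 = df$volume_um3,
    head_radius_um = ifelse(is.na(df$volume_um3), NA_real_,
                            (3 * df$volume_um3 / (4 * pi))^(1 / 3)),
    sas_um2 = df$sas_um2,
    on_shaft = df$on_shaft,
    stringsAsFactors = FALSE
  )
  heads <- !out$on_shaft
  .row_errors(heads & out$sas_um2 > 4 * pi * out$head_radius_um^2 *
                (1 + 1e-9),
              "SAS exceeds the spherical-cap bound 4*pi*r^2")
  class(out) <- c("spine_table", "data.frame")
  out
}

#' Write a 3D spine measurement table
#'
#' @param spines Spine table (or a `"neuropil"` object).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spine_table <- function(spines, path) {
  if (inherits(spines, "neuropil")) spines <- spines$spines
  out <- data.frame(spine_id = spines$spine_id,
                    volume_um3 = spines$head_volume_um3,
                    sas_um2 = spines$sas_um2,
                    on_shaft = spines$on_shaft,
                    x = spines$x, y = spines$y, z = spines$z)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
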