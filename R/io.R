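# Delimited-text readers for the five input tables.
#
# All readers accept a `columns` mapping (canonical name -> column name in the
# file) so externally produced tables need not be renamed, and a `delim`
# (default comma; tab accepted).

read_delim_quiet <- function(path, delim = ",") {
  if (!file.exists(path)) {
    np_abort(sprintf("input file not found: %s", path), "netpharm_io_error")
  }
  readr::read_delim(
    path,
    delim = delim, show_col_types = FALSE, progress = FALSE,
    trim_ws = TRUE
  )
}

apply_column_mapping <- function(df, columns, table) {
  if (is.null(columns)) {
    return(df)
  }
  for (canonical in names(columns)) {
    src <- columns[[canonical]]
    if (!src %in% names(df)) {
      np_abort(
        sprintf("table '%s': mapped column '%s' not found in file", table, src),
        class = "netpharm_schema_error"
      )
    }
    names(df)[names(df) == src] <- canonical
  }
  df
}

#' Read a compound table
#'
#' Expects columns `compound_id`, `name`, `chem_class`, plus one numeric
#' abundance column per tissue. Abundances are relative intensities in
#' arbitrary units; zero or missing means not detected in that tissue.
#'
#' @param path file path.
#' @param delim field delimiter (default `","`; `"\t"` for TSV).
#' @param columns optional named list mapping canonical column names to the
#'   names used in the file.
#' @param tissues optional character vector naming the tissue columns;
#'   defaults to every column other than the three identity columns.
#' @return tibble with attribute `"tissues"`; gene of record is `compound_id`,
#'   unique within the table; abundances validated non-negative.
#' @export
read_compound_table <- function(path, delim = ",", columns = NULL,
                                tissues = NULL) {
  df <- apply_column_mapping(read_delim_quiet(path, delim), columns, "compounds")
  check_required_columns(df, c("compound_id", "name", "chem_class"), "compounds")
  df$compound_id <- trimws(as.character(df$compound_id))
  df$chem_class <- trimws(as.character(df$chem_class))
  check_unique_keys(df, "compound_id", "compounds")
  tissues <- tissues %||% setdiff(names(df), c("compound_id", "name", "chem_class"))
  if (length(tissues) == 0) {
    np_abort("table 'compounds' has no tissue abundance columns",
      class = "netpharm_schema_error"
    )
  }
  for (t in tissues) {
    df[[t]] <- as.numeric(df[[t]])
    df[[t]][is.na(df[[t]])] <- 0
    check_range(df, t, 0, NA, "compounds")
  }
  out <- as_tibble(df[c("compound_id", "name", "chem_class", tissues)])
  attr(out, "tissues") <- tissues
  out
}

#' Read an ADMET property table
#'
#' One row per compound with the predicted properties named by
#' [admet_fields()]. Bounded fields are validated against their ranges
#' (scores in \[0, 1\], PPB in \[0, 100\], counts non-negative).
#'
#' @inheritParams read_compound_table
#' @return validated tibble, one profile per `compound_id`.
#' @export
read_admet_table <- function(path, delim = ",", columns = NULL) {
  df <- apply_column_mapping(read_delim_quiet(path, delim), columns, "admet")
  check_required_columns(df, c("compound_id", admet_fields()), "admet")
  df$compound_id <- trimws(as.character(df$compound_id))
  check_unique_keys(df, "compound_id", "admet")
  bounds <- admet_bounds()
  for (f in admet_fields()) {
    df[[f]] <- as.numeric(df[[f]])
    check_range(df, f, bounds[[f]][1], bounds[[f]][2], "admet")
  }
  as_tibble(df[c("compound_id", admet_fields())])
}

#' Read compound-to-target predictions
#'
#' @inheritParams read_compound_table
#' @return tibble with `compound_id`, `target_symbol`, `probability` in
#'   \[0, 1\]; `(compound_id, target_symbol)` pairs unique. Target symbols are
#'   trimmed, case-sensitive opaque keys; no alias resolution is attempted.
#' @export
read_target_predictions <- function(path, delim = ",", columns = NULL) {
  df <- apply_column_mapping(read_delim_quiet(path, delim), columns, "predictions")
  check_required_columns(df, c("compound_id", "target_symbol", "probability"),
    "predictions"
  )
  df$compound_id <- trimws(as.character(df$compound_id))
  df$target_symbol <- trimws(as.character(df$target_symbol))
  df$probability <- as.numeric(df$probability)
  check_unique_keys(df, c("compound_id", "target_symbol"), "predictions")
  check_range(df, "probability", 0, 1, "predictions")
  as_tibble(df[c("compound_id", "target_symbol", "probability")])
}

#' Read target-to-pathway annotations
#'
#' The table is assumed to be enrichment-filtered upstream (e.g. FDR < 0.05);
#' no enrichment statistics are recomputed here. Rows duplicated at the
#' `(target_symbol, pathway_id)` level are collapsed with a message reporting
#' the collapsed count, since multiple compounds can contribute the same
#' annotation.
#'
#' @inheritParams read_compound_table
#' @return tibble with `target_symbol`, `pathway_id`, `pathway_name`; pairs
#'   unique after collapsing.
#' @export
read_pathway_annotations <- function(path, delim = ",", columns = NULL) {
  df <- apply_column_mapping(read_delim_quiet(path, delim), columns, "annotations")
  check_required_columns(df, c("target_symbol", "pathway_id"), "annotations")
  if (!"pathway_name" %in% names(df)) df$pathway_name <- df$pathway_id
  df$target_symbol <- trimws(as.character(df$target_symbol))
  df$pathway_id <- trimws(as.character(df$pathway_id))
  df <- as_tibble(df[c("target_symbol", "pathway_id", "pathway_name")])
  n0 <- nrow(df)
  df <- distinct(df, .data$target_symbol, .data$pathway_id, .keep_all = TRUE)
  if (nrow(df) < n0) {
    inform(sprintf(
      "annotations: collapsed %d duplicated (target, pathway) row(s)",
      n0 - nrow(df)
    ))
  }
  df
}

#' Read pathway-to-disease-category mappings
#'
#' @inheritParams read_compound_table
#' @return tibble with `pathway_id`, `disease_category`; pairs unique.
#' @export
read_disease_mappings <- function(path, delim = ",", columns = NULL) {
  df <- apply_column_mapping(read_delim_quiet(path, delim), columns, "diseases")
  check_required_columns(df, c("pathway_id", "disease_category"), "diseases")
  df$pathway_id <- trimws(as.character(df$pathway_id))
  df$disease_category <- trimws(as.character(df$disease_category))
  check_unique_keys(df, c("pathway_id", "disease_category"), "diseases")
  as_tibble(df[c("pathway_id", "disease_category")])
}

#' Read all five input tables
#'
#' @param paths named list/vector with elements `compounds`, `admet`,
#'   `predictions`, `annotations`, `diseases` giving file locations.
#' @param delim field delimiter shared by all tables.
#' @param columns optional named list of per-table column mappings, e.g.
#'   `list(admet = list(qed = "QED"))`.
#' @return named list of the five validated tibbles.
#' @export
read_tables <- function(paths, delim = ",", columns = list()) {
  required <- c("compounds", "admet", "predictions", "annotations", "diseases")
  missing <- setdiff(required, names(paths))
  if (length(missing) > 0) {
    np_abort(
      sprintf("paths must name all five tables; missing: %s",
        paste(missing, collapse = ", ")
      ),
      class = "netpharm_io_error"
    )
  }
  list(
    compounds = read_compound_table(paths[["compounds"]], delim, columns$compounds),
    admet = read_admet_table(paths[["admet"]], delim, columns$admet),
    predictions = read_target_predictions(paths[["predictions"]], delim, columns$predictions),
    annotations = read_pathway_annotations(paths[["annotations"]], delim, columns$annotations),
    diseases = read_disease_mappings(paths[["diseases"]], delim, columns$diseases)
  )
}
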