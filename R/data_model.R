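# Domain tables, their schemas and invariant checks.
#
# Five tabular inputs drive the pipeline:
#   compounds    - one row per metabolite: id, name, chemical class, and one
#                  abundance column per tissue (0 / absent = not detected)
#   admet        - one row per compound: predicted ADMET / drug-likeness
#                  properties used by the rule screen
#   predictions  - compound -> target predictions with a probability score
#   annotations  - target -> pathway annotations (assumed already
#                  enrichment-filtered upstream)
#   diseases     - pathway -> disease-category mapping
#
# Readers return validated tibbles; invariant violations are reported with
# row numbers and never silently repaired.

#' ADMET property fields understood by the screen
#'
#' @return character vector of canonical ADMET column names.
#' @export
admet_fields <- function() {
  c(
    "qed", "lipinski_violations", "caco2", "hia", "ppb", "fu", "cl",
    "h_ht", "herg", "f20", "f30", "ames", "fsp3", "mce18",
    "pains_alerts", "golden_triangle_violations"
  )
}

# closed [lo, hi] bounds per field; NA = unbounded on that side
admet_bounds <- function() {
  list(
    qed = c(0, 1), lipinski_violations = c(0, NA), caco2 = c(NA, NA),
    hia = c(0, 1), ppb = c(0, 100), fu = c(0, NA), cl = c(0, NA),
    h_ht = c(0, 1), herg = c(0, 1), f20 = c(0, 1), f30 = c(0, 1),
    ames = c(0, 1), fsp3 = c(0, 1), mce18 = c(0, NA),
    pains_alerts = c(0, NA), golden_triangle_violations = c(0, NA)
  )
}

check_required_columns <- function(df, required, table) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    np_abort(
      sprintf(
        "table '%s' is missing required column(s): %s",
        table, paste(missing, collapse = ", ")
      ),
      class = "netpharm_schema_error"
    )
  }
  invisible(df)
}

check_unique_keys <- function(df, key_cols, table) {
  keys <- do.call(paste, c(df[key_cols], sep = "\r"))
  dup <- duplicated(keys)
  if (any(dup)) {
    bad <- unique(do.call(paste, c(df[dup, key_cols, drop = FALSE], sep = ", ")))
    rows <- which(keys %in% keys[dup])
    np_abort(
      sprintf(
        "table '%s' has duplicated key(s) [%s]: %s (rows %s)",
        table, paste(key_cols, collapse = ", "),
        paste(bad, collapse = "; "), paste(rows, collapse = ", ")
      ),
      class = "netpharm_validation_error"
    )
  }
  invisible(df)
}

check_range <- function(df, col, lo, hi, table) {
  x <- df[[col]]
  bad <- !is.na(x) & ((!is.na(lo) & x < lo) | (!is.na(hi) & x > hi))
  if (any(bad)) {
    np_abort(
      sprintf(
        "table '%s', column '%s': %d value(s) outside [%s, %s] (rows %s; e.g. %s)",
        table, col, sum(bad),
        ifelse(is.na(lo), "-Inf", lo), ifelse(is.na(hi), "Inf", hi),
        paste(head(which(bad), 5), collapse = ", "), x[which(bad)[1]]
      ),
      class = "netpharm_validation_error"
    )
  }
  invisible(df)
}

#' Tissue labels of a compound table
#'
#' @param compounds a compound tibble as returned by [read_compound_table()].
#' @return character vector of tissue column names.
#' @export
tissue_labels <- function(compounds) {
  attr(compounds, "tissues") %||% setdiff(
    names(compounds), c("compound_id", "name", "chem_class")
  )
}
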