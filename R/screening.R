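# Compound-level ADMET / drug-likeness screen, target probability filter and
# tissue composition summaries.

#' Default ADMET screening criteria
#'
#' The default rule set follows the ADMETlab "excellent" bands commonly used
#' to shortlist natural products with fine drug-likeness and low predicted
#' toxicity: QED >= 0.67, fewer than 2 Lipinski violations, Caco-2
#' permeability > -5.15 log cm/s, each toxicity/absorption risk score
#' (HIA, H-HT, hERG, F20%, F30%, Ames) <= 0.3, PPB <= 90%, Fu >= 5%,
#' CL >= 5 mL/min/kg, Fsp3 >= 0.42, MCE-18 > 45, zero PAINS alerts and zero
#' Golden Triangle violations. A compound passes only if it satisfies every
#' enabled rule.
#'
#' @return a `screen_criteria` tibble with columns `field`, `op`
#'   (`ge`, `gt`, `le`, `lt`, `eq`), `value`, `enabled`.
#' @export
default_screen_criteria <- function() {
  screen_criteria(tibble(
    field = c(
      "qed", "lipinski_violations", "caco2", "hia", "ppb", "fu", "cl",
      "h_ht", "herg", "f20", "f30", "ames", "fsp3", "mce18",
      "pains_alerts", "golden_triangle_violations"
    ),
    op = c(
      "ge", "lt", "gt", "le", "le", "ge", "ge",
      "le", "le", "le", "le", "le", "ge", "gt",
      "eq", "eq"
    ),
    value = c(
      0.67, 2, -5.15, 0.3, 90, 5, 5,
      0.3, 0.3, 0.3, 0.3, 0.3, 0.42, 45,
      0, 0
    ),
    enabled = TRUE
  ))
}

#' Construct (and validate) a screening rule set
#'
#' @param rules a data frame with columns `field`, `op`, `value` and
#'   optionally `enabled` (default `TRUE`). Every enabled `field` must be one
#'   of [admet_fields()]; `op` is one of `ge`, `gt`, `le`, `lt`, `eq`.
#' @return a validated `screen_criteria` tibble.
#' @export
screen_criteria <- function(rules) {
  rules <- as_tibble(rules)
  check_required_columns(rules, c("field", "op", "value"), "criteria")
  if (!"enabled" %in% names(rules)) rules$enabled <- TRUE
  bad_field <- setdiff(rules$field[rules$enabled], admet_fields())
  if (length(bad_field) > 0) {
    np_abort(
      sprintf("unknown ADMET field(s) in criteria: %s", paste(bad_field, collapse = ", ")),
      class = "netpharm_validation_error"
    )
  }
  bad_op <- setdiff(rules$op, c("ge", "gt", "le", "lt", "eq"))
  if (length(bad_op) > 0) {
    np_abort(sprintf("unknown comparator(s): %s", paste(bad_op, collapse = ", ")),
      class = "netpharm_validation_error"
    )
  }
  if (any(!is.finite(rules$value))) {
    np_abort("criteria thresholds must be finite", "netpharm_validation_error")
  }
  check_unique_keys(rules, "field", "criteria")
  structure(rules[c("field", "op", "value", "enabled")],
    class = c("screen_criteria", class(rules))
  )
}

#' Load screening criteria from a YAML or JSON file
#'
#' The file holds a mapping keyed by ADMET field name, each entry an
#' `{op, value, enabled}` block, e.g. `qed: {op: ge, value: 0.67}`.
#' Fields not mentioned keep their default rule; `enabled: false` switches a
#' default rule off.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file path.
#' @param base criteria to override (default [default_screen_criteria()]).
#' @return a `screen_criteria` tibble.
#' @export
read_screen_criteria <- function(path, base = default_screen_criteria()) {
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  rules <- as_tibble(base)
  for (field in names(spec)) {
    entry <- spec[[field]]
    i <- match(field, rules$field)
    if (is.na(i)) {
      rules <- rbind(rules, tibble(
        field = field, op = entry$op %||% "ge",
        value = as.numeric(entry$value %||% 0),
        enabled = isTRUE(entry$enabled %||% TRUE)
      ))
    } else {
      if (!is.null(entry$op)) rules$op[i] <- entry$op
      if (!is.null(entry$value)) rules$value[i] <- as.numeric(entry$value)
      if (!is.null(entry$enabled)) rules$enabled[i] <- isTRUE(entry$enabled)
    }
  }
  screen_criteria(rules)
}

compare_rule <- function(x, op, value) {
  switch(op,
    ge = x >= value,
    gt = x > value,
    le = x <= value,
    lt = x < value,
    eq = x == value
  )
}

#' Apply the ADMET/drug-likeness screen
#'
#' A compound passes iff it satisfies **all** enabled rules (ties at a `ge`/
#' `le` threshold pass; `gt`/`lt` are strict). A compound with a missing value
#' for an enabled rule fails that rule with reason `"missing"`.
#'
#' @param profiles ADMET tibble as returned by [read_admet_table()].
#' @param criteria a `screen_criteria` rule set
#'   (default [default_screen_criteria()]).
#' @return list with `passing` (character vector of compound ids, input
#'   order) and `report` (tibble `compound_id`, `rule`, `reason` with one row
#'   per failed rule per rejected compound).
#' @export
apply_admet_screen <- function(profiles, criteria = default_screen_criteria()) {
  criteria <- screen_criteria(criteria)
  active <- criteria[criteria$enabled, , drop = FALSE]
  if (nrow(profiles) == 0) {
    warn("apply_admet_screen: empty profile set")
    return(list(
      passing = character(),
      report = tibble(compound_id = character(), rule = character(), reason = character())
    ))
  }
  check_required_columns(profiles, c("compound_id", active$field), "admet")
  fails <- vector("list", nrow(active))
  ok <- rep(TRUE, nrow(profiles))
  for (j in seq_len(nrow(active))) {
    x <- profiles[[active$field[j]]]
    pass <- compare_rule(x, active$op[j], active$value[j])
    missing <- is.na(x)
    pass[missing] <- FALSE
    ok <- ok & pass
    if (any(!pass)) {
      fails[[j]] <- tibble(
        compound_id = profiles$compound_id[!pass],
        rule = active$field[j],
        reason = ifelse(missing[!pass], "missing", "failed")
      )
    }
  }
  report <- bind_rows(fails)
  if (nrow(report) > 0) {
    report <- arrange(report, match(.data$compound_id, profiles$compound_id), .data$rule)
  }
  list(passing = profiles$compound_id[ok], report = report)
}

#' Filter predicted targets by interaction probability
#'
#' Retains (compound, target) pairs with probability **strictly greater** than
#' the threshold; the target set is the union over retained pairs.
#'
#' @param predictions prediction tibble (`compound_id`, `target_symbol`,
#'   `probability`).
#' @param threshold probability cutoff in `[0, 1)`; default 0.1.
#' @return list with `targets` (sorted unique symbols) and `support` (the
#'   retained prediction rows).
#' @export
filter_targets <- function(predictions, threshold = 0.1) {
  if (!is.numeric(threshold) || threshold < 0 || threshold >= 1) {
    np_abort("threshold must lie in [0, 1)", "netpharm_usage_error")
  }
  keep <- predictions[!is.na(predictions$probability) &
    predictions$probability > threshold, , drop = FALSE]
  list(targets = sort(unique(keep$target_symbol)), support = as_tibble(keep))
}

#' Per-tissue chemical-class composition
#'
#' Counts the compounds detected (abundance > 0) in a tissue and tabulates
#' them by chemical class; percentages are rounded half-up to two decimals.
#'
#' @param compounds compound tibble (see [read_compound_table()]).
#' @param tissue tissue label (one of [tissue_labels()]).
#' @return tibble (`chem_class`, `count`, `percent`) sorted by decreasing
#'   count, with attributes `tissue` and `total_detected`.
#' @export
composition_summary <- function(compounds, tissue) {
  tissues <- tissue_labels(compounds)
  if (!tissue %in% tissues) {
    np_abort(
      sprintf(
        "unknown tissue '%s'; known tissues: %s",
        tissue, paste(tissues, collapse = ", ")
      ),
      class = "netpharm_usage_error"
    )
  }
  detected <- compounds[!is.na(compounds[[tissue]]) & compounds[[tissue]] > 0, , drop = FALSE]
  if (nrow(detected) == 0) {
    np_abort(sprintf("no compounds detected in tissue '%s'", tissue),
      class = "netpharm_usage_error"
    )
  }
  out <- detected |>
    count(.data$chem_class, name = "count") |>
    mutate(percent = percent_of(.data$count, nrow(detected))) |>
    arrange(desc(.data$count), .data$chem_class)
  attr(out, "tissue") <- tissue
  attr(out, "total_detected") <- nrow(detected)
  out
}
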