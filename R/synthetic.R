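# Synthetic input generator with planted ground truth.
#
# Emulates the five input tables of a widely-targeted-metabolomics /
# network-pharmacology study: a compound panel with per-tissue abundances, an
# ADMET property table with a controlled pass fraction, compound->target
# predictions with Beta-distributed probabilities, target->pathway
# annotations following a bipartite block model (planted functional modules
# with one boosted hub target per block), and pathway->disease mappings
# concentrated on one block per disease. The bipartite block model keeps the
# one-mode projection step on the test path: the planted communities exist in
# the target-pathway layer, exactly where a real study's structure lives.
#
# One RNG substream per table (derived from the master seed) ensures that
# regenerating one table never perturbs the others.

#' Synthetic-data configuration
#'
#' Defaults mirror the scale of a single-herb network-pharmacology study:
#' 200 screened compounds, 167 targets, 63 enriched pathways, 10 disease
#' categories and 5 functional modules. Block structure is controlled by
#' `p_in`/`p_out` (the probability that a target annotates a pathway inside /
#' outside its block); one designated hub per block annotates in-block
#' pathways with probability `min(1, hub_boost * p_in)`.
#'
#' @param seed master seed; every table draws from its own substream.
#' @param n_compounds,n_targets,n_pathways,n_diseases,n_blocks positive counts;
#'   `n_blocks` must not exceed `n_targets`, `n_pathways` or `n_diseases`.
#' @param p_in,p_out in-/out-of-block annotation probabilities.
#' @param hub_boost multiplier on the hub target's in-block annotation
#'   probability.
#' @param admet_pass_fraction expected fraction of compounds passing
#'   [default_screen_criteria()] (pass/fail is drawn per compound, so the
#'   observed fraction varies within binomial error).
#' @param prob_dist length-2 vector `c(alpha, beta)` of the Beta distribution
#'   for compound-target probabilities.
#' @param tissue_labels abundance column names of the compound table.
#' @param class_weights named sampling weights over chemical classes.
#' @param disease_purity fraction of each disease's pathway links drawn from
#'   its dominant block (>= 0.8 keeps diseases block-concentrated).
#' @param links_per_disease pathway links per disease; default
#'   `max(3, ceiling(n_pathways / n_diseases))`.
#' @param detect_prob probability a compound is detected in a given tissue.
#' @param mean_targets_per_compound mean number of predicted targets per
#'   compound.
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         n_compounds = 200L,
                         n_targets = 167L,
                         n_pathways = 63L,
                         n_diseases = 10L,
                         n_blocks = 5L,
                         p_in = 0.6,
                         p_out = 0.02,
                         hub_boost = 3,
                         admet_pass_fraction = 0.39,
                         prob_dist = c(2, 5),
                         tissue_labels = c("StR", "StS", "StF"),
                         class_weights = NULL,
                         disease_purity = 0.9,
                         links_per_disease = NULL,
                         detect_prob = 0.9,
                         mean_targets_per_compound = 8) {
  class_weights <- class_weights %||% c(
    lipid = 0.20, alkaloid = 0.17, phenolic_acid = 0.12, amino_acid = 0.12,
    organic_acid = 0.10, flavonoid = 0.08, nucleotide = 0.07, lignan = 0.05,
    other = 0.09
  )
  cfg <- list(
    seed = as.integer(seed),
    n_compounds = as.integer(n_compounds), n_targets = as.integer(n_targets),
    n_pathways = as.integer(n_pathways), n_diseases = as.integer(n_diseases),
    n_blocks = as.integer(n_blocks),
    p_in = p_in, p_out = p_out, hub_boost = hub_boost,
    admet_pass_fraction = admet_pass_fraction,
    prob_dist = as.numeric(prob_dist),
    tissue_labels = tissue_labels, class_weights = class_weights,
    disease_purity = disease_purity,
    links_per_disease = links_per_disease %||%
      max(3L, ceiling(n_pathways / n_diseases)),
    detect_prob = detect_prob,
    mean_targets_per_compound = mean_targets_per_compound
  )
  counts <- c(
    cfg$n_compounds, cfg$n_targets, cfg$n_pathways, cfg$n_diseases, cfg$n_blocks
  )
  if (any(counts < 1)) {
    np_abort("all counts must be positive", "netpharm_config_error")
  }
  if (cfg$n_blocks > cfg$n_targets || cfg$n_blocks > cfg$n_pathways) {
    np_abort("n_blocks may not exceed n_targets or n_pathways",
      class = "netpharm_config_error"
    )
  }
  probs <- c(cfg$p_in, cfg$p_out, cfg$admet_pass_fraction, cfg$detect_prob,
    cfg$disease_purity
  )
  if (any(probs < 0 | probs > 1)) {
    np_abort("probabilities must lie in [0, 1]", "netpharm_config_error")
  }
  if (length(cfg$prob_dist) != 2 || any(cfg$prob_dist <= 0)) {
    np_abort("prob_dist must be two positive Beta parameters",
      class = "netpharm_config_error"
    )
  }
  structure(cfg, class = "synth_config")
}

#' Study-scale preset configuration
#'
#' Scale preset for end-to-end smoke runs: 200 compounds, 167 targets, 63
#' pathways, 10 disease categories, 5 planted modules.
#'
#' @param seed master seed.
#' @return a `synth_config`.
#' @export
paper_scale_preset <- function(seed = 42L) {
  synth_config(
    seed = seed, n_compounds = 200L, n_targets = 167L, n_pathways = 63L,
    n_diseases = 10L, n_blocks = 5L
  )
}

label_seq <- function(prefix, n) {
  sprintf(paste0(prefix, "%0", max(3, nchar(n)), "d"), seq_len(n))
}

#' Generate the five synthetic input tables with ground truth
#'
#' @param config a [synth_config()].
#' @return list with `tables` (named list `compounds`, `admet`, `predictions`,
#'   `annotations`, `diseases`) and `truth` (`block_of_target`,
#'   `hub_targets`, `disease_block`).
#' @export
generate_synthetic_data <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  targets <- label_seq("TG", config$n_targets)
  pathways <- label_seq("PW", config$n_pathways)
  diseases <- label_seq("DS", config$n_diseases)
  compounds <- label_seq("CMP", config$n_compounds)

  block_of_target <- setNames(
    rep(seq_len(config$n_blocks), length.out = config$n_targets), targets
  )
  block_of_pathway <- setNames(
    rep(seq_len(config$n_blocks), length.out = config$n_pathways), pathways
  )
  hub_targets <- vapply(
    seq_len(config$n_blocks),
    function(b) targets[which(block_of_target == b)[1]], character(1)
  )

  compounds_tbl <- withr::with_seed(substream_seed(config$seed, 1), {
    classes <- sample(names(config$class_weights), config$n_compounds,
      replace = TRUE, prob = config$class_weights
    )
    tbl <- tibble(
      compound_id = compounds,
      name = paste("Metabolite", seq_along(compounds)),
      chem_class = classes
    )
    for (t in config$tissue_labels) {
      detected <- rbinom(config$n_compounds, 1, config$detect_prob)
      tbl[[t]] <- detected * round(rlnorm(config$n_compounds, 12, 1.5), 1)
    }
    tbl
  })

  admet_tbl <- withr::with_seed(
    substream_seed(config$seed, 2),
    synth_admet(compounds, config$admet_pass_fraction)
  )

  predictions_tbl <- withr::with_seed(substream_seed(config$seed, 3), {
    rows <- lapply(compounds, function(cid) {
      k <- min(
        config$n_targets,
        1 + rpois(1, max(0, config$mean_targets_per_compound - 1))
      )
      tibble(
        compound_id = cid,
        target_symbol = sort(sample(targets, k)),
        probability = round(
          rbeta(k, config$prob_dist[1], config$prob_dist[2]), 6
        )
      )
    })
    bind_rows(rows)
  })

  annotations_tbl <- withr::with_seed(substream_seed(config$seed, 4), {
    p <- matrix(config$p_out, config$n_targets, config$n_pathways)
    same <- outer(block_of_target, block_of_pathway, "==")
    p[same] <- config$p_in
    hub_rows <- match(hub_targets, targets)
    ph <- p[hub_rows, , drop = FALSE]
    ph[same[hub_rows, , drop = FALSE]] <- min(1, config$hub_boost * config$p_in)
    p[hub_rows, ] <- ph
    draw <- matrix(
      runif(length(p)) < p, config$n_targets, config$n_pathways
    )
    idx <- which(draw, arr.ind = TRUE)
    tibble(
      target_symbol = targets[idx[, 1]],
      pathway_id = pathways[idx[, 2]],
      pathway_name = paste("Pathway", pathways[idx[, 2]])
    ) |> arrange(.data$target_symbol, .data$pathway_id)
  })

  disease_block <- setNames(
    rep(seq_len(config$n_blocks), length.out = config$n_diseases), diseases
  )
  diseases_tbl <- withr::with_seed(substream_seed(config$seed, 5), {
    rows <- lapply(diseases, function(d) {
      b <- disease_block[[d]]
      own <- pathways[block_of_pathway == b]
      other <- pathways[block_of_pathway != b]
      n_links <- min(config$links_per_disease, config$n_pathways)
      n_in <- min(ceiling(config$disease_purity * n_links), length(own))
      n_out <- min(n_links - n_in, length(other))
      tibble(
        pathway_id = c(
          sample(own, n_in),
          if (n_out > 0) sample(other, n_out) else character()
        ),
        disease_category = d
      )
    })
    bind_rows(rows) |> arrange(.data$disease_category, .data$pathway_id)
  })

  list(
    tables = list(
      compounds = compounds_tbl, admet = admet_tbl,
      predictions = predictions_tbl, annotations = annotations_tbl,
      diseases = diseases_tbl
    ),
    truth = list(
      block_of_target = block_of_target,
      hub_targets = hub_targets,
      disease_block = disease_block
    ),
    config = config
  )
}

# per-field samplers: a value on the passing side / a violating value
admet_samplers <- function() {
  risk_pass <- function(n) round(runif(n, 0, 0.3), 3)
  risk_fail <- function(n) round(runif(n, 0.31, 1), 3)
  list(
    qed = list(function(n) round(runif(n, 0.67, 0.95), 3),
      function(n) round(runif(n, 0, 0.66), 3)
    ),
    lipinski_violations = list(
      function(n) sample(0:1, n, TRUE),
      function(n) sample(2:4, n, TRUE)
    ),
    caco2 = list(function(n) round(runif(n, -5.1, -4.0), 3),
      function(n) round(runif(n, -7, -5.2), 3)
    ),
    hia = list(risk_pass, risk_fail),
    ppb = list(function(n) round(runif(n, 40, 90), 2),
      function(n) round(runif(n, 90.5, 100), 2)
    ),
    fu = list(function(n) round(runif(n, 5, 60), 2),
      function(n) round(runif(n, 0, 4.9), 2)
    ),
    cl = list(function(n) round(runif(n, 5, 15), 2),
      function(n) round(runif(n, 0, 4.9), 2)
    ),
    h_ht = list(risk_pass, risk_fail),
    herg = list(risk_pass, risk_fail),
    f20 = list(risk_pass, risk_fail),
    f30 = list(risk_pass, risk_fail),
    ames = list(risk_pass, risk_fail),
    fsp3 = list(function(n) round(runif(n, 0.42, 0.9), 3),
      function(n) round(runif(n, 0, 0.41), 3)
    ),
    mce18 = list(function(n) round(runif(n, 46, 120), 1),
      function(n) round(runif(n, 0, 45), 1)
    ),
    pains_alerts = list(function(n) rep(0L, n),
      function(n) sample(1:2, n, TRUE)
    ),
    golden_triangle_violations = list(function(n) rep(0L, n),
      function(n) sample(1:2, n, TRUE)
    )
  )
}

synth_admet <- function(compound_ids, pass_fraction) {
  n <- length(compound_ids)
  samplers <- admet_samplers()
  tbl <- tibble(compound_id = compound_ids)
  for (f in admet_fields()) tbl[[f]] <- samplers[[f]][[1]](n)
  passes <- runif(n) < pass_fraction
  for (i in which(!passes)) {
    broken <- sample(admet_fields(), sample(1:3, 1))
    for (f in broken) tbl[[f]][i] <- samplers[[f]][[2]](1)
  }
  tbl
}

#' Write synthetic tables (and ground truth) to a directory
#'
#' @param synth result of [generate_synthetic_data()].
#' @param dir output directory (created if needed).
#' @return named vector of written file paths, invisibly.
#' @export
write_synthetic_data <- function(synth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    compounds = file.path(dir, "compounds.csv"),
    admet = file.path(dir, "admet.csv"),
    predictions = file.path(dir, "predictions.csv"),
    annotations = file.path(dir, "annotations.csv"),
    diseases = file.path(dir, "diseases.csv")
  )
  for (nm in names(paths)) {
    readr::write_csv(synth$tables[[nm]], paths[nm], progress = FALSE)
  }
  jsonlite::write_json(
    list(
      block_of_target = as.list(synth$truth$block_of_target),
      hub_targets = synth$truth$hub_targets,
      disease_block = as.list(synth$truth$disease_block)
    ),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(c(paths, ground_truth = file.path(dir, "ground_truth.json")))
}
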