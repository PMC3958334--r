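#' Run the full screen-analysis pipeline
#'
#' Chains every stage over a well table: plate normalization and replicate
#' aggregation, Z'-factor QC, two-round hit calling on the primary (RASV12)
#' assay, promoter false-positive filtering against the reporter assays,
#' epistasis-interval assignment of validated hits, interval census,
#' specificity scoring, and functional-profile clustering. With the default
#' `wells = NULL` a synthetic screen is generated from `config`, making the
#' whole run deterministic for a fixed seed.
#'
#' All results are computed before anything is written, so a failing stage
#' leaves no partial output directory behind.
#'
#' @param config A [sim_config()] used when `wells` is `NULL` (also recorded
#'   in the output).
#' @param wells Optional well table (as from [generate_screen()] or
#'   [read_well_table()]); when supplied, simulation is skipped and `truth`
#'   is absent from the results.
#' @param out_dir Optional directory; when given, every stage output is
#'   written there as TSV (plus the cluster tree as Newick and the config as
#'   a key: value file).
#' @param hit_cfg A [hit_config()].
#' @param spec_cfg A [specificity_config()].
#' @param panel An [epistasis_panel()].
#' @return A list of class `screen_pipeline` with elements `wells`, `truth`
#'   (simulated runs only), `normalized`, `profiles`, `qc`, `hits`,
#'   `validated`, `calls`, `census`, `specificity`, `clustering`, `config`.
#' @examples
#' res <- run_pipeline(sim_config(n_genes = 40, seed = 3))
#' res$census
#' @export
run_pipeline <- function(config = sim_config(), wells = NULL, out_dir = NULL,
                         hit_cfg = hit_config(),
                         spec_cfg = specificity_config(),
                         panel = epistasis_panel()) {
  truth <- NULL
  if (is.null(wells)) {
    sim <- generate_screen(config)
    wells <- sim$wells
    truth <- sim$truth
  }

  normalized <- normalize_wells(wells)
  qc <- screen_qc(normalized)
  aggregated <- aggregate_replicates(normalized)

  # two-round hit calling on the primary assay: replicate 1 = primary
  # screen, replicate 2 = confirmation
  if (!"replicate" %in% names(normalized)) {
    normalized$replicate <- 1L
    hit_cfg$require_confirmation <- FALSE
  }
  primary_tab <- normalized |>
    dplyr::filter(.data$role == "sample", .data$assay == panel$assays[1]) |>
    dplyr::group_by(.data$reagent_id, .data$replicate) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "replicate", values_from = "value",
                       names_prefix = "rep")
  values <- tibble::tibble(
    reagent_id = primary_tab$reagent_id,
    primary = primary_tab$rep1
  )
  if (hit_cfg$require_confirmation) {
    if (!"rep2" %in% names(primary_tab)) {
      stop("confirmation round requires >= 2 replicates of the primary assay",
           call. = FALSE)
    }
    values$confirmation <- primary_tab$rep2
  }
  hits <- call_primary_hits(values, config = hit_cfg)

  # promoter filter on the hit set: strongest reporter effect vs pMAPK
  sample_agg <- dplyr::filter(aggregated, .data$role == "sample")
  wide <- tidyr::pivot_wider(sample_agg, id_cols = "reagent_id",
                             names_from = "assay", values_from = "value")
  reporter_assays <- intersect(c("PMET_GFP", "PMET_HA_RASV12"), names(wide))
  hit_set <- dplyr::filter(hits, .data$hit)
  if (length(reporter_assays) > 0L && nrow(hit_set) > 0L) {
    rep_vals <- as.matrix(wide[reporter_assays])
    reporter <- rep_vals[cbind(seq_len(nrow(wide)),
                               max.col(abs(rep_vals), ties.method = "first"))]
    filt <- promoter_filter(
      tibble::tibble(reagent_id = wide$reagent_id,
                     pmapk = wide[[panel$assays[1]]],
                     reporter = reporter),
      config = hit_cfg)
    validated <- hit_set |>
      dplyr::left_join(dplyr::select(filt, "reagent_id", "reporter",
                                     "promoter_pass"),
                       by = "reagent_id") |>
      dplyr::filter(.data$promoter_pass)
  } else {
    validated <- dplyr::mutate(hit_set, promoter_pass = TRUE)
  }

  # epistasis assignment for validated candidates
  profiles <- wide |>
    dplyr::filter(.data$reagent_id %in% validated$reagent_id) |>
    dplyr::select(dplyr::all_of(c("reagent_id", panel$assays))) |>
    dplyr::rename(gene = "reagent_id")
  calls <- if (nrow(profiles) > 0L) {
    classify_epistasis(profiles, panel = panel)
  } else {
    classify_epistasis(
      tibble::tibble(gene = character(),
                     !!!stats::setNames(rep(list(numeric()), 6),
                                        panel$assays)),
      panel = panel)
  }
  census <- interval_census(calls)

  # specificity inputs from the available assays; components without a
  # measured counterpart stay NA and are skipped with renormalized weights
  spec_inputs <- wide |>
    dplyr::filter(.data$reagent_id %in% validated$reagent_id) |>
    dplyr::transmute(
      gene = .data$reagent_id,
      pmapk_effect = .data[[panel$assays[1]]],
      prior_screen_hits = 0,
      jnk_effect_rac = if ("RAC1V12_PJNK" %in% names(wide))
        .data$RAC1V12_PJNK else NA_real_,
      jnk_effect_pgn = if ("PGN_PJNK" %in% names(wide))
        .data$PGN_PJNK else NA_real_,
      pmet_gfp_effect = if ("PMET_GFP" %in% names(wide))
        .data$PMET_GFP else NA_real_,
      western_flag = NA_character_,
      export_retention_index = NA_real_,
      cell_count_effect = NA_real_
    )
  specificity <- if (nrow(spec_inputs) > 0L) {
    specificity_score(spec_inputs, config = spec_cfg)
  } else {
    NULL
  }

  # profile clustering of validated candidates across all assays
  clust_profiles <- wide |>
    dplyr::filter(.data$reagent_id %in% validated$reagent_id) |>
    dplyr::rename(gene = "reagent_id")
  clustering <- if (nrow(clust_profiles) >= 2L) {
    cluster_profiles(clust_profiles)
  } else {
    NULL
  }

  res <- structure(
    list(wells = wells, truth = truth, normalized = normalized,
         profiles = wide, qc = qc, hits = hits, validated = validated,
         calls = calls, census = census, specificity = specificity,
         clustering = clustering, config = config),
    class = "screen_pipeline"
  )

  if (!is.null(out_dir)) {
    write_pipeline(res, out_dir)
  }
  invisible(res)
}

#' Write pipeline stage outputs to a directory
#'
#' @param res A `screen_pipeline` result.
#' @param out_dir Directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline <- function(res, out_dir) {
  stopifnot(inherits(res, "screen_pipeline"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(res$wells, file.path(out_dir, "wells.tsv"))
  if (!is.null(res$truth)) {
    readr::write_tsv(res$truth, file.path(out_dir, "truth.tsv"))
  }
  readr::write_tsv(res$normalized, file.path(out_dir, "normalized.tsv"))
  readr::write_tsv(res$qc, file.path(out_dir, "qc.tsv"))
  readr::write_tsv(res$hits, file.path(out_dir, "hits.tsv"))
  readr::write_tsv(res$validated, file.path(out_dir, "validated.tsv"))
  readr::write_tsv(res$calls, file.path(out_dir, "epistasis_calls.tsv"))
  readr::write_tsv(res$census, file.path(out_dir, "census.tsv"))
  if (!is.null(res$specificity)) {
    readr::write_tsv(res$specificity, file.path(out_dir, "specificity.tsv"))
  }
  if (!is.null(res$clustering)) {
    write_newick(res$clustering, file.path(out_dir, "clusters.newick"))
  }
  if (inherits(res$config, "sim_config")) {
    write_sim_config(res$config, file.path(out_dir, "config.txt"))
  }
  summary_tab <- tibble::tibble(
    stage = c("wells", "hits", "validated", "assigned"),
    n = c(nrow(res$wells), sum(res$hits$hit), nrow(res$validated),
          sum(res$calls$status != "unassigned"))
  )
  readr::write_tsv(summary_tab, file.path(out_dir, "summary.tsv"))
  invisible(out_dir)
}

#' @export
print.screen_pipeline <- function(x, ...) {
  cat("<screen_pipeline>\n")
  cat("  wells:     ", nrow(x$wells), "\n")
  cat("  hits:      ", sum(x$hits$hit), "of", nrow(x$hits), "reagents\n")
  cat("  validated: ", nrow(x$validated), "\n")
  cat("  assigned:  ", sum(x$calls$status == "assigned"),
      "( ambiguous:", sum(x$calls$status == "ambiguous"),
      ", unassigned:", sum(x$calls$status == "unassigned"), ")\n")
  invisible(x)
}
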