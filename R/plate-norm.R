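#' Normalize well signals to in-plate negative controls
#'
#' Each well's signal is expressed as a log-ratio to the center of the
#' negative-control (GFP dsRNA) wells on the same plate and assay. The
#' center is the median by default — robust to a single contaminated control
#' well — or the geometric mean, under which control wells average exactly 0
#' after normalization. Epistasis-type assays are conventionally reported in
#' log10; expression-type summaries in log2 (set `log_base` accordingly).
#'
#' Normalization is invariant to plate-wide rescaling: multiplying every
#' signal on a plate by a positive constant leaves all values unchanged.
#'
#' @param wells Data frame of well records with columns `plate`, `assay`,
#'   `reagent_id`, `role`, `signal` (and optionally `well`, `replicate`).
#' @param log_base Base of the logarithm (default 10).
#' @param center `"median"` (default) or `"geomean"`.
#' @param pseudocount Added to every signal before taking ratios. `NULL`
#'   (default) rejects nonpositive-signal wells instead, with a reported
#'   count.
#' @return Tibble with the grouping/metadata columns plus `value`, the
#'   normalized log-ratio. Rejected wells (nonpositive signal when
#'   `pseudocount` is `NULL`) are dropped with a warning giving the count.
#' @examples
#' sim <- generate_screen(sim_config(n_genes = 20, seed = 1))
#' nv <- normalize_wells(sim$wells)
#' head(nv)
#' @export
normalize_wells <- function(wells, log_base = 10,
                            center = c("median", "geomean"),
                            pseudocount = NULL) {
  stopifnot(is.data.frame(wells))
  center <- match.arg(center)
  needed <- c("plate", "assay", "reagent_id", "role", "signal")
  missing_cols <- setdiff(needed, names(wells))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  wells <- tibble::as_tibble(wells)
  if (!is.null(pseudocount)) {
    wells$signal <- wells$signal + pseudocount
  }
  bad <- !is.finite(wells$signal) | wells$signal <= 0
  if (any(bad)) {
    warning(sum(bad), " well(s) with nonpositive or non-finite signal ",
            "rejected before log transform", call. = FALSE)
    wells <- wells[!bad, , drop = FALSE]
  }

  center_fun <- switch(center,
    median = function(x) stats::median(x),
    geomean = function(x) exp(mean(log(x)))
  )

  wells |>
    dplyr::group_by(.data$plate, .data$assay) |>
    dplyr::group_modify(function(df, key) {
      neg <- df$signal[df$role == "neg_ctrl"]
      if (length(neg) == 0L) {
        stop("no negative-control wells on plate ", key$plate,
             " (assay ", key$assay, ")", call. = FALSE)
      }
      ctr <- center_fun(neg)
      if (!is.finite(ctr) || ctr <= 0) {
        stop("nonpositive negative-control center on plate ", key$plate,
             " (assay ", key$assay, ")", call. = FALSE)
      }
      df$value <- log(df$signal / ctr, base = log_base)
      df
    }) |>
    dplyr::ungroup()
}

#' Average replicate normalized values per reagent and assay
#'
#' @param values Tibble from [normalize_wells()] (columns `reagent_id`,
#'   `assay`, `value`, `role`).
#' @return Tibble with one row per reagent x assay: `value` (mean of
#'   replicate log-values), `n_replicates`, and `dispersion` (sample sd;
#'   `NA` when a single replicate, which callers should treat as flagged).
#' @export
aggregate_replicates <- function(values) {
  stopifnot(is.data.frame(values))
  needed <- c("reagent_id", "assay", "value")
  missing_cols <- setdiff(needed, names(values))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  grp <- c("reagent_id", "assay", intersect("role", names(values)))
  values |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      dispersion = stats::sd(.data$value),
      value = mean(.data$value),
      .groups = "drop"
    ) |>
    dplyr::relocate("value", .before = "n_replicates")
}

#' Z'-factor assay quality statistic
#'
#' \deqn{Z' = 1 - \frac{3(\sigma_p + \sigma_n)}{|\mu_p - \mu_n|}}
#' computed with sample (n−1) standard deviations. `Z' > 0.5` (configurable)
#' marks a robust screening assay. When the group means coincide the
#' statistic is undefined and the result is flagged.
#'
#' @param pos_values,neg_values Numeric vectors of positive- and
#'   negative-control measurements (at least 2 each).
#' @param robust_cutoff Threshold above which the assay is flagged robust.
#' @param assay Optional assay label carried into the output.
#' @return One-row tibble with `assay`, `mu_pos`, `sd_pos`, `mu_neg`,
#'   `sd_neg`, `zprime` (`NA` when undefined), `robust`.
#' @examples
#' zprime(c(10, 10, 10, 10), c(0, 0, 0, 2))
#' @export
zprime <- function(pos_values, neg_values, robust_cutoff = 0.5,
                   assay = NA_character_) {
  if (length(pos_values) < 2L || length(neg_values) < 2L) {
    stop("need at least 2 values per control group", call. = FALSE)
  }
  mu_p <- mean(pos_values); sd_p <- stats::sd(pos_values)
  mu_n <- mean(neg_values); sd_n <- stats::sd(neg_values)
  if (mu_p == mu_n) {
    zp <- NA_real_
  } else {
    zp <- 1 - 3 * (sd_p + sd_n) / abs(mu_p - mu_n)
  }
  tibble::tibble(assay = assay, mu_pos = mu_p, sd_pos = sd_p,
                 mu_neg = mu_n, sd_neg = sd_n, zprime = zp,
                 robust = !is.na(zp) && zp > robust_cutoff)
}

#' Per-assay Z'-factor QC from control wells
#'
#' Computes [zprime()] for every assay from the positive- and
#' negative-control wells of a (normalized or raw) well table.
#'
#' @param wells Data frame with columns `assay`, `role` and a measurement
#'   column.
#' @param measure Name of the measurement column (default `"value"`, i.e. a
#'   table from [normalize_wells()]).
#' @param pos_role Which positive-control role to test against the negative
#'   controls (`"pos_ctrl_down"` or `"pos_ctrl_up"`).
#' @inheritParams zprime
#' @return Tibble with one QC row per assay.
#' @export
screen_qc <- function(wells, measure = "value", pos_role = "pos_ctrl_down",
                      robust_cutoff = 0.5) {
  stopifnot(is.data.frame(wells))
  if (!measure %in% names(wells)) {
    stop("missing measurement column: ", measure, call. = FALSE)
  }
  wells |>
    dplyr::group_by(.data$assay) |>
    dplyr::group_modify(function(df, key) {
      pos <- df[[measure]][df$role == pos_role]
      neg <- df[[measure]][df$role == "neg_ctrl"]
      zprime(pos, neg, robust_cutoff = robust_cutoff)[-1L]
    }) |>
    dplyr::ungroup()
}
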