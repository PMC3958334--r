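#' Epistasis assay panel
#'
#' Describes the six activated-pathway assays used to position a candidate
#' regulator within the RAS->RAF->MEK->MAPK cascade, the per-assay weights,
#' and the three predetermined interval profiles. A gene depleted by RNAi is
#' assayed against pathway activation at successive levels: activated RAS
#' (`RASV12`), three activated RAF variants (`RAFED`, `RAFCT`, `RAFEDCT`),
#' activated MEK (`MEKEE`), and activated MEK with `PTP-ER` co-depletion
#' (`MEKEE_PTPER`). A regulator acting upstream of a given kinase loses its
#' effect once that kinase is constitutively activated, so the pattern of
#' suppression across the six assays encodes the interval at which the gene
#' acts:
#'
#' * `RAS-RAF`: affects only the RAS assay, profile `[1 0 0 0 0 0]`
#' * `RAF-MEK`: affects RAS and RAF assays, profile `[1 1 1 1 0 0]`
#' * `MEK-MAPK`: affects all six assays, profile `[1 1 1 1 1 1]`
#'
#' Assay order is fixed and validated by name wherever a panel is consumed,
#' so the weight vector can never be silently permuted against the data.
#'
#' @param assays Character vector of six assay ids, in pathway order.
#' @param weights Nonnegative numeric vector of six per-assay weights.
#'   The default `c(3, 1, 1, 1, 1, 2)` up-weights the RAS assay (the primary
#'   readout) and the PTP-ER co-depletion assay (the most downstream
#'   discriminator).
#' @param profiles Named list of three numeric six-vectors, one ideal profile
#'   per interval.
#'
#' @return An object of class `epistasis_panel`: a list with elements
#'   `assays`, `weights` and `profiles`.
#' @examples
#' epistasis_panel()
#' @export
epistasis_panel <- function(assays = c("RASV12", "RAFED", "RAFCT", "RAFEDCT",
                                       "MEKEE", "MEKEE_PTPER"),
                            weights = c(3, 1, 1, 1, 1, 2),
                            profiles = list(
                              "RAS-RAF"  = c(1, 0, 0, 0, 0, 0),
                              "RAF-MEK"  = c(1, 1, 1, 1, 0, 0),
                              "MEK-MAPK" = c(1, 1, 1, 1, 1, 1)
                            )) {
  if (length(assays) != 6L || anyDuplicated(assays) > 0L) {
    stop("`assays` must be six distinct assay ids", call. = FALSE)
  }
  if (length(weights) != 6L || any(!is.finite(weights)) || any(weights < 0) ||
      sum(weights) <= 0) {
    stop("`weights` must be six nonnegative finite values with positive sum",
         call. = FALSE)
  }
  if (!is.list(profiles) || is.null(names(profiles)) ||
      any(!nzchar(names(profiles))) ||
      any(vapply(profiles, length, integer(1)) != 6L)) {
    stop("`profiles` must be a named list of six-vectors", call. = FALSE)
  }
  structure(
    list(assays = as.character(assays), weights = as.numeric(weights),
         profiles = lapply(profiles, as.numeric)),
    class = "epistasis_panel"
  )
}

#' @export
print.epistasis_panel <- function(x, ...) {
  cat("<epistasis_panel>\n")
  cat("  assays:  ", paste(x$assays, collapse = ", "), "\n")
  cat("  weights: ", paste(format(x$weights), collapse = " "), "\n")
  for (nm in names(x$profiles)) {
    cat("  profile ", format(nm, width = 9), "[",
        paste(x$profiles[[nm]], collapse = " "), "]\n")
  }
  invisible(x)
}

#' Ideal epistasis profile for an interval
#'
#' @param class One of `"RAS-RAF"`, `"RAF-MEK"`, `"MEK-MAPK"`.
#' @param panel An [epistasis_panel()].
#' @return Numeric six-vector.
#' @examples
#' ideal_profile("RAS-RAF")
#' @export
ideal_profile <- function(class, panel = epistasis_panel()) {
  if (length(class) != 1L || !class %in% names(panel$profiles)) {
    stop("unknown epistasis interval: ",
         paste(setdiff(class, names(panel$profiles)), collapse = ", "),
         " (expected one of ",
         paste(names(panel$profiles), collapse = ", "), ")", call. = FALSE)
  }
  panel$profiles[[class]]
}

#' Weighted uncentered Pearson correlation
#'
#' Cosine-type similarity between two vectors computed without mean
#' centering, with a per-coordinate weight:
#' \deqn{r = \frac{\sum_i w_i x_i y_i}
#'   {\sqrt{\sum_i w_i x_i^2 \; \sum_i w_i y_i^2}}}
#' Because the vectors are not centered, `r` compares profiles by direction
#' through the origin: a gene with no effect anywhere (zero vector) has no
#' direction and is rejected rather than mapped to `r = 0`.
#'
#' @param x,y Numeric vectors of equal length.
#' @param w Nonnegative weights, recycled from `rep(1, length(x))` if omitted.
#' @return A single correlation in `[-1, 1]`.
#' @examples
#' weighted_uncentered_pearson(c(1, 0, 0, 0, 0, 0), c(1, 0, 0, 0, 0, 0))
#' weighted_uncentered_pearson(rep(-1, 6), c(1, 1, 1, 1, 1, 1),
#'                             w = c(3, 1, 1, 1, 1, 2))
#' @export
weighted_uncentered_pearson <- function(x, y, w = rep(1, length(x))) {
  if (length(x) != length(y) || length(x) != length(w)) {
    stop("`x`, `y` and `w` must have equal length", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("`x` and `y` must be finite", call. = FALSE)
  }
  if (any(w < 0)) stop("`w` must be nonnegative", call. = FALSE)
  sxx <- sum(w * x * x)
  syy <- sum(w * y * y)
  if (sxx <= 0 || syy <= 0) {
    stop("zero-norm vector under `w`: uncentered correlation is undefined",
         call. = FALSE)
  }
  r <- sum(w * x * y) / sqrt(sxx * syy)
  # guard against rounding excursions outside [-1, 1]
  max(-1, min(1, r))
}

#' Assign genes to epistasis intervals
#'
#' For each gene, correlates its six-assay profile with the three
#' predetermined interval profiles using [weighted_uncentered_pearson()] and
#' assigns the interval with the highest absolute correlation. The sign of
#' the winning correlation encodes the regulator direction: negative `r`
#' (knockdown decreases pathway output) marks a positive regulator.
#'
#' Calls are qualified by two rules:
#' * if all three correlations lie within `[-unassigned_r, unassigned_r]`
#'   (default 0.5) the gene cannot be positioned and is reported
#'   `unassigned`;
#' * otherwise `confidence = |r_best| - |r_second|`; calls with confidence
#'   below `ambiguous_confidence` (default 0.2) keep their interval but are
#'   flagged `ambiguous`. An exact tie is reported ambiguous with confidence
#'   0 and the co-leading interval recorded in `tied_with`.
#'
#' A profile that is exactly zero under the weights (possible for inert genes
#' in noise-free simulations) is reported `unassigned` with `NA`
#' correlations.
#'
#' @param profiles Data frame with a `gene` column and one numeric column per
#'   panel assay (log10 normalized pathway signal).
#' @param panel An [epistasis_panel()].
#' @param unassigned_r Absolute-correlation radius inside which no interval
#'   is assigned.
#' @param ambiguous_confidence Confidence below which an assigned call is
#'   flagged ambiguous.
#' @return A tibble of class `epistasis_calls` with columns `gene`,
#'   `r_ras_raf`, `r_raf_mek`, `r_mek_mapk`, `interval`
#'   (`RAS-RAF`/`RAF-MEK`/`MEK-MAPK`/`unassigned`), `sign`
#'   (`positive`/`negative`/`NA`), `confidence`, `status`
#'   (`assigned`/`ambiguous`/`unassigned`) and `tied_with`.
#' @examples
#' profs <- tibble::tibble(
#'   gene = c("cnk", "Cdc37", "mapk"),
#'   RASV12 = c(-1, -1, -1), RAFED = c(0, -1, -1), RAFCT = c(0, -1, -1),
#'   RAFEDCT = c(0, -1, -1), MEKEE = c(0, 0, -1), MEKEE_PTPER = c(0, 0, -1)
#' )
#' classify_epistasis(profs)
#' @export
classify_epistasis <- function(profiles, panel = epistasis_panel(),
                               unassigned_r = 0.5,
                               ambiguous_confidence = 0.2) {
  stopifnot(is.data.frame(profiles))
  if (!"gene" %in% names(profiles)) {
    stop("`profiles` must have a `gene` column", call. = FALSE)
  }
  missing_assays <- setdiff(panel$assays, names(profiles))
  if (length(missing_assays) > 0L) {
    stop("missing assay column(s): ", paste(missing_assays, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(profiles) == 0L) {
    out <- tibble::tibble(
      gene = character(), r_ras_raf = numeric(), r_raf_mek = numeric(),
      r_mek_mapk = numeric(), interval = character(), sign = character(),
      confidence = numeric(), status = character(), tied_with = character())
    class(out) <- c("epistasis_calls", class(out))
    return(out)
  }
  x_mat <- as.matrix(profiles[panel$assays])
  if (!is.numeric(x_mat)) stop("assay columns must be numeric", call. = FALSE)
  if (anyNA(x_mat)) {
    bad <- which(is.na(x_mat), arr.ind = TRUE)
    stop("missing value in assay ", panel$assays[bad[1L, 2L]],
         " for gene ", profiles$gene[bad[1L, 1L]], call. = FALSE)
  }

  w <- panel$weights
  interval_names <- names(panel$profiles)
  calls <- purrr::map(seq_len(nrow(x_mat)), function(i) {
    x <- x_mat[i, ]
    if (sum(w * x * x) <= 0) {
      return(tibble::tibble(
        r = list(stats::setNames(rep(NA_real_, 3L), interval_names)),
        interval = "unassigned", sign = NA_character_,
        confidence = NA_real_, status = "unassigned",
        tied_with = NA_character_
      ))
    }
    r <- vapply(panel$profiles, weighted_uncentered_pearson,
                numeric(1), x = x, w = w)
    if (all(abs(r) <= unassigned_r)) {
      return(tibble::tibble(
        r = list(r), interval = "unassigned", sign = NA_character_,
        confidence = NA_real_, status = "unassigned",
        tied_with = NA_character_
      ))
    }
    ord <- order(abs(r), decreasing = TRUE)
    best <- ord[1L]
    confidence <- unname(abs(r[best]) - abs(r[ord[2L]]))
    tied <- abs(abs(r[ord[2L]]) - abs(r[best])) < 1e-12
    call_sign <- if (r[best] < 0) "positive" else "negative"
    call_status <- if (tied || confidence < ambiguous_confidence) {
      "ambiguous"
    } else {
      "assigned"
    }
    tibble::tibble(
      r = list(r),
      interval = interval_names[best],
      sign = call_sign,
      confidence = confidence,
      status = call_status,
      tied_with = if (tied) interval_names[ord[2L]] else NA_character_
    )
  })
  calls <- dplyr::bind_rows(calls)
  r_mat <- do.call(rbind, calls$r)
  out <- tibble::tibble(
    gene = profiles$gene,
    r_ras_raf = r_mat[, "RAS-RAF"],
    r_raf_mek = r_mat[, "RAF-MEK"],
    r_mek_mapk = r_mat[, "MEK-MAPK"],
    interval = calls$interval,
    sign = calls$sign,
    confidence = calls$confidence,
    status = calls$status,
    tied_with = calls$tied_with
  )
  class(out) <- c("epistasis_calls", class(out))
  out
}

#' Tabulate epistasis calls by interval, sign and status
#'
#' @param calls An `epistasis_calls` tibble from [classify_epistasis()].
#' @return A tibble with columns `interval`, `sign`, `status`, `n`; the
#'   counts sum to `nrow(calls)`.
#' @export
interval_census <- function(calls) {
  stopifnot(is.data.frame(calls))
  needed <- c("interval", "sign", "status")
  if (!all(needed %in% names(calls))) {
    stop("`calls` must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  lv <- c("RAS-RAF", "RAF-MEK", "MEK-MAPK", "unassigned")
  calls |>
    dplyr::count(
      interval = factor(.data$interval, levels = lv),
      sign = .data$sign, status = .data$status
    ) |>
    dplyr::arrange(.data$interval, .data$sign, .data$status) |>
    dplyr::mutate(interval = as.character(.data$interval)) |>
    tibble::as_tibble()
}

#' @export
print.epistasis_calls <- function(x, ...) {
  n <- nrow(x)
  cat("# Epistasis calls for", n, "gene(s)\n")
  tab <- table(x$status)
  cat("# ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  NextMethod()
}

#' Plot epistasis calls
#'
#' Scatter of the RAS-RAF correlation against the MEK-MAPK correlation,
#' colored by assigned interval, with the unassignable region (all
#' correlations within the cutoff radius) shaded. Positive regulators fall
#' in the negative-correlation quadrant.
#'
#' @param object An `epistasis_calls` tibble.
#' @param unassigned_r Radius used to shade the unassignable region; should
#'   match the value used in [classify_epistasis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.epistasis_calls <- function(object, unassigned_r = 0.5, ...) {
  df <- dplyr::filter(object, !is.na(.data$r_ras_raf))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r_ras_raf, y = .data$r_mek_mapk,
                                   colour = .data$interval,
                                   shape = .data$status)) +
    ggplot2::annotate("rect", xmin = -unassigned_r, xmax = unassigned_r,
                      ymin = -unassigned_r, ymax = unassigned_r,
                      alpha = 0.1, fill = "grey40") +
    ggplot2::geom_point() +
    ggplot2::coord_cartesian(xlim = c(-1, 1), ylim = c(-1, 1)) +
    ggplot2::labs(x = "r (RAS-RAF profile)", y = "r (MEK-MAPK profile)",
                  colour = "interval", shape = "status") +
    ggplot2::theme_minimal()
}
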