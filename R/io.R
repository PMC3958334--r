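#' Read a well-level screen table
#'
#' Reads a delimited (TSV by default) table of well measurements. Columns
#' are resolved by header name, order-free. Rows with a non-numeric or
#' missing signal are rejected and reported.
#'
#' @param path Path to the file.
#' @param delim Field delimiter.
#' @return Tibble with columns `plate`, `well`, `reagent_id`, `role`,
#'   `assay`, `signal`, `cells` (plus `replicate` when present), with an
#'   attribute `n_rejected` giving the number of dropped rows.
#' @export
read_well_table <- function(path, delim = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
  needed <- c("plate", "well", "reagent_id", "role", "assay", "signal",
              "cells")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  signal <- suppressWarnings(as.numeric(raw$signal))
  cells <- suppressWarnings(as.numeric(raw$cells))
  bad <- is.na(signal) | signal < 0
  if (any(bad)) {
    warning(sum(bad), " row(s) with missing/non-numeric/negative signal ",
            "rejected in ", basename(path), call. = FALSE)
  }
  known_roles <- c("sample", "neg_ctrl", "pos_ctrl_down", "pos_ctrl_up")
  bad_role <- !raw$role %in% known_roles
  if (any(bad_role & !bad)) {
    warning(sum(bad_role & !bad), " row(s) with unknown role rejected in ",
            basename(path), call. = FALSE)
  }
  keep <- !bad & !bad_role
  out <- tibble::tibble(
    plate = raw$plate[keep], well = raw$well[keep],
    reagent_id = raw$reagent_id[keep], role = raw$role[keep],
    assay = raw$assay[keep], signal = signal[keep], cells = cells[keep]
  )
  if ("replicate" %in% names(raw)) {
    out$replicate <- suppressWarnings(as.integer(raw$replicate[keep]))
  }
  attr(out, "n_rejected") <- sum(!keep)
  out
}

#' Write a well table as TSV
#'
#' @param wells Well tibble (see [generate_screen()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_well_table <- function(wells, path) {
  readr::write_tsv(wells, path)
  invisible(path)
}

#' Read a per-gene profile table
#'
#' A delimited table with a `gene` column and one numeric column per assay
#' (at minimum the six epistasis assays of the supplied panel).
#'
#' @param path Path to the file.
#' @param panel An [epistasis_panel()] naming the required assay columns.
#' @param delim Field delimiter.
#' @return Tibble of gene profiles; rows with any non-numeric assay value
#'   are rejected with a reported count.
#' @export
read_profile_table <- function(path, panel = epistasis_panel(),
                               delim = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
  if (!"gene" %in% names(raw)) {
    stop("missing required column: gene", call. = FALSE)
  }
  missing_cols <- setdiff(panel$assays, names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing assay column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  vals <- suppressWarnings(
    vapply(panel$assays, function(a) as.numeric(raw[[a]]),
           numeric(nrow(raw)))
  )
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(NULL, panel$assays))
  bad <- rowSums(is.na(vals)) > 0
  if (any(bad)) {
    warning(sum(bad), " row(s) with non-numeric assay value rejected in ",
            basename(path), call. = FALSE)
  }
  out <- dplyr::bind_cols(
    tibble::tibble(gene = raw$gene[bad == FALSE]),
    tibble::as_tibble(vals[!bad, , drop = FALSE])
  )
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Read an epistasis-results sheet in the supplementary layout
#'
#' Reads a delimited export of the epistasis supplementary-table layout:
#' a gene column, the six log10 screen columns, and (optionally) the
#' reported correlations, interval and confidence. Screen columns may be
#' named either by assay id or `screen1` ... `screen6` in pathway order.
#'
#' @param path Path to a TSV/CSV export of the sheet.
#' @param panel An [epistasis_panel()].
#' @param delim Field delimiter (`"\t"` default; use `","` for CSV).
#' @return A list with `profiles` (tibble ready for [classify_epistasis()])
#'   and `reported` (tibble of any reported `interval`/`confidence`/`r_*`
#'   columns found, or `NULL`).
#' @export
read_supplementary_s3 <- function(path, panel = epistasis_panel(),
                                  delim = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
  names(raw)[tolower(names(raw)) == "gene"] <- "gene"
  if (!"gene" %in% names(raw)) {
    stop("missing required column: gene", call. = FALSE)
  }
  screen_alias <- paste0("screen", 1:6)
  if (all(screen_alias %in% names(raw))) {
    names(raw)[match(screen_alias, names(raw))] <- panel$assays
  }
  missing_cols <- setdiff(panel$assays, names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing screen column(s): ", paste(missing_cols, collapse = ", "),
         " (or screen1..screen6)", call. = FALSE)
  }
  profiles <- raw |>
    dplyr::select(dplyr::all_of(c("gene", panel$assays))) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(panel$assays), as.numeric))
  bad <- rowSums(is.na(profiles[panel$assays])) > 0
  if (any(bad)) {
    warning(sum(bad), " row(s) with non-numeric screen value rejected in ",
            basename(path), call. = FALSE)
    profiles <- profiles[!bad, , drop = FALSE]
  }
  reported_cols <- intersect(
    c("interval", "confidence", "r_ras_raf", "r_raf_mek", "r_mek_mapk"),
    names(raw))
  reported <- if (length(reported_cols) > 0L) {
    raw[!bad, c("gene", reported_cols), drop = FALSE] |>
      dplyr::mutate(dplyr::across(
        dplyr::any_of(c("confidence", "r_ras_raf", "r_raf_mek",
                        "r_mek_mapk")),
        as.numeric))
  } else {
    NULL
  }
  list(profiles = profiles, reported = reported)
}

#' Write a simulation config as a key: value text file
#'
#' @param config A [sim_config()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  fmt <- function(x) {
    if (!is.null(names(x)) && length(x) > 1L) {
      paste(sprintf("%s=%s", names(x), format(x, trim = TRUE)),
            collapse = ",")
    } else {
      paste(format(x, trim = TRUE), collapse = ",")
    }
  }
  lines <- vapply(names(config), function(k) {
    sprintf("%s: %s", k, fmt(config[[k]]))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
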