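#' Hit-calling configuration
#'
#' Thresholds for the two-stage primary hit calling and the signal-dependent
#' promoter false-positive filter. The screen's published cutoff margins are
#' not printed numerically, so both cutoffs are free parameters; the default
#' of ±0.3 log10 corresponds to roughly a 2-fold signal change.
#'
#' @param up_cutoff Log10 value above which a reagent is an up hit
#'   (candidate negative regulator).
#' @param down_cutoff Log10 value below which a reagent is a down hit
#'   (candidate positive regulator). Must be negative.
#' @param require_confirmation If `TRUE` (default), a reagent must exceed
#'   the cutoff in the same direction in both the primary and the
#'   confirmation round.
#' @param promoter_slope,promoter_intercept Parameters of the linear
#'   promoter-filter cutoff: a reagent fails when
#'   `|reporter| >= intercept + slope * |pMAPK|`. This is a reconstruction
#'   of a cutoff that is a function of the primary-screen pMAPK signal.
#' @return A list of class `hit_config`.
#' @export
hit_config <- function(up_cutoff = 0.3, down_cutoff = -0.3,
                       require_confirmation = TRUE,
                       promoter_slope = 0.5, promoter_intercept = 0.3) {
  if (!(down_cutoff < 0 && 0 < up_cutoff)) {
    stop("need down_cutoff < 0 < up_cutoff", call. = FALSE)
  }
  structure(
    list(up_cutoff = up_cutoff, down_cutoff = down_cutoff,
         require_confirmation = isTRUE(require_confirmation),
         promoter_slope = promoter_slope,
         promoter_intercept = promoter_intercept),
    class = "hit_config"
  )
}

#' Call primary screen hits
#'
#' A reagent is a hit when its normalized log10 value falls outside the
#' cutoff margins, in the same direction in the primary and (when required)
#' confirmation rounds. Direction `up` marks a candidate negative regulator
#' (knockdown raises pMAPK), `down` a candidate positive regulator.
#'
#' Widening the cutoff margins can only remove hits, never add them.
#'
#' @param values Data frame with columns `reagent_id`, `primary` and, when
#'   confirmation is required, `confirmation` (normalized log10 values).
#' @param config A [hit_config()].
#' @return Tibble with `reagent_id`, `primary`, `confirmation` (if present),
#'   `hit` (logical) and `direction` (`"up"`, `"down"`, or `NA`).
#' @examples
#' vals <- tibble::tibble(reagent_id = c("a", "b", "c"),
#'                        primary = c(-1, -1, 0.1),
#'                        confirmation = c(-0.9, 0.1, 0.05))
#' call_primary_hits(vals)
#' @export
call_primary_hits <- function(values, config = hit_config()) {
  stopifnot(is.data.frame(values), inherits(config, "hit_config"))
  if (!all(c("reagent_id", "primary") %in% names(values))) {
    stop("`values` must have columns reagent_id and primary", call. = FALSE)
  }
  if (config$require_confirmation && !"confirmation" %in% names(values)) {
    stop("confirmation values required but `confirmation` column missing",
         call. = FALSE)
  }
  up <- values$primary >= config$up_cutoff
  down <- values$primary <= config$down_cutoff
  if (config$require_confirmation) {
    up <- up & values$confirmation >= config$up_cutoff
    down <- down & values$confirmation <= config$down_cutoff
  }
  tibble::as_tibble(values) |>
    dplyr::mutate(
      hit = up | down,
      direction = dplyr::case_when(up ~ "up", down ~ "down",
                                   TRUE ~ NA_character_)
    )
}

#' Promoter-system false-positive filter
#'
#' Candidates whose effect runs through the inducible expression system
#' (rather than the pathway) show a reporter effect commensurate with their
#' pMAPK effect in dedicated pMet-GFP / pMet-HA-RasV12 reporter screens. A
#' reagent fails the filter when
#' `|reporter| >= promoter_intercept + promoter_slope * |pMAPK|`.
#'
#' @param values Data frame with columns `reagent_id`, `pmapk` (primary
#'   screen log value) and `reporter` (reporter screen log value).
#' @param config A [hit_config()].
#' @return Input tibble plus `promoter_pass` (logical; `FALSE` = flagged as
#'   promoter artifact).
#' @examples
#' promoter_filter(tibble::tibble(reagent_id = c("ok", "artifact"),
#'                                pmapk = c(-1, -1), reporter = c(0, -1)))
#' @export
promoter_filter <- function(values, config = hit_config()) {
  stopifnot(is.data.frame(values), inherits(config, "hit_config"))
  needed <- c("reagent_id", "pmapk", "reporter")
  missing_cols <- setdiff(needed, names(values))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(values) |>
    dplyr::mutate(
      promoter_pass = abs(.data$reporter) <
        config$promoter_intercept + config$promoter_slope * abs(.data$pmapk)
    )
}
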