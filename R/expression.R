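#' Expression-call configuration
#'
#' Decision rule for qPCR knockdown-like calls: a transcript is called
#' depleted when its mean log2 ratio falls below `log2_threshold` and the
#' unpaired two-tailed Student's t-test p-value falls below `p_threshold`.
#' Raw p-values are reported by default; Benjamini-Hochberg adjustment is
#' available behind `adjust` for users screening many transcripts at once.
#'
#' @param log2_threshold Log2-ratio threshold for a knockdown-like call
#'   (default −0.75).
#' @param p_threshold P-value threshold (default 1e-4).
#' @param adjust If `TRUE`, apply Benjamini-Hochberg adjustment across the
#'   calls of one [call_expression_changes()] table before applying
#'   `p_threshold`. Off by default.
#' @return A list of class `expression_config`.
#' @export
expression_config <- function(log2_threshold = -0.75, p_threshold = 1e-4,
                              adjust = FALSE) {
  if (!(p_threshold > 0 && p_threshold < 1)) {
    stop("`p_threshold` must be in (0, 1)", call. = FALSE)
  }
  structure(
    list(log2_threshold = log2_threshold, p_threshold = p_threshold,
         adjust = isTRUE(adjust)),
    class = "expression_config"
  )
}

#' Differential call for one transcript
#'
#' Compares replicate log2 quantities between a dsRNA-treated group and a
#' control group with an unpaired two-tailed Student's t-test (equal
#' variances, as in classical qPCR practice). The effect is the difference
#' of group means on the log2 scale, i.e. the mean log2 ratio to control.
#'
#' @param treated_reps,control_reps Numeric vectors of replicate log2
#'   quantities (at least 2 each).
#' @param config An [expression_config()].
#' @return One-row tibble with `log2fc`, `t`, `df`, `p` and `verdict`
#'   (`TRUE` = knockdown-like).
#' @examples
#' expression_call(c(-2.1, -1.9, -2.0), c(0.05, -0.02, 0.01))
#' @export
expression_call <- function(treated_reps, control_reps,
                            config = expression_config()) {
  if (length(treated_reps) < 2L || length(control_reps) < 2L) {
    stop("need at least 2 replicates per group", call. = FALSE)
  }
  tt <- stats::t.test(treated_reps, control_reps, var.equal = TRUE,
                      alternative = "two.sided")
  log2fc <- mean(treated_reps) - mean(control_reps)
  tibble::tibble(
    log2fc = log2fc,
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p = tt$p.value,
    verdict = log2fc < config$log2_threshold & tt$p.value < config$p_threshold
  )
}

#' Differential calls for a replicate table
#'
#' Applies [expression_call()] per reagent x target transcript, comparing
#' `treated` against `control` replicates.
#'
#' @param replicates Data frame with columns `reagent_id`, `target`,
#'   `group` (`"treated"`/`"control"`), `log2_value`.
#' @param config An [expression_config()].
#' @return Tibble with one call per reagent x target. When `config$adjust`
#'   is set, `p_adj` (Benjamini-Hochberg across the table) is added and used
#'   for the verdict instead of `p`.
#' @export
call_expression_changes <- function(replicates,
                                    config = expression_config()) {
  stopifnot(is.data.frame(replicates))
  needed <- c("reagent_id", "target", "group", "log2_value")
  missing_cols <- setdiff(needed, names(replicates))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- replicates |>
    dplyr::group_by(.data$reagent_id, .data$target) |>
    dplyr::group_modify(function(df, key) {
      expression_call(df$log2_value[df$group == "treated"],
                      df$log2_value[df$group == "control"],
                      config = config)
    }) |>
    dplyr::ungroup()
  if (config$adjust) {
    out <- out |>
      dplyr::mutate(
        p_adj = stats::p.adjust(.data$p, method = "BH"),
        verdict = .data$log2fc < config$log2_threshold &
          .data$p_adj < config$p_threshold
      )
  }
  out
}

#' Transcript exon model
#'
#' Exon lengths in transcript order with the CDS anchored by the exon and
#' 1-based offset of its first (start codon) and last (stop codon) base.
#'
#' @param exon_ids Exon identifiers, 5' to 3'.
#' @param exon_lengths Positive exon lengths in nt.
#' @param cds_start Length-2 vector `(exon_id, offset)` of the first CDS
#'   base.
#' @param cds_end Length-2 vector `(exon_id, offset)` of the last CDS base.
#' @param intron_lengths Optional numeric vector of the
#'   `length(exon_ids) - 1` intron lengths (needed to classify retained
#'   introns).
#' @return A list of class `exon_model` with per-exon CDS overlap
#'   precomputed.
#' @examples
#' exon_model(c("I", "II", "III"), c(100, 120, 200),
#'            cds_start = c("II", 10), cds_end = c("III", 60))
#' @export
exon_model <- function(exon_ids, exon_lengths, cds_start, cds_end,
                       intron_lengths = NULL) {
  exon_ids <- as.character(exon_ids)
  exon_lengths <- as.numeric(exon_lengths)
  if (length(exon_ids) != length(exon_lengths) ||
      anyDuplicated(exon_ids) > 0L) {
    stop("`exon_ids` must be distinct and match `exon_lengths`",
         call. = FALSE)
  }
  if (any(exon_lengths <= 0)) stop("exon lengths must be > 0", call. = FALSE)
  anchor <- function(a, what) {
    ex <- as.character(a[1]); off <- as.numeric(a[2])
    i <- match(ex, exon_ids)
    if (is.na(i)) stop(what, " exon not in `exon_ids`: ", ex, call. = FALSE)
    if (off < 1 || off > exon_lengths[i]) {
      stop(what, " offset outside exon ", ex, call. = FALSE)
    }
    list(exon = i, offset = off)
  }
  s <- anchor(cds_start, "cds_start")
  e <- anchor(cds_end, "cds_end")
  cum <- cumsum(c(0, exon_lengths))
  start_pos <- cum[s$exon] + s$offset
  end_pos <- cum[e$exon] + e$offset
  if (start_pos >= end_pos) {
    stop("cds_start must precede cds_end in transcript coordinates",
         call. = FALSE)
  }
  if (!is.null(intron_lengths) &&
      length(intron_lengths) != length(exon_ids) - 1L) {
    stop("`intron_lengths` must have length(exon_ids) - 1 entries",
         call. = FALSE)
  }
  # CDS overlap of each exon, in nt
  ex_start <- cum[-length(cum)] + 1
  ex_end <- cum[-1]
  cds_overlap <- pmax(0, pmin(ex_end, end_pos) - pmax(ex_start, start_pos) + 1)
  structure(
    list(exon_ids = exon_ids, exon_lengths = exon_lengths,
         start_exon = s$exon, end_exon = e$exon,
         cds_start_pos = start_pos, cds_end_pos = end_pos,
         cds_overlap = cds_overlap, intron_lengths = intron_lengths),
    class = "exon_model"
  )
}

#' @export
print.exon_model <- function(x, ...) {
  cat("<exon_model>", length(x$exon_ids), "exons;",
      "CDS", x$cds_start_pos, "-", x$cds_end_pos, "nt\n")
  df <- tibble::tibble(exon = x$exon_ids, length = x$exon_lengths,
                       cds_nt = x$cds_overlap)
  print(df, n = nrow(df))
  invisible(x)
}

#' Synthetic mapk-like exon model
#'
#' A synthetic eight-exon transcript model (exons I-VIII) built to carry
#' the frame properties of the Drosophila mapk transcript relevant to
#' isoform classification, whose true exon lengths are not reproduced here:
#' exon I is noncoding, exon II carries the start codon (skipping it loses
#' the start site), the CDS portions of exons IV and VII are multiples of 3
#' (skipping either yields an in-frame deletion), the CDS portion of exon
#' III is not (skipping it frameshifts), and the stop codon lies in exon
#' VIII. The long first intron mirrors an intron-retention isoform whose
#' retained intron precedes the CDS and therefore leaves the protein
#' normal.
#'
#' @return An [exon_model()].
#' @export
mapk_exon_model <- function() {
  exon_model(
    exon_ids = c("I", "II", "III", "IV", "V", "VI", "VII", "VIII"),
    exon_lengths = c(150, 120, 100, 141, 130, 96, 159, 400),
    cds_start = c("II", 61),
    cds_end = c("VIII", 100),
    intron_lengths = c(1900, 60, 70, 65, 80, 75, 90)
  )
}

#' Classify the ORF consequence of an exon-inclusion pattern
#'
#' Given an exon model and an observed inclusion mask (1 = exon present in
#' the sequenced clone, 0 = skipped), classifies the encoded protein
#' product:
#'
#' * `no_start` — the exon carrying the start codon is skipped; no
#'   translation from the annotated start (frameshifting/start-loss class);
#' * `N` — normal: every CDS-overlapping exon included and no CDS intron
#'   retained;
#' * `T` — truncated: total removed/inserted CDS length is a multiple of 3
#'   and the start and stop codons survive (in-frame deletion or insertion);
#' * `F` — frameshifted: the removed/inserted CDS length is not a multiple
#'   of 3, or the stop-codon exon is lost.
#'
#' Retained introns contribute their length to the frame computation when
#' they fall inside the CDS (both flanking exons included and the CDS
#' spanning the junction); a retained intron outside the CDS is silent.
#'
#' @param model An [exon_model()].
#' @param mask Logical or 0/1 vector, one entry per exon.
#' @param retained_introns Integer indices of retained introns (intron `i`
#'   separates exons `i` and `i + 1`); requires `intron_lengths` in the
#'   model.
#' @return A single string: `"N"`, `"T"`, `"F"` or `"no_start"`.
#' @examples
#' m <- mapk_exon_model()
#' classify_splice_product(m, rep(1, 8))                   # "N"
#' classify_splice_product(m, c(1, 1, 1, 0, 1, 1, 1, 1))   # exon IV out: "T"
#' classify_splice_product(m, c(1, 0, 1, 1, 1, 1, 1, 1))   # start lost
#' @export
classify_splice_product <- function(model, mask, retained_introns = NULL) {
  stopifnot(inherits(model, "exon_model"))
  mask <- as.logical(mask)
  if (length(mask) != length(model$exon_ids) || anyNA(mask)) {
    stop("`mask` must be one non-NA entry per exon (",
         length(model$exon_ids), ")", call. = FALSE)
  }
  cum <- cumsum(c(0, model$exon_lengths))
  exon_of <- function(pos) findInterval(pos, cum, left.open = TRUE)
  # start/stop codons can span an exon junction: every base must survive
  start_exons <- unique(exon_of(model$cds_start_pos + 0:2))
  stop_exons <- unique(exon_of(model$cds_end_pos - 2:0))
  if (!all(mask[start_exons])) {
    return("no_start")
  }
  if (!all(mask[stop_exons])) {
    return("F")
  }
  skipped_cds <- sum(model$cds_overlap[!mask])
  retained_cds <- 0
  if (length(retained_introns) > 0L) {
    if (is.null(model$intron_lengths)) {
      stop("model has no `intron_lengths`; cannot classify retained introns",
           call. = FALSE)
    }
    retained_introns <- as.integer(retained_introns)
    if (any(retained_introns < 1L |
            retained_introns > length(model$intron_lengths))) {
      stop("retained intron index out of range", call. = FALSE)
    }
    for (i in retained_introns) {
      if (!mask[i] || !mask[i + 1L]) {
        stop("retained intron ", i, " has a skipped flanking exon",
             call. = FALSE)
      }
      # intron i lies within the CDS iff the CDS spans the exon i / i+1
      # junction in transcript coordinates
      junction_left <- cum[i + 1L]
      if (model$cds_start_pos <= junction_left &&
          model$cds_end_pos > junction_left) {
        retained_cds <- retained_cds + model$intron_lengths[i]
      }
    }
  }
  if (skipped_cds == 0 && retained_cds == 0) {
    return("N")
  }
  if ((skipped_cds + retained_cds) %% 3 == 0) "T" else "F"
}

#' Classify a table of sequenced clones
#'
#' Vectorized wrapper around [classify_splice_product()] for a clone table
#' in the supplementary layout: one row per sequenced clone, exon inclusion
#' indicated by 1/0 columns named after the model's exons.
#'
#' @param clones Data frame with a `clone` column and one 0/1 column per
#'   exon id of `model`; an optional `retained_introns` list-column gives
#'   retained intron indices per clone.
#' @param model An [exon_model()].
#' @return Input tibble plus a `product` column (`N`/`T`/`F`/`no_start`).
#' @export
classify_clone_table <- function(clones, model) {
  stopifnot(is.data.frame(clones), inherits(model, "exon_model"))
  missing_cols <- setdiff(model$exon_ids, names(clones))
  if (length(missing_cols) > 0L) {
    stop("missing exon column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  masks <- as.matrix(clones[model$exon_ids])
  ri <- if ("retained_introns" %in% names(clones)) {
    clones$retained_introns
  } else {
    rep(list(NULL), nrow(clones))
  }
  tibble::as_tibble(clones) |>
    dplyr::mutate(product = purrr::map_chr(seq_len(nrow(clones)), function(i) {
      classify_splice_product(model, masks[i, ], retained_introns = ri[[i]])
    }))
}
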