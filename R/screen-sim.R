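#' Simulation configuration for a synthetic RNAi screen
#'
#' Defines the study conditions for a simulated quantitative-immunofluorescence
#' screen: 96-well plates carrying negative-control (GFP dsRNA) and
#' positive-control (mek, down; PTP-ER, up) wells on every plate,
#' multiplicative plate effects, log-normal well noise (additive Gaussian on
#' the log10 scale, since immunofluorescence intensity errors are
#' multiplicative), and planted regulator genes whose six-assay epistasis
#' profiles follow the three ideal interval profiles.
#'
#' Gene classes:
#' * `none` — inert gene, no effect anywhere;
#' * `RAS-RAF`, `RAF-MEK`, `MEK-MAPK` — true pathway regulators; the expected
#'   log10 normalized signal in assay k is `s * effect * y[k]` where `y` is
#'   the interval's ideal profile and `s` is −1 for positive regulators
#'   (knockdown lowers pMAPK) and +1 for negative regulators;
#' * `promoter-artifact` — a gene that perturbs the metallothionein-promoter
#'   expression system rather than the pathway: it shows a MEK-MAPK-like
#'   apparent profile on all six (promoter-driven) assays and an equal effect
#'   on the two promoter-reporter assays (`PMET_GFP`, `PMET_HA_RASV12`),
#'   scaled by `promoter_coupling`, so the promoter filter has something to
#'   catch;
#' * `jnk-nonspecific` — a non-specific gene with a MEK-MAPK-like pathway
#'   profile that equally perturbs the two JNK assays (`RAC1V12_PJNK`,
#'   `PGN_PJNK`).
#'
#' @param n_genes Number of library genes.
#' @param class_fractions Named proportions per class; must sum to 1.
#' @param effect_size Mean |effect| in log10 units for perturbing classes.
#' @param effect_sd Between-gene sd of the drawn |effect| (0 = all genes get
#'   exactly `effect_size`).
#' @param noise_sd Well-level noise sd on the log10 scale.
#' @param plate_effect_sd Per-plate multiplicative bias sd on the log10 scale.
#' @param wells_per_plate Plate capacity (default 96).
#' @param n_neg_controls_per_plate,n_pos_controls_per_plate Control wells per
#'   plate; positive controls are split evenly between the down (mek) and up
#'   (PTP-ER) reagents.
#' @param replicates Wells per gene per assay.
#' @param prob_positive_regulator Probability that a perturbing gene is a
#'   positive regulator (sign −1).
#' @param pos_down_effect,pos_up_effect Log10 effects of the two positive
#'   controls.
#' @param promoter_coupling Reporter effect per unit pMAPK effect for
#'   promoter-artifact genes.
#' @param base_signal Raw intensity corresponding to log10 value 0.
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @return A list of class `sim_config`.
#' @examples
#' sim_config(n_genes = 60, seed = 1)
#' @export
sim_config <- function(n_genes = 300,
                       class_fractions = c("none" = 0.70,
                                           "RAS-RAF" = 0.05,
                                           "RAF-MEK" = 0.03,
                                           "MEK-MAPK" = 0.12,
                                           "promoter-artifact" = 0.06,
                                           "jnk-nonspecific" = 0.04),
                       effect_size = 1.0,
                       effect_sd = 0,
                       noise_sd = 0.06,
                       plate_effect_sd = 0.05,
                       wells_per_plate = 96,
                       n_neg_controls_per_plate = 4,
                       n_pos_controls_per_plate = 4,
                       replicates = 2,
                       prob_positive_regulator = 0.7,
                       pos_down_effect = -1.0,
                       pos_up_effect = 0.44,
                       promoter_coupling = 1.0,
                       base_signal = 1000,
                       seed = 1L) {
  known <- c("none", "RAS-RAF", "RAF-MEK", "MEK-MAPK",
             "promoter-artifact", "jnk-nonspecific")
  if (is.null(names(class_fractions)) ||
      !all(names(class_fractions) %in% known)) {
    stop("`class_fractions` must be named with classes among: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  if (abs(sum(class_fractions) - 1) > 1e-9 || any(class_fractions < 0)) {
    stop("`class_fractions` must be nonnegative and sum to 1", call. = FALSE)
  }
  if (noise_sd < 0 || plate_effect_sd < 0 || effect_sd < 0) {
    stop("standard deviations must be >= 0", call. = FALSE)
  }
  if (replicates < 1) stop("`replicates` must be >= 1", call. = FALSE)
  if (n_neg_controls_per_plate < 1) {
    stop("at least one negative-control well per plate is required",
         call. = FALSE)
  }
  if (n_pos_controls_per_plate < 2) {
    stop("at least two positive-control wells per plate are required ",
         "(one down, one up)", call. = FALSE)
  }
  n_ctrl <- n_neg_controls_per_plate + n_pos_controls_per_plate
  if (wells_per_plate <= n_ctrl) {
    stop("`wells_per_plate` leaves no sample wells after controls",
         call. = FALSE)
  }
  structure(
    list(n_genes = as.integer(n_genes),
         class_fractions = class_fractions,
         effect_size = effect_size, effect_sd = effect_sd,
         noise_sd = noise_sd, plate_effect_sd = plate_effect_sd,
         wells_per_plate = as.integer(wells_per_plate),
         n_neg_controls_per_plate = as.integer(n_neg_controls_per_plate),
         n_pos_controls_per_plate = as.integer(n_pos_controls_per_plate),
         replicates = as.integer(replicates),
         prob_positive_regulator = prob_positive_regulator,
         pos_down_effect = pos_down_effect, pos_up_effect = pos_up_effect,
         promoter_coupling = promoter_coupling,
         base_signal = base_signal, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# assay panel used by the simulator: the six epistasis assays plus the two
# promoter reporters and the two JNK-specificity assays
sim_assays <- function() {
  c(epistasis_panel()$assays,
    "PMET_GFP", "PMET_HA_RASV12", "RAC1V12_PJNK", "PGN_PJNK")
}

# expected log10 effect matrix: genes x assays
expected_effects <- function(truth, assays) {
  panel <- epistasis_panel()
  eff <- matrix(0, nrow = nrow(truth), ncol = length(assays),
                dimnames = list(truth$gene_id, assays))
  s <- ifelse(truth$sign == "positive", -1,
              ifelse(truth$sign == "negative", 1, 0))
  for (i in seq_len(nrow(truth))) {
    cls <- truth$regulator_class[i]
    if (cls == "none") next
    amp <- s[i] * truth$effect[i]
    if (cls %in% names(panel$profiles)) {
      eff[i, panel$assays] <- amp * panel$profiles[[cls]]
    } else if (cls == "promoter-artifact") {
      # all six epistasis assays are driven by the same inducible promoter,
      # so a promoter-level artifact mimics a MEK-MAPK profile
      eff[i, panel$assays] <- amp
      eff[i, c("PMET_GFP", "PMET_HA_RASV12")] <-
        amp * attr(truth, "promoter_coupling")
    } else if (cls == "jnk-nonspecific") {
      eff[i, panel$assays] <- amp
      eff[i, c("RAC1V12_PJNK", "PGN_PJNK")] <- amp
    }
  }
  eff
}

#' Generate a synthetic screen with known ground truth
#'
#' Lays genes out round-robin onto plates (in gene order, plate order
#' recorded), adds the configured control wells to every plate, draws a
#' per-plate log10 bias and per-well log10 noise, and emits one well per
#' gene x assay x replicate. Raw signal is
#' `base_signal * 10^(plate_effect + expected_effect + noise)`.
#'
#' @param config A [sim_config()].
#' @return A list of class `screen_sim` with elements
#' * `wells`: tibble with columns `plate`, `well`, `reagent_id`, `role`
#'   (`sample`/`neg_ctrl`/`pos_ctrl_down`/`pos_ctrl_up`), `assay`,
#'   `replicate`, `signal`, `cells`;
#' * `truth`: tibble with columns `gene_id`, `regulator_class`, `sign`,
#'   `effect`;
#' * `plate_effects`: tibble of the drawn per-plate log10 biases (for
#'   diagnostics and testing);
#' * `config`: the input configuration.
#' @examples
#' sim <- generate_screen(sim_config(n_genes = 30, seed = 7))
#' head(sim$wells)
#' dplyr::count(sim$truth, regulator_class)
#' @export
generate_screen <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  n <- config$n_genes
  classes <- names(config$class_fractions)
  # deterministic class counts (largest-remainder), then a seeded shuffle
  raw <- config$class_fractions * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    topup <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[topup] <- cnt[topup] + 1
  }
  gene_class <- sample(rep(classes, times = cnt))
  gene_id <- sprintf("gene%04d", seq_len(n))

  perturbing <- gene_class != "none"
  sign <- rep("none", n)
  sign[perturbing] <- ifelse(
    stats::runif(sum(perturbing)) < config$prob_positive_regulator,
    "positive", "negative")
  effect <- rep(0, n)
  if (config$effect_sd > 0) {
    effect[perturbing] <- abs(stats::rnorm(sum(perturbing),
                                           mean = config$effect_size,
                                           sd = config$effect_sd))
  } else {
    effect[perturbing] <- config$effect_size
  }

  truth <- tibble::tibble(gene_id = gene_id, regulator_class = gene_class,
                          sign = sign, effect = effect)
  attr(truth, "promoter_coupling") <- config$promoter_coupling
  assays <- sim_assays()
  eff <- expected_effects(truth, assays)

  # plate layout: round-robin in gene order within each assay x replicate
  n_ctrl <- config$n_neg_controls_per_plate + config$n_pos_controls_per_plate
  samples_per_plate <- config$wells_per_plate - n_ctrl
  n_plates_per_pass <- ceiling(n / samples_per_plate)
  n_pos_down <- ceiling(config$n_pos_controls_per_plate / 2)
  n_pos_up <- config$n_pos_controls_per_plate - n_pos_down

  well_ids <- function(k) {
    row <- ((seq_len(k) - 1L) %/% 12L) + 1L
    col <- ((seq_len(k) - 1L) %% 12L) + 1L
    sprintf("%s%02d", LETTERS[row], col)
  }

  passes <- expand.grid(replicate = seq_len(config$replicates),
                        assay = assays, stringsAsFactors = FALSE)
  plate_counter <- 0L
  all_wells <- vector("list", nrow(passes))
  all_effects <- vector("list", nrow(passes))
  for (p in seq_len(nrow(passes))) {
    assay <- passes$assay[p]
    repl <- passes$replicate[p]
    plate_in_pass <- ((seq_len(n) - 1L) %/% samples_per_plate) + 1L
    plates <- plate_counter + seq_len(n_plates_per_pass)
    plate_counter <- plate_counter + n_plates_per_pass
    plate_bias <- stats::rnorm(n_plates_per_pass, 0, config$plate_effect_sd)

    per_plate <- lapply(seq_len(n_plates_per_pass), function(j) {
      idx <- which(plate_in_pass == j)
      roles <- c(rep("neg_ctrl", config$n_neg_controls_per_plate),
                 rep("pos_ctrl_down", n_pos_down),
                 rep("pos_ctrl_up", n_pos_up),
                 rep("sample", length(idx)))
      reagents <- c(rep("GFP", config$n_neg_controls_per_plate),
                    rep("mek", n_pos_down), rep("PTP-ER", n_pos_up),
                    gene_id[idx])
      mu <- unname(c(rep(0, config$n_neg_controls_per_plate),
                     rep(config$pos_down_effect, n_pos_down),
                     rep(config$pos_up_effect, n_pos_up),
                     eff[idx, assay]))
      k <- length(roles)
      log10_val <- plate_bias[j] + mu + stats::rnorm(k, 0, config$noise_sd)
      tibble::tibble(
        plate = sprintf("P%04d", plates[j]),
        well = well_ids(k),
        reagent_id = reagents,
        role = roles,
        assay = assay,
        replicate = repl,
        signal = config$base_signal * 10^log10_val,
        cells = stats::rpois(k, lambda = 2000)
      )
    })
    all_wells[[p]] <- dplyr::bind_rows(per_plate)
    all_effects[[p]] <- tibble::tibble(
      plate = sprintf("P%04d", plates), assay = assay,
      log10_bias = plate_bias)
  }

  structure(
    list(wells = dplyr::bind_rows(all_wells), truth = truth,
         plate_effects = dplyr::bind_rows(all_effects), config = config),
    class = "screen_sim"
  )
}

#' @export
print.screen_sim <- function(x, ...) {
  cat("<screen_sim>\n")
  cat("  genes:  ", x$config$n_genes, "\n")
  cat("  wells:  ", nrow(x$wells), "across",
      length(unique(x$wells$plate)), "plates,",
      length(unique(x$wells$assay)), "assays\n")
  tab <- table(x$truth$regulator_class)
  cat("  truth:  ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}
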