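# Independent reference implementations used as oracles. These are written
# deliberately in plain loops so they share no code path with the package.

# uncentered weighted Pearson via explicit loops
loop_uncentered_pearson <- function(x, y, w) {
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_along(x)) {
    num <- num + w[i] * x[i] * y[i]
    dx <- dx + w[i] * x[i]^2
    dy <- dy + w[i] * y[i]^2
  }
  num / sqrt(dx * dy)
}

# exhaustive interval assignment using the loop correlation
loop_classify <- function(x, w = c(3, 1, 1, 1, 1, 2)) {
  profiles <- list("RAS-RAF" = c(1, 0, 0, 0, 0, 0),
                   "RAF-MEK" = c(1, 1, 1, 1, 0, 0),
                   "MEK-MAPK" = c(1, 1, 1, 1, 1, 1))
  r <- sapply(profiles, function(y) loop_uncentered_pearson(x, y, w))
  if (all(abs(r) <= 0.5)) {
    return(list(interval = "unassigned", sign = NA_character_, r = r))
  }
  best <- which.max(abs(r))
  list(interval = names(profiles)[best],
       sign = if (r[best] < 0) "positive" else "negative", r = r)
}

# naive average-linkage agglomeration on a distance matrix; returns the
# sorted merge heights
loop_average_linkage_heights <- function(d) {
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dij <- mean(d[clusters[[i]], clusters[[j]]])
        if (dij < best_d) {
          best_d <- dij; best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# translation-by-provenance oracle for the splice classifier: walk the
# spliced base-index vector codon by codon from the start codon and test
# whether the original stop-codon triplet is reached in frame
translate_oracle <- function(model, mask) {
  cum <- cumsum(c(0, model$exon_lengths))
  spliced <- integer(0)
  for (i in seq_along(mask)) {
    if (mask[i]) spliced <- c(spliced, (cum[i] + 1L):cum[i + 1L])
  }
  s <- model$cds_start_pos
  e <- model$cds_end_pos
  pos <- match(s, spliced)
  start_ok <- !is.na(pos) && pos + 2L <= length(spliced) &&
    all(spliced[pos + 0:2] == s + 0:2)
  if (!start_ok) return("no_start")
  k <- pos
  while (k + 2L <= length(spliced)) {
    if (all(spliced[k + 0:2] == (e - 2L):e)) {
      cds_idx <- s:e
      if (all(cds_idx %in% spliced)) return("N")
      return("T")
    }
    k <- k + 3L
  }
  "F"
}

# random exon model + inclusion mask for classifier fuzzing
random_exon_case <- function() {
  n <- sample(3:8, 1)
  lens <- sample(30:200, n, replace = TRUE)
  total <- sum(lens)
  cum <- cumsum(c(0, lens))
  s_pos <- sample(seq_len(total - 12L), 1)
  # a well-formed ORF: CDS length a multiple of 3
  max_codons <- (total - s_pos + 1L) %/% 3L
  e_pos <- s_pos + 3L * sample(3:max_codons, 1) - 1L
  exon_of <- function(p) findInterval(p, cum, left.open = TRUE)
  ids <- as.character(seq_len(n))
  model <- exon_model(
    ids, lens,
    cds_start = c(ids[exon_of(s_pos)], s_pos - cum[exon_of(s_pos)]),
    cds_end = c(ids[exon_of(e_pos)], e_pos - cum[exon_of(e_pos)])
  )
  mask <- stats::runif(n) > 0.3
  list(model = model, mask = mask)
}

# small helper: gene profiles tibble from a matrix
profiles_tbl <- function(mat, genes = sprintf("g%02d", seq_len(nrow(mat))),
                         assays = epistasis_panel()$assays) {
  colnames(mat) <- assays
  dplyr::bind_cols(tibble::tibble(gene = genes), tibble::as_tibble(mat))
}

# end-to-end interval recovery rate on a simulated screen: classify the
# aggregated six-assay profiles of the planted regulators against truth
recovery_rate <- function(sim) {
  panel <- epistasis_panel()
  profs <- sim$wells |>
    normalize_wells() |>
    aggregate_replicates() |>
    dplyr::filter(role == "sample") |>
    tidyr::pivot_wider(id_cols = reagent_id, names_from = assay,
                       values_from = value) |>
    dplyr::rename(gene = reagent_id)
  calls <- classify_epistasis(
    dplyr::select(profs, dplyr::all_of(c("gene", panel$assays))))
  merged <- dplyr::inner_join(calls, sim$truth,
                              by = c(gene = "gene_id"),
                              suffix = c("", "_true"))
  reg <- dplyr::filter(merged,
                       regulator_class %in% c("RAS-RAF", "RAF-MEK",
                                              "MEK-MAPK"))
  list(
    interval_ok = mean(reg$interval == reg$regulator_class),
    sign_ok = mean(reg$sign == reg$sign_true),
    both_ok = mean(reg$interval == reg$regulator_class &
                     reg$sign == reg$sign_true),
    calls = calls, merged = merged
  )
}
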