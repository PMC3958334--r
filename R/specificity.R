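#' Specificity scoring configuration
#'
#' Weights and scale parameters of the additive penalty model behind
#' [specificity_score()]. Each component penalty lies in `[0, 1]`; the final
#' score is `1 - weighted mean(penalties)`, so 1 is a perfectly specific
#' gene and worsening any single component can only lower the score.
#'
#' @param weights Named weights for the components `prior`, `jnk`, `pmet`,
#'   `western`, `export`, `cells`.
#' @param prior_cap Prior-screen occurrence count at which the `prior`
#'   penalty saturates at 1.
#' @param export_scale Excess nuclear-retention index (above the
#'   control-normalized baseline of 1) at which the `export` penalty
#'   saturates.
#' @param cells_scale Log10 cell-count drop at which the `cells` penalty
#'   saturates.
#' @param high_cutoff,low_cutoff Final-score thresholds for the
#'   `high`/`medium`/`low` specificity groups.
#' @return A list of class `specificity_config`.
#' @export
specificity_config <- function(weights = c(prior = 1, jnk = 1, pmet = 1,
                                           western = 1, export = 1,
                                           cells = 1),
                               prior_cap = 5,
                               export_scale = 1,
                               cells_scale = 1,
                               high_cutoff = 2 / 3,
                               low_cutoff = 1 / 3) {
  comp <- c("prior", "jnk", "pmet", "western", "export", "cells")
  if (!all(comp %in% names(weights)) || any(weights < 0)) {
    stop("`weights` must be nonnegative and named: ",
         paste(comp, collapse = ", "), call. = FALSE)
  }
  if (!(low_cutoff < high_cutoff)) {
    stop("need low_cutoff < high_cutoff", call. = FALSE)
  }
  structure(
    list(weights = weights[comp], prior_cap = prior_cap,
         export_scale = export_scale, cells_scale = cells_scale,
         high_cutoff = high_cutoff, low_cutoff = low_cutoff),
    class = "specificity_config"
  )
}

#' Composite specificity score
#'
#' Scores how specifically a candidate acts on RAS/MAPK signaling, combining
#' the signals the screen used to demote non-specific hits: occurrence in
#' previously published RNAi screens, effect on the two pJNK assays relative
#' to the gene's pMAPK effect, effect on pMet-driven reporter expression,
#' non-specific protein-level changes on Western blot, excess nuclear mRNA
#' retention, and loss of cell count (toxicity). Component penalties:
#'
#' * `prior`: `min(prior_screen_hits / prior_cap, 1)`
#' * `jnk`: `min(max(|jnk1|, |jnk2|) / |pmapk|, 1)` — a pJNK effect equal to
#'   the pMAPK effect is maximally non-specific
#' * `pmet`: `min(|pmet_gfp| / |pmapk|, 1)`
#' * `western`: 1 for a `nonspecific` flag, else 0
#' * `export`: `min(max(index - 1, 0) / export_scale, 1)` for a
#'   control-normalized retention index
#' * `cells`: `min(max(-cell_count_effect, 0) / cells_scale, 1)`
#'
#' Missing (`NA`) components are skipped with the remaining weights
#' renormalized; the number skipped is reported per gene.
#'
#' @param inputs Data frame with columns `gene`, `pmapk_effect`,
#'   `prior_screen_hits`, `jnk_effect_rac`, `jnk_effect_pgn`,
#'   `pmet_gfp_effect`, `western_flag` (`specific`/`nonspecific`/
#'   `no_effect`), `export_retention_index`, `cell_count_effect`. Any of the
#'   component columns may contain `NA`.
#' @param config A [specificity_config()].
#' @return Tibble with the per-component penalties (`penalty_*`),
#'   `n_missing`, `final_score` in `[0, 1]` and `group`
#'   (`high`/`medium`/`low`).
#' @examples
#' clean <- tibble::tibble(gene = "g1", pmapk_effect = -1,
#'   prior_screen_hits = 0, jnk_effect_rac = 0, jnk_effect_pgn = 0,
#'   pmet_gfp_effect = 0, western_flag = "specific",
#'   export_retention_index = 1, cell_count_effect = 0)
#' specificity_score(clean)
#' @export
specificity_score <- function(inputs, config = specificity_config()) {
  stopifnot(is.data.frame(inputs), inherits(config, "specificity_config"))
  needed <- c("gene", "pmapk_effect", "prior_screen_hits", "jnk_effect_rac",
              "jnk_effect_pgn", "pmet_gfp_effect", "western_flag",
              "export_retention_index", "cell_count_effect")
  missing_cols <- setdiff(needed, names(inputs))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(inputs$prior_screen_hits < 0, na.rm = TRUE)) {
    stop("`prior_screen_hits` must be >= 0", call. = FALSE)
  }
  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  ref <- pmax(abs(inputs$pmapk_effect), .Machine$double.eps)

  pen <- tibble::tibble(
    penalty_prior = clamp01(inputs$prior_screen_hits / config$prior_cap),
    penalty_jnk = clamp01(
      pmax(abs(inputs$jnk_effect_rac), abs(inputs$jnk_effect_pgn)) / ref),
    penalty_pmet = clamp01(abs(inputs$pmet_gfp_effect) / ref),
    penalty_western = as.numeric(inputs$western_flag == "nonspecific"),
    penalty_export = clamp01(
      pmax(inputs$export_retention_index - 1, 0) / config$export_scale),
    penalty_cells = clamp01(
      pmax(-inputs$cell_count_effect, 0) / config$cells_scale)
  )
  w <- config$weights
  pen_mat <- as.matrix(pen)
  w_mat <- matrix(w, nrow = nrow(pen_mat), ncol = 6L, byrow = TRUE)
  w_mat[is.na(pen_mat)] <- 0
  n_missing <- rowSums(is.na(pen_mat))
  wsum <- rowSums(w_mat)
  if (any(wsum <= 0)) {
    stop("all components missing (or zero-weighted) for gene(s): ",
         paste(inputs$gene[wsum <= 0], collapse = ", "), call. = FALSE)
  }
  pen_mat[is.na(pen_mat)] <- 0
  final <- 1 - rowSums(pen_mat * w_mat) / wsum

  dplyr::bind_cols(tibble::tibble(gene = inputs$gene), pen) |>
    dplyr::mutate(
      n_missing = n_missing,
      final_score = final,
      group = dplyr::case_when(
        final >= config$high_cutoff ~ "high",
        final < config$low_cutoff ~ "low",
        TRUE ~ "medium"
      )
    )
}

# pairwise uncentered correlation matrix between the rows of x
uncentered_cor <- function(x) {
  norms <- sqrt(rowSums(x^2))
  (x %*% t(x)) / (norms %o% norms)
}

#' Hierarchical clustering of functional profiles
#'
#' Unsupervised agglomerative clustering of per-gene secondary-screen
#' profiles with distance `1 - uncentered correlation` and average linkage,
#' the combination under which genes acting in the same complex (identical
#' effect direction and shape across assays) merge near distance 0. Rows
#' are sorted by gene id before clustering so the tree and its leaf order
#' are deterministic for a given input set regardless of input order.
#'
#' @param profiles Data frame with a `gene` column and numeric assay
#'   columns.
#' @return An object of class `profile_clust`: list with `hclust` (the
#'   tree), `genes`, `assays`, and `dist` (the distance matrix).
#' @examples
#' sim <- generate_screen(sim_config(n_genes = 20, seed = 1))
#' profs <- sim$wells |>
#'   normalize_wells() |>
#'   aggregate_replicates() |>
#'   dplyr::filter(role == "sample") |>
#'   tidyr::pivot_wider(id_cols = reagent_id, names_from = assay,
#'                      values_from = value) |>
#'   dplyr::rename(gene = reagent_id)
#' ok <- rowSums(as.matrix(profs[-1])^2) > 0.05
#' cl <- cluster_profiles(profs[ok, ])
#' leaf_order(cl)
#' @export
cluster_profiles <- function(profiles) {
  stopifnot(is.data.frame(profiles))
  if (!"gene" %in% names(profiles)) {
    stop("`profiles` must have a `gene` column", call. = FALSE)
  }
  if (nrow(profiles) < 2L) {
    stop("need at least 2 genes to cluster", call. = FALSE)
  }
  if (anyDuplicated(profiles$gene) > 0L) {
    stop("duplicate gene ids in `profiles`", call. = FALSE)
  }
  profiles <- dplyr::arrange(profiles, .data$gene)
  x <- as.matrix(profiles[setdiff(names(profiles), "gene")])
  if (!is.numeric(x) || anyNA(x)) {
    stop("assay columns must be numeric without NA", call. = FALSE)
  }
  zero <- rowSums(x^2) <= 0
  if (any(zero)) {
    stop("zero-norm profile row(s): ",
         paste(profiles$gene[zero], collapse = ", "), call. = FALSE)
  }
  rownames(x) <- profiles$gene
  d <- 1 - uncentered_cor(x)
  d[d < 0] <- 0  # rounding guard
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  structure(
    list(hclust = hc, genes = profiles$gene,
         assays = setdiff(names(profiles), "gene"), dist = d),
    class = "profile_clust"
  )
}

#' Leaf order of a profile clustering
#'
#' @param x A `profile_clust` object.
#' @return Character vector of gene ids in dendrogram leaf order.
#' @export
leaf_order <- function(x) {
  stopifnot(inherits(x, "profile_clust"))
  x$genes[x$hclust$order]
}

#' Export a profile clustering as a Newick tree
#'
#' @param x A `profile_clust` object.
#' @param path File to write; when `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to file.
#' @export
write_newick <- function(x, path = NULL) {
  stopifnot(inherits(x, "profile_clust"))
  phy <- ape::as.phylo(x$hclust)
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(ape::write.tree(phy))
  }
}

#' @export
print.profile_clust <- function(x, ...) {
  cat("<profile_clust>", length(x$genes), "genes x", length(x$assays),
      "assays; average linkage on 1 - uncentered correlation\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a profile clustering
#'
#' One row per agglomeration step with the merge height (1 - uncentered
#' correlation at which the two clusters join) and resulting cluster size.
#'
#' @param x A `profile_clust` object.
#' @param ... Unused.
#' @return Tibble with columns `step`, `height`, `size`.
#' @export
tidy.profile_clust <- function(x, ...) {
  hc <- x$hclust
  size <- integer(nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    sz <- function(j) if (j < 0) 1L else size[j]
    size[i] <- sz(hc$merge[i, 1]) + sz(hc$merge[i, 2])
  }
  tibble::tibble(step = seq_along(hc$height), height = hc$height,
                 size = size)
}

#' Glance at a profile clustering
#'
#' @param x A `profile_clust` object.
#' @param ... Unused.
#' @return One-row tibble with `n_genes`, `n_assays`, `max_height`, and the
#'   cophenetic correlation between tree and input distances.
#' @export
glance.profile_clust <- function(x, ...) {
  coph <- stats::cophenetic(x$hclust)
  tibble::tibble(
    n_genes = length(x$genes),
    n_assays = length(x$assays),
    max_height = max(x$hclust$height),
    cophenetic_cor = stats::cor(as.vector(coph),
                                as.vector(stats::as.dist(x$dist)))
  )
}

# dendrogram segments for ggplot drawing
hclust_segments <- function(hc) {
  n <- length(hc$order)
  leaf_x <- numeric(n)
  leaf_x[hc$order] <- seq_len(n)
  cx <- numeric(nrow(hc$merge))
  ch <- numeric(nrow(hc$merge))
  segs <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    pos <- function(j) {
      if (j < 0) c(leaf_x[-j], 0) else c(cx[j], ch[j])
    }
    a <- pos(hc$merge[i, 1]); b <- pos(hc$merge[i, 2])
    h <- hc$height[i]
    cx[i] <- (a[1] + b[1]) / 2
    ch[i] <- h
    segs[[i]] <- tibble::tibble(
      x = c(a[1], a[1], b[1]), xend = c(a[1], b[1], b[1]),
      y = c(a[2], h, h), yend = c(h, h, b[2])
    )
  }
  dplyr::bind_rows(segs)
}

#' Plot a profile clustering dendrogram
#'
#' @param object A `profile_clust` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.profile_clust <- function(object, ...) {
  hc <- object$hclust
  segs <- hclust_segments(hc)
  leaves <- tibble::tibble(x = seq_along(hc$order),
                           gene = object$genes[hc$order])
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$x, xend = .data$xend,
                   y = .data$y, yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = leaves$x, labels = leaves$gene) +
    ggplot2::labs(x = NULL, y = "1 - uncentered correlation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}
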