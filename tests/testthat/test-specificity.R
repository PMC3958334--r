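clean_inputs <- function(gene = "g1", ...) {
  base <- tibble::tibble(
    gene = gene, pmapk_effect = -1, prior_screen_hits = 0,
    jnk_effect_rac = 0, jnk_effect_pgn = 0, pmet_gfp_effect = 0,
    western_flag = "specific", export_retention_index = 1,
    cell_count_effect = 0)
  dplyr::mutate(base, ...)
}

test_that("a clean candidate scores 1 and lands in the high group", {
  rep <- specificity_score(clean_inputs())
  expect_equal(rep$final_score, 1)
  expect_identical(rep$group, "high")
  expect_true(all(as.matrix(rep[grep("penalty_", names(rep))]) == 0))
})

test_that("a pJNK effect equal to the pMAPK effect is maximally penalized", {
  rep <- specificity_score(clean_inputs(jnk_effect_rac = -1))
  expect_equal(rep$penalty_jnk, 1)
  expect_lt(rep$final_score, 1)
})

test_that("worsening any single component never raises the score", {
  base <- specificity_score(clean_inputs())$final_score
  worse <- list(
    clean_inputs(prior_screen_hits = 3),
    clean_inputs(jnk_effect_pgn = -0.5),
    clean_inputs(pmet_gfp_effect = 0.4),
    clean_inputs(western_flag = "nonspecific"),
    clean_inputs(export_retention_index = 1.8),
    clean_inputs(cell_count_effect = -0.6))
  for (w in worse) {
    expect_lt(specificity_score(w)$final_score, base)
  }
  # and worsening further keeps moving down (monotone within a component)
  s1 <- specificity_score(clean_inputs(prior_screen_hits = 1))$final_score
  s2 <- specificity_score(clean_inputs(prior_screen_hits = 4))$final_score
  expect_lt(s2, s1)
})

test_that("missing components are skipped with renormalized weights", {
  rep <- specificity_score(clean_inputs(export_retention_index = NA,
                                        western_flag = NA))
  expect_identical(rep$n_missing, 2)
  expect_equal(rep$final_score, 1)
  # a half-penalty among 3 present components vs 6: same weighted mean
  a <- specificity_score(clean_inputs(
    jnk_effect_rac = -0.5, pmet_gfp_effect = NA, western_flag = NA,
    export_retention_index = NA))
  expect_equal(a$final_score, 1 - 0.5 / 3)
  expect_error(
    specificity_score(clean_inputs(
      pmapk_effect = -1, prior_screen_hits = NA, jnk_effect_rac = NA,
      jnk_effect_pgn = NA, pmet_gfp_effect = NA, western_flag = NA,
      export_retention_index = NA, cell_count_effect = NA)),
    "all components missing")
})

test_that("simulated non-specific genes score below planted regulators", {
  sim <- generate_screen(sim_config(
    n_genes = 80,
    class_fractions = c("MEK-MAPK" = 0.5, "jnk-nonspecific" = 0.5),
    noise_sd = 0.06, seed = 61))
  profs <- sim$wells |>
    normalize_wells() |>
    aggregate_replicates() |>
    dplyr::filter(role == "sample") |>
    tidyr::pivot_wider(id_cols = reagent_id, names_from = assay,
                       values_from = value)
  inputs <- tibble::tibble(
    gene = profs$reagent_id, pmapk_effect = profs$RASV12,
    prior_screen_hits = 0, jnk_effect_rac = profs$RAC1V12_PJNK,
    jnk_effect_pgn = profs$PGN_PJNK, pmet_gfp_effect = profs$PMET_GFP,
    western_flag = NA_character_, export_retention_index = NA_real_,
    cell_count_effect = NA_real_)
  scores <- specificity_score(inputs) |>
    dplyr::inner_join(sim$truth, by = c(gene = "gene_id"))
  spec <- scores$final_score[scores$regulator_class == "MEK-MAPK"]
  nonspec <- scores$final_score[scores$regulator_class == "jnk-nonspecific"]
  pairs <- outer(nonspec, spec, "<")
  expect_gte(mean(pairs), 0.95)
})

test_that("identical profiles merge at distance zero", {
  profs <- profiles_tbl(rbind(c(1, 1, 0, 0, 1, 0),
                              c(2, 2, 0, 0, 2, 0),   # same direction
                              c(-1, 0, 1, 0, 0, 1)),
                        genes = c("a", "b", "c"))
  cl <- cluster_profiles(profs)
  expect_equal(min(cl$hclust$height), 0, tolerance = 1e-12)
  first_pair <- sort(cl$genes[-cl$hclust$merge[1, ]])
  expect_identical(first_pair, c("a", "b"))
})

test_that("tree heights match a brute-force average-linkage agglomeration", {
  set.seed(83)
  for (rep in 1:5) {
    n <- sample(4:6, 1)
    profs <- profiles_tbl(matrix(rnorm(n * 6), ncol = 6),
                          genes = sprintf("g%02d", 1:n))
    cl <- cluster_profiles(profs)
    ref <- loop_average_linkage_heights(cl$dist)
    expect_equal(sort(cl$hclust$height), ref, tolerance = 1e-12)
  }
})

test_that("a planted co-functional block forms its own clade", {
  set.seed(29)
  block_profile <- c(-1, -0.8, -0.9, -1.1, 0.1, 0)
  block <- t(replicate(5, block_profile + rnorm(6, 0, 0.05)))
  others <- matrix(rnorm(15 * 6, 0, 0.8), ncol = 6)
  profs <- profiles_tbl(rbind(block, others),
                        genes = c(sprintf("stripak%d", 1:5),
                                  sprintf("other%02d", 1:15)))
  cl <- cluster_profiles(profs)
  # walk the merge tree; the smallest cluster containing all five block
  # genes must contain exactly those five
  hc <- cl$hclust
  members <- list()
  target <- sort(sprintf("stripak%d", 1:5))
  smallest <- NULL
  for (i in seq_len(nrow(hc$merge))) {
    get <- function(j) if (j < 0) cl$genes[-j] else members[[j]]
    members[[i]] <- c(get(hc$merge[i, 1]), get(hc$merge[i, 2]))
    if (is.null(smallest) && all(target %in% members[[i]])) {
      smallest <- members[[i]]
    }
  }
  expect_identical(sort(smallest), target)
})

test_that("clustering is input-order invariant with deterministic leaves", {
  set.seed(47)
  profs <- profiles_tbl(matrix(rnorm(8 * 6), ncol = 6),
                        genes = sprintf("g%02d", 1:8))
  cl1 <- cluster_profiles(profs)
  cl2 <- cluster_profiles(profs[sample(1:8), ])
  expect_identical(leaf_order(cl1), leaf_order(cl2))
  expect_equal(cl1$hclust$height, cl2$hclust$height)
})

test_that("constant-zero profiles are rejected with gene names", {
  profs <- profiles_tbl(rbind(c(1, 0, 0, 0, 0, 0), rep(0, 6)),
                        genes = c("ok", "flatgene"))
  expect_error(cluster_profiles(profs), "flatgene")
  expect_error(cluster_profiles(profs[1, ]), "at least 2")
})

test_that("tidy, glance and newick export describe the tree consistently", {
  set.seed(55)
  profs <- profiles_tbl(matrix(rnorm(6 * 6), ncol = 6),
                        genes = sprintf("g%d", 1:6))
  cl <- cluster_profiles(profs)
  td <- generics::tidy(cl)
  expect_identical(nrow(td), 5L)
  expect_identical(td$size[5], 6L)
  expect_true(all(diff(td$height) >= -1e-12))
  gl <- generics::glance(cl)
  expect_identical(gl$n_genes, 6L)
  expect_true(gl$cophenetic_cor > 0)
  nwk <- write_newick(cl)
  expect_match(nwk, "^\\(")
  expect_true(all(vapply(cl$genes, grepl, logical(1), x = nwk,
                         fixed = TRUE)))
})
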