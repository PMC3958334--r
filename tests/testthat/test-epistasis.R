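test_that("weighted uncentered correlation matches its closed forms", {
  w <- c(3, 1, 1, 1, 1, 2)
  x <- rep(-1, 6)
  expect_equal(weighted_uncentered_pearson(x, ideal_profile("RAS-RAF"), w),
               -1 / sqrt(3), tolerance = 1e-15)
  expect_equal(weighted_uncentered_pearson(x, ideal_profile("RAF-MEK"), w),
               -sqrt(2 / 3), tolerance = 1e-15)
  expect_equal(weighted_uncentered_pearson(x, ideal_profile("MEK-MAPK"), w),
               -1, tolerance = 1e-15)
  # self correlation and cross-profile margin sqrt(w1 / sum(w)) = 1/sqrt(3)
  e1 <- c(1, 0, 0, 0, 0, 0)
  expect_identical(weighted_uncentered_pearson(e1, e1, w), 1)
  expect_equal(
    weighted_uncentered_pearson(ideal_profile("RAS-RAF"),
                                ideal_profile("MEK-MAPK"), w),
    sqrt(3 / 9), tolerance = 1e-15)
})

test_that("correlation agrees with a loop-based reference on random input", {
  set.seed(41)
  for (i in 1:500) {
    x <- rnorm(6); y <- rnorm(6); w <- runif(6, 0.1, 4)
    expect_equal(weighted_uncentered_pearson(x, y, w),
                 loop_uncentered_pearson(x, y, w), tolerance = 1e-12)
  }
  # uniform weights reduce to the cosine similarity
  set.seed(42)
  x <- rnorm(6); y <- rnorm(6)
  expect_equal(weighted_uncentered_pearson(x, y),
               sum(x * y) / sqrt(sum(x^2) * sum(y^2)), tolerance = 1e-12)
})

test_that("correlation has the symmetry, scaling and boundedness properties", {
  set.seed(7)
  for (i in 1:50) {
    x <- rnorm(6); y <- rnorm(6); w <- runif(6, 0.1, 3)
    r <- weighted_uncentered_pearson(x, y, w)
    expect_lte(abs(r), 1)
    expect_equal(weighted_uncentered_pearson(y, x, w), r)
    a <- runif(1, 0.1, 5)
    expect_equal(weighted_uncentered_pearson(a * x, y, w), r,
                 tolerance = 1e-12)
    expect_equal(weighted_uncentered_pearson(-a * x, y, w), -r,
                 tolerance = 1e-12)
  }
  # r = +/-1 exactly iff x is a scalar multiple of y on the support of w
  y <- c(1, 1, 0, 2, 0, 1)
  expect_equal(weighted_uncentered_pearson(3 * y, y, rep(1, 6)), 1)
  expect_equal(weighted_uncentered_pearson(-0.5 * y, y, rep(1, 6)), -1)
  expect_lt(abs(weighted_uncentered_pearson(y + c(0.3, 0, 0, 0, 0, 0), y,
                                            rep(1, 6))), 1)
})

test_that("zero-norm vectors are rejected, distinguishably from r = 0", {
  expect_error(weighted_uncentered_pearson(rep(0, 6), rep(1, 6)),
               "zero-norm")
  # zero only on the support of w counts as zero-norm too
  expect_error(
    weighted_uncentered_pearson(c(0, 0, 0, 0, 0, 1), rep(1, 6),
                                w = c(1, 1, 1, 1, 1, 0)),
    "zero-norm")
  expect_error(weighted_uncentered_pearson(1:3, 1:4), "equal length")
})

test_that("ideal_profile returns the three predetermined profiles only", {
  expect_identical(ideal_profile("RAS-RAF"), c(1, 0, 0, 0, 0, 0))
  expect_identical(ideal_profile("RAF-MEK"), c(1, 1, 1, 1, 0, 0))
  expect_identical(ideal_profile("MEK-MAPK"), c(1, 1, 1, 1, 1, 1))
  expect_error(ideal_profile("none"), "unknown epistasis interval")
})

test_that("classify_epistasis reproduces the worked examples", {
  assays <- epistasis_panel()$assays
  profs <- profiles_tbl(rbind(
    c(-1, 0, 0, 0, 0, 0),      # pure RAS-RAF positive regulator
    rep(-1, 6),                # MEK-MAPK positive, intrinsically low margin
    rep(0.8, 6)                # MEK-MAPK negative regulator
  ), genes = c("rasraf", "allneg", "allpos"))
  calls <- classify_epistasis(profs)
  expect_identical(calls$interval,
                   c("RAS-RAF", "MEK-MAPK", "MEK-MAPK"))
  expect_identical(calls$sign, c("positive", "positive", "negative"))
  expect_equal(calls$r_ras_raf[1], -1)
  # the all-minus-one profile: confidence 1 - sqrt(2/3), below 0.2
  expect_equal(calls$confidence[2], 1 - sqrt(2 / 3), tolerance = 1e-12)
  expect_identical(calls$status[2], "ambiguous")
})

test_that("missing or broken profile input is reported by name", {
  profs <- profiles_tbl(matrix(rnorm(6), 1), genes = "g1")
  expect_error(classify_epistasis(profs[-2]), "RASV12")
  profs$RAFCT[1] <- NA
  expect_error(classify_epistasis(profs), "RAFCT")
})

test_that("exactly-zero profiles are unassigned rather than an error", {
  profs <- profiles_tbl(rbind(rep(0, 6), c(-1, 0, 0, 0, 0, 0)),
                        genes = c("inert", "reg"))
  calls <- classify_epistasis(profs)
  expect_identical(calls$status[1], "unassigned")
  expect_true(is.na(calls$r_ras_raf[1]))
  expect_identical(calls$interval[2], "RAS-RAF")
})

test_that("assignment agrees with exhaustive enumeration over {-1,0,1}^6", {
  grid <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), 6)))
  grid <- grid[rowSums(grid^2) > 0, ]
  calls <- classify_epistasis(profiles_tbl(
    grid, genes = sprintf("g%03d", seq_len(nrow(grid)))))
  for (i in seq_len(nrow(grid))) {
    ref <- loop_classify(as.numeric(grid[i, ]))
    if (!is.na(calls$tied_with[i])) next  # ties: argmax order-dependent
    expect_identical(calls$interval[i], ref$interval)
    if (ref$interval != "unassigned") {
      expect_identical(calls$sign[i], ref$sign)
    }
  }
})

test_that("classification is scale invariant and sign flips direction only", {
  set.seed(11)
  base <- matrix(rnorm(10 * 6, sd = 1), ncol = 6)
  base <- base[rowSums(abs(base) > 0.6) > 2, , drop = FALSE]
  calls1 <- classify_epistasis(profiles_tbl(base))
  calls2 <- classify_epistasis(profiles_tbl(3.7 * base))
  calls3 <- classify_epistasis(profiles_tbl(-base))
  expect_identical(calls1$interval, calls2$interval)
  expect_identical(calls1$sign, calls2$sign)
  expect_identical(calls1$interval, calls3$interval)
  assigned <- calls1$status != "unassigned"
  expect_true(all(calls1$sign[assigned] != calls3$sign[assigned]))
})

test_that("pure-noise profiles are mostly unassigned or ambiguous", {
  # the correlation is scale invariant, so a pure-noise profile is a random
  # direction: a minority land outside the cutoff with a clear margin, and
  # that fraction is independent of the noise magnitude
  set.seed(99)
  for (noise_sd in c(0.05, 0.5)) {
    noise <- matrix(rnorm(200 * 6, sd = noise_sd), ncol = 6)
    calls <- classify_epistasis(profiles_tbl(
      noise, genes = sprintf("n%03d", 1:200)))
    inconclusive <- mean(calls$status %in% c("unassigned", "ambiguous"))
    expect_gt(inconclusive, 0.5)
  }
})

test_that("interval census conserves gene counts", {
  empty <- classify_epistasis(profiles_tbl(matrix(0, 0, 6),
                                           genes = character(0)))
  expect_identical(sum(interval_census(empty)$n), 0L)

  set.seed(3)
  sim <- generate_screen(sim_config(
    n_genes = 30,
    class_fractions = c("RAS-RAF" = 1 / 3, "RAF-MEK" = 1 / 3,
                        "MEK-MAPK" = 1 / 3),
    noise_sd = 0.1, replicates = 2, seed = 13))
  rec <- recovery_rate(sim)
  census <- interval_census(rec$calls)
  expect_identical(sum(census$n), nrow(rec$calls))
  # 10/10/10 planted regulators recovered within <= 1 misassignment per class
  per_class <- rec$merged |>
    dplyr::group_by(regulator_class) |>
    dplyr::summarise(hits = sum(interval == regulator_class))
  expect_true(all(per_class$hits >= 9))
})
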