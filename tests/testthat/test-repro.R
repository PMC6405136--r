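test_that("ICC(A,k) matches hand-computed and oracle values", {
  # identical columns with subject variance: perfect absolute agreement
  expect_equal(icc_a_k(cbind(1:5, 1:5, 1:5)), 1)
  # consistent offset: MSR = 10/3, MSC = 2, MSE = 0 -> 3.3333/3.8333
  expect_equal(icc_a_k(cbind(1:4, 2:5)), (10 / 3) / (10 / 3 + 2 / 4),
               tolerance = 1e-12)
  # constant matrix: undefined
  expect_true(is.na(icc_a_k(matrix(3, 5, 2))))
})

test_that("ICC(A,k) agrees with an ANOVA-table oracle on random matrices", {
  withr::with_seed(21, {
    for (rep in 1:100) {
      n <- sample(4:12, 1); k <- sample(2:4, 1)
      x <- matrix(rnorm(n * k, sd = runif(1, 0.5, 3)), n, k) +
        rnorm(n) # subject effect
      expect_equal(icc_a_k(x), oracle_icc_avg(x), tolerance = 1e-10)
    }
  })
})

test_that("independently shuffled columns give near-zero ICC at large n", {
  withr::with_seed(22, {
    base <- rnorm(200)
    x <- cbind(sample(base), sample(base))
    expect_lt(abs(icc_a_k(x)), 0.2)
  })
})

test_that("Lin's CCC matches hand evaluation and bounds", {
  expect_equal(lin_ccc(1:4, 2:5), 2 * 1.25 / (1.25 + 1.25 + 1),
               tolerance = 1e-12)
  x <- c(1, 2, 3, 4)
  expect_equal(lin_ccc(x, x), 1)
  y <- c(2, 1, -1, -2)
  expect_equal(lin_ccc(y, -y), -1)
  expect_true(is.na(lin_ccc(rep(1, 4), rep(1, 4))))
  withr::with_seed(23, {
    for (rep in 1:50) {
      a <- rnorm(20); b <- 0.5 * a + rnorm(20)
      ccc <- lin_ccc(a, b)
      expect_gte(ccc, -1); expect_lte(ccc, 1)
      # CCC = Pearson r times a bias-correction factor <= 1
      r <- stats::cor(a, b)
      if (abs(r) > 1e-12) expect_lte(abs(ccc / r), 1 + 1e-12)
    }
  })
})

make_feature_table <- function(n_subj, values_by_session, feature = "f1") {
  tidyr::expand_grid(roi = paste0("roi", seq_len(n_subj)),
                     session = names(values_by_session)) |>
    dplyr::mutate(
      feature = feature,
      value = purrr::map2_dbl(roi, session, function(r, s) {
        values_by_session[[s]][match(r, paste0("roi", seq_len(n_subj)))]
      })
    )
}

test_that("selection requires all ICCs > 0.8 and CCC > 0.9, strictly", {
  base <- c(1, 5, 3, 9, 7, 2, 8, 4)
  tab <- make_feature_table(8, list(R1 = base, R2a = base, R2b = base))
  rep1 <- select_reproducible(tab, reading_design())
  expect_true(all(rep1$selected))
  # independent redraws: not selected
  withr::with_seed(24, {
    tab2 <- make_feature_table(8, list(R1 = rnorm(8), R2a = rnorm(8),
                                       R2b = rnorm(8)))
    rep2 <- select_reproducible(tab2, reading_design())
    expect_false(any(rep2$selected))
  })
  # a CCC exactly at the threshold is rejected (strict inequality)
  x <- c(1, 2, 3, 4, 5, 6)
  a <- (1 - sqrt(1 - 0.9^2)) / 0.9 # 2a/(1+a^2) ~ 0.9, shrunk about the mean
  y <- mean(x) + a * (x - mean(x))
  expect_equal(lin_ccc(x, y), 0.9, tolerance = 1e-12)
  tab3 <- make_feature_table(6, list(R1 = x, R2a = x, R2b = y))
  d_tie <- reading_design(ccc_threshold = lin_ccc(x, y)) # threshold == value
  rep3 <- select_reproducible(tab3, d_tie)
  expect_false(any(rep3$selected))
})

test_that("raising a threshold never increases the selected count", {
  withr::with_seed(25, {
    tabs <- purrr::map(1:20, function(i) {
      base <- rnorm(12)
      noise <- runif(1, 0.05, 1.5)
      make_feature_table(12, list(R1 = base + rnorm(12, 0, noise),
                                  R2a = base + rnorm(12, 0, noise),
                                  R2b = base + rnorm(12, 0, noise)),
                         feature = paste0("f", i))
    }) |> dplyr::bind_rows()
    loose <- select_reproducible(tabs, reading_design(icc_threshold = 0.6,
                                                      ccc_threshold = 0.6))
    strict <- select_reproducible(tabs, reading_design(icc_threshold = 0.9,
                                                       ccc_threshold = 0.95))
    expect_lte(sum(strict$selected), sum(loose$selected))
  })
})

test_that("constant features yield undefined coefficients and are dropped", {
  tab <- make_feature_table(6, list(R1 = rep(2, 6), R2a = rep(2, 6),
                                    R2b = rep(2, 6)))
  rep_ <- select_reproducible(tab, reading_design())
  expect_true(all(is.na(rep_$icc_R1_R2a)))
  expect_false(any(rep_$selected))
})

test_that("simulated-pair selection uses ICC only, against the reference", {
  withr::with_seed(26, {
    ref <- tibble::tibble(roi = paste0("r", 1:10), feature = "f",
                          value = rnorm(10, sd = 3))
    sim_same <- ref
    sel1 <- icc_pairwise_simulated(ref, sim_same)
    expect_true(all(sel1$selected))
    sim_bad <- dplyr::mutate(ref, value = rnorm(10))
    sel2 <- icc_pairwise_simulated(ref, sim_bad)
    expect_false(any(sel2$selected))
    const <- dplyr::mutate(ref, value = 1)
    sel3 <- icc_pairwise_simulated(const, const)
    expect_false(any(sel3$selected)) # undefined ICC -> not selected
  })
})
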