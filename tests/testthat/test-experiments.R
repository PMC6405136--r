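test_that("Fisher exact p-values match enumeration and known cases", {
  expect_equal(fisher_exact_2x2(matrix(c(10, 10, 10, 10), 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2)), 2 / choose(10, 5),
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(3, 0, 0, 0), 2)), 1) # zero margin
})

test_that("Fisher exact agrees with full enumeration for all margins <= 30", {
  withr::with_seed(30, {
    for (rep in 1:200) {
      tab <- matrix(sample(0:15, 4, replace = TRUE), 2)
      expect_equal(fisher_exact_2x2(tab), oracle_fisher(tab),
                   tolerance = 1e-12)
      # and against the standard implementation
      if (sum(tab) > 0) {
        expect_equal(fisher_exact_2x2(tab),
                     stats::fisher.test(tab)$p.value, tolerance = 1e-9)
      }
    }
  })
})

test_that("chi-square homogeneity matches the 2x2 closed form", {
  expect_equal(chisq_homogeneity(rbind(c(10, 59), c(10, 59))), 1)
  withr::with_seed(31, {
    for (rep in 1:20) {
      tab <- matrix(sample(1:60, 4, replace = TRUE), 2)
      a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
      N <- sum(tab)
      stat <- N * (a * d - b * c_)^2 /
        ((a + b) * (c_ + d) * (a + c_) * (b + d))
      expect_equal(chisq_homogeneity(tab),
                   stats::pchisq(stat, 1, lower.tail = FALSE),
                   tolerance = 1e-12)
    }
  })
  # strongly varying counts: overwhelming evidence of heterogeneity
  expect_lt(chisq_homogeneity(rbind(c(60, 9), c(5, 64))), 1e-6)
  expect_true(is.na(chisq_homogeneity(rbind(c(0, 10), c(0, 20)))))
})

test_that("a zero-perturbation study selects everything and Fisher p is 1", {
  spec <- dataset_spec(n_patients = 4, regions_per_patient = 1,
                       n_sequences = 2, reader_dice_target = 1,
                       intra_dice_target = 1, seed = 404)
  st <- generate_study(spec)
  ex <- run_grid(st, schemes = c("fbs:25", "fbn:32"))
  expect_true(all(ex$summary$fisher_p == 1))
  # all features with a defined coefficient are selected at every setting
  rep_ <- tidy(ex$report)
  defined <- !is.na(rep_$ccc) & !is.na(rep_$icc_R1_R2a)
  expect_true(all(rep_$selected[defined]))
  expect_equal(unique(ex$counts$n_selected[ex$counts$method == "fbs"]),
               unique(ex$counts$n_selected[ex$counts$method == "fbn"]))
})

test_that("run_grid summarizes best settings, ties going to smaller bins", {
  st <- tiny_study()
  ex <- cached("tiny_grid", function() {
    run_grid(st, schemes = c("fbs:5", "fbs:20", "fbn:32", "fbn:256"))
  })
  expect_equal(nrow(ex$summary), 2) # one row per sequence
  expect_true(all(ex$summary$best_fbs ==
                    tapply(ex$counts$n_selected[ex$counts$method == "fbs"],
                           ex$counts$sequence[ex$counts$method == "fbs"], max)))
  expect_true(all(ex$summary$fisher_p >= 0 & ex$summary$fisher_p <= 1))
  # tie-break: if both settings tie, the reported scheme is the smaller bin
  counts <- ex$counts
  for (sq in unique(counts$sequence)) {
    d <- counts[counts$sequence == sq & counts$method == "fbs", ]
    if (length(unique(d$n_selected)) == 1) {
      expect_equal(ex$summary$best_fbs_scheme[ex$summary$sequence == sq],
                   d$scheme[which.min(d$parameter)])
    }
  }
})

test_that("selection counts are invariant to feature ordering", {
  st <- tiny_study()
  feats <- cached("tiny_features", function() {
    extract_features(st, c("fbs:25", "fbn:32"))
  })
  ex1 <- run_grid(st, schemes = c("fbs:25", "fbn:32"), features = feats)
  shuffled <- withr::with_seed(33, feats[sample(nrow(feats)), ])
  ex2 <- run_grid(st, schemes = c("fbs:25", "fbn:32"), features = shuffled)
  expect_equal(
    dplyr::arrange(ex1$counts, scheme, sequence)$n_selected,
    dplyr::arrange(ex2$counts, scheme, sequence)$n_selected
  )
})

test_that("missing scheme results raise a hard error listing the gap", {
  st <- tiny_study()
  feats <- cached("tiny_features", function() {
    extract_features(st, c("fbs:25", "fbn:32"))
  })
  expect_error(
    run_grid(st, schemes = c("fbs:25", "fbn:32", "fbn:64"), features = feats),
    regexp = "fbn:64", class = "texrepro_error_input"
  )
})
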