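test_that("dataset specification validates its invariants", {
  expect_error(dataset_spec(sequence_intensity_ranges = list(c(5, 5)),
                            n_sequences = 1),
               class = "texrepro_error_spec")
  expect_error(dataset_spec(image_size = 40, lesion_radius_range = c(10, 30)),
               class = "texrepro_error_spec")
  spec <- dataset_spec()
  expect_equal(spec$n_patients * spec$regions_per_patient * spec$n_sequences,
               444)
})

test_that("textured images land in their sequence intensity ranges", {
  spec <- dataset_spec(n_patients = 2, n_sequences = 2,
                       sequence_intensity_ranges = list(a = c(0, 100),
                                                        b = c(0, 4000)),
                       seed = 7)
  g1 <- generate_textured_image(spec, 1, 1, 1)
  g2 <- generate_textured_image(spec, 1, 1, 2)
  lesion1 <- g1$image[g1$lesion_mask == 1]
  lesion2 <- g2$image[g2$lesion_mask == 1]
  expect_true(all(lesion1 >= 0 & lesion1 <= 100))
  expect_true(all(lesion2 >= 0 & lesion2 <= 4000))
  # lesion and background have distinct mean intensities
  expect_gt(mean(lesion1), mean(g1$image[g1$lesion_mask == 0]))
  # determinism: same ids and seed give bit-identical output
  expect_identical(g1, generate_textured_image(spec, 1, 1, 1))
  # distinct rois differ
  expect_false(identical(g1$image, generate_textured_image(spec, 2, 1, 1)$image))
})

test_that("zero correlation length gives per-pixel independent lesion noise", {
  spec <- dataset_spec(n_patients = 1, n_sequences = 1,
                       texture_correlation_length = 0, seed = 8)
  g <- generate_textured_image(spec, 1, 1, 1)
  les <- g$image[g$lesion_mask == 1]
  # neighbouring lesion pixels should be uncorrelated
  idx <- which(g$lesion_mask == 1 &
                 rbind(g$lesion_mask[-1, ], 0) == 1)
  a <- g$image[idx]
  b <- g$image[idx + 1]
  expect_lt(abs(stats::cor(a, b)), 0.15)
})

test_that("the study layout has one image and three session masks per ROI", {
  st <- small_study()
  n_roi <- st$spec$n_patients * st$spec$regions_per_patient *
    st$spec$n_sequences
  expect_length(st$images, n_roi)
  expect_equal(names(st$masks), c("R1", "R2a", "R2b"))
  for (sess in names(st$masks)) expect_length(st$masks[[sess]], n_roi)
  # masks are non-empty, inside the image, and pairwise distinct
  for (key in names(st$images)[1:10]) {
    for (sess in names(st$masks)) {
      m <- st$masks[[sess]][[key]]
      expect_gt(sum(m), 0)
      expect_equal(dim(m), dim(st$images[[key]]))
    }
    expect_false(identical(st$masks$R1[[key]], st$masks$R2a[[key]]))
    expect_false(identical(st$masks$R2a[[key]], st$masks$R2b[[key]]))
  }
})

test_that("achieved study Dice means stay within tolerance of the targets", {
  st <- small_study()
  expect_lt(abs(st$achieved["inter"] - st$spec$reader_dice_target), 0.03)
  expect_lt(abs(st$achieved["intra"] - st$spec$intra_dice_target), 0.03)
})

test_that("a reader Dice target of 1 reproduces the reference masks", {
  spec <- dataset_spec(n_patients = 2, regions_per_patient = 1,
                       n_sequences = 1, reader_dice_target = 1,
                       intra_dice_target = 1, seed = 9)
  st <- generate_study(spec)
  for (key in names(st$images)) {
    expect_identical(st$masks$R2a[[key]], st$masks$R1[[key]])
    expect_identical(st$masks$R2b[[key]], st$masks$R1[[key]])
  }
})

test_that("study generation is reproducible from the seed", {
  spec <- dataset_spec(n_patients = 2, regions_per_patient = 1,
                       n_sequences = 2, seed = 77)
  s1 <- generate_study(spec)
  s2 <- generate_study(spec)
  expect_identical(s1$images, s2$images)
  expect_identical(s1$masks, s2$masks)
})

test_that("a 30-lesion single-sequence spec emulates the second dataset", {
  spec <- dataset_spec(n_patients = 30, regions_per_patient = 1,
                       n_sequences = 1, seed = 55)
  expect_equal(spec$n_patients * spec$regions_per_patient * spec$n_sequences,
               30)
})
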