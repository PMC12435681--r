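test_that("patch generation is deterministic given seed and style", {
  prof <- class_profiles()[4, ]
  style <- list(hue = 0.05, brightness = -0.02)
  set.seed(10); p1 <- generate_patch(prof, "IHC", 96, style)
  set.seed(10); p2 <- generate_patch(prof, "IHC", 96, style)
  expect_identical(p1$image, p2$image)
  expect_identical(p1$mask, p2$mask)
  set.seed(11); p3 <- generate_patch(prof, "IHC", 96, style)
  expect_false(identical(p1$image, p3$image))
})

test_that("strongly positive patches carry brown rings, negatives do not", {
  set.seed(3)
  p3 <- generate_patch(class_profiles()[4, ], "IHC", 128)
  expect_gt(sum(p3$mask), 0)
  brown <- p3$image[, , 1] - p3$image[, , 3]    # DAB has high red, low blue
  ring <- p3$mask > 0
  expect_gt(mean(brown[ring]), mean(brown[!ring]))
  set.seed(3)
  p0 <- generate_patch(class_profiles()[1, ], "IHC", 128)
  expect_lt(sum(p0$mask), 0.02 * length(p0$mask))
  expect_true(all(p3$image >= 0 & p3$image <= 1))
  expect_error(generate_patch(class_profiles()[1, ], "IHC", 32), ">= 64")
})

test_that("H&E patches have no membrane mask and subtler class signal", {
  set.seed(4)
  p <- generate_patch(class_profiles()[4, ], "HE", 96)
  expect_identical(sum(p$mask), 0)
  expect_true(all(dim(p$image) == c(96, 96, 3)))
})

test_that("ring brown intensity is monotone non-decreasing in HER2 score", {
  prof <- class_profiles()
  set.seed(42)
  mean_brown <- vapply(2:4, function(i) {
    vals <- replicate(6, {
      g <- generate_patch(prof[i, ], "IHC", 96)
      ring <- g$mask > 0
      if (!any(ring)) NA_real_
      else mean(g$image[, , 1][ring] - g$image[, , 3][ring])
    })
    mean(vals, na.rm = TRUE)
  }, 0)
  expect_true(all(diff(mean_brown) > -1e-9))
})

test_that("cohorts have the documented structure and are reproducible", {
  co <- generate_cohort(12, 10, "IHC", size = 64, seed = 7)
  expect_identical(nrow(co$manifest), 120L)
  pat <- unique(co$manifest[, c("patient_id", "her2_score")])
  expect_identical(nrow(pat), 12L)
  expect_true(all(table(pat$her2_score) == 3))   # balanced: 3 patients/class
  # one score per patient across all patches
  expect_identical(nrow(unique(co$manifest[, c("patient_id", "her2_score")])),
                   length(unique(co$manifest$patient_id)))
  expect_true(all(c("path", "patient_id", "stain", "her2_score",
                    "mask_path") %in% names(co$manifest)))
  co2 <- generate_cohort(12, 10, "IHC", size = 64, seed = 7)
  expect_identical(co$manifest, co2$manifest)
  expect_identical(co$images, co2$images)
  expect_error(generate_cohort(3, 5, "IHC"), "at least one patient")
  expect_error(generate_cohort(5, 2, "IHC",
                               class_mix = c("0" = 0.97, "3+" = 0.03)),
               "impossible class_mix")
})

test_that("cohorts round-trip through PNG files on disk", {
  dir <- file.path(tempdir(), "cohort_rt")
  co <- generate_cohort(4, 2, "IHC", size = 64, seed = 5, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- load_cohort(dir)
  expect_identical(back$manifest$patient_id, co$manifest$patient_id)
  # 8-bit quantization tolerance
  expect_lt(max(abs(back$images[[1]] - co$images[[1]])), 1 / 254)
  expect_identical(back$masks[[3]], co$masks[[3]])
  unlink(dir, recursive = TRUE)
})

test_that("random splits partition patches; subject splits partition patients", {
  co <- generate_cohort(10, 6, "IHC", size = 64, seed = 9,
                        class_mix = c("0" = 0.5, "3+" = 0.5))
  sr <- split_random(co$manifest, 0.3, seed = 1)
  expect_identical(nrow(sr$train) + nrow(sr$test), 60L)
  expect_identical(nrow(sr$test), 18L)
  key <- function(m) paste(m$patient_id, m$path)
  expect_length(intersect(key(sr$train), key(sr$test)), 0)
  expect_setequal(c(key(sr$train), key(sr$test)), key(co$manifest))

  ss <- split_subjectwise(co$manifest, 0.3, seed = 1)
  expect_length(intersect(unique(ss$train$patient_id),
                          unique(ss$test$patient_id)), 0)
  expect_identical(length(unique(ss$test$patient_id)), 3L)
  expect_identical(nrow(ss$train) + nrow(ss$test), 60L)

  expect_error(split_random(co$manifest, 0), "strictly between")
  expect_error(split_random(co$manifest, 1), "strictly between")
  one_per_class <- generate_cohort(2, 2, "IHC", size = 64,
                                   class_mix = c("0" = 0.5, "3+" = 0.5))
  expect_error(split_subjectwise(one_per_class$manifest, 0.5),
               "too few patients")
})

test_that("cohort_data applies label schemes and stacks arrays", {
  co <- generate_cohort(8, 3, "IHC", size = 64, seed = 3)
  d <- cohort_data(co, "binary")
  expect_identical(dim(d$x), c(64L, 64L, 3L, length(d$y)))
  expect_identical(length(d$y), 18L)            # 2+ patients dropped (2 of 8)
  expect_setequal(unique(d$y), 0:1)
  expect_identical(d$levels, c("negative", "positive"))
  d4 <- cohort_data(co, "four_class")
  expect_identical(length(d4$y), 24L)
})

test_that("the tumour pretraining cohort separates its two classes", {
  co <- generate_tumor_cohort(6, 3, size = 64, seed = 2)
  d <- tumor_data(co)
  expect_identical(length(d$y), 18L)
  expect_setequal(unique(d$y), 0:1)
  # malignant patches are denser in nuclei: darker on average
  bright <- vapply(seq_along(co$images),
                   function(i) mean(co$images[[i]]), 0)
  expect_lt(mean(bright[d$y == 1]), mean(bright[d$y == 0]))
})
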