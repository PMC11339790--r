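# Synthetic fundus generation and annotation summaries.

test_that("defect-free images get all-good labels; labels are a pure function", {
  f <- make_fundus(seed = 81, side = 64, defects = defect_spec())
  expect_equal(unname(f$labels), c(1L, 1L, 1L, 1L))
  expect_equal(dim(f$image), c(64L, 64L, 3L))
  expect_true(min(f$image) >= 0 && max(f$image) <= 1)
  # labels depend only on the defect spec, not on the image noise / seed
  d <- defect_spec(illum = "gradient", illum_strength = 0.5, blur_sigma = 3,
                   contrast_keep = 0.4, noise_var = 0.05)
  l1 <- make_fundus(seed = 1, side = 64, defects = d)$labels
  l2 <- make_fundus(seed = 2, side = 64, defects = d)$labels
  expect_identical(l1, l2)
  expect_equal(unname(l1), c(0L, 0L, 0L, 0L))
  # thresholds: strength 0.3 / sigma 2 / keep 0.5 flip the labels
  expect_equal(ns$labels_from_defects(defect_spec("gradient", 0.29))[["ic"]], 1L)
  expect_equal(ns$labels_from_defects(defect_spec("gradient", 0.3))[["ic"]], 0L)
  expect_equal(ns$labels_from_defects(defect_spec(blur_sigma = 2))[["blur"]], 0L)
  expect_equal(ns$labels_from_defects(defect_spec(contrast_keep = 0.5))[["lc"]], 0L)
  expect_error(defect_spec(blur_sigma = -1), "nonnegative")
  expect_error(make_fundus(side = 60), "multiple of 32")
})

test_that("blur sigma 4 halves the Laplacian-response variance", {
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  lap_var <- function(img) {
    g <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
    r <- as.array(EBImage::filter2(EBImage::Image(t(g)), lap))
    stats::var(as.vector(r))
  }
  sharp <- make_fundus(seed = 82, side = 128, defects = defect_spec())$image
  blurred <- make_fundus(seed = 82, side = 128,
                         defects = defect_spec(blur_sigma = 4))$image
  expect_lte(lap_var(blurred), 0.5 * lap_var(sharp))
})

test_that("contrast_keep 0.4 at least halves RMS contrast inside the eye", {
  clean <- make_fundus(seed = 83, side = 128, defects = defect_spec())$image
  low <- make_fundus(seed = 83, side = 128,
                     defects = defect_spec(contrast_keep = 0.4))$image
  mask <- compute_eye_mask(clean) == 1
  rms <- function(img) {
    g <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
    stats::sd(g[mask])
  }
  expect_lte(rms(low), 0.5 * rms(clean))
})

test_that("dataset prevalence lands inside 99% binomial bounds; determinism", {
  ds <- make_dataset(100, prevalence = c(ic = 0.6, blur = 0.6, lc = 0.7),
                     seed = 84, side = 64)
  expect_equal(nrow(ds$table), 100L)
  n_good_blur <- sum(ds$table$blur == 1)
  expect_gte(n_good_blur, qbinom(0.005, 100, 0.6))   # 99% interval [46, 74]
  expect_lte(n_good_blur, qbinom(0.995, 100, 0.6))
  # byte-level reproducibility of images and table
  ds2 <- make_dataset(100, prevalence = c(ic = 0.6, blur = 0.6, lc = 0.7),
                      seed = 84, side = 64)
  expect_identical(ds$table, ds2$table)
  expect_identical(ds$images, ds2$images)
  # overall = and of the three items
  expect_equal(ds$table$overall,
               as.integer(ds$table$ic & ds$table$blur & ds$table$lc))
  # minimal case
  expect_equal(nrow(make_dataset(1, seed = 1, side = 64)$table), 1L)
  expect_error(make_dataset(0), "at least 1")
})

test_that("dataset writing round-trips through PNG + CSV", {
  dir <- withr::local_tempdir()
  ds <- make_dataset(3, seed = 85, side = 64, out_dir = dir)
  expect_true(file.exists(file.path(dir, "annotations.csv")))
  expect_length(list.files(dir, pattern = "synth_.*\\.png"), 3L)
  tab <- read_annotations(file.path(dir, "annotations.csv"))
  expect_equal(tab$overall, ds$table$overall)
  img <- read_image(tab$image_path[1])
  expect_lt(max(abs(img - ds$images[, , , 1])), 1 / 255)  # 8-bit quantization
  # summarize counts survive the round trip
  s1 <- summarize_table(ds$table)$pooled
  s2 <- summarize_table(tab)$pooled
  expect_equal(s1, s2)
})

test_that("packaged annotation counts reproduce the published fractions", {
  counts <- mshf_annotation_counts()
  expect_equal(nrow(counts), 36L)
  cfp <- setdiff(unique(counts$dataset), "DR_UWF")
  pooled <- summarize_counts(counts, cfp)
  expect_equal(pooled$frac_good[pooled$item == "ic"], 632 / 1036)
  expect_equal(round(100 * pooled$frac_good[pooled$item == "ic"], 1), 61.0)
  expect_equal(round(100 * pooled$frac_good[pooled$item == "blur"], 1), 58.6)
  expect_equal(round(100 * pooled$frac_good[pooled$item == "lc"], 1), 68.3)
  glu <- summarize_counts(counts, "GLU")
  expect_equal(round(100 * glu$frac_poor[glu$item == "ic"], 1), 86.5)
  uwf <- summarize_counts(counts, "DR_UWF")
  expect_equal(round(100 * uwf$frac_good[uwf$item == "overall"], 1), 66.4)
  # good and poor fractions sum to one per item
  expect_equal(pooled$frac_good + pooled$frac_poor, rep(1, 4))
  expect_error(summarize_counts(counts, "NOPE"), "unknown dataset")
  expect_error(summarize_counts(counts, character(0)), "empty dataset filter")
})

test_that("summarize_table reports per-dataset and pooled fractions", {
  tab <- data.frame(image_path = sprintf("i%d.png", 1:6),
                    dataset = rep(c("A", "B"), each = 3),
                    ic = c(1, 1, 0, 0, 0, 1), blur = c(1, 1, 1, 0, 0, 0),
                    lc = 1, overall = c(1, 1, 0, 0, 0, 0))
  s <- summarize_table(tab)
  expect_equal(s$pooled$frac_good[s$pooled$item == "ic"], 0.5)
  a <- s$per_dataset
  expect_equal(a$frac_good[a$dataset == "A" & a$item == "blur"], 1)
  expect_equal(a$frac_good[a$dataset == "B" & a$item == "blur"], 0)
  sb <- summarize_table(tab, "B")
  expect_equal(sb$pooled$frac_good[sb$pooled$item == "ic"], 1 / 3)
  expect_error(summarize_table(tab, "C"), "unknown dataset")
  expect_error(summarize_table(tab[0, ]), "empty annotation table")
})
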