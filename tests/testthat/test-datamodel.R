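test_that("manifest round trip groups pictures per specimen per view", {
  cfg <- synth_config(n_genera = 2, specimens_per_genus = 3, image_size = 16,
                      extra_picture_prob = 0, seed = 9)
  ds <- generate_dataset(cfg)
  dir <- withr::local_tempdir()
  manifest <- write_dataset(ds, dir)
  ds2 <- read_manifest(manifest)

  expect_equal(n_specimens(ds2), n_specimens(ds))
  expect_equal(ds2$n_labels, ds$n_labels)
  expect_equal(nrow(flatten_to_samples(ds2)), nrow(flatten_to_samples(ds)))
  # PNG round trip is 8-bit: intensities match to quantisation accuracy
  a <- ds$specimens[[1]]$images$head[[1]]
  b <- ds2$specimens[[names(ds$specimens)[1]]]$images$head[[1]]
  expect_lt(max(abs(a - b)), 1 / 255)
})

test_that("a duplicated (specimen, view) manifest row yields a view list of length 2", {
  dir <- withr::local_tempdir()
  png::writePNG(gray_img(0.3), file.path(dir, "a.png"))
  png::writePNG(gray_img(0.6), file.path(dir, "b.png"))
  rows <- c("specimen_id,genus,view,path",
            "s1,antgenus,head,a.png",
            "s1,antgenus,head,b.png",
            "s1,antgenus,dorsum,a.png",
            "s1,antgenus,profile,a.png")
  manifest <- file.path(dir, "manifest.csv")
  writeLines(rows, manifest)
  ds <- read_manifest(manifest)
  expect_equal(length(ds$specimens$s1$images$head), 2L)
  expect_equal(length(ds$specimens$s1$images$dorsum), 1L)
})

test_that("unknown view tokens and missing files are reported with the row", {
  dir <- withr::local_tempdir()
  png::writePNG(gray_img(), file.path(dir, "a.png"))
  manifest <- file.path(dir, "manifest.csv")
  writeLines(c("specimen_id,genus,view,path",
               "s1,g,head,a.png",
               "s1,g,side,a.png"), manifest)
  expect_error(read_manifest(manifest), "row 2.*side")
  writeLines(c("specimen_id,genus,view,path",
               "s1,g,head,nope.png"), manifest)
  expect_error(read_manifest(manifest), "row 1")
  expect_error(read_manifest(file.path(dir, "absent.csv")), "not found")
})

test_that("JSON-lines manifests are accepted", {
  dir <- withr::local_tempdir()
  png::writePNG(gray_img(), file.path(dir, "a.png"))
  manifest <- file.path(dir, "manifest.jsonl")
  writeLines(c(
    '{"specimen_id":"s1","genus":"x","view":"head","path":"a.png"}',
    '{"specimen_id":"s1","genus":"x","view":"dorsum","path":"a.png"}'
  ), manifest)
  ds <- read_manifest(manifest)
  expect_equal(n_specimens(ds), 1L)
  expect_equal(length(ds$specimens$s1$images$dorsum), 1L)
})

test_that("label-support filtering keeps well-supported genera and re-indexes", {
  ds <- toy_dataset(list(A = 3, B = 1))
  expect_equal(n_specimens(filter_labels_by_support(ds, 1)), 4L)

  kept <- filter_labels_by_support(ds, 2)
  expect_equal(n_specimens(kept), 3L)
  expect_equal(kept$n_labels, 1L)
  expect_equal(unique(vapply(kept$specimens, `[[`, integer(1), "genus")), 1L)
  lm <- attr(kept, "label_map")
  expect_equal(lm$old_label, 1L)
  expect_equal(lm$new_label, 1L)
  expect_equal(lm$name, "A")

  expect_error(filter_labels_by_support(ds, 5),
               class = "triview_empty_dataset")
})

test_that("label-support filtering is idempotent at a fixed threshold", {
  ds <- toy_dataset(list(A = 4, B = 2, C = 1))
  once <- filter_labels_by_support(ds, 2)
  twice <- filter_labels_by_support(once, 2)
  expect_equal(n_specimens(twice), n_specimens(once))
  expect_equal(twice$label_names, once$label_names)
})

test_that("cardinality summary counts the standard constraints", {
  ds <- toy_dataset(list(A = 1, B = 1))
  cs <- cardinality_summary(ds)
  expect_equal(cs$n_specimens[cs$constraint == "N_h = N_p = N_d = 1"], 2L)
  expect_equal(cs$rate[cs$constraint == "N_h = N_p = N_d = 1"], 1.0)

  # one of three specimens loses its dorsal image
  ds3 <- toy_dataset(list(A = 3))
  ds3$specimens[[1]]$images$dorsum <- list()
  cs3 <- cardinality_summary(ds3)
  expect_equal(
    cs3$n_specimens[cs3$constraint == "N_h >= 1 and N_p >= 1 and N_d >= 1"],
    2L)
  expect_equal(
    cs3$rate[cs3$constraint == "N_h >= 1 and N_p >= 1 and N_d >= 1"], 2 / 3)
  expect_equal(cs3$n_specimens[cs3$constraint == "N_d >= 1"], 2L)

  empty <- mv_dataset(list(), character(0))
  cs0 <- cardinality_summary(empty)
  expect_true(all(cs0$n_specimens == 0L))
  expect_true(all(cs0$rate == 0))
})

test_that("every rate equals count over total", {
  cfg <- synth_config(n_genera = 3, specimens_per_genus = 5, image_size = 16,
                      seed = 4)
  ds <- generate_dataset(cfg)
  cs <- cardinality_summary(ds)
  expect_equal(cs$rate, cs$n_specimens / n_specimens(ds))
})

test_that("degenerate fractions put everything in training", {
  ds <- toy_dataset(list(A = 3, B = 2))
  sp <- split_dataset(ds, c(1, 0, 0), seed = 1)
  expect_equal(n_specimens(sp$train), 5L)
  expect_equal(n_specimens(sp$validation), 0L)
  expect_equal(n_specimens(sp$test), 0L)
})

test_that("largest-remainder quotas give 7/2/1 on ten eligible specimens", {
  ds <- toy_dataset(list(A = 10))
  sp <- split_dataset(ds, c(0.7, 0.2, 0.1), seed = 3)
  expect_equal(n_specimens(sp$train), 7L)
  expect_equal(n_specimens(sp$validation), 2L)
  expect_equal(n_specimens(sp$test), 1L)
})

test_that("splits are deterministic, disjoint and exhaustive", {
  cfg <- synth_config(n_genera = 3, specimens_per_genus = 8, image_size = 16,
                      seed = 6)
  ds <- generate_dataset(cfg)
  a <- split_dataset(ds, seed = 11)
  b <- split_dataset(ds, seed = 11)
  ids <- function(part) sort(names(part$specimens))
  expect_identical(ids(a$train), ids(b$train))
  expect_identical(ids(a$validation), ids(b$validation))
  expect_identical(ids(a$test), ids(b$test))

  all_ids <- c(ids(a$train), ids(a$validation), ids(a$test))
  expect_equal(anyDuplicated(all_ids), 0L)
  expect_setequal(all_ids, names(ds$specimens))
})

test_that("validation and test hold exactly one picture per view", {
  cfg <- synth_config(n_genera = 3, specimens_per_genus = 10, image_size = 16,
                      extra_picture_prob = 0.5, seed = 8)
  ds <- generate_dataset(cfg)
  # heavy extra-picture rate: some genera may underfill val/test, which warns
  sp <- suppressWarnings(split_dataset(ds, seed = 2))
  for (part in list(sp$validation, sp$test)) {
    cnt <- specimen_view_counts(part)
    expect_true(all(cnt$n_head == 1 & cnt$n_dorsum == 1 & cnt$n_profile == 1))
  }
})

test_that("a genus starved of eligible specimens warns and under-fills", {
  ds <- toy_dataset(list(A = 6, B = 6))
  # genus B: every specimen gets a second head picture -> none eligible
  for (i in 7:12) {
    ds$specimens[[i]]$images$head <-
      c(ds$specimens[[i]]$images$head, list(gray_img(0.9)))
  }
  expect_warning(sp <- split_dataset(ds, seed = 1), "genus: B")
  genera_val <- vapply(sp$validation$specimens, `[[`, integer(1), "genus")
  expect_false(2L %in% genera_val)
  expect_equal(n_specimens(sp$train) + n_specimens(sp$validation) +
                 n_specimens(sp$test), 12L)
})

test_that("flattening yields one row per picture and respects view filters", {
  ds <- toy_dataset(list(A = 1, B = 1))
  expect_equal(nrow(flatten_to_samples(ds)), 6L)
  expect_equal(nrow(flatten_to_samples(ds, views = "head")), 2L)

  ds$specimens[[1]]$images$profile <-
    c(ds$specimens[[1]]$images$profile, list(gray_img(0.2)))
  fl <- flatten_to_samples(ds, views = "profile")
  expect_equal(nrow(fl), 3L)
  expect_equal(sum(fl$specimen_id == "A_01"), 2L)

  # count identity against per-specimen view counts
  cfg <- synth_config(n_genera = 2, specimens_per_genus = 5, image_size = 16,
                      extra_picture_prob = 0.4, seed = 13)
  big <- generate_dataset(cfg)
  cnt <- specimen_view_counts(big)
  expect_equal(nrow(flatten_to_samples(big)),
               sum(cnt$n_head + cnt$n_dorsum + cnt$n_profile))
  expect_equal(nrow(flatten_to_samples(big, views = c("head", "dorsum"))),
               sum(cnt$n_head + cnt$n_dorsum))
})

test_that("flatten shuffling is deterministic and a permutation", {
  ds <- toy_dataset(list(A = 2, B = 2))
  a <- flatten_to_samples(ds, shuffle_seed = 5)
  b <- flatten_to_samples(ds, shuffle_seed = 5)
  expect_identical(a$specimen_id, b$specimen_id)
  expect_setequal(paste(a$specimen_id, a$view),
                  paste(flatten_to_samples(ds)$specimen_id,
                        flatten_to_samples(ds)$view))
})
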