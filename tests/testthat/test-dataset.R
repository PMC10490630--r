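# Dataset generator: determinism, geometry, subject bookkeeping, and the
# PNG + manifest round trip.

test_that("generation is a deterministic function of the seed", {
  a <- generate_dataset(n_subjects = 2L, per_class = 5L, seed = 9L)
  b <- generate_dataset(n_subjects = 2L, per_class = 5L, seed = 9L)
  expect_identical(a$images, b$images)
  expect_identical(a$labels, b$labels)
  expect_identical(a$subject, b$subject)
  c <- generate_dataset(n_subjects = 2L, per_class = 5L, seed = 10L)
  expect_false(identical(a$images, c$images))
})

test_that("the corpus geometry is balanced with 2-3 repetitions per subject", {
  ds <- tiny_dataset()
  expect_equal(length(ds), 6L * 9L)
  expect_true(all(table(ds$labels) == 9L))
  expect_true(all(ds$images >= 0L & ds$images <= 255L))
  expect_equal(dim(ds$images)[1:2], c(75L, 75L))
  reps <- table(ds$subject, ds$labels)
  expect_true(all(reps >= 2L & reps <= 3L))
  expect_error(generate_dataset(n_subjects = 4L, per_class = 20L, seed = 1L),
               "repetitions")
})

test_that("subject-wise splits are subject-disjoint partitions", {
  ds <- tiny_dataset()
  for (seed in c(1L, 2L, 3L)) {
    sw <- subject_wise_split(ds, n_train = 3L, n_test = 1L, seed = seed)
    expect_length(intersect(sw$train_subjects, sw$test_subjects), 0)
    expect_length(intersect(unique(sw$train$subject),
                            unique(sw$test$subject)), 0)
    # per-class counts add up to the full per-class count
    tot <- table(sw$train$labels) + table(sw$test$labels)
    expect_equal(as.integer(tot), rep(9L, 6L))
    # counts agree with the generator's per-subject bookkeeping
    keep <- ds$subject %in% sw$train_subjects
    expect_equal(as.integer(table(sw$train$labels)),
                 as.integer(table(ds$labels[keep])))
  }
  expect_error(subject_wise_split(ds, n_train = 4L, n_test = 1L), "fewer")
})

test_that("raw-pixel nearest-centroid accuracy is above chance", {
  ds <- tiny_dataset()
  n <- length(ds)
  X <- t(matrix(ds$images, 75L * 75L, n))
  tr <- seq(1L, n, 2L); te <- seq(2L, n, 2L)
  cls <- levels(ds$labels)
  cent <- vapply(cls, function(cl)
    colMeans(X[tr, , drop = FALSE][ds$labels[tr] == cl, , drop = FALSE]),
    numeric(ncol(X)))
  pred <- cls[apply(X[te, ], 1L, function(x) which.min(colSums((cent - x)^2)))]
  expect_gt(mean(pred == as.character(ds$labels[te])), 1 / 6)
})

test_that("PNG + manifest export round-trips bit-exactly", {
  ds <- tiny_dataset()[1:8]
  dir <- withr::local_tempdir()
  mf <- write_signatures(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_signatures(dir)
  expect_identical(back$images, ds$images)
  expect_identical(back$labels, ds$labels)
  expect_identical(back$subject, ds$subject)
})

test_that("externally supplied 75 x 75 grayscale images are ingested", {
  dir <- withr::local_tempdir()
  set.seed(4)
  img <- matrix(runif(75 * 75), 75, 75)
  png::writePNG(img, file.path(dir, "ext.png"))
  utils::write.csv(data.frame(path = "ext.png", class_label = "falling",
                              subject_id = 1L, repetition_id = 1L),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  ds <- read_signatures(dir)
  expect_equal(length(ds), 1L)
  expect_equal(as.character(ds$labels), "falling")
  expect_equal(dim(ds$images), c(75L, 75L, 1L))
})
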