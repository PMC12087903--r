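test_that("window construction yields exactly L - 2d contiguous slices", {
  set.seed(1)
  tr <- trial_features(rand_window(15, 4, 3), label = 1, subject_id = "S1")
  w <- make_windows(tr, d = 3)
  expect_length(w, 9)
  expect_equal(dim(w[[1]]$tensor), c(7, 4, 3))
  expect_equal(vapply(w, `[[`, 0L, "center_index"), 3:11)
  expect_equal(w[[1]]$tensor, tr$features[1:7, , , drop = FALSE])
  expect_true(all(vapply(w, `[[`, 0L, "label") == 1L))

  w0 <- make_windows(trial_features(rand_window(5, 4, 3), 0, "S1"), d = 0)
  expect_length(w0, 5)
  expect_equal(dim(w0[[1]]$tensor), c(1, 4, 3))

  expect_error(
    make_windows(trial_features(rand_window(6, 4, 3), 0, "S1"), d = 3),
    "trial too short")
})

test_that("window count and tiling hold over random trial lengths", {
  set.seed(7)
  for (rep in 1:20) {
    d <- sample(0:4, 1)
    L <- 2 * d + sample(1:10, 1)
    tr <- trial_features(rand_window(L, 3, 2), 0, "S1")
    w <- make_windows(tr, d)
    expect_length(w, L - 2 * d)
    for (i in seq_along(w)) {           # windows tile the trial
      expect_equal(w[[i]]$tensor[d + 1, , ], tr$features[d + i, , ])
    }
  }
})

test_that("container round trip is lossless", {
  set.seed(2)
  trs <- lapply(1:3, function(i) {
    trial_features(rand_window(6, 4, 3), label = i %% 2,
                   subject_id = sprintf("S%d", i), session_id = "2",
                   channel_names = paste0("E", 1:4))
  })
  ds <- eeg_dataset(trs, class_names = c("neg", "pos"),
                    band_defs = list(c(1, 4), c(4, 8), c(8, 14)))
  path <- file.path(tempdir(), "roundtrip.json")
  write_container(ds, path)
  expect_true(file.exists(paste0(path, ".meta.json")))
  back <- read_container(path)
  expect_identical(back$class_names, ds$class_names)
  expect_identical(back$n_channels, ds$n_channels)
  for (i in seq_along(trs)) {
    expect_identical(back$trials[[i]]$features, trs[[i]]$features)
    expect_identical(back$trials[[i]]$label, trs[[i]]$label)
    expect_identical(back$trials[[i]]$channel_names, trs[[i]]$channel_names)
  }
})

test_that("container schema violations are reported by field", {
  set.seed(3)
  ds <- eeg_dataset(list(trial_features(rand_window(4, 3, 2), 0, "S1")),
                    class_names = c("a", "b"))
  path <- file.path(tempdir(), "schema.json")
  write_container(ds, path)
  doc <- jsonlite::read_json(path)
  doc$n_channels <- 99
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  expect_error(read_container(path), "schema mismatch")

  doc$n_channels <- NULL
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  expect_error(read_container(path), "n_channels")
  expect_error(read_container(file.path(tempdir(), "nope.json")), "no such file")
})

test_that("an empty container is valid and round-trips", {
  ds <- eeg_dataset(list(), class_names = c("a", "b"),
                    n_channels = 5, n_bands = 3)
  path <- file.path(tempdir(), "empty.json")
  write_container(ds, path)
  back <- read_container(path)
  expect_length(back$trials, 0)
  expect_identical(back$n_channels, 5L)
})

test_that("DE of in-band unit-variance noise matches the Gaussian closed form", {
  set.seed(11)
  fs <- 128
  n <- fs * 12
  filt <- signal::butter(4, c(4, 30) / (fs / 2), type = "pass")
  x <- signal::filtfilt(filt, rnorm(n))
  x <- x / sd(x)
  de <- compute_de_features(cbind(x), fs, bands = list(c(4, 30)))
  # 0.5 * log(2*pi*e) = 1.4189; tolerance covers per-epoch sampling variance
  expect_equal(mean(de), 0.5 * log(2 * pi * exp(1)), tolerance = 0.05)
})

test_that("scaling a signal by a adds log(a) to its DE", {
  set.seed(12)
  fs <- 64
  x <- cbind(rnorm(fs * 6), rnorm(fs * 6))
  de1 <- compute_de_features(x, fs, bands = list(c(2, 8), c(8, 20)))
  de3 <- compute_de_features(3 * x, fs, bands = list(c(2, 8), c(8, 20)))
  expect_equal(de3, de1 + log(3), tolerance = 1e-8)
})

test_that("zero-variance signals hit the variance floor with a warning", {
  fs <- 64
  x <- cbind(rep(0, fs * 2))   # flat signal: band-passed output is exactly 0
  expect_warning(
    de <- compute_de_features(x, fs, bands = list(c(2, 8))),
    "floored")
  expect_equal(unique(as.numeric(de)), 0.5 * log(2 * pi * exp(1) * 1e-12),
               tolerance = 1e-6)
  expect_error(compute_de_features(x, fs = 10, bands = list(c(2, 8))),
               "twice the highest band edge")
})

test_that("MAT v5 arrays survive a write/read round trip", {
  vars <- list(a = matrix(rnorm(12), 3), b = array(rnorm(24), c(2, 3, 4)),
               label = matrix(c(1, 0, -1, 1), 1))
  path <- file.path(tempdir(), "rt.mat")
  write_mat5(vars, path)
  back <- read_mat5(path)
  expect_equal(back$a, vars$a, ignore_attr = TRUE)
  expect_equal(dim(back$b), c(2L, 3L, 4L))
  expect_equal(as.numeric(back$b), as.numeric(vars$b))
})

test_that("SEED-layout directories load into a dataset", {
  set.seed(4)
  dir <- file.path(tempdir(), "seedlike")
  dir.create(dir, showWarnings = FALSE)
  # labels for 2 trials in the SEED convention (-1/0/1 scale)
  write_mat5(list(label = matrix(c(1, -1), 1)), file.path(dir, "label.mat"))
  for (s in 1:2) {
    # N x L x F_de per trial, non-62-channel on purpose
    vars <- list(de_LDS1 = array(rnorm(6 * 10 * 5), c(6, 10, 5)),
                 de_LDS2 = array(rnorm(6 * 8 * 5), c(6, 8, 5)))
    write_mat5(vars, file.path(dir, sprintf("sub%d.mat", s)))
  }
  expect_warning(ds <- read_seed_layout(dir), "62-channel")
  expect_length(ds$trials, 4)
  expect_equal(ds$n_channels, 6L)
  expect_equal(dim(ds$trials[[1]]$features), c(10L, 6L, 5L))
  expect_setequal(vapply(ds$trials, `[[`, 0L, "label"), c(0L, 2L))

  unlink(file.path(dir, "label.mat"))
  expect_error(suppressWarnings(read_seed_layout(dir)), "label")
})
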