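test_that("single-feature operations reproduce their defining formulas", {
  expect_equal(f_mean(c(1, 2, 3, 4)), 2.5)
  expect_equal(f_mean(rep(7.3, 50)), 7.3)
  expect_equal(f_std(rep(2, 10)), 0)
  expect_equal(f_std(c(1, 2, 3, 4)), sqrt(1.25))
  expect_equal(f_cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(f_cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(f_cosine_similarity(c(0, 0), c(1, 1)), 0)  # degenerate rule
  expect_equal(f_rms(rep(-3, 5)), 3)
  expect_equal(f_rms(c(3, 4)), sqrt(12.5))
  expect_equal(f_skewness(c(1, 2, 3)), 0)
  expect_equal(f_skewness(rep(5, 10)), 0)
  expect_equal(f_kurtosis(rep(5, 10)), 0)
  expect_equal(f_kurtosis(c(-1, 1, -1, 1)), 1)
  expect_equal(unname(f_minmax(c(3, -1, 7))), c(-1, 7))
  expect_equal(unname(f_minmax(rep(2, 4))), c(2, 2))
  expect_equal(f_zero_crossings(c(1, -1, 1)), 2)
  expect_equal(f_zero_crossings(c(1, 2, 3)), 0)
  expect_equal(f_zero_crossings(c(1, 0, -1)), 0)  # exact zeros do not cross
  expect_equal(f_entropy(rep(1, 50)), 0)
  # 64 samples spread uniformly over the 16 bins -> maximal entropy log2(16)
  u <- rep(seq(0.5, 15.5, by = 1), length.out = 64) / 16
  expect_equal(f_entropy(sort(u), bins = 16), 4)
  expect_equal(f_quartile_q1(rep(3.3, 10)), 3.3)
  q1 <- f_quartile_q1(1:100, bins = 10)
  expect_lt(abs(q1 - 25.5), (100 - 1) / 10)  # within one class width
  x <- numeric(50); x[11] <- 5; x[41] <- -5
  expect_equal(f_peak_time_diff(x, fs = 50), 0.6)
  expect_equal(f_peak_time_diff(rep(1, 50)), 0)
  expect_error(f_mean(numeric(0)), "empty")
})

test_that("spectral features behave on canonical signals", {
  # constant acceleration: mean removal kills the DC term, all six are 0
  const_acc <- matrix(rep(c(0.1, -0.6, 0.78), each = 50), 50, 3)
  expect_equal(unname(f_fft_features(const_acc)), rep(0, 6))
  # a pure 5 Hz magnitude oscillation peaks at bin k = 5 (N = 50, 50 Hz)
  t <- (0:49) / 50
  acc <- cbind(1 + 0.3 * sin(2 * pi * 5 * t), 0, 0)
  ff <- f_fft_features(acc)
  mags <- Mod(stats::fft(sqrt(rowSums(acc^2)) -
                           mean(sqrt(rowSums(acc^2)))))[2:26]
  expect_equal(which.max(mags), 5)
  expect_equal(unname(ff["peakf"]), max(mags))
  expect_lt(max(ff[c("lowf1", "lowf2", "lowf3")]), 1e-9 * ff[["peakf"]])
  # frequency-of-peak variant reports Hz
  ff_hz <- f_fft_features(acc, spec = feature_spec(peak_as_frequency = TRUE))
  expect_equal(unname(ff_hz["peakf"]), 5)
  expect_error(f_fft_features(acc[1:3, ]), "N >= 4")
})

test_that("every feature family matches its brute-force oracle on random windows", {
  withr::with_seed(202, {
    for (trial in 1:200) {
      n <- sample(c(50, 100), 1)
      x <- rnorm(n, sd = runif(1, 0.01, 5))
      y <- rnorm(n)
      expect_equal(f_mean(x), oracle_mean(x), tolerance = 1e-12)
      expect_equal(f_std(x), oracle_std(x), tolerance = 1e-9)
      expect_equal(f_cosine_similarity(x, y), oracle_cos(x, y), tolerance = 1e-9)
      expect_equal(f_rms(x), oracle_rms(x), tolerance = 1e-9)
      expect_equal(f_skewness(x), oracle_skew(x), tolerance = 1e-9)
      expect_equal(f_kurtosis(x), oracle_kurt(x), tolerance = 1e-9)
      expect_identical(f_zero_crossings(x), oracle_zc(x))
      expect_equal(f_entropy(x), oracle_entropy(x), tolerance = 1e-9)
      expect_equal(f_quartile_q1(x), oracle_q1(x), tolerance = 1e-9)
      expect_equal(f_peak_time_diff(x), oracle_peak_dt(x), tolerance = 1e-12)
    }
  })
})

test_that("FFT features match a naive DFT oracle", {
  withr::with_seed(303, {
    for (trial in 1:25) {
      n <- sample(c(50, 100), 1)
      acc <- matrix(rnorm(3 * n), n, 3)
      expect_equal(f_fft_features(acc), oracle_fft_features(acc),
                   tolerance = 1e-9)
    }
  })
})

test_that("the feature vector has 43 entries in the canonical family order", {
  fn <- feature_names()
  expect_length(fn, 43)
  fam <- c(mean = 4, std = 3, cos = 3, rms = 3, skew = 3, kurt = 3,
           max = 3, min = 3, zc = 3, spectral = 6, entropy = 3, q1 = 3,
           peak_dt = 3)
  expect_equal(sum(fam), 43)
  counts <- c(
    sum(startsWith(fn, "mean_")), sum(startsWith(fn, "std_")),
    sum(startsWith(fn, "cos_")), sum(startsWith(fn, "rms_")),
    sum(startsWith(fn, "skew_")), sum(startsWith(fn, "kurt_")),
    sum(startsWith(fn, "max_")), sum(startsWith(fn, "min_")),
    sum(startsWith(fn, "zc_")),
    sum(fn %in% c("peakf", "lowf1", "lowf2", "lowf3", "medf", "highf")),
    sum(startsWith(fn, "entropy_")), sum(startsWith(fn, "q1_")),
    sum(startsWith(fn, "peak_dt_")))
  expect_equal(counts, unname(fam))
  w <- make_window()
  expect_length(extract_feature_vector(w), 43)
})

test_that("the composite extractor agrees with the individual operations", {
  spec <- feature_spec()
  withr::with_seed(404, {
    for (trial in 1:20) {
      w <- make_window(n = sample(c(50, 100), 1))
      v <- extract_feature_vector(w, spec)
      expect_equal(unname(v["mean_acc_x"]), f_mean(w$acc[, 1]))
      expect_equal(unname(v["mean_temp"]), f_mean(w$temp))
      expect_equal(unname(v["std_acc_y"]), f_std(w$acc[, 2]))
      expect_equal(unname(v["cos_acc_xz"]),
                   f_cosine_similarity(w$acc[, 1], w$acc[, 3]))
      expect_equal(unname(v["rms_gyro_z"]), f_rms(w$gyro[, 3]))
      expect_equal(unname(v["skew_acc_x"]), f_skewness(w$acc[, 1]))
      expect_equal(unname(v["kurt_acc_z"]), f_kurtosis(w$acc[, 3]))
      expect_equal(unname(v["max_acc_y"]), max(w$acc[, 2]))
      expect_equal(unname(v["min_acc_y"]), min(w$acc[, 2]))
      expect_equal(unname(v["zc_acc_x"]), f_zero_crossings(w$acc[, 1]))
      expect_equal(unname(v[c("peakf", "lowf1", "lowf2", "lowf3",
                              "medf", "highf")]),
                   unname(f_fft_features(w$acc, fs = w$fs, spec = spec)))
      expect_equal(unname(v["entropy_acc_z"]), f_entropy(w$acc[, 3]))
      expect_equal(unname(v["q1_acc_x"]), f_quartile_q1(w$acc[, 1]))
      expect_equal(unname(v["peak_dt_acc_y"]),
                   f_peak_time_diff(w$acc[, 2], fs = w$fs))
      # structural invariants of any feature vector
      expect_true(all(is.finite(v)))
      expect_true(all(abs(v[startsWith(names(v), "cos_")]) <= 1))
      expect_true(all(v[startsWith(names(v), "entropy_")] >= 0))
      expect_true(v["max_acc_x"] >= v["mean_acc_x"] &&
                    v["mean_acc_x"] >= v["min_acc_x"])
    }
  })
})

test_that("a constant window yields the degenerate feature values", {
  w <- make_window(acc = matrix(rep(c(0.2, -0.5, 0.8), each = 50), 50, 3),
                   gyro = matrix(0, 50, 3), temp = rep(34, 50))
  v <- extract_feature_vector(w)
  expect_equal(unname(v[c("mean_acc_x", "mean_acc_y", "mean_acc_z", "mean_temp")]),
               c(0.2, -0.5, 0.8, 34))
  zero_feats <- c("std_acc_x", "std_acc_y", "std_acc_z",
                  "skew_acc_x", "skew_acc_y", "skew_acc_z",
                  "kurt_acc_x", "kurt_acc_y", "kurt_acc_z",
                  "zc_acc_x", "zc_acc_y", "zc_acc_z",
                  "entropy_acc_x", "entropy_acc_y", "entropy_acc_z",
                  "peak_dt_acc_x", "peak_dt_acc_y", "peak_dt_acc_z",
                  "peakf", "lowf1", "lowf2", "lowf3", "medf", "highf",
                  "rms_gyro_x", "rms_gyro_y", "rms_gyro_z")
  expect_equal(unname(v[zero_feats]), rep(0, length(zero_feats)))
  expect_equal(unname(v[c("q1_acc_x", "q1_acc_y", "q1_acc_z")]),
               c(0.2, -0.5, 0.8))
})

test_that("features shift and scale the way their formulas demand", {
  withr::with_seed(505, {
    for (trial in 1:10) {
      x <- rnorm(50)
      shift <- runif(1, -3, 3)
      scale <- runif(1, 0.5, 4)
      # shift invariance
      expect_equal(f_std(x + shift), f_std(x), tolerance = 1e-9)
      expect_equal(f_skewness(x + shift), f_skewness(x), tolerance = 1e-6)
      expect_equal(f_kurtosis(x + shift), f_kurtosis(x), tolerance = 1e-6)
      expect_equal(f_peak_time_diff(x + shift), f_peak_time_diff(x))
      expect_equal(max(x + shift), max(x) + shift)
      expect_equal(f_mean(x + shift), f_mean(x) + shift, tolerance = 1e-9)
      # positive scale covariance / invariance
      expect_equal(f_std(x * scale), f_std(x) * scale, tolerance = 1e-9)
      expect_equal(f_rms(x * scale), f_rms(x) * scale, tolerance = 1e-9)
      expect_equal(max(x * scale), max(x) * scale)
      expect_equal(min(x * scale), min(x) * scale)
      expect_equal(f_skewness(x * scale), f_skewness(x), tolerance = 1e-6)
      expect_equal(f_kurtosis(x * scale), f_kurtosis(x), tolerance = 1e-6)
      expect_identical(f_zero_crossings(x * scale), f_zero_crossings(x))
      y <- rnorm(50)
      expect_equal(f_cosine_similarity(x * scale, y * scale),
                   f_cosine_similarity(x, y), tolerance = 1e-9)
    }
  })
})

test_that("paper-literal normalisation modes relate to the defaults exactly", {
  withr::with_seed(606, {
    x <- rnorm(50)
    expect_equal(f_skewness(x, literal = TRUE), 50 * f_skewness(x))
    expect_equal(f_entropy(x, literal = TRUE), f_entropy(x) / 50)
    w <- make_window()
    spec_lit <- feature_spec(literal_skewness = TRUE, literal_entropy = TRUE)
    v <- extract_feature_vector(w, feature_spec())
    vl <- extract_feature_vector(w, spec_lit)
    expect_equal(unname(vl["skew_acc_x"]), unname(v["skew_acc_x"]) * 50)
    expect_equal(unname(vl["entropy_acc_x"]), unname(v["entropy_acc_x"]) / 50)
  })
})

test_that("feature tables map the extractor over windows in order", {
  rec <- generate_bout(default_profiles()$MPA7, duration = 10, seed = 9)
  ws <- segment(rec, windowing_config(1, TRUE))
  expect_length(ws, 19)
  tab <- extract_feature_table(ws)
  expect_equal(nrow(tab), 19)
  for (i in c(1, 10, 19)) {
    expect_equal(unname(as.numeric(tab[i, feature_names()])),
                 unname(as.numeric(extract_feature_vector(ws[[i]]))))
  }
  expect_true(all(tab$activity_label == "MPA7"))
  empty <- extract_feature_table(list())
  expect_equal(nrow(empty), 0)
  expect_identical(names(empty), c("subject_id", "activity_label", feature_names()))
})
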