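# Independent brute-force oracles for the window statistics, written as
# plain elementwise loops so they share no code path with the package
# implementations they check.

oracle_mean <- function(x) {
  s <- 0
  for (v in x) s <- s + v
  s / length(x)
}

oracle_std <- function(x) {
  mu <- oracle_mean(x)
  s <- 0
  for (v in x) s <- s + (v - mu)^2
  sqrt(s / length(x))
}

oracle_cos <- function(a, b) {
  dot <- 0; na <- 0; nb <- 0
  for (i in seq_along(a)) {
    dot <- dot + a[i] * b[i]
    na <- na + a[i]^2
    nb <- nb + b[i]^2
  }
  if (na == 0 || nb == 0) return(0)
  dot / (sqrt(na) * sqrt(nb))
}

oracle_rms <- function(x) {
  s <- 0
  for (v in x) s <- s + v^2
  sqrt(s / length(x))
}

oracle_skew <- function(x) {
  mu <- oracle_mean(x)
  sg <- oracle_std(x)
  if (sg == 0) return(0)
  s <- 0
  for (v in x) s <- s + ((v - mu) / sg)^3
  s / length(x)
}

oracle_kurt <- function(x) {
  mu <- oracle_mean(x)
  sg <- oracle_std(x)
  if (sg == 0) return(0)
  s <- 0
  for (v in x) s <- s + (v - mu)^4
  s / (length(x) * sg^4)
}

oracle_zc <- function(x) {
  count <- 0L
  for (i in seq_len(length(x) - 1)) {
    if ((x[i] < 0 && x[i + 1] > 0) || (x[i] > 0 && x[i + 1] < 0)) {
      count <- count + 1L
    }
  }
  count
}

# naive O(N^2) one-sided DFT magnitudes, k = 1..floor(N/2)
oracle_dft_mags <- function(x) {
  n <- length(x)
  ks <- 1:(n %/% 2)
  vapply(ks, function(k) {
    acc <- 0 + 0i
    for (m in 0:(n - 1)) {
      acc <- acc + x[m + 1] * exp(-2i * pi * k * m / n)
    }
    Mod(acc)
  }, 0)
}

oracle_fft_features <- function(acc, fs = 50, med_band = c(5, 15),
                                high_band = c(15, 25)) {
  n <- nrow(acc)
  m <- numeric(n)
  for (i in seq_len(n)) {
    m[i] <- sqrt(acc[i, 1]^2 + acc[i, 2]^2 + acc[i, 3]^2)
  }
  x <- m - oracle_mean(m)
  mags <- oracle_dft_mags(x)
  freqs <- seq_along(mags) * fs / n
  med_sel <- freqs > med_band[1] & freqs <= med_band[2]
  high_sel <- freqs > high_band[1] & freqs <= high_band[2]
  c(peakf = max(mags), lowf1 = mags[1], lowf2 = mags[2], lowf3 = mags[3],
    medf = if (any(med_sel)) oracle_mean(mags[med_sel]) else 0,
    highf = if (any(high_sel)) oracle_mean(mags[high_sel]) else 0)
}

oracle_entropy <- function(x, bins = 16) {
  n <- length(x)
  lo <- min(x); hi <- max(x)
  if (lo == hi) return(0)
  width <- (hi - lo) / bins
  counts <- integer(bins)
  for (v in x) {
    b <- floor((v - lo) / width) + 1
    if (b > bins) b <- bins
    if (b < 1) b <- 1
    counts[b] <- counts[b] + 1
  }
  h <- 0
  for (c in counts) {
    if (c > 0) {
      p <- c / n
      h <- h - p * log2(p)
    }
  }
  h
}

oracle_q1 <- function(x, bins = 10) {
  n <- length(x)
  lo <- min(x); hi <- max(x)
  if (lo == hi) return(lo)
  width <- (hi - lo) / bins
  counts <- integer(bins)
  for (v in x) {
    b <- floor((v - lo) / width) + 1
    if (b > bins) b <- bins
    if (b < 1) b <- 1
    counts[b] <- counts[b] + 1
  }
  r <- ceiling(n / 4)
  cum <- 0
  for (j in seq_len(bins)) {
    if (cum + counts[j] >= r) {
      l <- lo + (j - 1) * width
      return(l + (width / counts[j]) * (n / 4 - cum))
    }
    cum <- cum + counts[j]
  }
  stop("unreachable")
}

oracle_peak_dt <- function(x, fs = 50) {
  imax <- 1; imin <- 1
  for (i in seq_along(x)) {
    if (x[i] > x[imax]) imax <- i
    if (x[i] < x[imin]) imin <- i
  }
  abs(imax - imin) / fs
}

# expected alert count for contiguous fixed-width prediction windows:
# run-length encode, then per qualifying proscribed run the alerts land at
# onset + sustain, + cooldown, ... while still covered by the run
oracle_alert_count <- function(labels, proscribed, sustain, cooldown, dt = 1) {
  r <- rle(labels)
  total <- 0
  for (j in seq_along(r$lengths)) {
    if (r$values[j] %in% proscribed) {
      covered <- r$lengths[j] * dt
      if (covered >= sustain) {
        total <- total + 1 + floor((covered - sustain) / cooldown)
      }
    }
  }
  total
}

# build a synthetic window object directly (bypasses segment())
make_window <- function(n = 50, fs = 50, acc = NULL, gyro = NULL,
                        temp = NULL, label = "MPA1", subject = "S01",
                        start_time = 0) {
  if (is.null(acc)) acc <- matrix(rnorm(n * 3), n, 3)
  if (is.null(gyro)) gyro <- matrix(rnorm(n * 3, sd = 20), n, 3)
  if (is.null(temp)) temp <- rep(33.5, n)
  structure(
    list(start_time = start_time, n = n, fs = fs, acc = acc, gyro = gyro,
         temp = temp, subject_id = subject, activity_label = label),
    class = "mpar_window"
  )
}

# small separable two-class feature table for classifier sanity checks
make_separable_table <- function(n_per_class = 30, seed = 1) {
  withr::with_seed(seed, {
    fn <- mpar::feature_names()
    mk <- function(label, center) {
      m <- matrix(rnorm(n_per_class * 43, mean = center, sd = 0.1),
                  n_per_class, 43)
      colnames(m) <- fn
      cbind(data.frame(subject_id = "S01", activity_label = label,
                       stringsAsFactors = FALSE),
            as.data.frame(m))
    }
    rbind(mk("MPA1", 0), mk("MPA7", 5))
  })
}

# random feature table with c balanced classes and unstructured features
make_random_table <- function(n_per_class = 30, classes = 10, seed = 1) {
  withr::with_seed(seed, {
    fn <- mpar::feature_names()
    labs <- rep(names(mpar::activity_labels())[seq_len(classes)],
                each = n_per_class)
    m <- matrix(rnorm(length(labs) * 43), length(labs), 43)
    colnames(m) <- fn
    cbind(data.frame(subject_id = "S01", activity_label = labs,
                     stringsAsFactors = FALSE),
          as.data.frame(m))
  })
}
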