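# Spectral preprocessing: baseline, TIC, peak picking/alignment,
# resampling.

test_that("baseline subtraction removes flat and offset backgrounds", {
  mz <- seq(600, 1600, 0.25)
  # flat spectrum -> all zeros
  expect_equal(subtract_baseline(rep(5, length(mz)), mz, 50),
               rep(0, length(mz)))
  # single Gaussian on zero baseline, window >> peak width: height kept
  peak <- 100 * exp(-((mz - 1000)^2) / (2 * (0.5 / 2.3548)^2))
  out <- subtract_baseline(peak, mz, 50)
  expect_lt(abs(max(out) - 100) / 100, 0.05)
  # shift invariance: adding a constant changes nothing
  out_shifted <- subtract_baseline(peak + 12, mz, 50)
  expect_equal(out_shifted, out, tolerance = 1e-8)
})

test_that("baseline never increases intensities and is non-negative", {
  mz <- seq(600, 1100, 0.5)
  set.seed(9)
  for (i in 1:5) {
    y <- abs(stats::rnorm(length(mz), 10, 3)) +
      50 * exp(-((mz - sample(700:1000, 1))^2) / 2)
    out <- subtract_baseline(y, mz, 25)
    expect_true(all(out >= 0))
    expect_true(all(out <= y + 1e-12))
  }
})

test_that("baseline window wider than the axis span is an error", {
  expect_error(subtract_baseline(1:10, seq(100, 109), 6), "wider")
})

test_that("TIC normalization hits its target sum and is idempotent", {
  expect_equal(tic_normalize(c(1, 2, 3), target_sum = 1),
               c(1 / 6, 1 / 3, 1 / 2))
  # two pixels, sums 10 and 30: both end at the mean TIC 20
  m <- rbind(c(4, 6), c(10, 20))
  norm <- tic_normalize(m)
  expect_equal(unname(rowSums(norm)), c(20, 20))
  # idempotence
  expect_equal(tic_normalize(norm), norm, tolerance = 1e-12)
  # all row sums equal to machine accuracy on a larger matrix
  set.seed(4)
  big <- matrix(stats::runif(200, 1, 5), 20)
  sums <- rowSums(tic_normalize(big))
  expect_lt(diff(range(sums)) / mean(sums), 1e-9)
})

test_that("TIC normalization names the offending all-zero pixel", {
  ds <- tiny_msi(rbind(c(1, 2), c(0, 0)))
  expect_error(tic_normalize(ds), "\\(2, 1\\)")
})

test_that("peak picking on a noise-free phantom finds the planted peaks", {
  # one all-tumor region so every sampled spectrum carries the same peaks
  spec <- clean_phantom_spec(
    regions = list(rect_region(1, 6, 1, 6, "ccRCC")), grid = 6
  )
  ds <- generate_msi_phantom(spec)
  pl <- pick_peaks(ds, stride = 1, snr_min = 3)
  found <- sort(unique(round(pl$peaks$mz, 1)))
  planted <- sort(c(723.5, 704.5, default_shared_peaks()$mz))
  expect_equal(length(found), length(planted))
  expect_true(all(abs(found - round(planted, 1)) <= 0.25))
})

test_that("peak picking stride and SNR guards behave", {
  ds <- generate_msi_phantom(clean_phantom_spec(grid = 4))
  pl <- pick_peaks(ds, stride = n_pixels(ds), snr_min = 3)
  expect_equal(pl$source_pixel_count, 1)
  expect_error(pick_peaks(ds, snr_min = 0), "snr_min")
  # pure noise with an absurd SNR floor: empty peak list
  set.seed(2)
  noisy <- tiny_msi(matrix(abs(stats::rnorm(400)), 2))
  expect_equal(nrow(pick_peaks(noisy, stride = 1, snr_min = 1000)$peaks), 0)
})

test_that("alignment merges within tolerance to the weighted mean", {
  pl <- peak_list(data.frame(mz = c(700.10, 700.15),
                             intensity = c(10, 30), snr = c(5, 15)), 2)
  out <- align_peaks(pl, 0.25)
  expect_equal(nrow(out$peaks), 1)
  expect_equal(out$peaks$mz, (700.10 * 10 + 700.15 * 30) / 40)
  # peaks 1 Da apart are both retained
  pl2 <- peak_list(data.frame(mz = c(700, 701), intensity = c(1, 1),
                              snr = c(3, 3)), 2)
  expect_equal(nrow(align_peaks(pl2, 0.25)$peaks), 2)
})

test_that("greedy ascending alignment resolves chains deterministically", {
  # chain 700.0, 700.2, 700.4 at tolerance 0.25 (equal intensities):
  # enumeration of merge orders shows left-to-right greedy gives
  # {mean(700.0, 700.2) = 700.1, 700.4} since 700.4 - 700.1 = 0.3 > 0.25
  pl <- peak_list(data.frame(mz = c(700.0, 700.2, 700.4),
                             intensity = c(1, 1, 1), snr = c(3, 3, 3)), 3)
  out <- align_peaks(pl, 0.25)
  expect_equal(out$peaks$mz, c(700.1, 700.4))
  # min-separation invariant on random peak sets
  set.seed(11)
  rand <- peak_list(data.frame(mz = sort(stats::runif(50, 700, 710)),
                               intensity = stats::runif(50, 1, 5),
                               snr = rep(3, 50)), 5)
  aligned <- align_peaks(rand, 0.25)
  expect_true(all(diff(aligned$peaks$mz) > 0.25))
})

test_that("height resampling takes window maxima and zeros outside support", {
  ds <- tiny_msi(rbind(c(0, 5, 1, 0), c(1, 1, 1, 1)),
                 mz = c(100, 100.1, 100.2, 103))
  ref <- peak_list(data.frame(mz = c(100.1, 200), intensity = c(5, 1),
                              snr = c(3, 3)), 1, tolerance = 0.25)
  fm <- resample_height(ds, ref, tolerance = 0.125)
  expect_equal(fm$values[1, ], c(5, 0))   # apex captured; 200 out of range
  expect_equal(fm$values[2, ], c(1, 0))
})

test_that("height resampling on a noise-free phantom recovers class structure", {
  ds <- generate_msi_phantom(clean_phantom_spec(grid = 8))
  truth <- ground_truth(ds)
  ref <- peak_list(data.frame(mz = 723.5, intensity = 120, snr = 99), 1)
  fm <- resample_height(ds, ref)
  tumor <- truth$label == "ccRCC"
  expect_true(all(fm$values[tumor, 1] > 0))
  expect_true(all(fm$values[!tumor, 1] == 0))
})

test_that("bin resampling produces the full inclusive grid", {
  ds <- generate_msi_phantom(clean_phantom_spec(grid = 3))
  fm <- bin_resample(ds)  # defaults 700-2500 at 0.25
  expect_equal(length(fm$feature_axis), 7201)
  expect_equal(fm$feature_axis[1], 700)
  expect_equal(fm$feature_axis[7201], 2500)
  # grid-aligned input values are copied unchanged
  sub <- bin_resample(ds, 700, 710, 0.25)
  idx <- match(sub$feature_axis, ds$mz)
  expect_equal(unname(sub$values), unname(ds$intensities[, idx]))
  # constant spectrum: every bin equals the constant
  const <- tiny_msi(matrix(3, 1, 9601), mz = seq(600, 3000, 0.25))
  expect_true(all(bin_resample(const)$values == 3))
})

test_that("frequency filtering drops one-off peaks", {
  pl <- peak_list(data.frame(mz = c(700, 800, 900),
                             intensity = c(1, 1, 1), snr = c(3, 3, 3),
                             count = c(9, 1, 5)), 10, tolerance = 0.25)
  out <- filter_peak_frequency(pl, min_freq = 0.3)
  expect_equal(out$peaks$mz, c(700, 900))
})
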