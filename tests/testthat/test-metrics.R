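test_that("SSIM of an image with itself is exactly one", {
  set.seed(51)
  for (img in list(rand_image(8), rand_image(16, 9),
                   generate_phantom(phantom_spec(size = 32, kind = "chest")))) {
    expect_identical(ssim(img, img), 1)
  }
})

test_that("SSIM between distinct constant images follows the closed form", {
  a <- 0.3; b <- 0.7
  cs <- ssim_constants()
  got <- ssim(matrix(a, 6, 6), matrix(b, 6, 6), cs)
  expect_equal(got, (2 * a * b + cs$c1) / (a^2 + b^2 + cs$c1),
               tolerance = 1e-15)
})

test_that("SSIM matches the hand-evaluated five-moment form on a 2x2 pair", {
  x <- matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE)
  y <- matrix(c(0, 1, 0, 1), 2, 2, byrow = TRUE)
  cs <- ssim_constants(c1 = 1e-4, c2 = 1e-4)
  ## moments computed independently: mx = my = 1/2, vx = vy = 1/4,
  ## cov = ((-.5)(-.5) + (.5)(.5) + (.5)(-.5) + (-.5)(.5)) / 4 = 0
  hand <- ((2 * 0.5 * 0.5 + 1e-4) * (2 * 0 + 1e-4)) /
    ((0.25 + 0.25 + 1e-4) * (0.25 + 0.25 + 1e-4))
  expect_equal(ssim(x, y, cs), hand, tolerance = 1e-15)
})

test_that("SSIM is symmetric and bounded by one with equality iff equal", {
  set.seed(52)
  for (i in 1:20) {
    x <- rand_image(10); y <- rand_image(10)
    expect_identical(ssim(x, y), ssim(y, x))
    expect_lt(ssim(x, y), 1)
  }
  x <- rand_image(10)
  expect_identical(ssim(x, x), 1)
})

test_that("windowed mean-SSIM behaves like a similarity index", {
  set.seed(53)
  x <- rand_image(16); y <- rand_image(16)
  expect_identical(ssim(x, x, window = 7), 1)
  expect_identical(ssim(x, y, window = 7), ssim(y, x, window = 7))
  expect_lt(ssim(x, y, window = 7), 1)
  expect_error(ssim(x, y, window = 4), "odd")
})

test_that("ISNR follows the squared-norm decibel convention", {
  set.seed(54)
  clean <- rand_image(8); obs <- rand_image(8)
  expect_equal(isnr(clean, obs, obs), 0)
  ## an estimate with one tenth of the squared error gains exactly 10 dB
  est <- clean + (obs - clean) / sqrt(10)
  expect_equal(isnr(clean, obs, est), 10, tolerance = 1e-10)
  ## direct-summation oracle
  est2 <- rand_image(8)
  direct <- 10 * log10(sum((clean - obs)^2) / sum((clean - est2)^2))
  expect_equal(isnr(clean, obs, est2), direct, tolerance = 1e-10)
  expect_identical(isnr(clean, obs, clean), Inf)
})

test_that("SNR follows the squared-norm decibel convention", {
  set.seed(55)
  clean <- rand_image(8)
  ## error norm equal to the signal norm gives 0 dB
  est <- clean + clean * (sqrt(sum(clean^2)) / sqrt(sum(clean^2)))
  expect_equal(snr(clean, clean + clean), 0, tolerance = 1e-12)
  ## squared error one hundredth of squared signal gives 20 dB
  d <- rand_image(8) - 0.5
  d <- d * sqrt(sum(clean^2) / 100 / sum(d^2))
  expect_equal(snr(clean, clean + d), 20, tolerance = 1e-10)
  est2 <- rand_image(8)
  expect_equal(snr(clean, est2),
               10 * log10(sum(clean^2) / sum((clean - est2)^2)),
               tolerance = 1e-10)
  expect_identical(snr(clean, clean), Inf)
  expect_error(snr(matrix(0, 4, 4), rand_image(4)), "zero")
})

test_that("SNR strictly decreases as independent noise grows", {
  set.seed(56)
  clean <- generate_phantom(phantom_spec(size = 32, kind = "chest"))
  noise <- matrix(rnorm(length(clean)), nrow(clean))
  vals <- vapply(c(0.01, 0.03, 0.1, 0.3, 1),
                 function(a) snr(clean, clean + a * noise), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("ISNR is positive exactly when the estimate improves on the observation", {
  set.seed(57)
  clean <- rand_image(8)
  err <- rand_image(8) - 0.5
  obs <- clean + err
  expect_gt(isnr(clean, obs, clean + 0.5 * err), 0)
  expect_lt(isnr(clean, obs, clean + 2 * err), 0)
})

test_that("metric inputs must agree in shape", {
  expect_error(ssim(rand_image(4), rand_image(5)), "dimensions")
  expect_error(isnr(rand_image(4), rand_image(4), rand_image(5)),
               "dimensions")
})

test_that("metrics rows export in the tabular layout", {
  set.seed(58)
  clean <- rand_image(8); obs <- rand_image(8); est <- rand_image(8)
  rep <- metrics_report(clean, obs, est)
  path <- withr::local_tempfile(fileext = ".csv")
  write_metrics_row(rep, path, image_id = "img1", noise_family = "gaussian")
  write_metrics_row(rep, path, image_id = "img2", noise_family = "poisson")
  got <- read.csv(path)
  expect_identical(names(got), c("image_id", "noise_family", "ssim", "isnr",
                                 "snr"))
  expect_identical(nrow(got), 2L)
  expect_equal(got$ssim[1], rep$ssim, tolerance = 1e-9)
})
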