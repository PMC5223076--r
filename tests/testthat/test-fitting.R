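test_that("coefficient of determination follows its standard definition", {
  expect_identical(r_squared(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)
  expect_identical(r_squared(c(1, 2, 3, 4), rep(2.5, 4)), 0)
  expect_equal(r_squared(c(1, 2, 3, 4), c(1, 2, 3, 5)), 0.8)
  expect_warning(r2 <- r_squared(rep(2, 5), 1:5), "constant")
  expect_true(is.na(r2))
})

test_that("initializer locates each tissue peak within one bin", {
  # genuinely well-separated peaks: each interval's maximum is its own mode
  tp <- trimodal_params(
    fat        = component_params(2e5, -80, 15, 0),
    connective = component_params(3e5, 5, 15, 0),
    muscle     = component_params(3e5, 55, 10, 0)
  )
  counts <- predicted_counts(tp, hu_bin_centers())
  init <- initialize_params(hu_histogram(counts))
  expect_lt(abs(init$fat$mu - tp$fat$mu), 3.125 + 1e-9)
  expect_lt(abs(init$connective$mu - tp$connective$mu), 3.125 + 1e-9)
  expect_lt(abs(init$muscle$mu - tp$muscle$mu), 3.125 + 1e-9)
  expect_true(init$fat$mu < init$connective$mu &&
                init$connective$mu < init$muscle$mu)
})

test_that("initializer handles degenerate histograms", {
  expect_error(initialize_params(hu_histogram(rep(0, 128))), "fat")
  # one nonzero bin per tissue interval: mu0 equals those bin centers
  centers <- hu_bin_centers()
  counts <- rep(0, 128)
  picks <- c(which(centers < -9.5)[10], which(centers > -9.5 & centers < 40.5)[5],
             which(centers > 40.5)[20])
  counts[picks] <- 100
  init <- initialize_params(hu_histogram(counts))
  expect_equal(init$fat$mu, centers[picks[1]])
  expect_equal(init$connective$mu, centers[picks[2]])
  expect_equal(init$muscle$mu, centers[picks[3]])
  # an empty muscle interval is named in the error
  counts[picks[3]] <- 0
  expect_error(initialize_params(hu_histogram(counts)), "muscle")
})

test_that("noiseless model counts are recovered almost exactly", {
  tp <- make_truth()
  hist <- hu_histogram(predicted_counts(tp, hu_bin_centers()))
  fit <- fit_trimodal(hist)
  expect_true(fit$converged)
  expect_gte(fit$r_squared, 0.9999)
  for (t in c("fat", "connective", "muscle")) {
    expect_lt(abs(fit$params[[t]]$N / tp[[t]]$N - 1), 0.01)
    expect_lt(abs(fit$params[[t]]$mu - tp[[t]]$mu), abs(tp[[t]]$mu) * 0.01 + 0.1)
    expect_lt(abs(fit$params[[t]]$sigma / tp[[t]]$sigma - 1), 0.01)
    expect_lt(abs(fit$params[[t]]$alpha - tp[[t]]$alpha), 0.05)
  }
  expect_identical(fit$params$connective$alpha, 0)
})

test_that("parameters are recovered from a sampled voxel population", {
  tp <- make_truth()
  n <- 1e6
  hist <- build_histogram(sample_trimodal(tp, n, seed = 20260930))
  fit <- fit_trimodal(hist)
  truth_N <- expected_fitted_N(tp, hist$n_total)
  est_N <- c(fit$params$fat$N, fit$params$connective$N, fit$params$muscle$N)
  expect_lt(max(abs(est_N / truth_N - 1)), 0.02)
  for (t in c("fat", "connective", "muscle")) {
    expect_lt(abs(fit$params[[t]]$mu - tp[[t]]$mu), 1)
    expect_lt(abs(fit$params[[t]]$sigma / tp[[t]]$sigma - 1), 0.05)
  }
  expect_gte(fit$r_squared, 0.999)
})

test_that("optimization never worsens the starting objective", {
  tp <- make_truth()
  set.seed(3)
  for (rep in 1:5) {
    hu <- sample_trimodal(tp, 5000, seed = rep)
    hist <- build_histogram(hu)
    fit <- fit_trimodal(hist, multi_start = 1)
    sse_init <- sum((hist$counts -
                       predicted_counts(fit$init_params, hu_bin_centers()))^2)
    expect_lte(fit$sse, sse_init + 1e-9)
  }
})

test_that("rescaling counts rescales only the amplitudes", {
  tp <- make_truth()
  hist <- build_histogram(sample_trimodal(tp, 5e4, seed = 5))
  scale <- 2.5
  hist2 <- hu_histogram(hist$counts * scale)
  f1 <- fit_trimodal(hist)
  f2 <- fit_trimodal(hist2)
  for (t in c("fat", "connective", "muscle")) {
    expect_equal(f2$params[[t]]$N / f1$params[[t]]$N, scale, tolerance = 0.005)
    expect_equal(f2$params[[t]]$mu, f1$params[[t]]$mu, tolerance = 0.05)
    expect_equal(f2$params[[t]]$sigma / f1$params[[t]]$sigma, 1,
                 tolerance = 0.005)
    expect_lt(abs(f2$params[[t]]$alpha - f1$params[[t]]$alpha), 0.02)
  }
})

test_that("median location error stays below 1 HU across seeded replicates", {
  # 3e5 voxels per replicate: the broad low-amplitude connective band needs
  # that much data before its location information floor drops below 1 HU
  tp <- make_truth()
  err <- matrix(NA_real_, nrow = 20, ncol = 3)
  for (r in 1:20) {
    hist <- build_histogram(sample_trimodal(tp, 3e5, seed = 1000 + r))
    fit <- fit_trimodal(hist)
    err[r, ] <- c(abs(fit$params$fat$mu - tp$fat$mu),
                  abs(fit$params$connective$mu - tp$connective$mu),
                  abs(fit$params$muscle$mu - tp$muscle$mu))
  }
  expect_true(all(apply(err, 2, median) < 1))
})

test_that("a symmetric truth keeps fitted skewness small and the curve stable", {
  # the skew-normal information matrix is singular at alpha = 0, so the
  # alpha estimate drifts along a ridge compensated by mu/sigma shifts;
  # the fitted curve itself stays pinned to the truth
  tp <- trimodal_params(
    fat        = component_params(5e5, -80, 22, 0),
    connective = component_params(1.5e5, 5, 30, 0),
    muscle     = component_params(1e6, 55, 13, 0)
  )
  hist <- build_histogram(sample_trimodal(tp, 3e5, seed = 77))
  fit <- fit_trimodal(hist)
  expect_lt(abs(fit$params$fat$alpha), 0.6)
  expect_lt(abs(fit$params$muscle$alpha), 0.6)
  truth_curve <- predicted_counts(tp, hu_bin_centers()) / sum(tp$fat$N,
    tp$connective$N, tp$muscle$N) * hist$n_total * 3.125
  expect_lt(max(abs(fit$fitted - truth_curve)) / max(truth_curve), 0.02)
})

test_that("fit reports serialize to JSON with provenance", {
  tp <- make_truth()
  hist <- build_histogram(sample_trimodal(tp, 2e4, seed = 9))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_histogram_csv(hist, csv)
  fit <- fit_trimodal(hist)
  out <- withr::local_tempfile(fileext = ".json")
  write_fit_report(fit, out, input_path = csv)
  rep <- jsonlite::read_json(out, simplifyVector = TRUE)
  expect_equal(rep$input_md5, unname(tools::md5sum(csv)))
  expect_equal(rep$r_squared, fit$r_squared, tolerance = 1e-12)
  expect_equal(rep$params$connective$alpha, 0)
  expect_true(is.character(rep$tool_version))
})
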