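test_that("the HRF kernel has the right shape, mode and normalization", {
  k <- hrf_kernel(tr = 2)
  expect_equal(sum(k), 1, tolerance = 1e-6)
  expect_equal(attr(k, "mode_s"), 4.5) # (shape - 1) * scale
  expect_equal(k[1], 0)                # gamma density with shape > 1 at t = 0
  # fine-grid argmax sits at the continuous mode
  fine <- protex:::hrf_fine(dt = 0.01)
  expect_equal((which.max(fine) - 1) * 0.01, 4.5, tolerance = 0.02)
  kp <- hrf_kernel(tr = 2, normalize = "peak")
  expect_equal(max(kp), 1)
})

test_that("build_design convolves 5-s boxcars scaled by the match values", {
  ev <- tibble::tibble(onset = 0, duration = 5)
  des <- build_design(ev, match_proto = 2, match_exem = 0.5, n_volumes = 30,
                      tr = 2)
  # direct oracle: oversampled boxcar convolved with the fine kernel
  os <- 16L; dt <- 2 / os
  box <- as.numeric(seq(0, by = dt, length.out = 30 * os) < 5)
  kern <- protex:::hrf_fine(dt)
  full <- convolve(box, rev(kern), type = "open")[seq_len(30 * os)]
  expected <- full[1 + (0:29) * os]
  expect_equal(des$onset, expected, tolerance = 1e-10)
  expect_equal(des$proto_mod, 2 * expected, tolerance = 1e-10)
  expect_equal(des$exem_mod, 0.5 * expected, tolerance = 1e-10)
})

test_that("design construction is linear in the match values and validates onsets", {
  ev <- tibble::tibble(onset = c(0, 12, 24, 40), duration = 5)
  m1 <- runif(4, 1, 2); m2 <- runif(4, 1, 5)
  d1 <- build_design(ev, m1, m2, n_volumes = 40, tr = 2)
  d3 <- build_design(ev, 3 * m1, 3 * m2, n_volumes = 40, tr = 2)
  expect_equal(d3$proto_mod, 3 * d1$proto_mod)
  expect_equal(d3$exem_mod, 3 * d1$exem_mod)
  expect_error(build_design(tibble::tibble(onset = 100, duration = 5),
                            1, 1, n_volumes = 40, tr = 2), "outside the run")
  d0 <- build_design(ev[0, ], numeric(0), numeric(0), n_volumes = 10, tr = 2)
  expect_true(all(d0$onset == 0) && all(d0$proto_mod == 0))
  # centering makes the modulator columns orthogonal to mean modulation
  dc <- build_design(ev, m1, m2, n_volumes = 40, tr = 2,
                     center_modulators = TRUE)
  expect_false(isTRUE(all.equal(dc$proto_mod, d1$proto_mod)))
})

test_that("collinearity screen flags identical and variability-free modulators", {
  ev <- tibble::tibble(onset = seq(0, 108, by = 12), duration = 5)
  m <- runif(10, 1, 3)
  rep_same <- collinearity_check(build_design(ev, m, m, n_volumes = 60, tr = 2))
  expect_equal(rep_same$r_proto_exem, 1)
  expect_true(rep_same$excluded)
  # constant exemplar match -> column proportional to the onset regressor
  rep_const <- collinearity_check(
    build_design(ev, m, rep(2, 10), n_volumes = 60, tr = 2))
  expect_true(rep_const$rank_deficient)
  expect_true(rep_const$excluded)
  # genuinely variable, weakly-correlated modulators pass
  p <- model_params(w = fx_strong_w, c = 3)
  trials <- test_trials(fx_sets$interim_1, seed = 3)
  aug <- augment_trials(trials, fx_structure, p, p)
  rep_ok <- collinearity_check(
    build_design(aug, aug$match_prototype, aug$match_exemplar,
                 n_volumes = 133, tr = 2))
  expect_lt(abs(rep_ok$r_proto_exem), 0.9)
  expect_false(rep_ok$excluded)
})

test_that("fit_glm recovers noiseless coefficients and refuses rank deficiency", {
  ev <- tibble::tibble(onset = seq(0, 108, by = 12), duration = 5)
  set.seed(5)
  des <- build_design(ev, runif(10, 1, 3), runif(10, 2, 8), n_volumes = 60,
                      tr = 2)
  x <- protex:::design_full_matrix(des)
  b_true <- c(0.5, 1, 2, -1)
  y <- x %*% b_true
  fit <- fit_glm(cbind(y, 2 * y), des)
  expect_equal(unname(fit$betas[, 1]), b_true, tolerance = 1e-8)
  expect_equal(unname(fit$betas[, 2]), 2 * b_true, tolerance = 1e-8)
  expect_equal(unname(fit$sigma2), c(0, 0), tolerance = 1e-12)
  # pure noise: modulator betas centered on zero
  yn <- matrix(rnorm(60 * 800), 60)
  fitn <- fit_glm(yn, des)
  expect_lt(abs(mean(fitn$betas["proto_mod", ])), 4 * sd(fitn$betas["proto_mod", ]) / sqrt(800))
  # rank-deficient design refused with report attached
  bad <- build_design(ev, rep(1, 10), rep(2, 10), n_volumes = 60, tr = 2)
  err <- tryCatch(fit_glm(yn, bad), condition = function(e) e)
  expect_s3_class(err, "protex_rank_deficient")
  expect_true(err$report$excluded)
})

test_that("roi_effect is mean/SD per run, averaged, and scale invariant", {
  expect_equal(roi_effect(c(3, 1, 2, -2, 1)),
               mean(c(3, 1, 2, -2, 1)) / sd(c(3, 1, 2, -2, 1)))
  betas <- c(rnorm(20, 1, 2), rnorm(20, 1, 2))
  run <- rep(1:2, each = 20)
  expect_equal(roi_effect(betas, run),
               mean(tapply(betas, run, function(b) mean(b) / sd(b))))
  expect_equal(roi_effect(5 * betas, run), roi_effect(betas, run))
  expect_warning(flat <- roi_effect(c(1, 1, 1)), "zero voxel SD")
  expect_true(is.na(flat))
})

test_that("a prototype-coding synthetic ROI yields a larger prototype effect", {
  p <- model_params(w = fx_strong_w, c = 3)
  trials <- test_trials(fx_sets$interim_2, seed = 6)
  aug <- augment_trials(trials, fx_structure, p, p)
  des <- build_design(aug, aug$match_prototype, aug$match_exemplar,
                      n_volumes = 133, tr = 2)
  spec <- bold_spec("vmpfc-like", weight_proto = 1, weight_exem = 0,
                    noise_sd = 2, n_voxels = 60, seed = 3)
  y <- simulate_bold(spec, des)
  eff <- roi_model_effects(fit_glm(y, des))
  expect_gt(eff$effect[eff$model == "prototype"],
            eff$effect[eff$model == "exemplar"])
})

test_that("NIfTI round trip preserves the ROI time-series matrix", {
  arr <- array(rnorm(4 * 4 * 3 * 10), c(4, 4, 3, 10))
  mask <- array(0L, c(4, 4, 3)); mask[2:3, 2:3, 2] <- 1L
  bold_path <- withr::local_tempfile(fileext = ".nii.gz")
  mask_path <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(arr), bold_path)
  RNifti::writeNifti(RNifti::asNifti(mask), mask_path)
  mat <- read_bold_matrix(bold_path, mask_path)
  expect_identical(dim(mat), c(10L, 4L))
  expect_equal(mat[7, ], arr[, , , 7][mask == 1], tolerance = 1e-6)
})
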