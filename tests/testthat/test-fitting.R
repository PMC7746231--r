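test_that("negative log likelihood matches closed forms", {
  expect_equal(negative_log_likelihood(rep("A", 5), rep(1, 5)), 0)
  expect_equal(negative_log_likelihood(rep("A", 10), rep(0.5, 10)),
               10 * log(2), tolerance = 1e-12)
  expect_equal(negative_log_likelihood(c("A", "B", "A"), c(0.9, 0.2, 0.6)),
               -(log(0.9) + log(0.8) + log(0.6)), tolerance = 1e-12)
  expect_error(negative_log_likelihood(c("A", "B"), 0.5), "equal length")
  expect_error(negative_log_likelihood("A", 1.2), "\\[0, 1\\]")
  # floor keeps an impossible response finite
  expect_equal(negative_log_likelihood("A", 0, epsilon = 1e-10),
               -log(1e-10))
})

test_that("the reparameterisation round-trips and respects constraints", {
  set.seed(3)
  for (i in 1:20) {
    g <- rexp(8); w <- g / sum(g)
    p <- model_params(w = w, c = runif(1, 0.01, 99))
    back <- protex:::theta_to_params(protex:::params_to_theta(p))
    expect_equal(back$w, p$w, tolerance = 1e-8)
    expect_equal(back$c, p$c, tolerance = 1e-6)
  }
  # arbitrary theta always lands inside the constraint set
  for (i in 1:20) {
    p <- protex:::theta_to_params(rnorm(8, 0, 5))
    expect_true(all(p$w >= 0))
    expect_equal(sum(p$w), 1, tolerance = 1e-12)
    expect_true(p$c >= 0 && p$c <= 100)
  }
})

test_that("fitting is deterministic and beats every start's initial point", {
  tr <- fx_observer_trials("prototype", seed = 21)
  cfg <- fit_config(n_starts = 6, seed = 5)
  f1 <- fit_model(tr, fx_structure, "prototype", cfg)
  f2 <- fit_model(tr, fx_structure, "prototype", cfg)
  expect_identical(f1[c("params", "nll", "theta")], f2[c("params", "nll", "theta")])
  expect_true(all(f1$nll <= f1$init_nll + 1e-12))
  expect_true(f1$converged)
  expect_identical(f1$n_trials, nrow(tr))
})

test_that("the C++ simplex search matches stats::optim on the same objective", {
  tr <- fx_observer_trials("exemplar", seed = 31)
  fd <- protex:::make_fit_data(tr, fx_structure)
  obj <- function(th) protex:::cpp_nll_theta(th, fd$mA, fd$mB, fd$exA, fd$exB,
                                             fd$stim_idx, fd$resp_a, 1L, 1e-10)
  th0 <- protex:::params_to_theta(model_params(c = 1))
  ref <- optim(th0, obj, method = "Nelder-Mead",
               control = list(maxit = 4000, reltol = 1e-8))
  f <- fit_model(tr, fx_structure, "exemplar", fit_config(n_starts = 8, seed = 2))
  # multi-start C++ fit should do at least as well as single-start optim
  expect_lte(f$nll, ref$value + 1e-3)
  # and the exported objective agrees with the R-side likelihood pipeline
  expect_equal(obj(f$theta),
               nll_at(tr, fx_structure, "exemplar", f$params), tolerance = 1e-8)
})

test_that("fitted misfit never exceeds the truth's misfit by more than 1e-3 per trial", {
  for (seed in c(41, 42, 43)) {
    tr <- fx_observer_trials("prototype", seed = seed, c = 4, w = rep(1 / 8, 8))
    truth <- model_params(w = rep(1 / 8, 8), c = 4)
    f <- fit_model(tr, fx_structure, "prototype", fit_config(n_starts = 10, seed = 1))
    expect_lte(f$nll, nll_at(tr, fx_structure, "prototype", truth) +
                 1e-3 * f$n_trials)
  }
})

test_that("random responders recover c near 0 and chance-level misfit", {
  tr <- fx_observer_trials("random", seed = 51)
  f <- fit_model(tr, fx_structure, "prototype", fit_config(n_starts = 10, seed = 3))
  n <- f$n_trials
  expect_equal(f$nll, n * log(2), tolerance = 0.01 * n * log(2))
  expect_lt(f$params$c, 1.5)
})

test_that("model recovery: the generating model is favoured on its own data", {
  # The two models mimic each other closely at single-phase trial counts
  # (see the vignette); prototype observers are still identified in a clear
  # majority of seeds, exemplar observers at least at parity, and the
  # asymmetry disappears at large n (checked below).
  hits_p <- vapply(1:10, function(i) {
    tr <- fx_observer_trials("prototype", seed = 600 + i)
    pair <- fit_both(tr, fx_structure, fit_config(n_starts = 8, seed = 2))
    pair$prototype$nll < pair$exemplar$nll
  }, logical(1))
  expect_gte(mean(hits_p), 0.7)
  hits_e <- vapply(1:10, function(i) {
    tr <- fx_observer_trials("exemplar", seed = 700 + i)
    pair <- fit_both(tr, fx_structure, fit_config(n_starts = 8, seed = 2))
    pair$exemplar$nll < pair$prototype$nll
  }, logical(1))
  expect_gte(mean(hits_e), 0.5)
  # at many trials the generating exemplar model wins decisively
  big <- replicate_test_set(fx_sets$final, 1500, seed = 5)
  spec <- observer_spec("exemplar", w = fx_strong_w, c = fx_strong_c, seed = 9301)
  tr_big <- simulate_responses(spec, list(final = big), fx_structure)
  pair_big <- fit_both(tr_big, fx_structure, fit_config(n_starts = 10, seed = 2))
  expect_lt(pair_big$exemplar$nll, pair_big$prototype$nll - 1)
})

test_that("fits of both models improve together as sensitivity grows", {
  nlls <- sapply(c(0.5, 2, 6), function(cc) {
    tr <- fx_observer_trials("prototype", c = cc, seed = 81)
    pair <- fit_both(tr, fx_structure, fit_config(n_starts = 6, seed = 2))
    c(pair$prototype$nll / pair$prototype$n_trials,
      pair$exemplar$nll / pair$exemplar$n_trials)
  })
  expect_true(all(diff(nlls[1, ]) < 0))
  expect_true(all(diff(nlls[2, ]) < 0))
})

test_that("empty or non-responded trial tables are rejected", {
  tr <- fx_observer_trials("prototype", seed = 91)
  tr$response <- "none"
  expect_error(fit_model(tr, fx_structure, "prototype"), "no responded trials")
  expect_error(fit_both(tr[0, ], fx_structure), "no responded trials")
})

test_that("fit_cohort emits the per-subject per-phase fit table", {
  cohort <- simulate_cohort(2, fx_structure, fx_sets,
                            strategy_mix = c(prototype = 1), c = fx_strong_c,
                            w = fx_strong_w, seed = 5)
  tab <- fit_cohort(cohort, fx_structure, fit_config(n_starts = 4, seed = 1))
  expect_identical(nrow(tab), 2L * 3L * 2L) # 2 subjects x 3 phases x 2 models
  expect_setequal(unique(tab$phase), c("learn_half1", "learn_half2", "final"))
  expect_true(all(c("nll", "c", paste0("w", 1:8), "converged") %in% names(tab)))
  # learning halves concatenate two interim tests (44 trials each)
  expect_true(all(tab$n_trials[tab$phase != "final"] <= 44))
  tidy_long <- tidy(fit_both(cohort[cohort$subject == "S01" &
                                      cohort$phase == "final", ],
                             fx_structure, fit_config(n_starts = 2, seed = 1)))
  expect_identical(nrow(tidy_long), 18L)
})
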