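#' Specify a synthetic observer
#'
#' A generative observer whose trial-by-trial choice probabilities come from
#' the prototype model, the exemplar model, a convex mixture of the two, or
#' random guessing (p = 0.5). Learning is emulated by a per-phase schedule
#' of sensitivity values (`c` typically increases as choices become more
#' deterministic).
#'
#' @param strategy One of `"prototype"`, `"exemplar"`, `"mixture"`,
#'   `"random"`.
#' @param w Attention weights (default uniform).
#' @param c Sensitivity used for every phase without a schedule entry.
#' @param mixture_weight Prototype share for mixture observers, in [0, 1].
#' @param learning_schedule Optional named numeric vector of per-phase `c`
#'   values (names are phase labels, e.g. `interim_1`).
#' @param seed Integer seed; all of this observer's randomness derives from
#'   it.
#' @return An object of class `observer_spec`.
#' @export
observer_spec <- function(strategy = c("prototype", "exemplar", "mixture", "random"),
                          w = rep(1 / 8, 8), c = 4, mixture_weight = 0.5,
                          learning_schedule = NULL, seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(mixture_weight >= 0, mixture_weight <= 1)
  params <- model_params(w = w, c = c)
  base::structure(
    list(strategy = strategy, params = params,
         mixture_weight = mixture_weight,
         learning_schedule = learning_schedule, seed = as.integer(seed)),
    class = "observer_spec")
}

observer_p_a <- function(spec, features, structure, c_value) {
  if (spec$strategy == "random") return(rep(0.5, nrow(features)))
  params <- model_params(w = spec$params$w, c = c_value)
  p <- function(kind) {
    s <- category_similarities(features, structure, kind, params)
    response_probability(s$s_a, s$s_b)
  }
  switch(spec$strategy,
         prototype = p("prototype"),
         exemplar = p("exemplar"),
         mixture = spec$mixture_weight * p("prototype") +
           (1 - spec$mixture_weight) * p("exemplar"))
}

#' Simulate a synthetic observer's classification responses
#'
#' Orders each test set into trials (shuffled, with onsets on the 5 s + 7 s
#' event grid; the final test is split across four runs) and draws an A/B
#' response per trial from the observer's choice probability.
#'
#' @param spec An [observer_spec()].
#' @param test_sets Named list of test sets (as from [build_test_sets()]).
#' @param structure A `category_structure`.
#' @return A trial tibble with `response` filled in and the generating
#'   probability in `p_a_gen`.
#' @export
simulate_responses <- function(spec, test_sets, structure) {
  out <- purrr::imap_dfr(test_sets, function(ts, phase) {
    n_runs <- if (phase == "final") 4L else 1L
    trials <- test_trials(ts, seed = derive_seed(spec$seed,
                                                 300L + match(phase, names(test_sets))),
                          n_runs = n_runs)
    c_value <- if (!is.null(spec$learning_schedule) &&
                   phase %in% names(spec$learning_schedule))
      spec$learning_schedule[[phase]] else spec$params$c
    trials$p_a_gen <- observer_p_a(spec, feature_matrix(trials), structure,
                                   c_value)
    trials
  })
  out$response <- with_seed(derive_seed(spec$seed, 400L),
                            ifelse(rbinom(nrow(out), 1, out$p_a_gen) == 1,
                                   "A", "B"))
  out
}

#' Simulate a cohort of synthetic observers
#'
#' Independent seeded observers drawn from a mix of strategies, all sharing
#' one category structure and test-set design. Every subject's randomness
#' derives from the master seed, so the whole cohort is reproducible.
#'
#' @param n_subjects Number of observers (the study analysed 29).
#' @param structure A `category_structure`.
#' @param test_sets Test sets from [build_test_sets()].
#' @param strategy_mix Named numeric vector of strategy proportions (e.g.
#'   `c(prototype = 0.6, similar = 0)`); names must be observer strategies.
#' @param c Sensitivity for every observer (or a function(subject_index)
#'   returning one).
#' @param w Attention weights for every observer.
#' @param learning_schedule Optional shared per-phase `c` schedule.
#' @param seed Master seed.
#' @return A single trial tibble with a `subject` column (`S01`, ...) and a
#'   `strategy` column carrying each observer's generating strategy.
#' @export
simulate_cohort <- function(n_subjects = 29L, structure,
                            test_sets = build_test_sets(structure),
                            strategy_mix = c(prototype = 1), c = 4,
                            w = rep(1 / 8, 8), learning_schedule = NULL,
                            seed = 1L) {
  stopifnot(all(names(strategy_mix) %in%
                  c("prototype", "exemplar", "mixture", "random")),
            sum(strategy_mix) > 0)
  probs <- strategy_mix / sum(strategy_mix)
  strategies <- with_seed(derive_seed(seed, 500L),
                          sample(names(probs), n_subjects, replace = TRUE,
                                 prob = probs))
  purrr::map_dfr(seq_len(n_subjects), function(i) {
    c_i <- if (is.function(c)) c(i) else c
    spec <- observer_spec(strategy = strategies[i], w = w, c = c_i,
                          learning_schedule = learning_schedule,
                          seed = derive_seed(seed, 1000L + i))
    dplyr::mutate(simulate_responses(spec, test_sets, structure),
                  subject = sprintf("S%02d", i), strategy = strategies[i],
                  .before = 1)
  })
}

#' Specify a synthetic ROI BOLD generator
#'
#' A region whose voxels linearly encode the onset regressor plus a weighted
#' combination of the prototype and exemplar representational-match
#' regressors, with Gaussian noise. A prototype-coding region has
#' `weight_proto > 0, weight_exem = 0`, and vice versa.
#'
#' @param roi_name Label for the region.
#' @param weight_proto,weight_exem True regression weights on the two
#'   modulator columns.
#' @param noise_sd Gaussian noise SD (> 0).
#' @param n_voxels Number of voxels (>= 2).
#' @param weight_jitter_sd SD of the per-voxel jitter on the true weights.
#' @param b_onset Weight on the onset regressor.
#' @param tr Repetition time (s).
#' @param seed Integer seed.
#' @return An object of class `bold_spec`.
#' @export
bold_spec <- function(roi_name = "roi", weight_proto = 1, weight_exem = 0,
                      noise_sd = 1, n_voxels = 50L, weight_jitter_sd = 0.05,
                      b_onset = 1, tr = 2, seed = 1L) {
  stopifnot(n_voxels >= 2, noise_sd >= 0)
  base::structure(
    list(roi_name = roi_name, weight_proto = weight_proto,
         weight_exem = weight_exem, noise_sd = noise_sd,
         n_voxels = as.integer(n_voxels),
         weight_jitter_sd = weight_jitter_sd, b_onset = b_onset, tr = tr,
         seed = as.integer(seed)),
    class = "bold_spec")
}

#' Simulate ROI BOLD from a design matrix
#'
#' Each voxel's time series is `b_onset * onset + (weight_proto + jitter) *
#' proto_mod + (weight_exem + jitter) * exem_mod + N(0, noise_sd)`, with
#' independent per-voxel jitter and noise.
#'
#' @param spec A [bold_spec()].
#' @param design A `design_matrix` built for the same run.
#' @return Numeric matrix, volumes x voxels.
#' @export
simulate_bold <- function(spec, design) {
  x <- design_task_matrix(design)
  n_vol <- nrow(x)
  with_seed(spec$seed, {
    wp <- spec$weight_proto + rnorm(spec$n_voxels, 0, spec$weight_jitter_sd)
    we <- spec$weight_exem + rnorm(spec$n_voxels, 0, spec$weight_jitter_sd)
    signal <- x[, "onset"] %o% rep(spec$b_onset, spec$n_voxels) +
      x[, "proto_mod"] %o% wp + x[, "exem_mod"] %o% we
    signal + matrix(rnorm(n_vol * spec$n_voxels, 0, spec$noise_sd), n_vol)
  })
}
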