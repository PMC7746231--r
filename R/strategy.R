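#' Permutation null distribution of model fits
#'
#' Builds a per-subject chance distribution by shuffling the order of
#' stimuli associated with the subject's actual string of responses, then
#' refitting both models to each randomized stimulus-response mapping. Each
#' refit starts the simplex search once from the observed fit's parameters
#' (warm start) plus `n_starts - 1` random restarts.
#'
#' @param trials Responded trial tibble for one subject and one analysis
#'   phase.
#' @param structure A `category_structure`.
#' @param config A [fit_config()]; `config$n_starts` here is the number of
#'   starts per permutation refit (default scaled down to 5).
#' @param n_perms Number of permutations (10,000 replicates the full
#'   procedure; 500 is a practical scaled-down default).
#' @param seed Integer seed for the permutation stream.
#' @param observed Optional `pe_fit_pair` of the observed fits (computed if
#'   missing) used for warm starts.
#' @return A tibble with `n_perms` rows: `perm`, `nll_prototype`,
#'   `nll_exemplar`, `diff` (exemplar minus prototype).
#' @export
permutation_null <- function(trials, structure, config = fit_config(n_starts = 5),
                             n_perms = 500L, seed = 1L, observed = NULL) {
  stopifnot(n_perms >= 1)
  fd <- make_fit_data(trials, structure)
  if (is.null(observed)) {
    observed <- base::structure(
      list(prototype = fit_from_data(fd, "prototype", config),
           exemplar = fit_from_data(fd, "exemplar", config)),
      class = "pe_fit_pair")
  }
  warm <- list(prototype = observed$prototype$theta,
               exemplar = observed$exemplar$theta)
  n <- length(fd$stim_idx)
  out <- with_seed(seed, {
    purrr::map_dfr(seq_len(n_perms), function(p) {
      fd_p <- fd
      # shuffle which stimulus each response is paired with
      fd_p$stim_idx <- fd$stim_idx[sample.int(n)]
      nlls <- vapply(c("prototype", "exemplar"), function(kind) {
        starts <- rbind(warm[[kind]],
                        random_starts(max(config$n_starts - 1L, 0L),
                                      config$c_start_range))
        fit_from_data(fd_p, kind, config, starts = starts)$nll
      }, numeric(1))
      tibble::tibble(perm = p, nll_prototype = nlls[["prototype"]],
                     nll_exemplar = nlls[["exemplar"]],
                     diff = nlls[["exemplar"]] - nlls[["prototype"]])
    })
  })
  attr(out, "observed") <- observed
  out
}

#' One-tailed above-chance test against a permutation null
#'
#' Tests whether an observed model fit is reliably better (lower negative
#' log likelihood) than expected if the subject had responded without regard
#' to the stimuli. The p-value uses the add-one permutation estimator
#' `(1 + #{null <= observed}) / (1 + n_perms)`, which can never be exactly
#' zero.
#'
#' @param observed_nll Observed fit value.
#' @param null_nlls Numeric vector of null fit values.
#' @param alpha Significance level (one-tailed).
#' @return A list with `p` and logical `above_chance`.
#' @export
above_chance <- function(observed_nll, null_nlls, alpha = 0.05) {
  if (length(null_nlls) == 0L)
    stop("null distribution is empty", call. = FALSE)
  p <- (1 + sum(null_nlls <= observed_nll)) / (1 + length(null_nlls))
  list(p = p, above_chance = p < alpha)
}

#' Classify a subject's categorization strategy
#'
#' Compares the observed difference in model fits (exemplar minus prototype
#' negative log likelihood) to its permutation null, two-tailed on the
#' absolute difference. Subjects whose difference is not reliably larger
#' than chance are labeled `"similar"`; otherwise the sign of the
#' difference picks `"prototype"` or `"exemplar"`. Each model's own fit is
#' also tested against chance (one-tailed).
#'
#' @param fit_pair A `pe_fit_pair` of the observed fits.
#' @param null A tibble from [permutation_null()].
#' @param alpha Significance level.
#' @return A one-row tibble: `label`, `observed_diff`, `p_diff`,
#'   `p_proto_chance`, `p_exem_chance`, `proto_above_chance`,
#'   `exem_above_chance`, `n_perms`.
#' @export
classify_strategy <- function(fit_pair, null, alpha = 0.05) {
  observed_diff <- fit_pair$exemplar$nll - fit_pair$prototype$nll
  n_perms <- nrow(null)
  p_diff <- (1 + sum(abs(null$diff) >= abs(observed_diff))) / (1 + n_perms)
  label <- if (p_diff >= alpha || observed_diff == 0) "similar"
           else if (observed_diff > 0) "prototype" else "exemplar"
  proto <- above_chance(fit_pair$prototype$nll, null$nll_prototype, alpha)
  exem <- above_chance(fit_pair$exemplar$nll, null$nll_exemplar, alpha)
  tibble::tibble(label = label, observed_diff = observed_diff,
                 p_diff = p_diff, p_proto_chance = proto$p,
                 p_exem_chance = exem$p,
                 proto_above_chance = proto$above_chance,
                 exem_above_chance = exem$above_chance, n_perms = n_perms)
}

#' Fit, permute and classify one subject-phase
#'
#' Convenience wrapper: observed [fit_both()], [permutation_null()], and
#' [classify_strategy()] in one call.
#'
#' @inheritParams permutation_null
#' @param alpha Significance level.
#' @param fit_config Configuration for the observed fits.
#' @param perm_config Configuration for the per-permutation refits (fewer
#'   starts by default).
#' @return A one-row tibble as in [classify_strategy()], plus `nll_prototype`
#'   and `nll_exemplar` of the observed fits.
#' @export
classify_subject <- function(trials, structure, n_perms = 500L, alpha = 0.05,
                             seed = 1L, fit_config = protex::fit_config(),
                             perm_config = protex::fit_config(n_starts = 5,
                                                             seed = seed)) {
  pair <- fit_both(trials, structure, fit_config)
  null <- permutation_null(trials, structure, perm_config, n_perms = n_perms,
                           seed = seed, observed = pair)
  dplyr::mutate(classify_strategy(pair, null, alpha),
                nll_prototype = pair$prototype$nll,
                nll_exemplar = pair$exemplar$nll, seed = seed)
}

#' Classify every subject-phase cell of a cohort
#'
#' @param trials Cohort trial tibble with `subject` and `phase` columns.
#' @inheritParams classify_subject
#' @return A tibble with one row per subject x analysis phase.
#' @export
classify_cohort <- function(trials, structure, n_perms = 500L, alpha = 0.05,
                            seed = 1L, fit_config = protex::fit_config(),
                            perm_config = protex::fit_config(n_starts = 5)) {
  trials <- fit_phases(trials)
  trials <- trials[!is.na(trials$fit_phase), ]
  cells <- dplyr::distinct(trials, .data$subject, .data$fit_phase)
  purrr::pmap_dfr(cells, function(subject, fit_phase) {
    sub <- trials[trials$subject == subject & trials$fit_phase == fit_phase, ]
    cell_seed <- derive_seed(seed, match(subject, unique(trials$subject)) * 8L +
                               match(fit_phase, c("learn_half1", "learn_half2", "final")))
    perm_config$seed <- cell_seed
    dplyr::mutate(
      classify_subject(sub, structure, n_perms = n_perms, alpha = alpha,
                       seed = cell_seed, fit_config = fit_config,
                       perm_config = perm_config),
      subject = subject, phase = fit_phase, .before = 1)
  })
}
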