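#' Fitting configuration
#'
#' Settings for maximum-likelihood model fitting. The likelihood is
#' multimodal in the attention weights, so fitting uses multi-start
#' derivative-free simplex (Nelder-Mead) minimisation in an unconstrained
#' reparameterisation: `w` via a softmax of 8 free reals with one pinned to
#' 0, `c` via a scaled logistic onto [0, 100].
#'
#' @param n_starts Number of random restarts (a fixed start at uniform `w`,
#'   `c = 1` is always added). Random starts draw `w` from a flat Dirichlet
#'   and `c` log-uniformly over `c_start_range`.
#' @param seed Integer seed controlling the random starts.
#' @param epsilon Probability floor inside the log-likelihood; the chosen
#'   option's probability is floored at `epsilon`.
#' @param reltol Relative convergence tolerance of the simplex search.
#' @param maxit Maximum function evaluations per start.
#' @param c_start_range Range for the log-uniform sensitivity starts.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(n_starts = 20L, seed = 1L, epsilon = 1e-10,
                       reltol = 1e-6, maxit = 2000L,
                       c_start_range = c(0.1, 20)) {
  stopifnot(n_starts >= 0, epsilon > 0, epsilon < 0.5, maxit >= 1)
  structure(list(n_starts = as.integer(n_starts), seed = as.integer(seed),
                 epsilon = epsilon, reltol = reltol, maxit = as.integer(maxit),
                 c_start_range = c_start_range),
            class = "fit_config")
}

#' Negative log likelihood of a response string
#'
#' The model-fit error metric: the negative sum of log-transformed
#' probabilities of the responses the subject actually gave. Lower is
#' better. The probability of the chosen option is floored at `epsilon` so
#' extreme sensitivities cannot produce an infinite misfit; perfectly
#' predicted responses contribute exactly zero.
#'
#' @param responses Character vector of `"A"`/`"B"` responses.
#' @param probs_a Model probability of responding A, per trial.
#' @param epsilon Probability floor.
#' @return Non-negative scalar.
#' @examples
#' negative_log_likelihood(c("A", "B"), c(0.8, 0.3))
#' @export
negative_log_likelihood <- function(responses, probs_a, epsilon = 1e-10) {
  if (length(responses) != length(probs_a))
    stop("responses and probs_a must have equal length", call. = FALSE)
  if (any(probs_a < 0 | probs_a > 1, na.rm = TRUE))
    stop("probs_a must be in [0, 1]", call. = FALSE)
  p_chosen <- ifelse(responses == "A", probs_a, 1 - probs_a)
  -sum(log(pmax(p_chosen, epsilon)))
}

# ---- unconstrained reparameterisation -------------------------------------

theta_to_params <- function(theta) {
  z <- c(theta[1:7], 0)
  w <- exp(z - max(z))
  model_params(w = w / sum(w), c = 100 * plogis(theta[8]))
}

params_to_theta <- function(params) {
  w <- pmax(params$w, 1e-12)
  c(pmin(pmax(log(w[1:7] / w[8]), -30), 30),
    qlogis(pmin(pmax(params$c / 100, 1e-12), 1 - 1e-12)))
}

random_starts <- function(n, c_range) {
  if (n == 0) return(matrix(numeric(0), 0, 8))
  t(vapply(seq_len(n), function(i) {
    g <- rexp(8)
    c_val <- exp(runif(1, log(c_range[1]), log(c_range[2])))
    params_to_theta(model_params(w = g / sum(g), c = c_val))
  }, numeric(8)))
}

# precompute the collapsed per-unique-stimulus mismatch representation the
# C++ likelihood consumes
make_fit_data <- function(trials, structure) {
  responded <- trials[!is.na(trials$response) & trials$response %in% c("A", "B"), ]
  if (nrow(responded) == 0L)
    stop("no responded trials to fit", call. = FALSE)
  ids <- responded$stim_id
  uniq <- !duplicated(ids)
  u_ids <- ids[uniq]
  m <- feature_matrix(responded[uniq, ])
  tr <- structure$training
  ex_a <- feature_matrix(tr[tr$category == "A", ])
  ex_b <- feature_matrix(tr[tr$category == "B", ])
  mismatch_to <- function(targets) {
    do.call(cbind, lapply(seq_len(nrow(targets)), function(e)
      abs(sweep(m, 2, targets[e, ]))))
  }
  list(
    mA = abs(sweep(m, 2, structure$proto_A)),
    mB = abs(sweep(m, 2, structure$proto_B)),
    exA = mismatch_to(ex_a), exB = mismatch_to(ex_b),
    stim_idx = match(ids, u_ids) - 1L,
    resp_a = responded$response == "A",
    n_trials = nrow(responded)
  )
}

fit_kind_code <- function(kind) match(kind, c("prototype", "exemplar")) - 1L

fit_from_data <- function(fd, kind, config, starts = NULL) {
  if (is.null(starts))
    starts <- rbind(
      params_to_theta(model_params(w = rep(1 / 8, 8), c = 1)),
      with_seed(config$seed, random_starts(config$n_starts, config$c_start_range))
    )
  res <- cpp_fit_model(fd$mA, fd$mB, fd$exA, fd$exB, fd$stim_idx, fd$resp_a,
                       fit_kind_code(kind), starts, config$maxit,
                       config$reltol, config$epsilon)
  base::structure(
    list(kind = kind, params = theta_to_params(res$par), nll = res$value,
         n_trials = fd$n_trials, n_starts = nrow(starts),
         converged = any(res$converged), theta = res$par,
         start_nll = res$start_nll, init_nll = res$init_nll,
         fevals = res$fevals, phase = NA_character_),
    class = "pe_fit"
  )
}

#' Fit one categorization model to a subject's responses
#'
#' Maximum-likelihood estimation of the attention weights and sensitivity
#' for the prototype or exemplar model, from a string of A/B classification
#' responses. Omitted trials (`response` missing or `"none"`) are excluded.
#' The best of `n_starts + 1` simplex searches is returned; with a fixed
#' seed the result is exactly reproducible.
#'
#' @param trials Trial tibble (feature columns `f1`-`f8`, `stim_id`,
#'   `response`).
#' @param structure A `category_structure`.
#' @param kind `"prototype"` or `"exemplar"`.
#' @param config A [fit_config()].
#' @return An object of class `pe_fit` with elements `kind`, `params`
#'   ([model_params()]), `nll`, `n_trials`, `n_starts`, `converged`, and
#'   optimizer diagnostics. [tidy()] and [glance()] methods are provided.
#' @export
fit_model <- function(trials, structure, kind = c("prototype", "exemplar"),
                      config = fit_config()) {
  kind <- match.arg(kind)
  fd <- make_fit_data(trials, structure)
  fit <- fit_from_data(fd, kind, config)
  if (!fit$converged)
    warning("no optimizer start converged; returning best point found")
  fit
}

#' Fit both models to the same trials
#'
#' Fits the prototype and exemplar models to the identical responded-trial
#' subset, as required for within-subject model comparison.
#'
#' @inheritParams fit_model
#' @return A list of class `pe_fit_pair` with elements `prototype` and
#'   `exemplar` (both `pe_fit`).
#' @export
fit_both <- function(trials, structure, config = fit_config()) {
  fd <- make_fit_data(trials, structure)
  base::structure(list(prototype = fit_from_data(fd, "prototype", config),
                       exemplar = fit_from_data(fd, "exemplar", config)),
                  class = "pe_fit_pair")
}

#' Negative log likelihood at given parameters
#'
#' Evaluates the misfit of a model at fixed parameters (e.g., the known
#' generating parameters of a simulated observer) without any optimisation.
#'
#' @inheritParams fit_model
#' @param params A [model_params()] object.
#' @param epsilon Probability floor.
#' @return Non-negative scalar.
#' @export
nll_at <- function(trials, structure, kind = c("prototype", "exemplar"),
                   params, epsilon = 1e-10) {
  kind <- match.arg(kind)
  responded <- trials[!is.na(trials$response) & trials$response %in% c("A", "B"), ]
  pred <- model_predictions(responded, structure, kind, params)
  negative_log_likelihood(responded$response, pred[[paste0("p_a_", kind)]],
                          epsilon)
}

#' Phase grouping of trial tables
#'
#' Interim tests are analysed as halves of the learning phase: cycles 1-2
#' concatenated as `learn_half1`, cycles 3-4 as `learn_half2`; the final
#' test is its own phase.
#'
#' @param trials A trial tibble with a `phase` column.
#' @return The tibble with a `fit_phase` column added.
#' @export
fit_phases <- function(trials) {
  dplyr::mutate(trials, fit_phase = dplyr::case_when(
    .data$phase %in% c("interim_1", "interim_2") ~ "learn_half1",
    .data$phase %in% c("interim_3", "interim_4") ~ "learn_half2",
    .data$phase == "final" ~ "final",
    TRUE ~ NA_character_
  ))
}

#' Fit both models per subject and phase
#'
#' Runs [fit_both()] on each subject x analysis-phase cell of a (cohort)
#' trial table and returns the tidy fit table.
#'
#' @param trials Trial tibble with `subject` and `phase` columns.
#' @param structure A `category_structure`.
#' @param config A [fit_config()].
#' @return A tibble: subject, phase, model, nll, c, w1-w8, n_trials,
#'   converged.
#' @export
fit_cohort <- function(trials, structure, config = fit_config()) {
  trials <- fit_phases(trials)
  trials <- trials[!is.na(trials$fit_phase), ]
  cells <- dplyr::distinct(trials, .data$subject, .data$fit_phase)
  purrr::pmap_dfr(cells, function(subject, fit_phase) {
    sub <- trials[trials$subject == subject & trials$fit_phase == fit_phase, ]
    pair <- fit_both(sub, structure, config)
    dplyr::mutate(tidy(pair, wide = TRUE),
                  subject = subject, phase = fit_phase, .before = 1)
  })
}

# ---- broom-style methods ---------------------------------------------------

#' @export
print.pe_fit <- function(x, ...) {
  cat(sprintf("%s model fit: nll = %.4f over %d trials (c = %.3f, %s)\n",
              x$kind, x$nll, x$n_trials, x$params$c,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Tidy a model fit
#'
#' @param x A `pe_fit` or `pe_fit_pair`.
#' @param wide For pairs: one row per model with `c` and `w1`-`w8` columns
#'   (the fit-table layout) instead of one row per parameter.
#' @param ... Unused.
#' @return A tibble of parameter estimates.
#' @export
tidy.pe_fit <- function(x, ...) {
  tibble::tibble(term = c("c", paste0("w", 1:8)),
                 estimate = c(x$params$c, x$params$w))
}

#' @rdname tidy.pe_fit
#' @export
glance.pe_fit <- function(x, ...) {
  tibble::tibble(model = x$kind, nll = x$nll, n_trials = x$n_trials,
                 n_starts = x$n_starts, converged = x$converged)
}

#' @rdname tidy.pe_fit
#' @export
tidy.pe_fit_pair <- function(x, wide = FALSE, ...) {
  if (wide) {
    purrr::map_dfr(x, function(f) {
      est <- setNames(as.list(c(f$nll, f$params$c, f$params$w)),
                      c("nll", "c", paste0("w", 1:8)))
      tibble::as_tibble(c(list(model = f$kind), est,
                          list(n_trials = f$n_trials, converged = f$converged)))
    })
  } else {
    purrr::map_dfr(x, function(f)
      dplyr::mutate(tidy(f), model = f$kind, .before = 1))
  }
}

#' @rdname tidy.pe_fit
#' @export
glance.pe_fit_pair <- function(x, ...) {
  purrr::map_dfr(x, glance)
}
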