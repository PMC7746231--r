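#' Model parameters: attention weights and sensitivity
#'
#' The prototype and exemplar models share one parameterisation: a vector of
#' eight non-negative attention weights `w` summing to 1 (how much each
#' binary feature contributes to psychological distance) and a sensitivity
#' `c` in [0, 100] giving the rate at which similarity decays exponentially
#' with weighted distance. The distance-metric exponent `r` is fixed at 1
#' (city-block metric, the natural choice for binary features); other values
#' are rejected.
#'
#' @param w Numeric vector of 8 non-negative weights summing to 1.
#' @param c Sensitivity, in [0, 100]. Dimensionless.
#' @param r Distance exponent; must be 1.
#' @return An object of class `model_params`.
#' @examples
#' model_params(w = rep(1 / 8, 8), c = 4)
#' @export
model_params <- function(w = rep(1 / 8, 8), c = 1, r = 1) {
  w <- as.numeric(w)
  if (length(w) != 8L || any(w < 0) || abs(sum(w) - 1) > 1e-9)
    stop("w must be 8 non-negative weights summing to 1", call. = FALSE)
  if (!is.numeric(c) || length(c) != 1L || c < 0 || c > 100)
    stop("c must be a single value in [0, 100]", call. = FALSE)
  if (!identical(as.numeric(r), 1))
    stop("only the city-block metric (r = 1) is supported", call. = FALSE)
  structure(list(w = w, c = as.numeric(c), r = 1), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("model_params: c =", format(x$c, digits = 4), " w =",
      paste(format(x$w, digits = 3), collapse = " "), "\n")
  invisible(x)
}

as_feature_matrix <- function(x) {
  m <- if (is.matrix(x)) x else matrix(as.numeric(x), nrow = 1)
  if (ncol(m) != 8L) stop("stimuli must have 8 features", call. = FALSE)
  storage.mode(m) <- "double"
  m
}

SIM_FLOOR <- 1e-300

#' Similarity of stimuli to a prototype
#'
#' Perceived similarity is an exponential decay in attention-weighted
#' city-block distance: `exp(-c * sum_i w_i |x_i - proto_i|)`. It equals 1
#' iff the stimulus is the prototype or `c = 0`, and is floored at 1e-300 to
#' keep downstream ratios finite at extreme sensitivities.
#'
#' @param x A binary feature vector or a matrix of stimuli (rows).
#' @param proto The prototype feature vector.
#' @param params A [model_params()] object.
#' @return Numeric similarity in (0, 1], one value per stimulus row.
#' @export
prototype_similarity <- function(x, proto, params) {
  stopifnot(inherits(params, "model_params"))
  m <- as_feature_matrix(x)
  d <- abs(sweep(m, 2, as.numeric(proto))) %*% params$w
  pmax(exp(-params$c * drop(d)), SIM_FLOOR)
}

#' Summed similarity of stimuli to a category's exemplars
#'
#' The exemplar (generalized context) model represents a category by its
#' stored training items; a stimulus's similarity to the category is the sum
#' over exemplars of the exponential-decay similarity used in
#' [prototype_similarity()]. The nonlinear decay weights the closest
#' exemplars most heavily; the sum lets several close exemplars all
#' contribute.
#'
#' @param x A binary feature vector or a matrix of stimuli (rows).
#' @param exemplars Matrix of exemplar feature vectors (rows), non-empty.
#' @param params A [model_params()] object.
#' @return Numeric summed similarity in (0, n_exemplars], per stimulus row.
#' @export
exemplar_similarity <- function(x, exemplars, params) {
  stopifnot(inherits(params, "model_params"))
  ex <- as_feature_matrix(exemplars)
  if (nrow(ex) == 0L) stop("exemplar list must be non-empty", call. = FALSE)
  m <- as_feature_matrix(x)
  # w-weighted mismatch between binary vectors: x + y - 2xy, summed over
  # features = Xw + Yw - 2 * X diag(w) Y'
  xw <- drop(m %*% params$w)
  yw <- drop(ex %*% params$w)
  cross <- (m * rep(params$w, each = nrow(m))) %*% t(ex)
  d <- outer(xw, yw, "+") - 2 * cross
  pmax(rowSums(exp(-params$c * d)), SIM_FLOOR)
}

#' Choice probability from category similarities
#'
#' The probability of assigning a stimulus to category A is its similarity
#' to A divided by the summed similarity to both categories (a Luce choice
#' rule over similarities).
#'
#' @param s_a,s_b Non-negative similarities to categories A and B
#'   (vectorised).
#' @return `s_a / (s_a + s_b)`, in [0, 1].
#' @export
response_probability <- function(s_a, s_b) {
  if (any(s_a < 0) || any(s_b < 0))
    stop("similarities must be non-negative", call. = FALSE)
  if (any(s_a + s_b == 0))
    stop("degenerate input: both similarities are zero", call. = FALSE)
  s_a / (s_a + s_b)
}

#' Representational match (summed similarity across both categories)
#'
#' The trial-wise latent used as the fMRI parametric modulator: the total
#' similarity of a stimulus to the category representations as a whole,
#' `S_A(x) + S_B(x)` -- the denominator of the choice rule -- under either
#' the prototype or the exemplar representation. It indexes how close the
#' item is to what has been learned, regardless of which category it is
#' closer to.
#'
#' @param x Stimulus feature vector or matrix of stimuli (rows).
#' @param structure A `category_structure`.
#' @param kind `"prototype"` or `"exemplar"`.
#' @param params A [model_params()] object (each model's own fitted
#'   parameters in the intended use).
#' @return Numeric vector; range (0, 2] for the prototype model and
#'   (0, 8] for the exemplar model with the standard 4 + 4 training set.
#' @export
representational_match <- function(x, structure, kind = c("prototype", "exemplar"),
                                   params) {
  kind <- match.arg(kind)
  s <- category_similarities(x, structure, kind, params)
  s$s_a + s$s_b
}

category_similarities <- function(x, structure, kind, params) {
  tr <- structure$training
  if (kind == "prototype") {
    list(s_a = prototype_similarity(x, structure$proto_A, params),
         s_b = prototype_similarity(x, structure$proto_B, params))
  } else {
    list(s_a = exemplar_similarity(x, feature_matrix(tr[tr$category == "A", ]), params),
         s_b = exemplar_similarity(x, feature_matrix(tr[tr$category == "B", ]), params))
  }
}

#' Per-trial model predictions
#'
#' Appends the model's choice probability `p_a` and representational match
#' `match` to a trial table, for one model kind under given parameters.
#'
#' @param trials A trial tibble with feature columns `f1`-`f8`.
#' @param structure A `category_structure`.
#' @param kind `"prototype"` or `"exemplar"`.
#' @param params A [model_params()] object.
#' @return The trial tibble with `p_a_<kind>` and `match_<kind>` columns
#'   appended.
#' @export
model_predictions <- function(trials, structure, kind = c("prototype", "exemplar"),
                              params) {
  kind <- match.arg(kind)
  m <- feature_matrix(trials)
  s <- category_similarities(m, structure, kind, params)
  trials[[paste0("p_a_", kind)]] <- response_probability(s$s_a, s$s_b)
  trials[[paste0("match_", kind)]] <- s$s_a + s$s_b
  trials
}

#' @rdname model_predictions
#' @param params_prototype,params_exemplar Parameters for the two models
#'   (typically each model's own behavioral fit).
#' @export
augment_trials <- function(trials, structure, params_prototype, params_exemplar) {
  trials |>
    model_predictions(structure, "prototype", params_prototype) |>
    model_predictions(structure, "exemplar", params_exemplar)
}
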