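#' Hamming distance between two binary feature vectors
#'
#' Physical distance between two stimuli is the number of features on which
#' they differ. Stimuli live in an 8-dimensional binary feature space, so the
#' distance ranges from 0 to 8.
#'
#' @param x,y Binary vectors of length 8 (entries 0 or 1).
#' @return Integer count of differing positions.
#' @examples
#' hamming_distance(rep(1, 8), rep(0, 8)) # prototypes share no features
#' @export
hamming_distance <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != 8L || length(y) != 8L)
    stop("feature vectors must have length 8", call. = FALSE)
  if (!all(x %in% c(0, 1)) || !all(y %in% c(0, 1)))
    stop("feature vectors must be binary (0/1)", call. = FALSE)
  as.integer(sum(x != y))
}

#' @rdname hamming_distance
#' @details `feature_names()` returns the display names of the eight binary
#'   stimulus dimensions (cartoon-animal features). These are metadata only:
#'   all computation happens in the canonical 0/1 coding.
#' @export
feature_names <- function() {
  c("neck", "tail", "foot", "snout", "head", "color", "body", "design")
}

# Canonical training-set pattern: category A rows; category B rows are the
# bit-complements. Each row is Hamming distance 2 from its own prototype and
# 6 from the other; A rows are pairwise distance 4.
training_pattern_A <- function() {
  matrix(c(1, 1, 1, 1, 1, 1, 0, 0,
           0, 1, 1, 1, 0, 1, 1, 1,
           1, 0, 1, 0, 1, 1, 1, 1,
           1, 1, 0, 1, 1, 0, 1, 1),
         nrow = 4, byrow = TRUE)
}

#' Default candidate prototypes
#'
#' The category-A prototype is drawn at random from a small set of candidate
#' stimuli; every other stimulus is then re-coded in reference to that
#' prototype so that internally the A prototype is always the all-1 vector
#' and the B prototype (sharing no features with it) the all-0 vector. The
#' default candidates are four mutually distant vectors (pairwise Hamming
#' distance 4); because of the re-coding the choice has no effect on any
#' analysis.
#'
#' @return A 4 x 8 binary matrix, one candidate per row.
#' @export
default_prototype_candidates <- function() {
  matrix(c(1, 1, 1, 1, 1, 1, 1, 1,
           0, 0, 0, 0, 1, 1, 1, 1,
           0, 0, 1, 1, 0, 0, 1, 1,
           0, 1, 0, 1, 0, 1, 0, 1),
         nrow = 4, byrow = TRUE)
}

stim_id_of <- function(features) {
  if (is.matrix(features)) apply(features, 1, paste, collapse = "")
  else paste(features, collapse = "")
}

feature_cols <- function() paste0("f", 1:8)

feature_matrix <- function(df) {
  m <- as.matrix(df[feature_cols()])
  storage.mode(m) <- "double"
  m
}

stimulus_tibble <- function(features, item_type, phase = NA_character_,
                            repetition = 1L) {
  m <- if (is.matrix(features)) features else matrix(features, nrow = 1)
  d <- as.integer(rowSums(m == 0)) # Hamming distance to the all-1 A prototype
  out <- tibble::as_tibble(as.data.frame(m))
  names(out) <- feature_cols()
  dplyr::mutate(out,
    stim_id = stim_id_of(m),
    dist_to_A = d,
    label = dplyr::case_when(d < 4L ~ "A", d > 4L ~ "B", TRUE ~ "equidistant"),
    item_type = item_type, phase = phase,
    repetition = as.integer(repetition),
    .before = 1
  )
}

#' Build the category structure
#'
#' Constructs the two prototypes and the eight training stimuli (four per
#' category, each two features from its own prototype and six from the
#' other). A raw category-A prototype is selected from `candidates` under
#' `seed`; all stimuli are then re-coded so that the A prototype is the all-1
#' vector. The raw prototype is kept as display metadata.
#'
#' @param seed Integer seed for the prototype selection.
#' @param candidates Matrix of candidate raw prototypes (rows), default
#'   [default_prototype_candidates()].
#' @param prototype Optional explicit raw prototype (overrides selection).
#' @return An object of class `category_structure`: a list with `proto_A`,
#'   `proto_B` (canonical feature vectors), `training` (a tibble of 8
#'   stimuli), and `raw_proto_A`.
#' @examples
#' s <- build_structure(seed = 1)
#' s$training
#' @export
build_structure <- function(seed = 1L, candidates = default_prototype_candidates(),
                            prototype = NULL) {
  if (is.null(prototype)) {
    stopifnot(is.matrix(candidates), ncol(candidates) == 8)
    row <- with_seed(seed, sample.int(nrow(candidates), 1L))
    prototype <- candidates[row, ]
  }
  if (length(prototype) != 8L || !all(prototype %in% c(0, 1)))
    stop("prototype must be a binary vector of length 8", call. = FALSE)
  patt <- training_pattern_A()
  training <- dplyr::bind_rows(
    stimulus_tibble(patt, item_type = "training"),
    stimulus_tibble(1 - patt, item_type = "training")
  )
  training$category <- rep(c("A", "B"), each = 4L)
  structure(
    list(proto_A = rep(1, 8), proto_B = rep(0, 8),
         training = training, raw_proto_A = as.numeric(prototype),
         feature_names = feature_names()),
    class = "category_structure"
  )
}

#' @export
print.category_structure <- function(x, ...) {
  cat("Category structure: 8 binary features, prototypes at distance 8\n")
  cat("Raw A prototype (display frame):",
      paste(x$raw_proto_A, collapse = ""), "\n")
  cat("Training stimuli (canonical frame):\n")
  print(x$training[, c("stim_id", "category", "dist_to_A")])
  invisible(x)
}

#' Re-code raw features into the canonical prototype frame
#'
#' Maps raw binary features to the canonical frame in which the category-A
#' prototype is all 1s: a feature is coded 1 when it matches the raw A
#' prototype. Applying this to any candidate prototype frame reproduces the
#' identical canonical training matrix.
#'
#' @param features Binary vector or matrix (rows = stimuli) in the raw frame.
#' @param raw_proto_A The raw category-A prototype.
#' @return Features in the canonical frame, same shape as the input.
#' @export
recode_features <- function(features, raw_proto_A) {
  m <- if (is.matrix(features)) features else matrix(features, nrow = 1)
  out <- 1 - abs(sweep(m, 2, as.numeric(raw_proto_A)))
  if (is.matrix(features)) out else drop(out)
}

#' Assign a stimulus to a category
#'
#' A stimulus belongs to category A when it shares more features with the A
#' prototype than the B prototype, and vice versa; stimuli equidistant from
#' both prototypes belong to neither.
#'
#' @param features Binary vector of length 8, or a matrix of stimuli (rows).
#' @param structure A `category_structure` (canonical frame; optional since
#'   the canonical prototypes are fixed).
#' @return Character label(s): `"A"`, `"B"` or `"equidistant"`.
#' @export
assign_category <- function(features, structure = NULL) {
  m <- if (is.matrix(features)) features else matrix(features, nrow = 1)
  if (ncol(m) != 8L || !all(m %in% c(0, 1)))
    stop("features must be binary with 8 columns", call. = FALSE)
  d <- rowSums(m == 0)
  ifelse(d < 4, "A", ifelse(d > 4, "B", "equidistant"))
}

#' Enumerate the full stimulus space
#'
#' All 256 binary feature vectors with distance to the A prototype and
#' category label; useful for exhaustive checks and for sampling test items.
#'
#' @return A tibble with one row per feature vector.
#' @export
all_stimuli <- function() {
  m <- as.matrix(expand.grid(rep(list(c(0, 1)), 8)))[, 8:1]
  colnames(m) <- feature_cols()
  stimulus_tibble(m, item_type = "new")
}

# all feature vectors at Hamming distance d from the all-1 A prototype
vectors_at_distance <- function(d) {
  if (d == 0) return(matrix(1, 1, 8))
  combs <- utils::combn(8, d)
  t(apply(combs, 2, function(idx) { v <- rep(1, 8); v[idx] <- 0; v }))
}

sample_new_items <- function(n_per_distance, used, distances = c(1:3, 5:7)) {
  picked <- lapply(distances, function(d) {
    pool <- vectors_at_distance(d)
    ids <- stim_id_of(pool)
    avail <- which(!(ids %in% used))
    if (length(avail) < n_per_distance)
      stop(sprintf("stimulus pool exhausted at distance %d (%d available, %d needed)",
                   d, length(avail), n_per_distance), call. = FALSE)
    pool[sample(avail, n_per_distance), , drop = FALSE]
  })
  do.call(rbind, picked)
}

#' Build an interim generalization test set
#'
#' Each interim test contains 22 unique stimuli presented once: the eight
#' training stimuli, the two prototypes, and two new stimuli at each distance
#' 1, 2, 3, 5, 6, 7 from the category-A prototype. New items are sampled
#' without replacement from the stimuli not in `used` (which should carry the
#' training items and new items of earlier cycles), so successive cycles use
#' disjoint new items; with two per cycle, four cycles exhaust the eight
#' distance-1 (and distance-7) items exactly.
#'
#' @param structure A `category_structure`.
#' @param cycle Interim test number, 1-4.
#' @param used Character vector of stimulus ids no longer available as new
#'   items.
#' @param seed Integer seed for item sampling.
#' @return A tibble of 22 stimuli (`phase = "interim_<cycle>"`, repetition 1).
#'   The sampled new-item ids are in `attr(, "new_ids")`.
#' @export
build_interim_set <- function(structure, cycle, used = character(), seed = 1L) {
  stopifnot(cycle %in% 1:4)
  used <- union(used, structure$training$stim_id)
  new_m <- with_seed(derive_seed(seed, 100L + cycle),
                     sample_new_items(2L, used))
  phase_label <- paste0("interim_", cycle)
  training <- structure$training[names(structure$training) != "category"]
  training$phase <- phase_label
  out <- dplyr::bind_rows(
    stimulus_tibble(rbind(rep(1, 8), rep(0, 8)), "prototype", phase_label),
    training,
    stimulus_tibble(new_m, "new", phase_label)
  )
  attr(out, "new_ids") <- stim_id_of(new_m)
  out
}

#' Build the final generalization test set
#'
#' The final test contains 58 unique stimuli: 48 new items (eight at each
#' distance 1, 2, 3, 5, 6, 7), presented once, plus the eight training
#' stimuli and the two prototypes, each presented twice, for 68 trials in
#' total. New items at distances 2, 3, 5, 6 are disjoint from the training
#' set and from all interim new items; the eight distance-1 (and distance-7)
#' items are necessarily reused from the interim tests.
#'
#' @inheritParams build_interim_set
#' @param used Character vector of ids used as new items in interim tests.
#' @return A tibble of 58 stimuli with a `repetition` column (2 for training
#'   items and prototypes).
#' @export
build_final_set <- function(structure, used = character(), seed = 1L) {
  used <- union(used, structure$training$stim_id)
  # distance-1/7 items are exempt from the used-item bookkeeping: there are
  # only eight of each, all consumed by the interim tests
  used_inner <- setdiff(used, stim_id_of(rbind(vectors_at_distance(1),
                                               vectors_at_distance(7))))
  used_inner <- union(used_inner, structure$training$stim_id)
  new_m <- with_seed(derive_seed(seed, 200L),
                     sample_new_items(8L, used_inner))
  training <- structure$training[names(structure$training) != "category"]
  training$phase <- "final"
  training$repetition <- 2L
  dplyr::bind_rows(
    stimulus_tibble(rbind(rep(1, 8), rep(0, 8)), "prototype", "final", 2L),
    training,
    stimulus_tibble(new_m, "new", "final")
  )
}

#' Build all five test sets with shared bookkeeping
#'
#' Convenience wrapper running [build_interim_set()] for cycles 1-4 and
#' [build_final_set()], threading the used-item set through so new items are
#' disjoint where the design requires it.
#'
#' @inheritParams build_interim_set
#' @return Named list of tibbles: `interim_1` ... `interim_4`, `final`.
#' @export
build_test_sets <- function(structure, seed = 1L) {
  used <- character()
  sets <- list()
  for (k in 1:4) {
    ts <- build_interim_set(structure, k, used = used, seed = seed)
    used <- union(used, attr(ts, "new_ids"))
    sets[[paste0("interim_", k)]] <- ts
  }
  sets$final <- build_final_set(structure, used = used, seed = seed)
  sets
}

#' Replicate a test set to a target trial count
#'
#' Reassigns repetition counts so the expanded test set has exactly
#' `n_trials` trials, spreading repetitions as evenly as possible over the
#' unique stimuli (the remainder goes to a random subset under `seed`).
#' Used to build longer sessions, e.g. for parameter-recovery simulations.
#'
#' @param test_set A test-set tibble.
#' @param n_trials Total number of trials wanted (>= number of stimuli).
#' @param seed Integer seed for the remainder assignment.
#' @return The test set with adjusted `repetition` counts.
#' @export
replicate_test_set <- function(test_set, n_trials, seed = 1L) {
  n_stim <- nrow(test_set)
  stopifnot(n_trials >= n_stim)
  reps <- rep(n_trials %/% n_stim, n_stim)
  extra <- n_trials %% n_stim
  if (extra > 0) {
    idx <- with_seed(derive_seed(seed, 600L), sample.int(n_stim, extra))
    reps[idx] <- reps[idx] + 1L
  }
  dplyr::mutate(test_set, repetition = as.integer(reps))
}

#' Expand a test set into an ordered trial table
#'
#' Expands repetitions, shuffles trial order uniformly at random under
#' `seed`, splits trials evenly across `n_runs`, and assigns onsets on a
#' fixed event grid (default: 5 s stimulus + 7 s inter-trial interval).
#'
#' @param test_set A tibble from [build_interim_set()] or [build_final_set()].
#' @param seed Integer seed for the trial-order shuffle.
#' @param n_runs Number of runs the phase is split across.
#' @param stim_duration,iti Event timing in seconds.
#' @return A trial tibble with `run`, `trial`, `onset`, `duration` columns
#'   and a `response` column initialised to `NA`.
#' @export
test_trials <- function(test_set, seed = 1L, n_runs = 1L, stim_duration = 5,
                        iti = 7) {
  expanded <- test_set[rep(seq_len(nrow(test_set)), test_set$repetition), ]
  ord <- with_seed(seed, sample.int(nrow(expanded)))
  expanded <- expanded[ord, ]
  n <- nrow(expanded)
  per_run <- ceiling(n / n_runs)
  dplyr::mutate(expanded,
    run = rep(seq_len(n_runs), each = per_run, length.out = n),
    trial = unlist(lapply(rle(.data$run)$lengths, seq_len))[seq_len(n)],
    onset = (.data$trial - 1) * (stim_duration + iti),
    duration = stim_duration,
    response = NA_character_
  )
}
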