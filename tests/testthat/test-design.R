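test_that("hamming_distance counts differing features and validates input", {
  expect_identical(hamming_distance(fx_structure$proto_A, fx_structure$proto_B), 8L)
  expect_identical(hamming_distance(rep(1, 8), rep(1, 8)), 0L)
  a1 <- c(1, 1, 1, 1, 1, 1, 0, 0)
  expect_identical(hamming_distance(fx_structure$proto_A, a1), 2L)
  expect_identical(hamming_distance(a1, fx_structure$proto_A), 2L) # symmetric
  expect_error(hamming_distance(rep(1, 7), rep(1, 8)), "length 8")
  expect_error(hamming_distance(rep(2, 8), rep(1, 8)), "binary")
})

test_that("training structure matches the canonical pattern", {
  tr <- fx_structure$training
  expect_identical(nrow(tr), 8L)
  expect_identical(sum(tr$category == "A"), 4L)
  # every training item: distance 2 from own prototype, 6 from the other
  feats <- as.matrix(tr[, paste0("f", 1:8)])
  d_a <- apply(feats, 1, hamming_distance, y = fx_structure$proto_A)
  expect_identical(d_a, ifelse(tr$category == "A", 2L, 6L))
  # A1 vs A2 are four features apart (pairwise-distant training pairs)
  expect_identical(hamming_distance(feats[1, ], feats[2, ]), 4L)
  # all within-category pairs distance 4
  for (i in 1:3) for (j in (i + 1):4)
    expect_identical(hamming_distance(feats[i, ], feats[j, ]), 4L)
  # B items are the complements of A items
  expect_identical(unname(feats[5:8, ]), unname(1 - feats[1:4, ]))
})

test_that("re-coding any candidate prototype reproduces the same canonical frame", {
  cands <- default_prototype_candidates()
  mats <- lapply(seq_len(nrow(cands)), function(i) {
    s <- build_structure(prototype = cands[i, ])
    as.matrix(s$training[, paste0("f", 1:8)])
  })
  for (i in 2:4) expect_identical(mats[[i]], mats[[1]])
  # and re-coding maps the raw prototype itself onto the all-1 vector
  for (i in 1:4)
    expect_identical(recode_features(cands[i, ], cands[i, ]), rep(1, 8))
})

test_that("category assignment follows prototype distance over all 256 stimuli", {
  all_s <- all_stimuli()
  expect_identical(nrow(all_s), 256L)
  feats <- as.matrix(all_s[, paste0("f", 1:8)])
  labels <- assign_category(feats)
  expect_identical(labels, all_s$label)
  d <- all_s$dist_to_A
  expect_true(all(labels[d < 4] == "A"))
  expect_true(all(labels[d > 4] == "B"))
  expect_true(all(labels[d == 4] == "equidistant"))
  expect_identical(sum(d == 4), 70L)       # C(8,4) equidistant vectors
  expect_identical(sum(d == 1), 8L)        # 8 one-feature neighbours
  expect_identical(assign_category(rep(1, 8)), "A")
})

test_that("interim sets have 22 unique stimuli, 2 new per distance, no equidistant items", {
  used <- character()
  for (k in 1:4) {
    ts <- build_interim_set(fx_structure, k, used = used, seed = 2)
    used <- union(used, attr(ts, "new_ids"))
    expect_identical(nrow(ts), 22L)
    expect_identical(length(unique(ts$stim_id)), 22L)
    expect_true(all(ts$repetition == 1L))
    expect_false(any(ts$dist_to_A == 4L))
    new_tab <- table(ts$dist_to_A[ts$item_type == "new"])
    expect_identical(as.integer(new_tab), rep(2L, 6))
    expect_identical(names(new_tab), as.character(c(1:3, 5:7)))
  }
})

test_that("interim new items are disjoint across cycles and deterministic under a seed", {
  sets_a <- build_test_sets(fx_structure, seed = 9)
  sets_b <- build_test_sets(fx_structure, seed = 9)
  expect_identical(sets_a, sets_b)
  new_ids <- lapply(sets_a[1:4], function(ts) ts$stim_id[ts$item_type == "new"])
  for (i in 1:3) for (j in (i + 1):4)
    expect_length(intersect(new_ids[[i]], new_ids[[j]]), 0)
  # four cycles x two new items exhaust the eight distance-1 items exactly
  d1_ids <- unname(unlist(lapply(sets_a[1:4], function(ts)
    ts$stim_id[ts$item_type == "new" & ts$dist_to_A == 1])))
  expect_identical(sort(unique(d1_ids)), sort(d1_ids))
  expect_length(d1_ids, 8)
})

test_that("final set: 58 unique stimuli, 48 new, 68 trials, correct reuse rules", {
  sets <- build_test_sets(fx_structure, seed = 2)
  fin <- sets$final
  expect_identical(nrow(fin), 58L)
  expect_identical(length(unique(fin$stim_id)), 58L)
  expect_identical(sum(fin$item_type == "new"), 48L)
  expect_identical(as.integer(table(fin$dist_to_A[fin$item_type == "new"])),
                   rep(8L, 6))
  expect_true(all(fin$repetition[fin$item_type %in% c("training", "prototype")] == 2L))
  expect_identical(sum(fin$repetition), 68L)
  # new items at distances 2,3,5,6 are disjoint from interim new items
  interim_new <- unlist(lapply(sets[1:4], function(ts)
    ts$stim_id[ts$item_type == "new"]))
  inner <- fin$stim_id[fin$item_type == "new" & !fin$dist_to_A %in% c(1, 7)]
  expect_length(intersect(inner, interim_new), 0)
  # distance-1/7 final items are exactly the 8+8 reused from interim tests
  outer <- fin$stim_id[fin$item_type == "new" & fin$dist_to_A %in% c(1, 7)]
  expect_length(outer, 16)
  expect_true(all(outer %in% interim_new))
})

test_that("exhausted pools raise a design error naming the distance", {
  all_d2 <- apply(protex:::vectors_at_distance(2), 1, paste, collapse = "")
  expect_error(build_interim_set(fx_structure, 1, used = all_d2, seed = 1),
               "distance 2")
})

test_that("test_trials expands repetitions, shuffles deterministically, assigns onsets", {
  tr1 <- test_trials(fx_sets$final, seed = 4, n_runs = 4)
  tr2 <- test_trials(fx_sets$final, seed = 4, n_runs = 4)
  expect_identical(tr1, tr2)
  expect_identical(nrow(tr1), 68L)
  expect_identical(as.integer(table(tr1$run)), rep(17L, 4))
  by_run <- split(tr1$onset, tr1$run)
  for (o in by_run) expect_identical(o, (seq_along(o) - 1) * 12)
  expect_false(identical(tr1$stim_id,
                         test_trials(fx_sets$final, seed = 5, n_runs = 4)$stim_id))
})

test_that("replicate_test_set hits the requested trial count", {
  rs <- replicate_test_set(fx_sets$final, 200, seed = 3)
  expect_identical(sum(rs$repetition), 200L)
  expect_identical(rs$stim_id, fx_sets$final$stim_id)
})

test_that("trial tables survive a TSV round trip", {
  tr <- head(test_trials(fx_sets$interim_1, seed = 1), 10)
  tr$response <- c("A", "B", NA, rep("A", 7))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trials(tr, path)
  back <- read_trials(path)
  expect_identical(back$stim_id, tr$stim_id)
  expect_identical(back$response, tr$response)
  expect_equal(back$onset, tr$onset)
})
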