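test_that("generated hierarchies honor their spec and are seed-deterministic", {
  spec <- hierarchy_spec(n = 11, level_count = 4, seed = 101)
  t1 <- generate_hierarchy(spec)
  t2 <- generate_hierarchy(spec)
  expect_identical(t1, t2)
  expect_identical(sort(unique(unname(t1$level))), 1:4)
  expect_length(t1$level, 11)
  expect_length(t1$panel, 10)
  t3 <- generate_hierarchy(hierarchy_spec(n = 11, level_count = 4, seed = 102))
  expect_false(identical(t1$relation, t3$relation))
  expect_error(hierarchy_spec(n = 3, level_count = 5), "1..n")
  expect_error(hierarchy_spec(agreement_prob = 1.2), "\\[0, 1\\]")
})

test_that("planted levels equal the condensation longest-path-to-sink strata", {
  for (seed in 1:40) {
    spec <- hierarchy_spec(n = sample(4:10, 1), level_count = sample(2:4, 1),
                           expert_count = 1, seed = seed)
    truth <- generate_hierarchy(spec)
    expect_identical(unname(truth$level), oracle_strata(truth$relation),
                     info = sprintf("seed %d", seed))
  }
})

test_that("SSIM encoding is inverted by reachability decoding", {
  for (seed in c(7, 19, 23)) {
    truth <- generate_hierarchy(hierarchy_spec(n = 8, level_count = 3,
                                               mutual_pair_prob = 0.5,
                                               expert_count = 1, seed = seed))
    decoded <- rm_binary(ssim_to_initial_rm(truth$ssim))
    expected <- truth$relation
    diag(expected) <- 1L
    expect_identical(unname(decoded), unname(expected))
  }
  # degenerate cases
  empty <- list(relation = matrix(0L, 3, 3, dimnames = list(1:3, 1:3)))
  expect_true(all(unclass(encode_ssim(empty))[upper.tri(diag(3))] == "O"))
  both <- list(relation = matrix(1L, 2, 2, dimnames = list(1:2, 1:2)))
  expect_identical(unclass(encode_ssim(both))[1, 2], "X")
})

test_that("perfectly agreeing panels reproduce the true SSIM exactly", {
  truth <- generate_hierarchy(hierarchy_spec(n = 9, level_count = 3,
                                             agreement_prob = 1, seed = 77))
  expect_true(all(vapply(truth$panel, function(e) {
    identical(unclass(e$ssim), unclass(truth$ssim))
  }, TRUE)))
  agg <- aggregate_judgments(truth$panel)
  expect_identical(unclass(agg$ssim), unclass(truth$ssim))
})

test_that("a one-expert panel aggregates to that expert's judgments", {
  truth <- generate_hierarchy(hierarchy_spec(n = 6, level_count = 2,
                                             expert_count = 1,
                                             agreement_prob = 0.5, seed = 5))
  agg <- aggregate_judgments(truth$panel)
  expect_identical(unclass(agg$ssim), unclass(truth$panel[[1]]$ssim))
})

test_that("majority aggregation beats a single noisy expert per pair", {
  # p = 0.9, E = 10: plurality recovery estimated over 200 simulated panels
  truth <- generate_hierarchy(hierarchy_spec(n = 6, level_count = 3, seed = 11))
  hits <- 0L; total <- 0L
  for (r in 1:200) {
    panel <- simulate_expert_panel(truth, E = 10, p = 0.9, seed = 1000 + r)
    agg <- aggregate_judgments(panel)
    up <- upper.tri(truth$ssim)
    hits <- hits + sum(unclass(agg$ssim)[up] == unclass(truth$ssim)[up])
    total <- total + sum(up)
  }
  expect_gt(hits / total, 0.9)   # single-expert accuracy is p = 0.9
})

test_that("noise-free runs recover the planted structure; noise degrades recovery", {
  clean <- recovery_experiment(hierarchy_spec(n = 7, level_count = 3,
                                              agreement_prob = 1, seed = 500),
                               reps = 30)
  expect_identical(clean$level_recovery_fraction, 1)
  expect_identical(clean$ssim_recovery_fraction, 1)
  noisy <- recovery_experiment(hierarchy_spec(n = 7, level_count = 3,
                                              expert_count = 3,
                                              agreement_prob = 0.5, seed = 500),
                               reps = 30)
  expect_lt(noisy$ssim_recovery_fraction, clean$ssim_recovery_fraction)
})

test_that("pipeline partitions match the brute-force oracle on small systems", {
  for (seed in 1:25) {
    truth <- generate_hierarchy(hierarchy_spec(n = sample(3:7, 1),
                                               level_count = sample(2:3, 1),
                                               agreement_prob = 1,
                                               expert_count = 3, seed = seed))
    agg <- aggregate_judgments(truth$panel)
    part <- partition_levels(transitive_closure(ssim_to_initial_rm(agg$ssim), "full"))
    expect_identical(unname(part$assignment), oracle_strata(truth$relation))
  }
})
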