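test_that("unanimous panels aggregate to their common judgment set", {
  s <- mk_ssim(3, c("V", "O", "X"))
  for (E in c(1L, 3L, 10L)) {
    agg <- aggregate_judgments(rep(list(s), E))
    expect_identical(unclass(agg$ssim), unclass(s))
    expect_true(all(agg$tallies$majority_kind == "absolute"))
    expect_false(any(agg$tallies$tie))
  }
})

test_that("plurality wins and is annotated as such", {
  # counts V:4 A:3 X:2 O:1 over ten experts on a single pair
  panel <- mk_pair_panel(c(rep("V", 4), rep("A", 3), rep("X", 2), "O"))
  agg <- aggregate_judgments(panel)
  expect_identical(agg$tallies$winner, "V")
  expect_identical(agg$tallies$majority_kind, "plurality")
  expect_identical(unname(unlist(agg$tallies[, c("V", "A", "X", "O")])),
                   c(4, 3, 2, 1))
})

test_that("aggregation ties follow the priority order and are always flagged", {
  panel <- mk_pair_panel(c(rep("V", 5), rep("A", 5)))
  agg <- aggregate_judgments(panel, tie_policy = "priority_order")
  expect_identical(agg$tallies$winner, "V")   # X > V > A > O, X not among tied
  expect_true(agg$tallies$tie)
  expect_identical(agg$tallies$majority_kind, "tie")
  expect_error(aggregate_judgments(panel, tie_policy = "error"),
               "tie on pair \\(1,2\\)")
  # a custom priority can prefer A
  agg2 <- aggregate_judgments(panel, priority = c("O", "A", "V", "X"))
  expect_identical(agg2$tallies$winner, "A")
})

test_that("incomplete judgment sets are rejected with the missing pair named", {
  long <- data.frame(expert_id = "E1",
                     row_code = c(1, 1), col_code = c(2, 3),
                     symbol = c("V", "O"))     # pair (2,3) missing
  expect_error(aggregate_judgments(long), "missing pair.*2,3")
  expect_error(
    expert_judgments(data.frame(row_code = 2, col_code = 1, symbol = "V")),
    "upper triangle")
})

test_that("tally counts always sum to E and the winner count is maximal", {
  set.seed(31)
  for (rep in 1:15) {
    E <- sample(1:9, 1)
    n <- sample(3:5, 1)
    panel <- lapply(seq_len(E), function(e) {
      mk_ssim(n, sample(c("V", "A", "X", "O"), n * (n - 1) / 2, replace = TRUE))
    })
    agg <- aggregate_judgments(panel)
    counts <- as.matrix(agg$tallies[, c("V", "A", "X", "O")])
    expect_true(all(rowSums(counts) == E))
    # brute-force recount from the raw panel
    for (k in seq_len(nrow(agg$tallies))) {
      i <- agg$tallies$row_code[k]; j <- agg$tallies$col_code[k]
      raw <- vapply(panel, function(s) unclass(s)[i, j], "")
      expect_identical(unname(counts[k, ]),
                       as.numeric(table(factor(raw, c("V", "A", "X", "O")))))
      expect_identical(max(counts[k, ]),
                       counts[k, agg$tallies$winner[k]][[1]])
    }
  }
})

test_that("long-form and list-form panels agree", {
  set.seed(5)
  panel <- lapply(1:4, function(e) {
    mk_ssim(4, sample(c("V", "A", "X", "O"), 6, replace = TRUE))
  })
  long <- do.call(rbind, lapply(seq_along(panel), function(e) {
    up <- which(upper.tri(panel[[e]]), arr.ind = TRUE)
    data.frame(expert_id = sprintf("E%d", e), row_code = up[, 1],
               col_code = up[, 2], symbol = unclass(panel[[e]])[up])
  }))
  expect_identical(unclass(aggregate_judgments(long)$ssim),
                   unclass(aggregate_judgments(panel)$ssim))
})
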