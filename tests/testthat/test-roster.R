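test_that("the packaged 11-determinant roster validates cleanly", {
  rep <- validate_roster(fx$roster)
  expect_true(rep$valid)
  expect_identical(rep$n, 11L)
})

test_that("roster validation reports gaps, duplicates, emptiness", {
  gap <- validate_roster(data.frame(code = c(1, 3), label = c("a", "b")))
  expect_false(gap$valid)
  expect_match(paste(gap$problems, collapse = " "), "not contiguous")

  dup <- validate_roster(data.frame(code = c(1, 1, 2), label = c("a", "b", "c")))
  expect_false(dup$valid)
  expect_match(paste(dup$problems, collapse = " "), "duplicate")

  nolabel <- validate_roster(data.frame(code = 1:2, label = c("a", " ")))
  expect_false(nolabel$valid)

  empty <- validate_roster(data.frame(code = integer(), label = character()))
  expect_false(empty$valid)
  expect_identical(empty$n, 0L)

  expect_error(determinant_roster(c("a", "b"), codes = c(1, 1)), "duplicate")
})

test_that("ratification reproduces the published voting sheet", {
  r <- ratify_determinants(fx$votes, tie_policy = "include")
  expect_identical(r$included_codes, 1:11)
  tal <- r$tallies
  expect_identical(tal$yes, c(8L, 9L, 9L, 5L, 10L, 6L, 9L, 9L, 9L, 9L, 10L))
  expect_identical(tal$yes + tal$no, rep(10L, 11))
  # unanimous factor 5: 10 yes, no tie; factor 4 deadlocked 5-5 and flagged
  expect_identical(tal$yes[tal$code == 5], 10L)
  expect_identical(r$tie_flags, 4L)
})

test_that("tie policy controls the disposition of deadlocked factors", {
  v <- data.frame(factor_code = 1:2,
                  e1 = c(1, 1), e2 = c(0, 1), e3 = c(1, 0), e4 = c(0, 0))
  inc <- ratify_determinants(v, "include")
  expect_identical(inc$included_codes, 1:2)
  expect_identical(inc$tie_flags, 1:2)
  exc <- ratify_determinants(v, "exclude")
  expect_identical(exc$included_codes, integer(0))
  expect_error(ratify_determinants(v, "error"), "tie vote.*1,2")
})

test_that("unanimous rejection excludes and empty panels error", {
  v <- data.frame(factor_code = 1:2, e1 = c(0, 1), e2 = c(0, 1))
  expect_identical(ratify_determinants(v)$excluded_codes, 1L)
  expect_error(ratify_determinants(data.frame(factor_code = 1:2)), "empty expert panel")
  expect_error(ratify_determinants(data.frame(factor_code = 1, e1 = "maybe")),
               "unparseable")
})

test_that("ratification is monotone in yes votes", {
  set.seed(7)
  for (rep in 1:20) {
    E <- sample(3:8, 1)
    v <- as.data.frame(matrix(rbinom(5 * E, 1, 0.5), 5, E))
    names(v) <- paste0("e", seq_len(E))
    v <- cbind(factor_code = 1:5, v)
    before <- ratify_determinants(v, "include")$included_codes
    # flip one random no to yes
    f <- sample(1:5, 1)
    col <- which(v[f, -1] == 0)
    if (!length(col)) next
    v[f, 1 + sample(rep(col, 2), 1)] <- 1
    after <- ratify_determinants(v, "include")$included_codes
    expect_true(all(before %in% after))
  }
})

test_that("vote cells accept yes/no and Y/N spellings", {
  v <- data.frame(factor_code = 1, a = "Yes", b = "N", c = "y", d = "1")
  expect_identical(ratify_determinants(v)$tallies$yes, 3L)
})
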