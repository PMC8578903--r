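test_that("the published quadrant labels and effectiveness column reproduce", {
  mc <- classify_factors(compute_powers(fx$final_rm))
  expect_identical(mc$quadrant[mc$code == 1], "independent")
  expect_identical(mc$quadrant[mc$code == 8], "dependent")
  expect_identical(mc$quadrant[!mc$code %in% c(1, 8)], rep("linkage", 9))
  expect_false(any(mc$quadrant == "autonomous"))
  expect_identical(tolower(fx$published_summary$cluster), mc$quadrant)
  expect_identical(mc$net_influence, fx$published_summary$effectiveness)
})

test_that("net influence is the driving-dependence difference and sums to zero", {
  expect_identical(net_influence(4, 11), -7L)
  expect_identical(net_influence(10, 10), 0L)
  expect_identical(net_influence(data.frame(driving = 3:5, dependence = 3:5)),
                   rep(0L, 3))
  set.seed(3)
  for (rep in 1:10) {
    pw <- compute_powers(rand_rm(sample(2:9, 1)))
    expect_identical(sum(net_influence(pw)), 0L)
  }
})

test_that("the strictly-greater boundary rule decides edge cases", {
  pw <- data.frame(code = 1:10, driving = c(5, rep(6, 9)),
                   dependence = c(5, rep(6, 9)))
  mc <- classify_factors(pw, micmac_config(10, boundary = 5))
  expect_identical(mc$quadrant[1], "autonomous")    # 5 is not > 5
  expect_identical(mc$quadrant[2], "linkage")
  expect_error(micmac_config(10, boundary = 0), "strictly between")
  expect_error(micmac_config(10, boundary = 10), "strictly between")
  expect_error(classify_factors(pw, micmac_config(4)), "n = 4")
})

test_that("quadrant labels are equivariant under factor relabeling", {
  set.seed(13)
  m <- rand_rm(6, 0.4)
  mc <- classify_factors(compute_powers(transitive_closure(m, "full")))
  perm <- sample(6)
  b <- rm_binary(m)[perm, perm]
  dimnames(b) <- list(1:6, 1:6)
  mc2 <- classify_factors(compute_powers(transitive_closure(
    reachability_matrix(b), "full")))
  expect_identical(mc2$quadrant, mc$quadrant[perm])
})

test_that("increasing driving power never demotes independent to dependent", {
  cfg <- micmac_config(11)
  for (drv in 1:10) {
    q1 <- classify_factors(data.frame(code = c(1, 2:11), driving = c(drv, rep(11, 10)),
                                      dependence = rep(2, 11)), cfg)$quadrant[1]
    q2 <- classify_factors(data.frame(code = c(1, 2:11), driving = c(drv + 1, rep(11, 10)),
                                      dependence = rep(2, 11)), cfg)$quadrant[1]
    if (q1 == "independent") expect_identical(q2, "independent")
  }
})

test_that("the summary flags deepest-level independent factors as key", {
  p <- partition_levels(fx$final_rm)
  mc <- classify_factors(compute_powers(fx$final_rm))
  s <- ism_summary(p, mc, roster = fx$roster,
                   ratification = ratify_determinants(fx$votes))
  expect_identical(s$code[s$key_factor], 1L)
  expect_identical(s$level, fx$published_summary$level)
  expect_identical(s$label, fx$published_summary$label)
  expect_identical(nrow(s), 11L)
  expect_identical(sort(s$code), 1:11)   # every factor exactly once
})

test_that("a single-factor system is trivially key when independent", {
  m <- reachability_matrix(matrix(1L, 2, 2))
  p <- partition_levels(m)
  mc <- classify_factors(data.frame(code = 1:2, driving = c(2, 1),
                                    dependence = c(1, 2)),
                         micmac_config(2, boundary = 1.5))
  s <- ism_summary(p, mc)
  expect_identical(s$code[s$key_factor], 1L)
  expect_error(ism_summary(partition_levels(reachability_matrix(matrix(1L, 3, 3))), mc),
               "different factors")
})
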