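test_that("SSIM decoding reproduces the published initial reachability matrix", {
  rm0 <- ssim_to_initial_rm(fx$ssim)
  expect_identical(rm_binary(rm0), rm_binary(fx$initial_rm))   # all 121 cells
  # symbol semantics, spot-checked per rule
  b <- rm_binary(rm0)
  expect_identical(unname(b[1, 2]), 1L); expect_identical(unname(b[2, 1]), 0L)  # V
  expect_identical(unname(b[2, 4]), 0L); expect_identical(unname(b[4, 2]), 1L)  # A
  expect_identical(unname(b[7, 11]), 1L); expect_identical(unname(b[11, 7]), 1L) # X
  expect_true(all(diag(b) == 1L))
})

test_that("an all-O SSIM decodes to the identity relation", {
  s <- mk_ssim(4, rep("O", 6))
  expect_identical(unname(rm_binary(ssim_to_initial_rm(s))), diag(1L, 4))
})

test_that("full closure adds forced transitive edges with provenance", {
  b <- diag(1L, 3); b[1, 2] <- b[2, 3] <- 1L
  cl <- transitive_closure(reachability_matrix(b), "full")
  expect_identical(unname(rm_binary(cl)[1, 3]), 1L)
  expect_identical(unname(attr(cl, "provenance")[1, 3]), "transitive")
  expect_identical(unname(attr(cl, "provenance")[1, 2]), "direct")
})

test_that("one-pass closure of the initial matrix matches the hand-marked row 8", {
  op <- transitive_closure(fx$initial_rm, "one_pass")
  b <- rm_binary(op)
  prov <- attr(op, "provenance")
  expect_identical(unname(b[8, 6]), 1L)
  expect_identical(unname(b[8, 7]), 1L)
  expect_identical(unname(prov[8, 6]), "transitive")
  expect_identical(unname(prov[8, 7]), "transitive")
  expect_identical(sum(b[8, ]), 4L)
})

test_that("full closure equals the boolean-power oracle and exceeds one-pass", {
  full <- transitive_closure(fx$initial_rm, "full")
  op <- transitive_closure(fx$initial_rm, "one_pass")
  expect_identical(unname(rm_binary(full)), unname(oracle_closure(fx$initial_rm)))
  expect_true(all(rm_binary(op) <= rm_binary(full)))
  expect_identical(unname(rm_binary(full)[8, 2]), 1L)   # length-3 path only
  expect_identical(unname(rm_binary(op)[8, 2]), 0L)
})

test_that("closure modes satisfy their algebraic properties on random matrices", {
  set.seed(23)
  for (rep in 1:40) {
    m <- rand_rm(sample(2:8, 1))
    full <- transitive_closure(m, "full")
    op <- transitive_closure(m, "one_pass")
    expect_identical(unname(rm_binary(full)), unname(oracle_closure(m)))
    # idempotence
    expect_identical(rm_binary(transitive_closure(full, "full")), rm_binary(full))
    # M subset one_pass(M) subset full(M)
    expect_true(all(rm_binary(m) <= rm_binary(op)))
    expect_true(all(rm_binary(op) <= rm_binary(full)))
    # as_given is the identity
    expect_identical(rm_binary(transitive_closure(m, "as_given")), rm_binary(m))
    # direct provenance is conserved
    expect_true(all(attr(full, "provenance")[attr(m, "provenance") == "direct"]
                    == "direct"))
  }
})

test_that("powers reproduce the published margins", {
  pw <- compute_powers(fx$final_rm)
  expect_identical(pw$driving, fx$published_summary$driving)
  expect_identical(pw$dependence, fx$published_summary$dependence)
  expect_identical(pw$driving[pw$code == 1], 11L)
  expect_identical(pw$dependence[pw$code == 1], 2L)
  expect_identical(pw$driving[pw$code == 8], 4L)
  expect_identical(pw$dependence[pw$code == 8], 11L)
  expect_identical(sum(pw$driving), 103L)
  expect_identical(sum(pw$dependence), 103L)
})

test_that("driving and dependence totals agree on any matrix", {
  id <- compute_powers(reachability_matrix(diag(1L, 3)))
  expect_true(all(id$driving == 1L) && all(id$dependence == 1L))
  set.seed(2)
  for (rep in 1:20) {
    pw <- compute_powers(rand_rm(sample(2:9, 1)))
    expect_identical(sum(pw$driving), sum(pw$dependence))
  }
})

test_that("malformed reachability inputs are rejected", {
  expect_error(reachability_matrix(matrix(1, 2, 3)), "square")
  expect_error(transitive_closure(fx$initial_rm, "sideways"), "arg")
  s <- unclass(fx$ssim); s[2, 1] <- "V"
  expect_error(ssim(s), "upper triangle")
})
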