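# AHP priority vectors + consistency, entropy weights, weight assembly

test_that("AHP recovers weights from consistent matrices with CR = 0", {
  w <- c(0.2, 0.15, 0.45, 0.2)                 # published level-1 weights
  P <- outer(w, w, `/`)
  res <- ahp_weights(P)
  expect_equal(res$weights, w, tolerance = 1e-8)
  expect_equal(res$cr, 0, tolerance = 1e-8)
  expect_true(res$consistent)

  res3 <- ahp_weights(matrix(1, 3, 3))
  expect_equal(res3$weights, rep(1 / 3, 3), tolerance = 1e-10)
  expect_equal(res3$cr, 0, tolerance = 1e-10)
})

test_that("AHP matches a dense eigensolver oracle on an inconsistent 3x3", {
  P <- matrix(c(1,   2, 4,
                1/2, 1, 3,
                1/4, 1/3, 1), 3, 3, byrow = TRUE)
  res <- ahp_weights(P)
  # independent oracle: full eigen decomposition
  eg <- eigen(P)
  i <- which.max(Re(eg$values))
  v <- Re(eg$vectors[, i]); v <- v / sum(v)
  lam <- Re(eg$values[i])
  expect_equal(res$weights, v, tolerance = 1e-8)
  expect_equal(res$lambda_max, lam, tolerance = 1e-8)
  expect_equal(res$cr, ((lam - 3) / 2) / 0.58, tolerance = 1e-7)
  expect_true(res$cr < 0.1)
  # geometric-mean variant agrees loosely on a near-consistent matrix
  resg <- ahp_weights(P, method = "geometric")
  expect_equal(resg$weights, res$weights, tolerance = 0.02)
})

test_that("AHP properties: consistent recovery over random weights, scale invariance", {
  set.seed(31)
  for (rep in 1:20) {
    k <- sample(2:9, 1)
    w <- runif(k, 0.05, 1); w <- w / sum(w)
    P <- outer(w, w, `/`)
    expect_lt(max(abs(ahp_weights(P)$weights - w)), 1e-8)
    # a_uv = (cw_u)/(cw_v) is the same matrix, so scale invariance is exact;
    # verify via an explicitly rescaled construction
    P2 <- outer(w * 7.3, w * 7.3, `/`)
    expect_equal(P2, P, tolerance = 1e-12)
  }
})

test_that("AHP flags inconsistent judgments and rejects malformed matrices", {
  P <- matrix(c(1, 9, 1/9,
                1/9, 1, 9,
                9, 1/9, 1), 3, 3, byrow = TRUE)  # maximally circular
  expect_warning(res <- ahp_weights(P), "inconsistent")
  expect_false(res$consistent)
  expect_gt(res$cr, 0.1)

  bad <- matrix(c(1, 2, 3, 1), 2, 2)             # not reciprocal
  expect_error(ahp_weights(bad), "reciprocal")
  expect_error(ahp_weights(matrix(c(1, -1, -1, 1), 2, 2)), "positive")
  expect_error(ahp_weights(matrix(1, 1, 1)), "size 2-15")
})

test_that("entropy weights match the hand example and trivial cases", {
  nm <- cbind(A = c(1, 0), B = c(0.5, 0.5))
  res <- entropy_weights(nm)
  expect_equal(unname(res$entropy), c(0, 1))
  expect_equal(unname(res$weights), c(1, 0))

  single <- entropy_weights(cbind(A = c(0.3, 0.9, 0.1)))
  expect_equal(unname(single$weights), 1)

  expect_warning(res0 <- entropy_weights(cbind(A = c(1, 1), B = c(0.5, 0.5))),
                 "degenerate")
  expect_equal(unname(res0$weights), c(0.5, 0.5))
})

test_that("entropy weights equal a brute-force reimplementation on 100 random matrices", {
  # independent oracle: direct transcription of the entropy-weight formulas
  oracle <- function(x) {
    n <- nrow(x)
    p <- apply(x, 2, function(col) col / sum(col))
    hj <- apply(p, 2, function(pc) {
      s <- 0
      for (v in pc) if (v > 0) s <- s + v * log(v)
      -s / log(n)
    })
    (1 - hj) / sum(1 - hj)
  }
  set.seed(7)
  for (rep in 1:100) {
    x <- matrix(runif(30), nrow = 5)             # 5 x 6, strictly positive
    x[sample(length(x), 3)] <- 0                 # exercise 0 ln 0 = 0
    res <- entropy_weights(x)
    expect_equal(unname(res$weights), unname(oracle(x)), tolerance = 1e-12)
    expect_equal(sum(res$weights), 1, tolerance = 1e-12)
    expect_true(all(res$entropy >= 0 & res$entropy <= 1 + 1e-12))
  }
})

test_that("entropy weighting is invariant to hospital permutation and splits duplicates", {
  set.seed(13)
  x <- matrix(runif(24), 6, 4)
  w <- entropy_weights(x)$weights
  perm <- sample(6)
  expect_equal(entropy_weights(x[perm, ])$weights, w, tolerance = 1e-12)

  xd <- cbind(x, x[, 2])                         # duplicate column
  wd <- entropy_weights(xd)$weights
  expect_equal(unname(wd[2]), unname(wd[5]), tolerance = 1e-12)
  # relative weights among the original columns are preserved
  expect_equal(unname(wd[1] / wd[3]), unname(w[1] / w[3]), tolerance = 1e-12)
})

test_that("assemble_weights multiplies the three levels and sums to 1", {
  h <- hubei_hierarchy()
  n_l2 <- vapply(h$level1, function(n1) length(n1$level2), 0L)
  uni_l2 <- lapply(n_l2, function(k) rep(1 / k, k))
  uni_l3 <- lapply(h$level1, function(n1)
    lapply(n1$level2, function(n2) rep(1 / length(n2$leaves), length(n2$leaves))))
  w <- assemble_weights(h, rep(0.25, 4), uni_l2, uni_l3)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  lt <- leaf_table(h)
  sib <- table(paste(lt$l1, lt$l2))[paste(lt$l1, lt$l2)]
  expect_equal(as.numeric(w),
               0.25 * (1 / n_l2[match(lt$l1, vapply(h$level1, `[[`, "", "name"))]) *
                 (1 / as.numeric(sib)),
               tolerance = 1e-12)

  # printed hierarchy weights reproduce the published 0.07
  wl1 <- vapply(h$level1, `[[`, 0, "weight")
  wl2 <- lapply(h$level1, function(n1) vapply(n1$level2, `[[`, 0, "weight"))
  wl3 <- lapply(h$level1, function(n1)
    lapply(n1$level2, function(n2) vapply(n2$leaves, `[[`, 0, "weight")))
  wp <- assemble_weights(h, wl1, wl2, wl3)
  expect_equal(unname(wp["patient_satisfaction_pct"]), 0.07)

  expect_error(assemble_weights(h, rep(0.25, 3), uni_l2, uni_l3), "level-1")
  uni_l2_bad <- uni_l2; uni_l2_bad[[2]] <- c(0.5, 0.5)
  expect_error(assemble_weights(h, rep(0.25, 4), uni_l2_bad, uni_l3), "Process")
})

test_that("random full-precision assemblies sum to 1 within 1e-12", {
  set.seed(17)
  for (rep in 1:10) {
    h <- random_hierarchy(rep + 40)
    rw <- function(k) { w <- runif(k, 0.1, 1); w / sum(w) }
    wl1 <- rw(length(h$level1))
    wl2 <- lapply(h$level1, function(n1) rw(length(n1$level2)))
    wl3 <- lapply(h$level1, function(n1)
      lapply(n1$level2, function(n2) rw(length(n2$leaves))))
    expect_equal(sum(assemble_weights(h, wl1, wl2, wl3)), 1, tolerance = 1e-12)
  }
})

test_that("hybrid_weights accepts AHP judgment matrices for levels 1-2", {
  h <- hubei_hierarchy()
  fx <- default_fixture(seed = 3)
  nm <- suppressWarnings(normalize_matrix(fx$matrix, h))
  wl1 <- vapply(h$level1, `[[`, 0, "weight")
  P1 <- simulate_pairwise(wl1, sd = 0, seed = 1)
  w_judged <- hybrid_weights(nm, h, pairwise_l1 = P1)
  w_stored <- hybrid_weights(nm, h)
  expect_equal(as.numeric(w_judged), as.numeric(w_stored), tolerance = 1e-6)
  expect_equal(sum(w_judged), 1, tolerance = 1e-10)
})
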