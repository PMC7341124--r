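test_that("a trait with no residual variation after fixed effects gives zero effects", {
  W <- rand_geno(6, 10)
  fit <- fit_ridge_blup(W, rep(3.2, 6))
  expect_equal(unname(fit$u_hat), rep(0, 10))
  expect_equal(unname(fit$b_hat), 3.2)
  expect_gt(fit$sigma2_u, 0)
  expect_gt(fit$sigma2_e, 0)
})

test_that("kernel-form BLUP at fixed lambda matches the dense ridge oracle", {
  set.seed(21)
  W <- matrix(rnorm(12), 4, 3)
  y <- rnorm(4)
  fit <- fit_ridge_blup(W, y, lambda = 1)
  r <- y - fit$b_hat
  oracle <- drop(solve(crossprod(W) + diag(3), crossprod(W, r)))
  expect_equal(unname(fit$u_hat), oracle, tolerance = 1e-10)
})

test_that("ridge kernel form equals penalized normal equations on random instances", {
  set.seed(22)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    m <- sample(3:20, 1)
    lam <- exp(runif(1, -2, 3))
    W <- matrix(rnorm(n * m), n, m)
    y <- rnorm(n)
    fit <- fit_ridge_blup(W, y, lambda = lam)
    r <- y - fit$b_hat
    oracle <- drop(solve(crossprod(W) + lam * diag(m), crossprod(W, r)))
    expect_equal(unname(fit$u_hat), oracle, tolerance = 1e-8)
  }
})

test_that("fit rejects degenerate input", {
  W <- matrix(-1, 5, 8)  # all lines identical
  expect_error(fit_ridge_blup(W, rnorm(5)), "identical")
  expect_error(fit_ridge_blup(rand_geno(5, 8), c(1, 2, NA, 4, 5)), "non-finite")
  G <- rand_geno(5, 8)
  G[2, 3] <- NA
  expect_error(fit_ridge_blup(G, rnorm(5)), "missing")
})

test_that("scale equivariance: scaling y scales effects and breeding values, not partitions", {
  set.seed(23)
  W <- rand_geno(30, 40)
  y <- rnorm(30)
  f1 <- fit_ridge_blup(W, y)
  f2 <- fit_ridge_blup(W, 5 * y)
  expect_equal(unname(f2$u_hat), 5 * unname(f1$u_hat), tolerance = 1e-6)
  p1 <- partition_effects(f1)
  p2 <- partition_effects(f2)
  expect_equal(p1$class, p2$class)
  expect_equal(ks_compare_effects(p1)$D, ks_compare_effects(p2)$D)
  rho1 <- expected_component_correlations(p1)
  rho2 <- expected_component_correlations(p2)
  expect_equal(rho1$rho1, rho2$rho1, tolerance = 1e-9)
  b1 <- predict_breeding_values(W, p1)
  b2 <- predict_breeding_values(W, p2)
  expect_equal(b2$a_hat, 5 * b1$a_hat, tolerance = 1e-6)
})

test_that("worked-example coefficients split into 7 primary and 3 secondary markers", {
  expect_equal(sum(tbl1_part$class == "P"), 7)
  expect_equal(sum(tbl1_part$class == "S"), 3)
  expect_equal(tbl1_part$u1 + tbl1_part$u2, tbl1_part$effect)

  # all-positive coefficients: everything favorable from the secondary parent
  allpos <- partition_effects(setNames(c(0.3, 0.1, 2), paste0("M", 1:3)))
  expect_equal(allpos$class, rep("S", 3))

  # favorable direction "lower" swaps the classes exactly
  lower <- partition_effects(tbl1$effects, "lower")
  expect_equal(lower$class, ifelse(tbl1_part$class == "P", "S",
                                   ifelse(tbl1_part$class == "S", "P", "Z")))
})

test_that("zero coefficients form their own class and drop out of both components", {
  part <- partition_effects(setNames(c(-1, 0, 2), paste0("M", 1:3)))
  expect_equal(part$class, c("P", "Z", "S"))
  expect_equal(part$u1, c(-1, 0, 0))
  expect_equal(part$u2, c(0, 0, 2))
})

test_that("worked-example breeding values are reproduced exactly", {
  bv <- predict_breeding_values(tbl1$genotypes, tbl1_part)
  expect_equal(bv$a_hat, tbl1$breeding_values$a_hat, tolerance = 1e-12)
  expect_equal(bv$a1_hat, tbl1$breeding_values$a1_hat, tolerance = 1e-12)
  expect_equal(bv$a2_hat, tbl1$breeding_values$a2_hat, tolerance = 1e-12)
})

test_that("total breeding value is the sum of its components on random fits", {
  set.seed(24)
  for (i in 1:10) {
    W <- rand_geno(20, 30, het = 0.1)
    fit <- fit_ridge_blup(W, rnorm(20))
    part <- partition_effects(fit)
    expect_equal(part$u1 + part$u2, part$effect)
    bv <- predict_breeding_values(W, part)
    expect_equal(bv$a_hat, bv$a1_hat + bv$a2_hat, tolerance = 1e-10)
  }
})

test_that("prediction errors on marker mismatch", {
  W <- rand_geno(5, 9)
  expect_error(predict_breeding_values(W, tbl1_part), "marker")
})

test_that("expected component correlations match the closed form and enumeration oracle", {
  rho <- expected_component_correlations(tbl1_part)
  expect_equal(round(rho$rho1, 2), 0.89)
  expect_equal(round(rho$rho2, 2), 0.45)

  # exact oracle: enumerate all 2^10 equiprobable homozygous genotype vectors
  grid <- as.matrix(expand.grid(rep(list(c(-1, 1)), 10)))
  a <- drop(grid %*% tbl1_part$effect)
  a1 <- drop(grid %*% tbl1_part$u1)
  a2 <- drop(grid %*% tbl1_part$u2)
  expect_equal(rho$rho1, cor(a, a1), tolerance = 1e-12)
  expect_equal(rho$rho2, cor(a, a2), tolerance = 1e-12)

  # degenerate cases
  onesided <- partition_effects(setNames(c(-1, -2), c("a", "b")))
  r1 <- expected_component_correlations(onesided)
  expect_equal(c(r1$rho1, r1$rho2), c(1, 0))
  expect_error(expected_component_correlations(partition_effects(setNames(c(0, 0), c("a", "b")))),
               "zero")
})

test_that("squared component correlations sum to one when no effect is zero", {
  set.seed(25)
  for (i in 1:20) {
    u <- rnorm(sample(5:50, 1))
    rho <- expected_component_correlations(partition_effects(u))
    expect_equal(rho$rho1^2 + rho$rho2^2, 1, tolerance = 1e-12)
  }
})

test_that("prediction accuracy returns expected correlations and NaN on zero variance", {
  bv <- predict_breeding_values(tbl1$genotypes, tbl1_part)
  acc <- prediction_accuracy(bv, 2 * bv$a_hat)
  expect_equal(acc$r_A, 1, tolerance = 1e-12)
  expect_warning(acc2 <- prediction_accuracy(bv, rep(1, 5)), "zero variance")
  expect_true(is.nan(acc2$r_A))
})

test_that("in-sample accuracy of the total never falls below its components (stochastic)", {
  set.seed(26)
  wins <- 0L
  for (i in 1:100) {
    W <- rand_geno(30, 40)
    y <- rnorm(30)
    fit <- fit_ridge_blup(W, y)
    bv <- predict_breeding_values(W, partition_effects(fit))
    acc <- suppressWarnings(prediction_accuracy(bv, fit))
    if (is.nan(acc$r_P) || is.nan(acc$r_S) ||
        acc$r_A >= max(acc$r_P, acc$r_S) - 1e-12) wins <- wins + 1L
  }
  expect_gte(wins, 95)
})

test_that("KS comparison matches hand-computed and brute-force values", {
  # identical multisets
  part <- partition_effects(setNames(c(-0.1, -0.5, 0.1, 0.5), paste0("M", 1:4)))
  ks <- ks_compare_effects(part)
  expect_equal(ks$D, 0)
  expect_equal(ks$p_value, 1)

  # fully separated samples
  part2 <- partition_effects(setNames(c(-0.1, -0.2, 0.5, 0.9), paste0("M", 1:4)))
  expect_equal(ks_compare_effects(part2)$D, 1)

  # direct ECDF evaluation: {0.1, 0.5} vs {0.2, 0.4, 0.9}
  part3 <- partition_effects(setNames(c(-0.1, -0.5, 0.2, 0.4, 0.9), paste0("M", 1:5)))
  ks3 <- ks_compare_effects(part3)
  expect_equal(ks3$D, ks_D_bruteforce(c(0.1, 0.5), c(0.2, 0.4, 0.9)))
  expect_equal(ks3$n_P, 2)
  expect_equal(ks3$n_S, 3)
  expect_equal(ks3$neglog10_p, -log10(ks3$p_value))

  # one empty class is an error
  expect_error(ks_compare_effects(partition_effects(setNames(c(-1, -2), c("a", "b")))),
               "no favorable alleles")
})

test_that("KS D is invariant to strictly monotone transforms of both samples", {
  set.seed(27)
  u <- c(-abs(rnorm(8)), abs(rnorm(5)))
  names(u) <- paste0("M", seq_along(u))
  part <- partition_effects(u)
  D0 <- ks_compare_effects(part)$D
  # apply x -> x^3 to |u| while keeping signs (strictly monotone on |u|)
  part2 <- partition_effects(setNames(sign(u) * abs(u)^3, names(u)))
  expect_equal(ks_compare_effects(part2)$D, D0)
})

test_that("Bonferroni flag uses 0.05 divided by the family count", {
  set.seed(28)
  u <- setNames(c(-abs(rnorm(20, 1, 0.01)), abs(rnorm(20, 3, 0.01))), paste0("M", 1:40))
  ks <- ks_compare_effects(partition_effects(u), bonferroni_n = 25)
  expect_true(ks$significant == (ks$p_value < 0.05 / 25))
})

test_that("tidy and glance return well-formed summaries", {
  set.seed(29)
  W <- rand_geno(12, 15)
  fit <- fit_ridge_blup(W, rnorm(12))
  td <- tidy(fit)
  expect_equal(names(td), c("marker", "effect"))
  expect_equal(nrow(td), 15)
  gl <- glance(fit)
  expect_equal(gl$n_lines, 12)
  expect_true(gl$lambda > 0)
  expect_true(gl$h2 >= 0 && gl$h2 <= 1)
})
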