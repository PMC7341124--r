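test_that("genome layout spreads markers evenly", {
  g <- sim_genome()
  expect_equal(g$markers_per_chrom, 775L)
  expect_equal(g$chrom_length, 155)
  expect_equal(g$spacing, 0.2)
  expect_equal(length(g$markers), 7750L)
  # adjacent spacing within a chromosome is constant
  d <- diff(g$pos[1:775])
  expect_true(all(abs(d - 0.2) < 1e-12))
  g2 <- sim_genome(1, 10, 100)
  expect_equal(g2$spacing, 10)
  expect_error(sim_genome(3, 10, 100), "divisible")
})

test_that("QTL models have the stated counts, signs and aggregate variance", {
  g <- sim_genome()
  set.seed(41)
  q <- sample_qtl_model(g, 2, 0.6)
  expect_equal(q$p, 775L)
  expect_equal(q$n_P, 465L)
  expect_equal(q$n_S, 310L)
  expect_true(all(q$qtl$effect[q$qtl$class == "P"] < 0))
  expect_true(all(q$qtl$effect[q$qtl$class == "S"] > 0))
  expect_equal(anyDuplicated(q$qtl$index), 0L)

  # aggregated QTL variance 1 by construction: mean of sum(u^2) over draws
  gsm <- small_genome()
  tot <- replicate(200, sum(sample_qtl_model(gsm, 4, 0.6)$qtl$effect^2))
  expect_lt(abs(mean(tot) - 1), 0.05)

  # all favorable alleles from one parent
  q1 <- sample_qtl_model(gsm, 4, 1)
  expect_true(all(q1$qtl$effect < 0))
})

test_that("gametes of a homozygous parent are constant; F1 segregates 1:1 with Haldane recombination", {
  g2 <- sim_genome(1, 2, 100)  # two markers at 25 and 75 cM
  hom <- osgs:::new_sim_pop(matrix(0L, 1, 2), matrix(0L, 1, 2), g2, "P")
  set.seed(42)
  expect_true(all(sim_gametes(hom, 1, 50) == 0))

  f1 <- osgs:::new_sim_pop(matrix(0L, 1, 2), matrix(1L, 1, 2), g2, "F1")
  gam <- sim_gametes(f1, 1, 20000)
  freq <- colMeans(gam)
  se <- sqrt(0.25 / 20000)
  expect_true(all(abs(freq - 0.5) < 2 * se + 1e-9))

  rec <- mean(gam[, 1] != gam[, 2])
  r_hald <- 0.5 * (1 - exp(-1))  # 50 cM under no interference
  se_r <- sqrt(r_hald * (1 - r_hald) / 20000)
  expect_lt(abs(rec - r_hald), 3 * se_r)
})

test_that("founded populations have the expected marker composition", {
  g <- small_genome()
  set.seed(43)
  f2 <- found_population("F2", 400, g)
  expect_lt(abs(mean(genotypes(f2))), 0.05)

  bc1 <- found_population("BC1", 200, g)
  expect_true(all(genotypes(bc1) <= 0))  # never homozygous secondary

  rbc1 <- found_population("rBC1", 400, g)
  dos_primary <- mean((1 - genotypes(rbc1)) / 2)
  expect_lt(abs(dos_primary - 0.25), 0.02)
})

test_that("single-seed descent halves heterozygosity per generation and fixes homozygotes", {
  g <- small_genome()
  set.seed(44)
  f2 <- found_population("F2", 500, g)
  h0 <- mean(genotypes(f2) == 0)
  for (gen in 1:3) {
    pop <- self_generations(f2, gen)
    h <- mean(genotypes(pop) == 0)
    expected <- h0 * 0.5^gen
    se <- sqrt(expected * (1 - expected) / length(genotypes(pop)))
    # markers within a line are linked, so allow a generous multiple of the
    # binomial SE
    expect_lt(abs(h - expected), 10 * se + 0.01)
    expect_lte(h, h0)
  }
  expect_identical(self_generations(f2, 0), f2)

  dh <- make_dh(f2, 1, 2, 30)
  fixed <- self_generations(dh, 2)
  expect_equal(genotypes(fixed), genotypes(dh))
})

test_that("double haploids are fully homozygous with Mendelian expectation", {
  g <- small_genome()
  set.seed(45)
  f2 <- found_population("F2", 10, g)
  dh <- make_dh(f2, 1, 2, 40)
  G <- genotypes(dh)
  expect_true(all(G %in% c(-1L, 1L)))
  expect_equal(n_lines(dh), 40L)

  # DH of a cross between two primary-identical inbreds is all -1
  prim2 <- osgs:::new_sim_pop(matrix(0L, 2, g$n_markers), matrix(0L, 2, g$n_markers), g, "P")
  dh_p <- make_dh(prim2, 1, 2, 10)
  expect_true(all(genotypes(dh_p) == -1L))

  # doubling gametes of the founder F1 gives mean genotype 0 per marker
  f1 <- osgs:::new_sim_pop(matrix(0L, 1, g$n_markers), matrix(1L, 1, g$n_markers), g, "F1")
  gam <- sim_gametes(f1, 1, 3000)
  expect_lt(abs(mean(2 * gam - 1)), 0.04)
})

test_that("true breeding values agree with prediction on the same coding", {
  g <- small_genome()
  set.seed(46)
  q <- sample_qtl_model(g, 4, 0.6)
  pop <- self_generations(found_population("F2", 50, g), 2)
  bv <- true_bv(pop, q)
  part <- qtl_partition(q, g)
  pred <- predict_breeding_values(genotypes(pop), part)
  expect_equal(bv$bv, pred$a_hat, tolerance = 1e-12)
  expect_equal(pred$a_hat, pred$a1_hat + pred$a2_hat, tolerance = 1e-12)

  # an all-heterozygous F1 has breeding value zero
  f1 <- osgs:::new_sim_pop(matrix(0L, 1, g$n_markers), matrix(1L, 1, g$n_markers), g, "F1")
  expect_equal(true_bv(f1, q)$bv, 0)
})

test_that("phenotypes add unit-variance residuals", {
  g <- small_genome()
  set.seed(47)
  q <- sample_qtl_model(g, 4, 0.6)
  pop <- found_population("F2", 10000, g)
  ph <- sim_phenotype(pop, q)
  res_var <- var(ph$y - ph$bv)
  se <- sqrt(2 / (10000 - 1))  # SE of a unit-variance sample variance
  expect_lt(abs(res_var - 1), 2 * se)
})

test_that("favorable proportions recover the parental table values", {
  g <- sim_genome()
  set.seed(48)
  q <- sample_qtl_model(g, 2, 0.6)
  pr_parents <- favorable_proportions(founders(g), q)
  expect_equal(pr_parents$P, c(0.6, 0), tolerance = 1e-12)
  expect_equal(pr_parents$S, c(0, 0.4), tolerance = 1e-12)
  # founder breeding values are symmetric
  expect_equal(sum(true_bv(founders(g), q)$bv), 0, tolerance = 1e-10)

  # per-line bounds
  pop <- found_population("F2", 30, small_genome())
  qs <- sample_qtl_model(small_genome(), 4, 0.7)
  pr <- favorable_proportions(pop, qs)
  expect_true(all(pr$P >= 0 & pr$P <= qs$n_P / qs$p + 1e-12))
  expect_true(all(pr$S >= 0 & pr$S <= qs$n_S / qs$p + 1e-12))
  expect_true(all(pr$P + pr$S <= 1 + 1e-12))
})

test_that("favorable proportions from a marker partition use favorable dosage over all markers", {
  G <- matrix(c(-1, -1, 1,
                 1, -1, -1), 2, 3, byrow = TRUE,
              dimnames = list(c("l1", "l2"), c("M1", "M2", "M3")))
  pop <- osgs:::new_sim_pop((G == 1) * 1L, (G != -1) * 1L,
                            sim_genome(1, 3, 30), "toy")
  # genotype reconstruction check
  expect_equal(unname(genotypes(pop)), unname(G))
  part <- partition_effects(setNames(c(-0.5, 0.3, -0.2), c("M1", "M2", "M3")))
  pr <- favorable_proportions(pop, part)
  # l1: P markers M1 (g=-1: dosage 1), M3 (g=1: dosage 0); S marker M2 (g=-1: 0)
  expect_equal(pr$P, c((1 + 0) / 3, (0 + 1) / 3))
  expect_equal(pr$S, c(0 / 3, 0 / 3))
})
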