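test_that("step_up matches worked examples and rejects the smallest p-values", {
  fam <- pvalue_family(c(0.9, 0.9, 0.9))
  sch <- threshold_schedule(rep(0.05, 3), 0.05, "step_up", "const")
  expect_equal(step_up(fam, sch)$R, 0L)

  fam2 <- pvalue_family(c(0.01, 0.02, 0.04))
  dec <- step_up(fam2, threshold_schedule(0.05 * (1:3) / 3, 0.05, "step_up"))
  expect_equal(dec$R, 3L)
  expect_true(all(dec$rejected))

  # a rejected set is exactly the hypotheses of the R smallest p-values:
  # thresholds (0.0125, 0.025, 0.0375, 0.05); p_(2) = 0.04 > 0.025 so R = 1
  fam3 <- pvalue_family(c(0.5, 0.001, 0.2, 0.04))
  dec3 <- step_up(fam3, threshold_schedule(0.05 * (1:4) / 4, 0.05, "step_up"))
  expect_equal(dec3$R, brute_force_step_up(fam3$values, 0.05 * (1:4) / 4))
  expect_equal(dec3$R, 1L)
  expect_equal(which(dec3$rejected), 2L)

  expect_error(step_up(fam2, threshold_schedule(c(0.01, 0.05), 0.05,
                                                "step_up")),
               "does not match")
  expect_error(step_up(fam2, threshold_schedule(rep(0.01, 3), 0.05,
                                                "step_down")),
               "kind")
})

test_that("step_down stops at the first threshold failure", {
  fam <- pvalue_family(rep(0, 4))
  sch <- threshold_schedule(rep(0.01, 4), 0.05, "step_down")
  expect_equal(step_down(fam, sch)$R, 4L)

  holm <- threshold_schedule(0.05 / (3:1), 0.05, "step_down", "Holm")
  expect_equal(step_down(pvalue_family(c(0.001, 0.02, 0.9)), holm)$R, 2L)
  expect_equal(step_down(pvalue_family(c(0.03, 0.9, 0.9)), holm)$R, 0L)
})

test_that("the engines agree with brute-force enumeration for small m", {
  set.seed(42)
  for (m in 1:12) {
    for (rep in 1:20) {
      p <- runif(m)
      delta <- sort(runif(m, 0, 0.6))
      fam <- pvalue_family(p)
      su <- threshold_schedule(delta, 0.05, "step_up")
      sd_ <- threshold_schedule(delta, 0.05, "step_down")
      expect_equal(step_up(fam, su)$R, brute_force_step_up(p, delta))
      expect_equal(step_down(fam, sd_)$R, brute_force_step_down(p, delta))
    }
  }
})

test_that("named procedures reproduce their hand-computed counts", {
  expect_equal(mtp(pvalue_family(c(1, 1, 1)), "bonferroni")$R, 0L)
  expect_equal(mtp(pvalue_family(c(0.001, 0.02, 0.9)), "bonferroni")$R, 1L)
  expect_equal(mtp(pvalue_family(c(0.001, 0.02, 0.9)), "holm")$R, 2L)
  expect_equal(mtp(pvalue_family(c(0.01, 0.02, 0.04)), "bh")$R, 3L)
  # BY at m = 3: thresholds (1:3) * 0.05 / (3 * 11/6), all below 0.01
  expect_equal(mtp(pvalue_family(c(0.01, 0.02, 0.04)), "by")$R, 0L)

  # Sidak constant 1 - 0.95^(1/3) ~ 0.016952 sits above the Bonferroni cut
  fam <- pvalue_family(c(0.0168, 0.9, 0.9))
  expect_equal(mtp(fam, "sidak")$R, 1L)
  expect_equal(mtp(fam, "bonferroni")$R, 0L)

  # single hypothesis: Sidak reduces to the plain alpha-level test
  expect_equal(mtp(pvalue_family(0.049), "sidak", 0.05)$R, 1L)
  expect_equal(mtp(pvalue_family(0.051), "sidak", 0.05)$R, 0L)

  expect_error(mtp(pvalue_family(0.5), "bh", alpha = 0), "alpha")
})

test_that("procedures agree with the adjusted-p-value oracle", {
  set.seed(7)
  for (i in 1:100) {
    fam <- random_family(sample(2:60, 1))
    alpha <- runif(1, 0.01, 0.2)
    p <- fam$values
    expect_equal(mtp(fam, "bh", alpha)$R,
                 sum(p.adjust(p, "BH") <= alpha))
    expect_equal(mtp(fam, "by", alpha)$R,
                 sum(p.adjust(p, "BY") <= alpha))
    expect_equal(mtp(fam, "holm", alpha)$R,
                 sum(p.adjust(p, "holm") <= alpha))
    expect_equal(mtp(fam, "bonferroni", alpha)$R,
                 sum(p.adjust(p, "bonferroni") <= alpha))
  }
})

test_that("threshold dominance and alpha monotonicity hold", {
  set.seed(13)
  alphas <- c(0.01, 0.05, 0.1, 0.2)
  for (i in 1:200) {
    fam <- random_family(sample(1:40, 1))
    expect_lte(mtp(fam, "bonferroni")$R, mtp(fam, "holm")$R)
    expect_lte(mtp(fam, "bonferroni")$R, mtp(fam, "sidak")$R)
    expect_lte(mtp(fam, "by")$R, mtp(fam, "bh")$R)
    for (meth in c("bonferroni", "holm", "sidak", "bh", "by")) {
      Rs <- vapply(alphas, function(a) mtp(fam, meth, a)$R, integer(1))
      expect_true(!is.unsorted(Rs))
    }
  }
})

test_that("decisions are invariant under hypothesis relabelling", {
  set.seed(99)
  fam <- random_family(30)
  perm <- sample(30)
  fam_p <- pvalue_family(fam$values[perm])
  for (meth in c("bonferroni", "holm", "sidak", "bh", "by")) {
    d1 <- mtp(fam, meth)
    d2 <- mtp(fam_p, meth)
    expect_equal(d2$R, d1$R)
    expect_equal(d2$rejected, d1$rejected[perm])
  }
})

test_that("weighted Bonferroni compares each p-value to alpha * w", {
  fam <- pvalue_family(c(0.03, 0.9))
  expect_equal(weighted_bonferroni(fam, c(0.9, 0.1), 0.05)$R, 1L)
  expect_equal(weighted_bonferroni(fam, c(0.1, 0.9), 0.05)$R, 0L)

  # equal weights recover the plain Bonferroni decision
  set.seed(4)
  fam2 <- random_family(20)
  expect_equal(weighted_bonferroni(fam2, rep(1 / 20, 20))$rejected,
               mtp(fam2, "bonferroni")$rejected)

  expect_error(weighted_bonferroni(fam, c(0.5, 0.4)), "sum to 1")
  expect_error(weighted_bonferroni(fam, c(1.5, -0.5)), "nonnegative")
  expect_error(weighted_bonferroni(fam, 1), "one weight per")
})

test_that("weighted Bonferroni sensitivity summarises random-weight counts", {
  fam0 <- pvalue_family(rep(0, 6))
  s0 <- weighted_bonferroni_sensitivity(fam0, n_draws = 50, seed = 1)
  expect_true(all(s0$R_draws == 6L))
  expect_equal(s0$sd_R, 0)

  # m = 1 reduces to the plain p <= alpha test for every draw
  s1 <- weighted_bonferroni_sensitivity(pvalue_family(0.04), n_draws = 20,
                                        seed = 2)
  expect_true(all(s1$R_draws == 1L))

  set.seed(8)
  fam <- random_family(50)
  a <- weighted_bonferroni_sensitivity(fam, n_draws = 100, seed = 3)
  b <- weighted_bonferroni_sensitivity(fam, n_draws = 100, seed = 3)
  expect_identical(a$R_draws, b$R_draws)
  expect_equal(a$mean_R, mean(a$R_draws))
  expect_error(weighted_bonferroni_sensitivity(fam, n_draws = 1), "at least 2")
})
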