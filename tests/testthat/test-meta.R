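test_that("fixed-effect pooling evaluates the inverse-variance formula", {
  eff <- data.frame(cohort_id = c("s1", "s2"), estimate = c(0.5, 1.0),
                    se = c(0.1, 0.2))
  mr <- pool_fixed(eff)
  expect_equal(mr$pooled, (0.5 * 100 + 1.0 * 25) / 125)  # = 0.6
  expect_equal(mr$se, 1 / sqrt(125))
  expect_equal(sum(mr$weights), 1)
  # single study is the identity
  one <- pool_fixed(data.frame(cohort_id = "s", estimate = 0.7, se = 0.3))
  expect_equal(one$pooled, 0.7)
  expect_equal(one$se, 0.3)
  # equal se -> arithmetic mean
  eq <- pool_fixed(data.frame(cohort_id = letters[1:3],
                              estimate = c(0.2, 0.5, 1.1), se = 0.2))
  expect_equal(eq$pooled, mean(c(0.2, 0.5, 1.1)))
  expect_error(pool_fixed(data.frame(estimate = c(1, Inf), se = c(1, 1))),
               "finite")
})

test_that("DerSimonian-Laird tau2 matches the scalar formula and truncates", {
  eff <- data.frame(cohort_id = c("a", "b", "c"), estimate = c(0, 1, 2),
                    se = 0.1)
  mr <- pool_dersimonian_laird(eff)
  w <- rep(100, 3)
  Q <- sum(w * (c(0, 1, 2) - 1)^2)
  C <- sum(w) - sum(w^2) / sum(w)
  expect_equal(mr$tau2, max(0, (Q - 2) / C), tolerance = 1e-10)
  expect_equal(mr$Q, Q, tolerance = 1e-10)
  # homogeneous studies with Q <= K-1 -> tau2 = 0, equals fixed
  hom <- data.frame(cohort_id = c("a", "b"), estimate = c(0.50, 0.52),
                    se = c(0.3, 0.3))
  r <- pool_dersimonian_laird(hom)
  f <- pool_fixed(hom)
  expect_equal(r$tau2, 0)
  expect_equal(r$pooled, f$pooled)
  expect_equal(r$se, f$se)
})

test_that("pooling invariants hold across randomized study sets", {
  for (seed in 1:10) {
    eff <- withr::with_seed(seed, data.frame(
      cohort_id = paste0("s", 1:6),
      estimate = rnorm(6), se = runif(6, 0.05, 0.5)))
    f <- pool_fixed(eff)
    r <- pool_dersimonian_laird(eff)
    # convex combination: pooled within the study range
    expect_gte(f$pooled, min(eff$estimate))
    expect_lte(f$pooled, max(eff$estimate))
    # random-effects se never smaller than fixed
    expect_gte(r$se, f$se - 1e-14)
    # permuting study order changes nothing
    perm <- eff[withr::with_seed(seed + 100, sample(6)), ]
    expect_equal(pool_dersimonian_laird(perm)$pooled, r$pooled, tolerance = 1e-12)
    expect_equal(pool_dersimonian_laird(perm)$tau2, r$tau2, tolerance = 1e-12)
  }
})

test_that("pooled values agree with metafor's DL implementation", {
  skip_if_not_installed("metafor")
  for (seed in c(2, 9)) {
    eff <- withr::with_seed(seed, data.frame(
      cohort_id = paste0("s", 1:5),
      estimate = rnorm(5, 0.3), se = runif(5, 0.1, 0.4)))
    ref <- metafor::rma(yi = eff$estimate, sei = eff$se, method = "DL")
    r <- pool_dersimonian_laird(eff)
    expect_equal(r$pooled, as.numeric(ref$beta), tolerance = 1e-8)
    expect_equal(r$se, ref$se, tolerance = 1e-8)
    expect_equal(r$tau2, ref$tau2, tolerance = 1e-8)
    fe <- metafor::rma(yi = eff$estimate, sei = eff$se, method = "FE")
    f <- pool_fixed(eff)
    expect_equal(f$pooled, as.numeric(fe$beta), tolerance = 1e-8)
  }
})

test_that("BH adjustment reproduces the step-up computation", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.03), 0.03)
  p <- c(0.001, 0.04, 0.2, 0.9)
  expect_true(all(bh_fdr(p) >= p))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("subgroup pooling equals filter-then-pool", {
  eff <- withr::with_seed(6, data.frame(
    cohort_id = paste0("s", 1:6), estimate = rnorm(6, 0.4),
    se = runif(6, 0.1, 0.3)))
  groups <- setNames(rep(c("hot", "cold"), each = 3), eff$cohort_id)
  sub <- subgroup_meta(eff, groups)
  expect_equal(sub$hot$pooled,
               pool_dersimonian_laird(eff[1:3, ])$pooled, tolerance = 1e-12)
  expect_equal(sub$cold$pooled,
               pool_dersimonian_laird(eff[4:6, ])$pooled, tolerance = 1e-12)
  # one subgroup containing everything equals plain pooling
  all_one <- subgroup_meta(eff, setNames(rep("all", 6), eff$cohort_id))
  expect_equal(all_one$all$pooled, pool_dersimonian_laird(eff)$pooled)
  # singleton subgroups return their own estimates
  singles <- subgroup_meta(eff, setNames(eff$cohort_id, eff$cohort_id))
  expect_equal(singles$s1$pooled, eff$estimate[1])
  expect_error(subgroup_meta(eff, groups[-1]), "unlabeled")
})

test_that("hot/cold configuration lists the expected strata", {
  hc <- hot_cold_types()
  expect_length(hc$hot, 18)
  expect_length(hc$cold, 15)
  expect_true(all(c("SKCM", "KIRC", "LUAD") %in% hc$hot))
  expect_true(all(c("GBM", "UVM", "THCA") %in% hc$cold))
  expect_length(intersect(hc$hot, hc$cold), 0)
})
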