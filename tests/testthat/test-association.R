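test_that("responder classification follows the RECIST + 6-month PFS rule", {
  expect_equal(classify_response("CR"), "R")
  expect_equal(classify_response("PR", 2, 1), "R")
  expect_equal(classify_response("PD"), "NR")
  expect_equal(classify_response("SD", 5, 1), "NR")          # SD, event by month 6
  expect_equal(classify_response("SD", 9, 1), "R")           # event after month 6
  expect_equal(classify_response("SD", 12, 0), "R")
  expect_equal(classify_response("SD", NA, NA), "non_assessable")
  expect_equal(classify_response(NA, 4, 1), "NR")            # PFS-only rule
  expect_equal(classify_response(NA, 4, 0), "R")
  expect_error(classify_response(NA, NA, NA), "neither")
})

test_that("Cox fit matches a brute-force partial-likelihood maximizer", {
  fixtures <- list(
    list(score = c(0.5, -1.2, 2.0, 0.1, -0.4, 1.5, -2.1, 0.9),
         time = c(3, 6, 2, 8, 5, 1, 9, 4), event = c(1, 1, 1, 0, 1, 1, 0, 1)),
    list(score = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12) / 4,
         time = c(5, 3, 9, 1, 7, 2, 8, 4, 6, 10, 2, 5),
         event = c(1, 1, 0, 1, 1, 1, 0, 1, 1, 0, 1, 1))
  )
  for (fx in fixtures) {
    est <- fit_cox_univariate(fx$score, fx$time, fx$event)$estimate
    opt <- optimize(function(b) -oracle_cox_loglik(b, fx$score, fx$time, fx$event),
                    c(-5, 5), tol = 1e-9)$minimum
    expect_equal(est, opt, tolerance = 1e-4)
  }
})

test_that("Cox estimate is symmetric, location-invariant and scale-equivariant", {
  fx <- list(score = c(0.5, -1.2, 2.0, 0.1, -0.4, 1.5, -2.1, 0.9),
             time = c(3, 6, 2, 8, 5, 1, 9, 4), event = c(1, 1, 1, 0, 1, 1, 0, 1))
  base <- fit_cox_univariate(fx$score, fx$time, fx$event)
  shifted <- fit_cox_univariate(fx$score + 10, fx$time, fx$event)
  scaled <- fit_cox_univariate(fx$score * 10, fx$time, fx$event)
  expect_equal(shifted$estimate, base$estimate, tolerance = 1e-8)
  expect_equal(scaled$estimate, base$estimate / 10, tolerance = 1e-8)
  expect_equal(scaled$se, base$se / 10, tolerance = 1e-8)
  expect_equal(scaled$p, base$p, tolerance = 1e-8)
  # two groups with identical event patterns under label swap -> estimate 0
  sym <- fit_cox_univariate(c(1, -1, 1, -1, 1, -1), rep(c(2, 5, 7), 2),
                            rep(1, 6))
  expect_equal(sym$estimate, 0, tolerance = 1e-8)
  expect_error(fit_cox_univariate(rep(1, 6), rep(c(2, 5, 7), 2), rep(1, 6)),
               "constant")
  expect_error(fit_cox_univariate(1:6, 1:6, rep(0, 6)), "2 events")
})

test_that("logistic logOR on a binary predictor matches log(ad/bc)", {
  # 2x2 table (a, b, c, d) = (6, 2, 3, 9): responders/non by high/low score
  x <- c(rep(1, 6 + 3), rep(0, 2 + 9))
  y <- c(rep(1, 6), rep(0, 3), rep(1, 2), rep(0, 9))
  est <- fit_logistic_univariate(x, y)
  expect_equal(est$estimate, log(9), tolerance = 1e-6)
  expect_true(est$converged)
  # label flip negates the estimate
  flip <- fit_logistic_univariate(x, 1 - y)
  expect_equal(flip$estimate, -est$estimate, tolerance = 1e-6)
  # agrees with glm on a continuous toy
  withr::with_seed(5, {
    s <- rnorm(60)
    r <- rbinom(60, 1, plogis(0.3 + 0.8 * s))
  })
  ours <- fit_logistic_univariate(s, r)
  ref <- glm(r ~ s, family = binomial())
  expect_equal(ours$estimate, unname(coef(ref)[2]), tolerance = 1e-6)
  expect_equal(ours$se, unname(sqrt(diag(vcov(ref)))[2]), tolerance = 1e-4)
})

test_that("perfect separation falls back to a finite Firth estimate", {
  x <- c(-3, -2, -1, 1, 2, 3)
  y <- c(0, 0, 0, 1, 1, 1)
  est <- fit_logistic_univariate(x, y)
  expect_false(est$converged)
  expect_equal(est$method, "logistic_firth")
  expect_true(is.finite(est$estimate) && is.finite(est$se))
  expect_true(est$estimate > 0)
  expect_error(fit_logistic_univariate(x, rep(1, 6)), "both response classes")
})

test_that("AUC equals the exhaustive pair count and respects its identities", {
  expect_equal(auc(c(1, 2, 3, 4), c("NR", "NR", "R", "R")), 1)
  expect_equal(auc(rep(2, 6), c("R", "R", "R", "NR", "NR", "NR")), 0.5)
  expect_equal(auc(c(1, 2, 3, 4), c("NR", "R", "NR", "R")), 0.75)
  withr::with_seed(2, {
    s <- rnorm(30)
    lab <- sample(c("R", "NR"), 30, replace = TRUE)
  })
  expect_equal(auc(s, lab), oracle_auc(s, lab == "R"), tolerance = 1e-12)
  expect_equal(auc(s, lab) + auc(-s, lab), 1, tolerance = 1e-12)
  expect_error(auc(s, rep("R", 30)), "both classes")
})

test_that("DeLong comparison handles identity, complement and matches pROC", {
  withr::with_seed(8, {
    a <- rnorm(40)
    lab <- rep(c("R", "NR"), each = 20)
    b <- a + rnorm(40, sd = 2)
  })
  same <- compare_auc(a, a, lab)
  expect_equal(same$delta_auc, 0)
  expect_equal(same$p, 1)
  comp <- compare_auc(a, -a, lab)
  expect_equal(comp$delta_auc, 2 * auc(a, lab) - 1, tolerance = 1e-12)
  skip_if_not_installed("pROC")
  ours <- compare_auc(a, b, lab)
  ref <- pROC::roc.test(pROC::roc(lab, a, levels = c("NR", "R"), direction = "<",
                                  quiet = TRUE),
                        pROC::roc(lab, b, levels = c("NR", "R"), direction = "<",
                                  quiet = TRUE), method = "delong")
  expect_equal(ours$p, ref$p.value, tolerance = 1e-8)
})

test_that("DeLong variance agrees with a bootstrap on a 10-sample toy", {
  score_a <- c(0.9, 0.8, 0.75, 0.6, 0.55, 0.5, 0.4, 0.35, 0.2, 0.1)
  score_b <- c(0.7, 0.9, 0.5, 0.65, 0.3, 0.6, 0.45, 0.2, 0.5, 0.15)
  lab <- c("R", "R", "R", "R", "R", "NR", "NR", "NR", "NR", "NR")
  ours <- compare_auc(score_a, score_b, lab)
  var_delong <- (ours$delta_auc / ours$z)^2
  boots <- withr::with_seed(77, vapply(seq_len(2000), function(i) {
    idx_r <- sample(1:5, 5, replace = TRUE)
    idx_n <- sample(6:10, 5, replace = TRUE)
    idx <- c(idx_r, idx_n)
    auc(score_a[idx], lab[idx]) - auc(score_b[idx], lab[idx])
  }, 0))
  expect_equal(var_delong, var(boots), tolerance = 0.15)
})

test_that("log-rank test matches the hand-computed observed-expected form", {
  # 6 subjects, no censoring, two arms fixed by the score's median split
  scores <- c(1, 2, 3, 10, 11, 12)
  time <- c(1, 3, 5, 2, 4, 6)
  event <- rep(1, 6)
  res <- km_logrank(scores, time, event)
  # hand computation of the 1-df log-rank statistic
  grp_high <- scores > median(scores)
  o <- e <- v <- 0
  for (t in sort(unique(time))) {
    at_risk <- time >= t
    d <- sum(time == t)
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp_high)
    o <- o + sum(time == t & grp_high)
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  expect_equal(res$chisq, (o - e)^2 / v, tolerance = 1e-10)
  # identical arms -> chisq 0, p 1
  same <- km_logrank(c(1, 1, 1, 2, 2, 2), rep(c(2, 5, 9), 2), rep(1, 6))
  expect_equal(same$chisq, 0, tolerance = 1e-10)
  expect_equal(same$p, 1, tolerance = 1e-10)
  # survival curves are non-increasing
  expect_true(all(diff(res$fit$surv) <= 1e-12 | diff(res$fit$time) < 0))
})

test_that("group comparison routes by type and size", {
  # Fisher on the 2x2 table (3,1,1,3): two-sided p = 34/70
  x <- c(rep("hi", 3), "lo")
  y <- c("hi", rep("lo", 3))
  ft <- compare_groups(x, y)
  expect_equal(ft$method, "fisher")
  expect_equal(ft$p, 34 / 70, tolerance = 1e-10)
  # identical small groups -> exact permutation, p = 1
  idt <- compare_groups(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(idt$method, "permutation_exact")
  expect_equal(idt$p, 1)
  # n = 4 vs 4 uses the permutation path; p granularity 1/C(8,4)
  pp <- compare_groups(c(5, 6, 7, 8), c(1, 2, 3, 4))
  expect_equal(pp$method, "permutation_exact")
  expect_equal(pp$p * 70, round(pp$p * 70), tolerance = 1e-9)
  # large groups use Wilcoxon
  withr::with_seed(3, big <- compare_groups(rnorm(15), rnorm(15)))
  expect_equal(big$method, "wilcoxon")
  expect_error(compare_groups(numeric(0), 1:3), "nonempty")
})

test_that("median Spearman correlation across cohorts behaves", {
  withr::with_seed(4, {
    mats <- lapply(1:3, function(i) {
      a <- rnorm(12)
      rbind(sigA = a, sigB = exp(a), sigC = rnorm(12))  # B monotone in A
    })
  })
  med <- correlate_signatures(mats)
  expect_equal(diag(med), c(sigA = 1, sigB = 1, sigC = 1))
  expect_equal(med["sigA", "sigB"], 1, tolerance = 1e-12)  # rank invariance
  expect_equal(med, t(med))
  # toy ranks (1,2,3) vs (3,2,1) -> -1
  m <- list(rbind(a = c(1, 2, 3), b = c(3, 2, 1)))
  expect_equal(correlate_signatures(m)["a", "b"], -1)
  # constant vector -> warning
  mc <- list(rbind(a = c(1, 2, 3, 4), b = rep(2, 4)))
  expect_warning(correlate_signatures(mc), "constant")
})
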