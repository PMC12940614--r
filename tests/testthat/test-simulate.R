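test_that("cohort simulation is seed-deterministic and leaves global RNG alone", {
  a <- toy_cohorts(seed = 123)
  b <- toy_cohorts(seed = 123)
  expect_identical(a, b)
  c <- toy_cohorts(seed = 124)
  expect_false(identical(a[[1]]$expression, c[[1]]$expression))
  # the generator must not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(toy_cohorts(seed = 5)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("simulated expression and clinical tables satisfy their invariants", {
  cohorts <- toy_cohorts(n_cohorts = 2, n = 30, seed = 7)
  for (co in cohorts) {
    expect_true(all(co$expression >= 0))
    expect_false(anyNA(co$expression))
    expect_equal(ncol(co$expression), nrow(co$clinical))
    expect_identical(colnames(co$expression), co$clinical$sample_id)
    expect_false(anyDuplicated(co$clinical$sample_id) > 0)
    expect_true(all(co$clinical$os_time > 0))
    expect_true(all(co$clinical$pfs_time > 0))
    expect_true(all(co$clinical$os_event %in% 0:1))
    expect_true(all(co$clinical$recist %in% c("CR", "PR", "SD", "PD")))
  }
  expect_error(simulate_cohorts(1, 2, 50, truth_set("g1"), seed = 1), ">= 4")
  expect_error(simulate_cohorts(1, 10, 3, truth_set(paste0("g", 1:5)), seed = 1),
               "exceed")
})

test_that("RECIST assignment is inverted exactly by classify_response", {
  cohorts <- toy_cohorts(n_cohorts = 3, n = 80, seed = 21)
  for (co in cohorts) {
    cl <- co$clinical
    lab <- classify_response(cl$recist, cl$pfs_time, cl$pfs_event)
    expect_true(all(lab %in% c("R", "NR")))
    expect_true(all(lab[cl$recist %in% c("CR", "PR")] == "R"))
    expect_true(all(lab[cl$recist == "PD"] == "NR"))
    sd_idx <- cl$recist == "SD"
    early <- cl$pfs_event == 1 & cl$pfs_time <= 6
    expect_true(all(lab[sd_idx & early] == "NR"))
    expect_true(all(lab[sd_idx & !early] == "R"))
  }
})

test_that("true activity predicts response at gamma = 2 (Mann-Whitney oracle)", {
  truth <- truth_set(paste0("g", 1:5), activity_effect_response = 2)
  co <- simulate_cohorts(1, 200, 50, truth, seed = 31)[[1]]
  lab <- classify_response(co$clinical$recist, co$clinical$pfs_time,
                           co$clinical$pfs_event)
  a_emp <- auc(co$latent_activity, lab)
  expect_gt(a_emp, 0.8)
  expect_equal(a_emp, oracle_auc(co$latent_activity, lab == "R"),
               tolerance = 1e-12)
})

test_that("null effects give chance-level association (AUC about 0.5)", {
  truth <- truth_set(paste0("g", 1:5), activity_effect_response = 0,
                     activity_effect_hazard = 0)
  co <- simulate_cohorts(1, 500, 50, truth, seed = 17)[[1]]
  lab <- classify_response(co$clinical$recist, co$clinical$pfs_time,
                           co$clinical$pfs_event)
  expect_lt(abs(auc(co$latent_activity, lab) - 0.5), 0.05)
  # survival also independent of activity: Cox z-score small
  est <- fit_cox_univariate(co$latent_activity, co$clinical$os_time,
                            co$clinical$os_event)
  expect_lt(abs(est$estimate / est$se), 3)
})

test_that("planted-program score and response are positively associated", {
  truth <- truth_set(sprintf("TLS%02d", 1:10), activity_effect_response = 2)
  co <- simulate_cohorts(1, 500, 100, truth, seed = 19)[[1]]
  z <- zscore_expression(co$expression)
  sc <- gsva_like_score(z, gene_set("planted", truth$signature_genes))
  lab <- classify_response(co$clinical$recist, co$clinical$pfs_time,
                           co$clinical$pfs_event)
  r_pb <- cor(sc, as.numeric(lab == "R"))
  expect_gt(r_pb, 0)
})

test_that("spatial disks match a brute-force geometric oracle", {
  sig <- gene_set("s", paste0("SG", 1:6))
  samp <- simulate_spatial(20, 20, n_tls = 2, radius = 3, signature = sig,
                           effect = 3, maturity = "mature", seed = 42)
  expect_equal(nrow(samp$spots), 400)
  expect_equal(length(samp$tls_annotation), 400)
  ann_n <- sum(samp$tls_annotation == "mature_tls")
  expect_gt(ann_n, 0)
  # geometric oracle: brute-force count of grid points within the placed disks
  oracle_n <- 0
  for (x in 1:20) for (y in 1:20) {
    inside <- FALSE
    for (r in seq_len(nrow(samp$centers)))
      if ((x - samp$centers[r, 1])^2 + (y - samp$centers[r, 2])^2 <= 3^2)
        inside <- TRUE
    oracle_n <- oracle_n + inside
  }
  expect_equal(ann_n, oracle_n)
  # placed disks do not overlap
  expect_gt(sum((samp$centers[1, ] - samp$centers[2, ])^2), (2 * 3)^2)
})

test_that("negative and immature spatial samples follow their contracts", {
  sig <- gene_set("s", paste0("SG", 1:6))
  neg <- simulate_spatial(15, 15, 2, 3, sig, effect = 3, maturity = "negative",
                          seed = 3)
  expect_true(all(neg$tls_annotation == "none"))
  imm <- simulate_spatial(15, 15, 2, 3, sig, effect = 3, maturity = "immature",
                          seed = 3)
  expect_true(any(imm$tls_annotation == "immature_tls"))
  expect_false(any(imm$tls_annotation == "mature_tls"))
  # zero effect: in-disk and out-disk signature means indistinguishable
  null_s <- simulate_spatial(20, 20, 2, 3, sig, effect = 0, maturity = "mature",
                             seed = 11)
  msig <- colMeans(null_s$expression[sig$members, ])
  in_disk <- null_s$tls_annotation == "mature_tls"
  p <- wilcox.test(msig[in_disk], msig[!in_disk])$p.value
  expect_gt(p, 0.001)
  expect_error(simulate_spatial(5, 5, 10, 3, sig, 1, "mature", seed = 1),
               "cannot fit")
})

test_that("mutation simulation hits the target TMB scale with valid classes", {
  mt <- simulate_mutations(1000, mean_tmb = 2, seed = 9)
  expect_identical(mt, simulate_mutations(1000, mean_tmb = 2, seed = 9))
  expect_named(mt, c("sample_id", "missense", "frameshift_indel", "stop_codon",
                     "synonymous", "other"))
  v <- tmb(mt)
  expect_gte(median(v), 1)
  expect_lte(median(v), 4)
  expect_true(all(mt$missense >= 0 & mt$frameshift_indel >= 0))
  expect_error(simulate_mutations(0, 2, seed = 1))
  expect_error(simulate_mutations(10, -1, seed = 1))
})
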