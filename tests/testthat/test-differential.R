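# Paired fit, count-dependent variance moderation, moderated statistics.

test_that("paired fit recovers textbook mean/variance of within-donor differences", {
  base <- matrix(0, 3, 3, dimnames = list(c("G1", "G2", "G3"), NULL))
  trt <- rbind(G1 = c(0.5, 0.5, 0.5),
               G2 = c(0.1, 0.2, 0.3),
               G3 = c(0, 0, 0))
  pq <- make_pq(base, trt)
  fit <- fit_paired_model(pq, "C", treatment = 60)
  expect_equal(fit$logFC[fit$gene == "G1"], 0.5)
  expect_equal(fit$s2[fit$gene == "G1"], 0)
  expect_equal(fit$df[fit$gene == "G1"], 2)
  expect_equal(fit$logFC[fit$gene == "G2"], 0.2)
  expect_equal(fit$s2[fit$gene == "G2"], 0.01)
  expect_equal(fit$logFC[fit$gene == "G3"], 0)  # baseline == treatment

  # a gene with < 2 complete donor pairs is untestable and excluded
  pq$log2ratio["G2", c(2, 4)] <- NA
  fit2 <- fit_paired_model(pq, "C", treatment = 60)
  expect_false("G2" %in% fit2$gene)
})

test_that("variance trend is flat for count-independent noise and has slope -1 for averaging noise", {
  set.seed(21)
  n <- 5000
  count <- sample(1:30, n, replace = TRUE)
  df <- rep(2, n)

  # count-independent variance
  s2_flat <- 0.05 * rchisq(n, 2) / 2
  tr_flat <- fit_variance_trend(
    data.frame(s2 = s2_flat, df = df, count = count))
  vals <- tr_flat$s0_fun(1:30)
  expect_lt(max(vals) / min(vals), 1.10)

  # variance proportional to 1/count: fitted log-log slope ~ -1
  s2_avg <- (0.1 / count) * rchisq(n, 2) / 2
  tr_avg <- fit_variance_trend(
    data.frame(s2 = s2_avg, df = df, count = count))
  grid <- 1:30
  slope <- coef(lm(log(tr_avg$s0_fun(grid)) ~ log(grid)))[2]
  expect_equal(unname(slope), -1, tolerance = 0.15)
})

test_that("degenerate trends: single distinct count gives a constant trend; all-zero variances hit the cap", {
  set.seed(4)
  fits <- data.frame(s2 = 0.02 * rchisq(100, 2) / 2,
                     df = 2, count = rep(5, 100))
  tr <- fit_variance_trend(fits)
  expect_equal(tr$method, "constant")
  expect_equal(tr$s0_fun(1), tr$s0_fun(50))  # flat everywhere

  tr0 <- fit_variance_trend(data.frame(s2 = rep(0, 30), df = 2, count = 5))
  expect_equal(tr0$d0, tr0$d0_cap)
  expect_equal(tr0$method, "constant")
})

test_that("scaled-F simulation: prior variance and prior df are recovered", {
  # s2 = s0^2 * F(d, d0): the estimator should recover both parameters
  set.seed(33)
  n <- 20000; d <- 2; d0_true <- 10; s0_true <- 0.04
  s2 <- s0_true * rf(n, d, d0_true)
  fits <- data.frame(s2 = s2, df = d, count = rep(4, n))
  tr <- fit_variance_trend(fits)
  expect_equal(tr$d0, d0_true, tolerance = 0.25)
  expect_equal(tr$s0_fun(4), s0_true, tolerance = 0.05)
})

test_that("constant-trend moderation agrees with the limma empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(7)
  n <- 2000; d <- 2
  s2 <- 0.05 * rf(n, d, 8)
  fits <- data.frame(s2 = s2, df = d, count = rep(3, n))
  tr <- fit_variance_trend(fits)
  ref <- limma::fitFDist(s2, df1 = d)
  expect_equal(tr$d0, ref$df2, tolerance = 1e-4)
  expect_equal(tr$s0_fun(3), ref$scale, tolerance = 1e-4)
})

test_that("moderated t with d0 = 0 equals the ordinary paired t-test to 1e-10", {
  set.seed(11)
  delta <- matrix(rnorm(20 * 3, sd = 0.3), 20, 3,
                  dimnames = list(paste0("G", 1:20), NULL))
  pq <- make_pq(matrix(0, 20, 3, dimnames = dimnames(delta)), delta)
  fit <- fit_paired_model(pq, "C", treatment = 60)
  mod <- moderate_statistics(fit, trend = NULL, d0 = 0)
  oracle <- oracle_paired_t(delta[fit$gene, ])
  expect_equal(mod$logFC, oracle$logFC, tolerance = 1e-12)
  expect_equal(mod$t, oracle$t, tolerance = 1e-10)
  expect_equal(mod$P, oracle$P, tolerance = 1e-10)
})

test_that("moderated t at the d0 cap reproduces the known-variance normal case", {
  set.seed(12)
  fits <- data.frame(
    gene = paste0("G", 1:50),
    logFC = rnorm(50, sd = 0.2), s2 = rchisq(50, 2) / 40,
    df = 2, n_pairs = 3, count = sample(1:9, 50, TRUE))
  s0 <- 0.03
  trend <- structure(list(s0_fun = function(n) rep(s0, length(n)),
                          d0 = 1e6, d0_cap = 1e6, method = "constant"),
                     class = "variance_trend")
  mod <- moderate_statistics(fits, trend)
  expect_equal(mod$posterior_var, rep(s0, 50))   # s2 fully shrunk away
  z <- fits$logFC / sqrt(s0 / 3)
  expect_equal(mod$P, 2 * pnorm(-abs(z)), tolerance = 1e-6)
})

test_that("moderated P is monotone decreasing in |logFC| and zero effect gives t = 0, P = 1", {
  fits <- data.frame(
    gene = paste0("G", 1:9),
    logFC = c(0, 0.05, -0.1, 0.2, -0.4, 0.6, -0.8, 1.2, -2),
    s2 = 0.04, df = 2, n_pairs = 3, count = 4)
  trend <- structure(list(s0_fun = function(n) rep(0.04, length(n)),
                          d0 = 6, d0_cap = 1e6, method = "constant"),
                     class = "variance_trend")
  mod <- moderate_statistics(fits, trend)
  expect_equal(mod$t[1], 0)
  expect_equal(mod$P[1], 1)
  ord <- order(abs(fits$logFC))
  expect_true(all(diff(mod$P[ord]) <= 0))
  expect_true(all(sign(mod$t) == sign(fits$logFC) | fits$logFC == 0))
  expect_true(all(mod$P > 0 & mod$P <= 1))
})

test_that("full fit object reports per-contrast trends and coef() returns the fold-change matrix", {
  sim <- simulate_experiment(simulation_config(n_proteins = 120,
                                               n_decoys = 0, seed = 6))
  ratios <- normalize_sample_median(compute_psm_ratios(sim$psms, sim$design))
  pq <- filter_full_quantitation(rollup_to_protein(ratios, sim$design))
  fit <- fit_fraction_diff(pq)
  expect_s3_class(fit, "fraction_diff")
  expect_setequal(unique(fit$stats$contrast), c(15, 60))
  fc <- coef(fit, contrast = 60)
  expect_equal(colnames(fc), c("C", "M", "N"))
  expect_true(all(rownames(fc) %in% rownames(pq$log2ratio)))
  expect_output(print(fit), "paired moderated fit")
  smry <- summary(fit)
  expect_output(print(smry), "translocation calls")
})
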