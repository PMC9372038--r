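test_that("the degenerate one-component fit has a closed form", {
  x <- rep(12.5, 6)
  sigma <- c(1, 1, 2, 2, 0.5, 3)
  fit <- fit_gaussian_mixture(x, sigma, K = 1, n_start = 1)
  expect_equal(fit$means, 12.5)
  expect_equal(fit$loglik, sum(dnorm(x, 12.5, sigma, log = TRUE)))
  # K = 1 in general: mean is the inverse-variance weighted mean
  set.seed(1)
  x2 <- rnorm(10, 50, 2)
  s2 <- runif(10, 0.5, 2)
  fit2 <- fit_gaussian_mixture(x2, s2, K = 1, n_start = 1)
  expect_equal(fit2$means, sum(x2 / s2^2) / sum(1 / s2^2), tolerance = 1e-8)
})

test_that("two well-separated clusters are recovered close to their means", {
  set.seed(21)
  x <- c(rnorm(20, 10, 1), rnorm(20, 90, 1))
  sigma <- rep(1, 40)
  fit <- fit_gaussian_mixture(x, sigma, K = 2, n_start = 5)
  # oracle: split at the midpoint, take cluster sample means
  oracle <- c(mean(x[x < 50]), mean(x[x >= 50]))
  expect_lt(max(abs(fit$means - oracle)), 0.5)
  # all five criteria prefer K = 2 here
  crit <- dplyr::bind_rows(lapply(1:6, function(K)
    compute_criteria(fit_gaussian_mixture(x, sigma, K, n_start = 5))))
  for (cn in c("AIC", "AICc", "AIC3", "BIC", "AWE")) {
    expect_equal(crit$K[which.min(crit[[cn]])], 2)
  }
})

test_that("adding a component never lowers the optimal log-likelihood", {
  set.seed(33)
  x <- c(rnorm(4, 5, 0.5), rnorm(3, 30, 0.5))
  sigma <- rep(0.5, 7)
  lls <- vapply(1:4, function(K)
    fit_gaussian_mixture(x, sigma, K, n_start = 30)$loglik, numeric(1))
  expect_true(all(diff(lls) > -1e-6))
  expect_error(fit_gaussian_mixture(x, sigma, K = 8), "K exceeds n")
})

test_that("criterion formulas follow their definitions", {
  set.seed(4)
  x <- c(rnorm(10, 5, 1), rnorm(10, 40, 1))
  fit <- fit_gaussian_mixture(x, rep(1, 20), K = 2, n_start = 3)
  crit <- compute_criteria(fit)
  d <- 2 * fit$K - 1
  n <- 20
  expect_equal(crit$AIC, -2 * fit$loglik + 2 * d)
  expect_equal(crit$AICc, crit$AIC + 2 * d * (d + 1) / (n - d - 1))
  expect_equal(crit$AIC3, -2 * fit$loglik + 3 * d)
  expect_equal(crit$BIC, -2 * fit$loglik + d * log(n))
  expect_lt(crit$AIC - crit$BIC, 0)     # 2d < d log n for n = 20
  # AICc undefined when n - d - 1 <= 0: n = 4, K = 2 -> d = 3
  small <- fit_gaussian_mixture(c(1, 2, 30, 31), rep(1, 4), K = 2, n_start = 3)
  expect_true(is.na(compute_criteria(small, n = 4)$AICc))
})

test_that("model selection needs three of five votes, else falls back to BIC", {
  tab <- function(aic, aicc, aic3, bic, awe) {
    tibble::tibble(K = seq_along(aic), loglik = 0, AIC = aic, AICc = aicc,
                   AIC3 = aic3, BIC = bic, AWE = awe)
  }
  # K=2 wins AIC, AICc, AIC3; K=1 wins BIC, AWE -> K=2
  sel <- select_model(tab(c(10, 5), c(10, 5), c(10, 5), c(5, 10), c(5, 10)))
  expect_equal(sel$K, 2)
  expect_equal(sel$rule, "vote")
  # unanimous K=1
  sel1 <- select_model(tab(c(1, 2), c(1, 2), c(1, 2), c(1, 2), c(1, 2)))
  expect_equal(sel1$K, 1)
  # 2/2/1 split -> BIC-minimal K
  sel2 <- select_model(tab(c(5, 10, 20), c(5, 10, 20),   # K=1 takes AIC, AICc
                           c(20, 5, 10),                 # K=2 takes AIC3
                           c(20, 10, 5), c(20, 10, 5)))  # K=3 takes BIC, AWE
  expect_equal(sel2$K, 3)
  expect_equal(sel2$rule, "bic_fallback")
})

test_that("EM log-likelihood matches the brute-force hard-assignment oracle", {
  set.seed(9)
  for (rep in 1:5) {
    n <- sample(5:8, 1)
    n1 <- sample(2:(n - 2), 1)
    x <- c(rnorm(n1, 10, 0.3), rnorm(n - n1, 60, 0.3))
    sigma <- runif(n, 0.4, 1.2)
    for (K in 1:2) {
      em <- fit_gaussian_mixture(x, sigma, K, n_start = 20)
      oracle <- brute_force_gmm_loglik(x, sigma, K)
      expect_equal(em$loglik, oracle, tolerance = 1e-6)
    }
  }
})

test_that("MQTL formation applies membership, discard and naming rules", {
  set.seed(14)
  x <- c(rnorm(6, 20, 0.5), rnorm(6, 80, 0.5), rnorm(3, 140, 0.5))
  sigma <- rep(0.5, 15)
  members <- tibble::tibble(
    qtl_id = paste0("q", 1:15),
    study_id = c(rep(c("s1", "s2", "s3"), 4), rep("s9", 3)), # third cluster: one study
    stress = c(rep(c("DS", "HS", "SS", "D+H", "PHS", "AS"), 2), rep("WS", 3)),
    lod = 5, pve = rep(c(8, 12, 10), 5))
  fit <- fit_gaussian_mixture(x, sigma, K = 3, n_start = 5)
  fm <- form_mqtls(fit, members, chromosome = "1A")
  expect_equal(nrow(fm$mqtls), 2)
  expect_equal(fm$mqtls$mqtl, c("MQTL1A.1", "MQTL1A.2")) # named by position
  expect_equal(fm$discards$reason, "single_study")
  # inverse-variance position and CI
  idx <- 1:6
  expect_equal(fm$mqtls$position_cm[1],
               sum(x[idx] / sigma[idx]^2) / sum(1 / sigma[idx]^2))
  expect_equal(fm$mqtls$ci_end_cm[1] - fm$mqtls$ci_start_cm[1],
               2 * 1.96 / sqrt(sum(1 / sigma[idx]^2)))
  # D+H counts toward both drought and heat in the tally
  tal <- parse_stress_tally(fm$mqtls$stress_tally[1])[[1]]
  expect_equal(unname(tal["DS"] >= 2), TRUE)
  expect_true(all(c("DS", "HS") %in% names(tal)))
})

test_that("a singleton component is set aside and pooling never widens the CI", {
  set.seed(3)
  x <- c(rnorm(8, 30, 0.4), 95)
  sigma <- runif(9, 0.4, 1.5)
  members <- tibble::tibble(qtl_id = paste0("q", 1:9),
                            study_id = rep(c("s1", "s2", "s3"), 3),
                            stress = "DS", lod = 4, pve = 10)
  fit <- fit_gaussian_mixture(x, sigma, K = 2, n_start = 5)
  fm <- form_mqtls(fit, members, "2B")
  expect_true("singleton" %in% fm$discards$reason)
  mem_ci <- 3.92 * sigma[1:8]
  expect_lte(fm$mqtls$ci_end_cm[1] - fm$mqtls$ci_start_cm[1], min(mem_ci))
  # mean PVE is the arithmetic mean of members
  expect_equal(fm$mqtls$mean_pve, 10)
})

test_that("meta_qtl recovers the planted components on synthetic chromosomes", {
  sc <- simulate_scenario(seed = 19)
  st <- simulate_studies(sc)
  cmap <- build_consensus(st$reference_maps)
  q <- estimate_ci(impute_defaults(validate_qtls(st$qtls), st$study_maps))
  pr <- project_qtls(q, st$study_maps, cmap)
  m <- meta_qtl(pr, k_max = 6, n_start = 5, seed = 7)
  truthK <- table(st$truth$chromosome)
  for (ch in names(truthK)) {
    expect_equal(m$selection$K[m$selection$chromosome == ch],
                 as.integer(truthK[[ch]]))
  }
  # every recovered position within 1 cM of a distinct true position
  for (ch in names(truthK)) {
    got <- sort(m$mqtls$position_cm[m$mqtls$chromosome == ch])
    want <- sort(st$truth$position_cm[st$truth$chromosome == ch])
    expect_equal(length(got), length(want))
    expect_lt(max(abs(got - want)), 1)
  }
  g <- glance(m)
  expect_gt(g$ci_fold_reduction, 1)
  expect_equal(tidy(m), m$mqtls)
})
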