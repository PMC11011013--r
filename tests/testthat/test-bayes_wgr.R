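test_that("chain schedule arithmetic and stored samples agree", {
  cfg <- bayes_config("BayesC", pi = 0.995)
  expect_equal(retained_samples(cfg), 10000L)
  expect_error(bayes_config(chain_length = 1005, burn_in = 100, thin = 10),
               "multiple")

  set.seed(61)
  g <- make_geno(matrix(rbinom(20 * 10, 2, 0.4), 20, 10))
  dv <- data.frame(animal = animal_ids(g), debv = rnorm(20))
  fit <- fit_bayes(g, dv, bayes_config("BayesC", pi = 0.5,
                                       chain_length = 1100, burn_in = 100,
                                       thin = 10, seed = 62))
  expect_equal(fit$retained, 100L)
  expect_equal(ncol(fit$samples), 100L)
  expect_equal(nrow(fit$variance_samples), 100L)
  expect_true(all(fit$effects$model_freq >= 0 & fit$effects$model_freq <= 1))
})

test_that("the sampler is deterministic under a seed", {
  set.seed(63)
  g <- make_geno(matrix(rbinom(30 * 20, 2, 0.3), 30, 20))
  dv <- data.frame(animal = animal_ids(g), debv = rnorm(30))
  cfg <- bayes_config("BayesB", pi = 0.8, chain_length = 600,
                      burn_in = 100, thin = 5, seed = 64)
  f1 <- fit_bayes(g, dv, cfg)
  f2 <- fit_bayes(g, dv, cfg)
  expect_identical(f1$effects, f2$effects)
  expect_identical(f1$variance_samples, f2$variance_samples)
})

test_that("BayesC with pi 0 and fixed variances reproduces weighted ridge", {
  set.seed(11)
  n <- 20; k <- 50
  Z <- matrix(rbinom(n * k, 2, 0.4), n, k)
  g <- make_geno(Z)
  y <- rnorm(n)
  s2u <- 0.01; s2e <- 0.5
  fit <- fit_bayes(g, data.frame(animal = animal_ids(g), debv = y),
                   bayes_config("BayesC", pi = 0, chain_length = 6000,
                                burn_in = 1000, thin = 5,
                                fix_marker_variance = TRUE,
                                fix_residual_variance = TRUE,
                                sigma_u2 = s2u, sigma_e2 = s2e, seed = 3))
  Zc <- scale(Z, center = TRUE, scale = FALSE)
  ridge <- drop(solve(crossprod(Zc) + diag(s2e / s2u, k), crossprod(Zc, y)))
  se <- apply(fit$samples, 1, sd) / sqrt(fit$retained)
  expect_true(all(abs(fit$effects$posterior_mean - ridge) < 3 * se + 1e-4))
  expect_true(all(fit$effects$model_freq == 1))
})

test_that("null data recover the prior inclusion rate", {
  set.seed(4)
  n <- 300; k <- 300
  g <- make_geno(matrix(rbinom(n * k, 2, 0.3), n, k))
  fit <- fit_bayes(g, data.frame(animal = animal_ids(g), debv = rnorm(n)),
                   bayes_config("BayesC", pi = 0.9, chain_length = 3000,
                                burn_in = 1000, thin = 4, seed = 5,
                                store_samples = FALSE))
  expect_lt(abs(mean(fit$effects$model_freq) - 0.1), 0.05)
  # sum of model frequencies ~ k * (1 - pi)
  expect_lt(abs(sum(fit$effects$model_freq) - k * 0.1), 0.5 * k * 0.1)
})

test_that("molecular breeding values behave like linear predictors", {
  g <- make_geno(matrix(c(0, 1, 2, 2, 1, 0), 3, 2,
                        dimnames = list(c("p", "q", "r"), c("s1", "s2"))))
  z <- predict_mbv(g, c(s1 = 0, s2 = 0), coding = "dosage012")
  expect_equal(z$mbv, c(0, 0, 0))
  one <- predict_mbv(g, c(s1 = 1, s2 = 0), centers = c(1, 0),
                     coding = "dosage012")
  expect_equal(one$mbv, c(-1, 0, 1))
  expect_error(predict_mbv(g, c(s1 = 1, s2 = 0)), "coding")
  expect_error(predict_mbv(g, c(sX = 1), coding = "dosage012"), "sX")
})

test_that("predictions are exchangeable and coding-invariant", {
  set.seed(66)
  g <- make_geno(matrix(rbinom(40 * 30, 2, 0.4), 40, 30))
  dv <- data.frame(animal = animal_ids(g), debv = rnorm(40))
  cfg <- bayes_config("BayesC", pi = 0.5, chain_length = 800, burn_in = 200,
                      thin = 3, seed = 67, store_samples = FALSE)
  fit <- fit_bayes(g, dv, cfg)
  mbv <- predict(fit, g)

  perm <- sample(nrow(g$calls))
  gp <- geno_matrix(g$calls[perm, , drop = FALSE], g$map)
  mbv_p <- predict(fit, gp)
  expect_equal(mbv_p$mbv[match(mbv$animal, mbv_p$animal)], mbv$mbv)

  # the GenSel -10/0/10 dialect converts internally to the same MBV
  g10 <- convert_coding(g, "gensel_pm10")
  expect_equal(predict(fit, g10)$mbv, mbv$mbv)
  fit10 <- fit_bayes(g10, dv, cfg)
  expect_equal(fit10$effects$posterior_mean, fit$effects$posterior_mean)
})

test_that("a huge record weight pins that record's fitted value", {
  set.seed(6)
  n <- 12; k <- 60
  g <- make_geno(matrix(rbinom(n * k, 2, 0.5), n, k))
  y <- rnorm(n)
  w <- rep(1, n); w[4] <- 1e6
  fit <- fit_bayes(g, data.frame(animal = animal_ids(g), debv = y,
                                 weight = w),
                   bayes_config("BayesC", pi = 0, chain_length = 6000,
                                burn_in = 1000, thin = 5, seed = 7,
                                store_samples = FALSE))
  fitted4 <- fit$mu + predict(fit, g)$mbv[4]
  expect_lt(abs(y[4] - fitted4), 0.01)
})

test_that("markers with large true effects earn higher model frequency", {
  pop <- sim_population(n_founders = 200, n_gen = 1, opm = 2,
                        n_snps = 500, seed = 71)
  tr <- simulate_trait(pop$geno, pi = 0.95, h2 = 0.4, seed = 72)
  dv <- data.frame(animal = tr$animals$animal, debv = tr$animals$y)
  fit <- fit_bayes(pop$geno, dv,
                   bayes_config("BayesB", pi = 0.95, chain_length = 1500,
                                burn_in = 500, thin = 2, seed = 73,
                                store_samples = FALSE))
  absu <- abs(tr$effects$true_effect)
  top <- absu > quantile(absu, 0.9)   # strict: the null mass sits at zero
  expect_gt(mean(fit$effects$model_freq[top]),
            mean(fit$effects$model_freq))
})
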