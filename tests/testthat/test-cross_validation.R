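test_that("tabular relationships match textbook values", {
  # founders are an identity block
  ped <- pedigree(data.frame(animal = c("A", "B"), sire = "0", dam = "0"))
  expect_equal(unname(build_nrm(ped)), diag(2))

  # parent-offspring 0.5; full sibs 0.5; offspring of full sibs F = 0.25
  ped2 <- pedigree(data.frame(
    animal = c("A", "B", "C", "D", "E"),
    sire = c("0", "0", "A", "A", "C"),
    dam = c("0", "0", "B", "B", "D")))
  A <- build_nrm(ped2)
  expect_equal(A["A", "C"], 0.5)
  expect_equal(A["C", "D"], 0.5)
  expect_equal(A["E", "E"], 1.25)
  expect_equal(inbreeding(A)[["E"]], 0.25)

  # plain data frames are re-sorted with a warning
  expect_warning(
    A2 <- build_nrm(data.frame(animal = c("C", "A", "B"),
                               sire = c("A", "0", "0"),
                               dam = c("B", "0", "0"))),
    "re-sorted")
  expect_equal(A2["A", "C"], 0.5)
})

test_that("tabular recursion agrees with path counting on small pedigrees", {
  for (p in enum_peds(3)) {
    expect_equal(tabular_nrm_idx(p$sire, p$dam),
                 path_nrm(p$sire, p$dam), tolerance = 1e-12)
  }
  set.seed(91)
  for (r in 1:10) {
    p <- rand_ped_idx(sample(5:7, 1))
    expect_equal(tabular_nrm_idx(p$sire, p$dam),
                 path_nrm(p$sire, p$dam), tolerance = 1e-12)
  }
})

test_that("K-means folds separate families and are deterministic", {
  # two unrelated half-sib families must split exactly at k = 2
  fam <- function(tag) data.frame(
    animal = paste0(tag, c("s", "d1", "d2", "o1", "o2", "o3", "o4")),
    sire = c("0", "0", "0", rep(paste0(tag, "s"), 4)),
    dam = c("0", "0", "0", paste0(tag, c("d1", "d1", "d2", "d2"))))
  ped <- pedigree(rbind(fam("L"), fam("R")))
  A <- build_nrm(ped)
  folds <- kmeans_folds(A, k = 2, seed = 1, restarts = 10)
  fl <- folds$fold[match(ped$animal, folds$animal)]
  left <- startsWith(ped$animal, "L")
  expect_equal(length(unique(fl[left])), 1)
  expect_equal(length(unique(fl[!left])), 1)
  expect_false(unique(fl[left]) == unique(fl[!left]))

  # animals at zero distance (relationship 1) always co-cluster
  At <- matrix(0.05, 6, 6); diag(At) <- 1
  At[1, 2] <- At[2, 1] <- 1   # "identical twins"
  rownames(At) <- colnames(At) <- paste0("t", 1:6)
  ftw <- kmeans_folds(At, k = 3, seed = 2, restarts = 10)
  expect_equal(ftw$fold[1], ftw$fold[2])

  f1 <- kmeans_folds(A, k = 2, seed = 9, restarts = 5)
  f2 <- kmeans_folds(A, k = 2, seed = 9, restarts = 5)
  expect_identical(f1, f2)
  expect_error(kmeans_folds(A, k = 50), "folds")
})

test_that("relatedness diagnostics summarise within and between folds", {
  # all founders: identity matrix, every statistic collapses to zero
  A <- diag(10); rownames(A) <- colnames(A) <- paste0("f", 1:10)
  folds <- structure(tibble::tibble(animal = rownames(A),
                                    fold = rep(1:2, each = 5)),
                     class = c("cv_folds", class(tibble::tibble())))
  st <- cluster_relatedness_stats(A, folds)
  expect_equal(st$inBreC, c(0, 0, 0))
  expect_equal(st$a_ij_within, c(0, 0, 0))
  expect_equal(st$a_ij_between, c(0, 0, 0))
  expect_equal(st$fold, c("1", "2", "Avg."))
  # the average row is the unweighted mean of the per-fold values
  expect_equal(st$n_animals[3], 10)

  # family-structured data reproduce the within > between pattern
  ped <- simulate_pedigree(60, 2, 3, seed = 95)
  Af <- build_nrm(ped)
  ff <- kmeans_folds(Af, k = 5, seed = 96, restarts = 10)
  stf <- cluster_relatedness_stats(Af, ff)
  avg <- stf[stf$fold == "Avg.", ]
  expect_lt(avg$a_ij_between, avg$a_ij_within)
  per <- stf[stf$fold != "Avg.", ]
  expect_equal(avg$a_ij_within, mean(per$a_ij_within))
})

test_that("cross-validation estimates accuracy and detects leakage", {
  pop <- sim_population(n_founders = 150, n_gen = 1, opm = 2,
                        n_snps = 300, seed = 97)
  tr <- simulate_trait(pop$geno, pi = 0.9, h2 = 0.5, seed = 98)
  eb <- simulate_ebv_records(tr, pop$ped, 0.5, 0.9, seed = 99)
  tp <- trait_params("T", 0.5, 0.5)
  dv <- deregress(eb, tp, "incPA")
  A <- build_nrm(pop$ped)
  folds <- kmeans_folds(A, k = 3, seed = 100, restarts = 10)
  cfg <- bayes_config("BayesC", pi = 0.9, chain_length = 800, burn_in = 200,
                      thin = 3, seed = 101, store_samples = FALSE)
  cv <- run_cv(pop$geno, dv, folds, cfg)
  expect_equal(nrow(cv), 3)
  expect_true(all(abs(cv$accuracy) <= 1, na.rm = TRUE))
  g <- glance(cv)
  expect_gte(g$se, 0)
  expect_gt(g$mean_accuracy, 0)

  # permuting the response wipes out the signal
  set.seed(102)
  dvp <- dv
  dvp$debv <- sample(dvp$debv)
  cvp <- run_cv(pop$geno, dvp, folds, cfg)
  expect_lt(abs(glance(cvp)$mean_accuracy), g$mean_accuracy)
  expect_lt(abs(glance(cvp)$mean_accuracy), 0.25)

  # leakage control: validating on the training fold flatters accuracy
  train1 <- dv[folds$fold[match(dv$animal, folds$animal)] != 1, ]
  valid1 <- dv[folds$fold[match(dv$animal, folds$animal)] == 1, ]
  cfg1 <- cfg; cfg1$seed <- cfg$seed + 1
  fit_out <- fit_bayes(pop$geno, train1, cfg1)
  fit_in <- fit_bayes(pop$geno, valid1, cfg1)
  mbv_out <- predict(fit_out, pop$geno)
  mbv_in <- predict(fit_in, pop$geno)
  acc_out <- cor(mbv_out$mbv[match(valid1$animal, mbv_out$animal)],
                 valid1$debv)
  acc_in <- cor(mbv_in$mbv[match(valid1$animal, mbv_in$animal)],
                valid1$debv)
  expect_gt(acc_in, acc_out)
})

test_that("accuracy is invariant to the genotype coding dialect", {
  pop <- sim_population(n_founders = 100, n_gen = 1, opm = 2,
                        n_snps = 150, seed = 103)
  tr <- simulate_trait(pop$geno, pi = 0.8, h2 = 0.5, seed = 104)
  dv <- tibble::tibble(animal = tr$animals$animal, debv = tr$animals$y,
                       weight = 1)
  A <- build_nrm(pop$ped)
  folds <- kmeans_folds(A, k = 3, seed = 105, restarts = 5)
  cfg <- bayes_config("BayesC", pi = 0.8, chain_length = 500, burn_in = 100,
                      thin = 2, seed = 106, store_samples = FALSE)
  cv1 <- run_cv(pop$geno, dv, folds, cfg)
  cv2 <- run_cv(convert_coding(pop$geno, "gensel_pm10"), dv, folds, cfg)
  expect_equal(cv1$accuracy, cv2$accuracy, tolerance = 1e-10)
})
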