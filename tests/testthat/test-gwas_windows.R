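test_that("window assignment follows the chr_Mb convention", {
  map <- marker_map(data.frame(
    snp_id = c("w", "x", "y", "z"),
    chr = c(6, 1, 1, 1),
    pos_bp = c(88500000, 1, 1000000, 1000001)))
  w <- assign_windows(map)
  expect_equal(w$window_id[w$snp_id == "w"], "6_88")
  expect_equal(w$mb[w$snp_id == "x"], 0L)
  expect_equal(w$mb[w$snp_id == "y"], 0L)   # closed right edge at 1 Mb
  expect_equal(w$mb[w$snp_id == "z"], 1L)
  # partition: every SNP in exactly one window
  expect_equal(nrow(w), nrow(map))
  expect_false(anyNA(w$window_id))
})

test_that("window shares sum to 100 and respect a planted architecture", {
  pop <- sim_population(n_founders = 300, n_gen = 1, opm = 2,
                        n_snps = 400, seed = 81, n_chr = 4,
                        spacing_bp = 100000)   # 10 windows of 10 SNPs per chr
  win <- assign_windows(pop$geno$map)
  causal <- which(win$window_id[match(pop$geno$map$snp_id, win$snp_id)] == "2_3")
  tr <- simulate_trait(pop$geno, pi = 0.975, h2 = 0.5, seed = 82,
                       causal_idx = causal)
  dv <- data.frame(animal = tr$animals$animal, debv = tr$animals$y)
  fit <- fit_bayes(pop$geno, dv,
                   bayes_config("BayesC", pi = 0.975, chain_length = 2000,
                                burn_in = 500, thin = 3, seed = 83))
  wp <- window_variance_profile(fit, pop$geno)
  expect_equal(sum(wp$gv_percent), 100, tolerance = 1e-8)
  expect_equal(sum(wp$n_snps), 400L)
  expect_gt(wp$gv_percent[wp$window_id == "2_3"], 50)
  others <- wp$gv_percent[wp$window_id != "2_3"]
  expect_lt(max(others), 10)

  # flagging picks the causal window and reports its member SNPs
  sig <- select_significant(wp)
  expect_true("2_3" %in% sig$window_id)
  info <- informative_snps(wp, fit)
  expect_true(all(info$window_id %in% wp$window_id[wp$significant]))
  expect_true(all(info$model_freq >= 0 & info$model_freq <= 1))
})

test_that("share bookkeeping is invariant to the variance denominator", {
  pop <- sim_population(n_founders = 100, n_gen = 1, opm = 2,
                        n_snps = 100, seed = 84, n_chr = 2,
                        spacing_bp = 200000)
  tr <- simulate_trait(pop$geno, pi = 0.5, h2 = 0.4, seed = 85)
  fit <- fit_bayes(pop$geno,
                   data.frame(animal = tr$animals$animal, debv = tr$animals$y),
                   bayes_config("BayesC", pi = 0.5, chain_length = 600,
                                burn_in = 100, thin = 5, seed = 86))
  wp <- window_variance_profile(fit, pop$geno)
  # recompute with the sample (1/(n-1)) variance: shares are scale-free
  Z <- dosage_calls(pop$geno)[fit$animals, fit$effects$snp_id]
  Zc <- sweep(Z, 2, fit$centers)
  win <- assign_windows(fit$map)
  wid <- win$window_id[match(colnames(Zc), win$snp_id)]
  V <- sapply(seq_len(ncol(fit$samples)), function(s) {
    g <- sapply(unique(wid), function(wd)
      var(drop(Zc[, wid == wd, drop = FALSE] %*%
                 fit$samples[wid == wd, s])))
  })
  gv2 <- rowMeans(sweep(V, 2, colSums(V), "/") * 100)
  expect_equal(wp$gv_percent[match(unique(wid), wp$window_id)],
               unname(gv2), tolerance = 1e-8)
})

test_that("the infinitesimal expectation and enrichment scale with W", {
  # a symmetric null-ish profile: equal windows, shares near 100/W
  prof <- structure(
    tibble::tibble(window_id = paste0("1_", 0:99), chr = 1L, mb = 0:99,
                   n_snps = 5L, gv_percent = rep(1, 100),
                   significant = TRUE),
    class = c("window_profile", class(tibble::tibble())))
  sig <- select_significant(prof, gv_threshold = 1)
  expect_equal(attr(sig, "infinitesimal_gv"), 1)
  expect_equal(attr(sig, "enrichment_factor"), 1)
  expect_equal(nrow(sig), 100)   # gv exactly at the threshold is flagged

  prof2524 <- structure(
    tibble::tibble(window_id = paste0("x_", seq_len(2524)), chr = 1L,
                   mb = seq_len(2524), n_snps = 1L,
                   gv_percent = 100 / 2524, significant = FALSE),
    class = c("window_profile", class(tibble::tibble())))
  sig2 <- select_significant(prof2524, gv_threshold = 1)
  expect_equal(attr(sig2, "enrichment_factor"), 2524 / 100)
  expect_equal(round(attr(sig2, "infinitesimal_gv"), 2), 0.04)
})

test_that("GFF3 gene spans reduce to annotation intervals", {
  skip_if_not_installed("rtracklayer")
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "6\ttest\tgene\t88700000\t88800000\t.\t+\t.\tID=gene1;Name=GC",
    "6\ttest\tmRNA\t88700000\t88800000\t.\t+\t.\tID=rna1;Parent=gene1",
    "15\ttest\tgene\t55100000\t55250000\t.\t-\t.\tID=gene2;Name=GDPD5"),
    path)
  gi <- read_gene_intervals(path)
  expect_equal(nrow(gi), 2)
  expect_setequal(gi$symbol, c("GC", "GDPD5"))
  expect_equal(gi$start[gi$symbol == "GC"], 88700000)
  ann <- annotate_nearest_gene(
    tibble::tibble(snp_id = "s", chr = 6, pos_bp = 88500000), gi)
  expect_equal(ann$symbol, "GC")
  expect_equal(ann$distance_bp, 200000L)
})

test_that("null traits leave every window below the threshold", {
  # pure-noise responses over 200 windows (expectation 0.5%): a dense
  # mixture (pi = 0.75) spreads posterior variance thinly, so no window
  # reaches the 1% significance level in any replicate
  flagged <- integer(3)
  for (s in 1:3) {
    ped <- simulate_pedigree(400, 1, 3, seed = 500 + s)
    g <- gene_drop_genotypes(ped, 2000, seed = 600 + s, n_chr = 10,
                             spacing_bp = 100000)
    set.seed(700 + s)
    y <- rnorm(nrow(g$calls))
    fit <- fit_bayes(g, data.frame(animal = animal_ids(g), debv = y),
                     bayes_config("BayesC", pi = 0.75, chain_length = 2500,
                                  burn_in = 500, thin = 4, seed = 800 + s))
    wp <- window_variance_profile(fit, g)
    flagged[s] <- sum(wp$significant)
  }
  expect_true(all(flagged == 0))
})

test_that("nearest-gene annotation classifies and measures distances", {
  genes <- tibble::tibble(chr = c(6, 6, 6),
                          start = c(88700000, 88100000, 89100000),
                          end = c(88800000, 88200000, 89200000),
                          symbol = c("GC", "AAA", "ZZZ"))
  snps <- tibble::tibble(snp_id = c("inside", "upstream"),
                         chr = 6,
                         pos_bp = c(88750000, 88547862))
  ann <- annotate_nearest_gene(snps, genes)
  expect_equal(ann$distance_bp[ann$snp_id == "inside"], 0L)
  expect_equal(ann$variant_class[ann$snp_id == "inside"], "genic")
  up <- ann[ann$snp_id == "upstream", ]
  expect_equal(up$symbol, "GC")
  expect_equal(up$distance_bp, 152138L)
  expect_equal(up$annotation, "GC (152,138)")

  # equidistant genes: both reported, ordered by symbol
  g2 <- tibble::tibble(chr = 1, start = c(2000, 4000), end = c(2500, 4500),
                       symbol = c("B", "A"))
  s2 <- tibble::tibble(snp_id = "mid", chr = 1, pos_bp = 3250)
  tie <- annotate_nearest_gene(s2, g2)
  expect_equal(tie$symbol, c("A", "B"))
  expect_equal(tie$distance_bp, c(750L, 750L))

  # chromosome without intervals
  s3 <- tibble::tibble(snp_id = "lonely", chr = 9, pos_bp = 100)
  expect_true(is.na(annotate_nearest_gene(s3, genes)$symbol))
})
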