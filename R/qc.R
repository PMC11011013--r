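#' Per-SNP quality-control statistics
#'
#' For each SNP: genotype counts among non-missing calls, call rate,
#' minor allele frequency, and a Hardy-Weinberg equilibrium p-value.
#' The default HWE test is the Pearson chi-square with 1 df on observed
#' versus HWE-expected genotype counts; `hwe_test = "exact"` switches to
#' the exact conditional test (sum over heterozygote counts no less
#' probable than the observed one).
#'
#' @param geno a `geno_matrix`.
#' @param hwe_test `"chisq"` (default) or `"exact"`.
#' @return Tibble with one row per SNP: `snp_id`, `n0`, `n1`, `n2`,
#'   `call_rate`, `maf`, `hwe_p`. SNPs with zero non-missing calls get
#'   `call_rate` 0 and `NA` for `maf`/`hwe_p` (still filterable).
#' @export
snp_stats <- function(geno, hwe_test = c("chisq", "exact")) {
  hwe_test <- match.arg(hwe_test)
  stopifnot(inherits(geno, "geno_matrix"))
  Z <- dosage_calls(geno)
  n_animals <- nrow(Z)
  n0 <- colSums(Z == 0, na.rm = TRUE)
  n1 <- colSums(Z == 1, na.rm = TRUE)
  n2 <- colSums(Z == 2, na.rm = TRUE)
  m <- n0 + n1 + n2
  p <- ifelse(m > 0, (2 * n2 + n1) / (2 * m), NA_real_)
  maf <- pmin(p, 1 - p)
  hwe_p <- if (hwe_test == "chisq") {
    hwe_chisq_p(n0, n1, n2)
  } else {
    purrr::pmap_dbl(list(n0, n1, n2), hwe_exact_p)
  }
  tibble::tibble(snp_id = colnames(Z), n0 = as.integer(n0),
                 n1 = as.integer(n1), n2 = as.integer(n2),
                 call_rate = unname(m / n_animals), maf = unname(maf),
                 hwe_p = unname(hwe_p))
}

# Pearson 1-df chi-square HWE p-value, vectorized over loci.
hwe_chisq_p <- function(n0, n1, n2) {
  m <- n0 + n1 + n2
  p <- (2 * n2 + n1) / (2 * m)
  e0 <- m * (1 - p)^2; e1 <- m * 2 * p * (1 - p); e2 <- m * p^2
  chi <- rep(NA_real_, length(m))
  ok <- m > 0 & p > 0 & p < 1
  chi[ok] <- (n0[ok] - e0[ok])^2 / e0[ok] +
    (n1[ok] - e1[ok])^2 / e1[ok] + (n2[ok] - e2[ok])^2 / e2[ok]
  chi[m > 0 & !ok] <- 0  # monomorphic: trivially in HWE
  out <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  out[m == 0] <- NA_real_
  out
}

# Exact conditional HWE test (two-sided by heterozygote probability).
hwe_exact_p <- function(n0, n1, n2) {
  m <- n0 + n1 + n2
  if (m == 0) return(NA_real_)
  n_a <- 2 * n2 + n1          # minor-or-major allele count, symmetry below
  if (n_a > m) n_a <- 2 * m - n_a
  hets <- seq(n_a %% 2, n_a, by = 2)
  logp <- lchoose(m, (n_a - hets) / 2) +
    lchoose(m - (n_a - hets) / 2, hets) + hets * log(2) -
    lchoose(2 * m, n_a)
  pr <- exp(logp - max(logp)); pr <- pr / sum(pr)
  obs <- which(hets == n1)
  if (length(obs) == 0) return(NA_real_)
  min(1, sum(pr[pr <= pr[obs] + 1e-12]))
}

#' Apply SNP quality-control filters
#'
#' Removes SNPs sequentially by criterion, in the order: not on the map
#' or on a non-autosome; call rate strictly below the threshold; minor
#' allele frequency strictly below the threshold; HWE p-value strictly
#' below the threshold ("below" removes, so a SNP sitting exactly on a
#' threshold is retained). Sequential application makes the
#' per-criterion removal counts unambiguous and sum to the total.
#'
#' @param geno a `geno_matrix`.
#' @param min_call_rate call-rate threshold (default 0.95).
#' @param min_maf minor-allele-frequency threshold (default 0.01).
#' @param min_hwe_p HWE p-value threshold (default 1e-4).
#' @param autosomes admissible chromosome labels (default `1:29`).
#' @param hwe_test passed to [snp_stats()].
#' @return The filtered `geno_matrix`, with the QC report attached as
#'   attribute `"qc_report"` (retrieve with [qc_report()]): a tibble of
#'   removed SNPs with the criterion that removed each, plus summary
#'   counts as attribute `"counts"`.
#' @export
apply_qc <- function(geno, min_call_rate = 0.95, min_maf = 0.01,
                     min_hwe_p = 1e-4, autosomes = 1:29,
                     hwe_test = "chisq") {
  stopifnot(inherits(geno, "geno_matrix"),
            min_call_rate >= 0, min_call_rate <= 1,
            min_maf >= 0, min_maf <= 0.5, min_hwe_p >= 0, min_hwe_p <= 1)
  stats_tbl <- snp_stats(geno, hwe_test = hwe_test)
  map <- geno$map
  removed <- list()
  alive <- stats_tbl$snp_id

  off_map <- alive[!(alive %in% map$snp_id[map$chr %in% autosomes])]
  removed$map <- off_map
  alive <- setdiff(alive, off_map)

  s <- stats_tbl[match(alive, stats_tbl$snp_id), ]
  lc <- s$snp_id[s$call_rate < min_call_rate]
  removed$call_rate <- lc
  alive <- setdiff(alive, lc)

  s <- stats_tbl[match(alive, stats_tbl$snp_id), ]
  lm <- s$snp_id[is.na(s$maf) | s$maf < min_maf]
  removed$maf <- lm
  alive <- setdiff(alive, lm)

  s <- stats_tbl[match(alive, stats_tbl$snp_id), ]
  hw <- s$snp_id[!is.na(s$hwe_p) & s$hwe_p < min_hwe_p]
  removed$hwe <- hw
  alive <- setdiff(alive, hw)

  if (length(alive) == 0) {
    stop("all SNPs removed by QC; review the thresholds")
  }
  report <- tibble::tibble(
    snp_id = unlist(removed, use.names = FALSE),
    criterion = rep(c("map", "call_rate", "maf", "hwe"),
                    lengths(removed)))
  attr(report, "counts") <- tibble::tibble(
    criterion = c("map", "call_rate", "maf", "hwe"),
    removed = lengths(removed), retained = length(alive),
    total = nrow(stats_tbl))
  out <- geno_matrix(geno$calls[, alive, drop = FALSE],
                     map[map$snp_id %in% alive, , drop = FALSE],
                     coding = geno$coding)
  attr(out, "qc_report") <- report
  out
}

#' Retrieve the QC report attached by [apply_qc()]
#' @param geno a filtered `geno_matrix`.
#' @return Tibble of removed SNPs (with per-criterion counts in its
#'   `"counts"` attribute), or `NULL` if no QC has been applied.
#' @export
qc_report <- function(geno) attr(geno, "qc_report")
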