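#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Simulate a multi-generation random-mating pedigree
#'
#' Generations are discrete and non-overlapping: generation 0 holds the
#' founders; each later generation is produced by randomly pairing the
#' previous generation into matings (no selfing) and giving each mating
#' a fixed number of offspring. The result is deterministic under a
#' fixed seed.
#'
#' @param n_founders even number of founders, >= 2.
#' @param n_generations number of offspring generations, >= 1.
#' @param offspring_per_mating offspring produced by each mating pair.
#' @param seed integer seed.
#' @return A `pedigree` tibble with an extra `generation` column.
#' @export
simulate_pedigree <- function(n_founders, n_generations,
                              offspring_per_mating = 2, seed = 1) {
  if (n_founders < 2 || n_founders %% 2 != 0) {
    stop("n_founders must be an even number >= 2")
  }
  stopifnot(n_generations >= 1, offspring_per_mating >= 1)
  with_seed(seed, {
    recs <- tibble::tibble(
      animal = sprintf("G0_%04d", seq_len(n_founders)),
      sire = NA_character_, dam = NA_character_, generation = 0L)
    prev <- recs$animal
    for (g in seq_len(n_generations)) {
      shuffled <- sample(prev)
      n_mate <- floor(length(shuffled) / 2)
      sires <- shuffled[seq_len(n_mate)]
      dams <- shuffled[n_mate + seq_len(n_mate)]
      kids <- tibble::tibble(
        sire = rep(sires, each = offspring_per_mating),
        dam = rep(dams, each = offspring_per_mating))
      kids$animal <- sprintf("G%d_%04d", g, seq_len(nrow(kids)))
      kids$generation <- g
      recs <- dplyr::bind_rows(recs, kids[c("animal", "sire", "dam", "generation")])
      prev <- kids$animal
    }
    gen <- recs$generation
    ped <- pedigree(recs[c("animal", "sire", "dam")])
    ped$generation <- gen[match(ped$animal, recs$animal)]
    ped
  })
}

#' Gene-drop genotypes through a pedigree
#'
#' Founder allele frequencies are drawn uniformly on
#' `[maf_low, maf_high]` and founder genotypes sampled in Hardy-Weinberg
#' proportions. Offspring receive one allele from each parent by
#' Mendelian sampling (loci unlinked, so transmission at each locus is a
#' Bernoulli draw with probability = parental dosage / 2). Map positions
#' are laid out sequentially across `n_chr` chromosomes at `spacing_bp`
#' intervals.
#'
#' @param ped a `pedigree` (topologically sorted).
#' @param n_snps number of loci, >= 1.
#' @param maf_low,maf_high founder minor-allele-frequency bounds, a
#'   subinterval of (0, 0.5].
#' @param seed integer seed.
#' @param n_chr number of chromosomes the map spans.
#' @param spacing_bp distance between adjacent markers in base pairs.
#' @return A `geno_matrix` (dosage coding, no missing calls) covering
#'   every pedigree animal.
#' @export
gene_drop_genotypes <- function(ped, n_snps, maf_low = 0.05, maf_high = 0.5,
                                seed = 1, n_chr = 10, spacing_bp = 100000L) {
  stopifnot(inherits(ped, "pedigree"))
  if (n_snps < 1) stop("n_snps must be >= 1")
  stopifnot(maf_low > 0, maf_high <= 0.5, maf_low <= maf_high)
  with_seed(seed, {
    n <- nrow(ped)
    p <- stats::runif(n_snps, maf_low, maf_high)
    calls <- matrix(NA_real_, n, n_snps,
                    dimnames = list(ped$animal,
                                    sprintf("snp%05d", seq_len(n_snps))))
    row_of <- stats::setNames(seq_len(n), ped$animal)
    for (i in seq_len(n)) {
      s <- ped$sire[i]; d <- ped$dam[i]
      if (is.na(s) && is.na(d)) {
        calls[i, ] <- stats::rbinom(n_snps, 2L, p)
      } else {
        from_s <- if (is.na(s)) stats::rbinom(n_snps, 1L, p)
                  else stats::rbinom(n_snps, 1L, calls[row_of[s], ] / 2)
        from_d <- if (is.na(d)) stats::rbinom(n_snps, 1L, p)
                  else stats::rbinom(n_snps, 1L, calls[row_of[d], ] / 2)
        calls[i, ] <- from_s + from_d
      }
    }
    per_chr <- ceiling(n_snps / n_chr)
    map <- tibble::tibble(
      snp_id = colnames(calls),
      chr = rep(seq_len(n_chr), each = per_chr)[seq_len(n_snps)],
      pos_bp = (((seq_len(n_snps) - 1) %% per_chr) * spacing_bp) + 1L)
    geno_matrix(calls, marker_map(map, autosomes = seq_len(n_chr)))
  })
}

#' Simulate a trait with a mixture (spike-and-slab) architecture
#'
#' A fraction `pi` of markers carries no effect; the remainder receive
#' independent normal effects, rescaled so the realized genetic variance
#' of centered dosages equals the target. Phenotypes are on the unit
#' scale: genetic variance `h2`, residual variance `1 - h2`.
#'
#' @param geno a `geno_matrix` with complete calls.
#' @param pi prior fraction of null markers, in \[0, 1).
#' @param h2 trait heritability, in (0, 1).
#' @param seed integer seed.
#' @param causal_idx optional integer vector of SNP columns; when given,
#'   exactly these loci are causal (`pi` still reported but not drawn).
#'   Used to plant architectures, e.g. all causal loci inside one 1-Mb
#'   window.
#' @return An object of class `true_trait`: list with `animals` (tibble
#'   `animal`, `tbv`, `y`), `effects` (tibble `snp_id`, `true_effect`,
#'   `is_null`), and scalars `pi`, `h2`, `sigma_a2`, `sigma_e2`, `seed`.
#' @export
simulate_trait <- function(geno, pi, h2, seed = 1, causal_idx = NULL) {
  stopifnot(inherits(geno, "geno_matrix"), pi >= 0, pi < 1, h2 > 0, h2 < 1)
  Z <- dosage_calls(geno)
  if (anyNA(Z)) stop("simulate_trait requires complete genotypes")
  k <- ncol(Z); n <- nrow(Z)
  with_seed(seed, {
    if (is.null(causal_idx)) {
      delta <- stats::rbinom(k, 1L, 1 - pi) == 1L
      if (!any(delta)) delta <- stats::rbinom(k, 1L, 1 - pi) == 1L
      if (!any(delta)) stop("all marker effects drawn null twice; ",
                            "increase the marker count or lower pi")
    } else {
      stopifnot(all(causal_idx >= 1), all(causal_idx <= k))
      delta <- seq_len(k) %in% causal_idx
    }
    u <- numeric(k)
    u[delta] <- stats::rnorm(sum(delta))
    Zc <- scale(Z, center = TRUE, scale = FALSE)
    g <- drop(Zc %*% u)
    sigma_a2 <- h2
    sigma_e2 <- 1 - h2
    vg <- stats::var(g) * (n - 1) / n
    if (vg <= 0) stop("degenerate genetic variance; markers may be monomorphic")
    u <- u * sqrt(sigma_a2 / vg)
    tbv <- g * sqrt(sigma_a2 / vg)
    y <- tbv + stats::rnorm(n, 0, sqrt(sigma_e2))
    structure(list(
      animals = tibble::tibble(animal = rownames(Z), tbv = tbv, y = y),
      effects = tibble::tibble(snp_id = colnames(Z), true_effect = u,
                               is_null = !delta),
      pi = pi, h2 = h2, sigma_a2 = sigma_a2, sigma_e2 = sigma_e2,
      seed = seed), class = "true_trait")
  })
}

#' Simulate EBV records with heterogeneous reliabilities
#'
#' Each animal's reliability is drawn uniformly on
#' `[rel_low, rel_high]`; its EBV is the reliability-shrunk true
#' breeding value plus noise calibrated so that the reliability keeps
#' its textbook meaning, `cor(EBV, TBV)^2 = r2` in expectation:
#' `EBV = r2 * TBV + e`, `var(e) = r2 (1 - r2) sigma_a2`. Sire and dam
#' EBVs (and reliabilities) are joined from the same table via the
#' pedigree, and the parent average is filled where both are known.
#'
#' @param trait a `true_trait` from [simulate_trait()].
#' @param ped the `pedigree` the animals belong to.
#' @param rel_low,rel_high reliability bounds, `0 < rel_low <= rel_high < 1`.
#' @param seed integer seed.
#' @return An `ebv_table` covering every animal in `trait`.
#' @export
simulate_ebv_records <- function(trait, ped, rel_low = 0.3, rel_high = 0.9,
                                 seed = 1) {
  stopifnot(inherits(trait, "true_trait"), inherits(ped, "pedigree"),
            rel_low > 0, rel_low <= rel_high, rel_high < 1)
  tb <- trait$animals
  missing_tbv <- setdiff(ped$animal, tb$animal)
  if (length(missing_tbv) > 0) {
    stop("animal(s) in pedigree without a simulated TBV: ",
         paste(utils::head(missing_tbv, 5), collapse = ", "))
  }
  with_seed(seed, {
    n <- nrow(tb)
    r2 <- stats::runif(n, rel_low, rel_high)
    eps <- stats::rnorm(n, 0, sqrt(r2 * (1 - r2) * trait$sigma_a2))
    df <- tibble::tibble(animal = tb$animal,
                         ebv = r2 * tb$tbv + eps, rel = r2)
    pedx <- ped[match(df$animal, ped$animal), ]
    df$sire_ebv <- df$ebv[match(pedx$sire, df$animal)]
    df$dam_ebv <- df$ebv[match(pedx$dam, df$animal)]
    df$sire_rel <- df$rel[match(pedx$sire, df$animal)]
    df$dam_rel <- df$rel[match(pedx$dam, df$animal)]
    ebv_table(df)
  })
}

#' Inject quality-control failure modes into a genotype matrix
#'
#' Disjoint random subsets of SNPs are corrupted so the QC filters have
#' something to catch: low call rate (strictly more than 5% of calls set
#' missing), low minor allele frequency (column replaced by a
#' near-monomorphic one with sample MAF strictly below 0.01), and
#' Hardy-Weinberg violation (column forced all-heterozygous, giving a
#' chi-square statistic equal to the animal count).
#'
#' @param geno a `geno_matrix`.
#' @param frac_lowcall,frac_lowmaf,frac_hwe fractions of SNPs given each
#'   failure mode; must sum to at most 0.5.
#' @param seed integer seed.
#' @return List with elements `genotypes` (corrupted `geno_matrix`, same
#'   coding as the input) and `manifest` (tibble `snp_id`,
#'   `failure_mode`).
#' @export
corrupt_for_qc <- function(geno, frac_lowcall = 0, frac_lowmaf = 0,
                           frac_hwe = 0, seed = 1) {
  stopifnot(inherits(geno, "geno_matrix"))
  if (frac_lowcall + frac_lowmaf + frac_hwe > 0.5) {
    stop("corruption fractions must sum to at most 0.5")
  }
  Z <- dosage_calls(geno)
  n <- nrow(Z); k <- ncol(Z)
  n_lc <- round(frac_lowcall * k)
  n_lm <- round(frac_lowmaf * k)
  n_hw <- round(frac_hwe * k)
  with_seed(seed, {
    pick <- sample(k, n_lc + n_lm + n_hw)
    lc <- pick[seq_len(n_lc)]
    lm <- pick[n_lc + seq_len(n_lm)]
    hw <- pick[n_lc + n_lm + seq_len(n_hw)]
    for (j in lc) {
      m <- floor(0.05 * n) + 1 + stats::rbinom(1, n %/% 10, 0.3)
      Z[sample(n, min(m, n)), j] <- NA
    }
    for (j in lm) {
      n_het <- max(0L, as.integer(ceiling(0.02 * n)) - 1L)
      col <- rep(0, n)
      if (n_het > 0) col[sample(n, n_het)] <- 1
      Z[, j] <- col
    }
    for (j in hw) Z[, j] <- 1
    manifest <- tibble::tibble(
      snp_id = colnames(Z)[c(lc, lm, hw)],
      failure_mode = rep(c("low_call_rate", "low_maf", "hwe_violation"),
                         c(n_lc, n_lm, n_hw)))
    out <- geno_matrix(Z, geno$map)
    list(genotypes = convert_coding(out, geno$coding), manifest = manifest)
  })
}
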