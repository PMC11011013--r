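#' Configuration for a weighted Bayesian whole-genome regression
#'
#' Bundles the mixture-model method, the prior null-marker proportion
#' `pi`, the chain schedule, and the variance priors. The production
#' schedule is 110,000 iterations with a 10,000-iteration burn-in and
#' thinning every 10th sample, retaining exactly 10,000 samples;
#' analyses at desk scale use shorter chains.
#'
#' Scaled-inverse-chi-square priors: the marker-effect prior scale is
#' solved from `target_genetic_variance` (defaults to half the weighted
#' variance of the response at fit time) spread over the expected
#' `(1 - pi) * sum(2 p q)` marker heterozygosity, with
#' `nu_effects = 4.2` degrees of freedom (the t-like tail used by the
#' GenSel lineage); BayesB gives each locus its own variance, BayesC a
#' single common one plus the inclusion probability.
#'
#' @param method `"BayesB"` or `"BayesC"`.
#' @param pi prior probability a marker has zero effect, in \[0, 1).
#'   Typical analysis grid: 0.75, 0.90, 0.99, 0.995.
#' @param chain_length,burn_in,thin chain schedule;
#'   `(chain_length - burn_in)` must be a positive multiple of `thin`.
#' @param nu_effects prior df for marker-effect variances.
#' @param nu_residual prior df for the residual variance.
#' @param target_genetic_variance,target_residual_variance prior means
#'   for the genetic and residual variance; `NULL` defers to fit time
#'   (half the response variance each).
#' @param fix_marker_variance,fix_residual_variance hold the variance(s)
#'   at `sigma_u2`/`sigma_e2` instead of sampling (used e.g. to compare
#'   against the ridge-regression closed form).
#' @param sigma_u2,sigma_e2 fixed values when the corresponding
#'   `fix_*` flag is set.
#' @param store_samples keep the retained marker-effect samples (needed
#'   by [window_variance_profile()]).
#' @param seed integer seed.
#' @return A list of class `bayes_config`.
#' @export
bayes_config <- function(method = c("BayesC", "BayesB"), pi = 0.99,
                         chain_length = 110000, burn_in = 10000, thin = 10,
                         nu_effects = 4.2, nu_residual = 4,
                         target_genetic_variance = NULL,
                         target_residual_variance = NULL,
                         fix_marker_variance = FALSE,
                         fix_residual_variance = FALSE,
                         sigma_u2 = NULL, sigma_e2 = NULL,
                         store_samples = TRUE, seed = 1) {
  method <- match.arg(method)
  stopifnot(pi >= 0, pi < 1, chain_length > burn_in, burn_in >= 0, thin >= 1)
  if ((chain_length - burn_in) %% thin != 0) {
    stop("(chain_length - burn_in) must be a multiple of thin")
  }
  if (fix_marker_variance && is.null(sigma_u2)) {
    stop("fix_marker_variance = TRUE requires sigma_u2")
  }
  if (fix_residual_variance && is.null(sigma_e2)) {
    stop("fix_residual_variance = TRUE requires sigma_e2")
  }
  structure(list(method = method, pi = pi, chain_length = chain_length,
                 burn_in = burn_in, thin = thin, nu_effects = nu_effects,
                 nu_residual = nu_residual,
                 target_genetic_variance = target_genetic_variance,
                 target_residual_variance = target_residual_variance,
                 fix_marker_variance = fix_marker_variance,
                 fix_residual_variance = fix_residual_variance,
                 sigma_u2 = sigma_u2, sigma_e2 = sigma_e2,
                 store_samples = store_samples, seed = seed),
            class = "bayes_config")
}

#' Retained-sample count of a chain schedule
#' @param config a `bayes_config`.
#' @return `(chain_length - burn_in) / thin`.
#' @export
retained_samples <- function(config) {
  stopifnot(inherits(config, "bayes_config"))
  as.integer((config$chain_length - config$burn_in) %/% config$thin)
}

#' Fit a weighted BayesB/BayesC whole-genome regression
#'
#' Gibbs sampling for the mixture model
#' \deqn{y_i = \mu + \sum_j Z_{ij} u_j \delta_j + e_i,\qquad
#'       e_i \sim N(0, \sigma_e^2 / w_i)}
#' where `delta_j` is a 0/1 inclusion indicator with prior
#' `P(delta_j = 0) = pi` and the record weights `w_i` come from the
#' deregression stage. Each sweep updates the mean, every indicator
#' (with the effect integrated out analytically) and effect, the
#' marker-effect variance(s), and the residual variance. Genotypes are
#' centered by twice the allele frequency of the training animals, so
#' fitting inside a cross-validation fold leaks nothing from validation
#' animals.
#'
#' @param geno a `geno_matrix` with complete calls covering at least the
#'   response animals (any coding dialect; dosages are used internally).
#' @param debv a `debv_table` (or data frame with `animal`, `debv`, and
#'   optionally `weight`; missing weights default to 1).
#' @param config a [bayes_config()].
#' @return An object of class `bayes_fit`: posterior-mean effects and
#'   model frequencies (via [tidy()]), variance samples, the training
#'   centering vector, and (if requested) the retained effect samples.
#' @export
fit_bayes <- function(geno, debv, config = bayes_config()) {
  stopifnot(inherits(geno, "geno_matrix"), inherits(config, "bayes_config"))
  if (!"animal" %in% names(debv) || !"debv" %in% names(debv)) {
    stop("debv must have columns animal and debv")
  }
  ids <- as.character(debv$animal)
  missing_ids <- setdiff(ids, animal_ids(geno))
  if (length(missing_ids) > 0) {
    stop("response animal(s) without genotypes: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  Z <- dosage_calls(geno)[ids, , drop = FALSE]
  if (anyNA(Z)) stop("fit_bayes requires complete genotypes (run QC first)")
  y <- debv$debv
  w <- if ("weight" %in% names(debv)) debv$weight else rep(1, length(y))
  if (any(w <= 0)) stop("record weights must be strictly positive")

  centers <- colMeans(Z)                     # = 2 * training allele freq
  Zc <- sweep(Z, 2, centers)
  p_hat <- centers / 2
  sum2pq <- sum(2 * p_hat * (1 - p_hat))
  vy <- stats::weighted.mean((y - stats::weighted.mean(y, w))^2, w)
  gv <- config$target_genetic_variance %||% (0.5 * vy)
  rv <- config$target_residual_variance %||% (0.5 * vy)

  nu_u <- config$nu_effects
  sigma_u2_bar <- if (config$fix_marker_variance) config$sigma_u2
                  else gv / max((1 - config$pi) * sum2pq, 1e-12)
  scale_u <- sigma_u2_bar * (nu_u - 2) / nu_u
  nu_e <- config$nu_residual
  sigma_e2_bar <- if (config$fix_residual_variance) config$sigma_e2 else rv
  scale_e <- sigma_e2_bar * (nu_e - 2) / nu_e

  res <- with_seed(config$seed,
    bayes_wgr_mcmc(Zc, y, w,
                   locus_variances = config$method == "BayesB",
                   pi = config$pi,
                   chain_length = config$chain_length,
                   burn_in = config$burn_in, thin = config$thin,
                   nu_u = nu_u, scale_u = scale_u,
                   nu_e = nu_e, scale_e = scale_e,
                   init_sigma_u2 = sigma_u2_bar,
                   init_sigma_e2 = sigma_e2_bar,
                   fix_sigma_u = config$fix_marker_variance,
                   fix_sigma_e = config$fix_residual_variance,
                   store_samples = config$store_samples))

  effects <- tibble::tibble(snp_id = colnames(Z),
                            posterior_mean = res$posterior_mean,
                            model_freq = res$model_freq)
  samples <- if (config$store_samples) {
    m <- res$samples; rownames(m) <- colnames(Z); m
  } else NULL
  structure(list(
    effects = effects, mu = res$mu, centers = centers,
    variance_samples = tibble::tibble(
      sample = seq_len(res$retained),
      sigma_u2 = res$sigma_u2_samples,
      sigma_e2 = res$sigma_e2_samples,
      n_included = res$n_included_samples),
    samples = samples, retained = res$retained,
    animals = ids, map = geno$map, config = config),
    class = "bayes_fit")
}

#' @export
print.bayes_fit <- function(x, ...) {
  cat("<bayes_fit> ", x$config$method, " (pi = ", x$config$pi, "), ",
      length(x$animals), " animals x ", nrow(x$effects), " SNPs, ",
      x$retained, " retained samples\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
#' @method tidy bayes_fit
#' @rdname fit_bayes
#' @param x a `bayes_fit`.
#' @param ... unused.
tidy.bayes_fit <- function(x, ...) x$effects

#' @export
#' @method glance bayes_fit
#' @rdname fit_bayes
glance.bayes_fit <- function(x, ...) {
  tibble::tibble(method = x$config$method, pi = x$config$pi,
                 n_animals = length(x$animals),
                 n_snps = nrow(x$effects),
                 retained = x$retained,
                 mu = x$mu,
                 sigma_u2 = mean(x$variance_samples$sigma_u2),
                 sigma_e2 = mean(x$variance_samples$sigma_e2),
                 mean_model_freq = mean(x$effects$model_freq))
}

#' Molecular breeding values from marker effects
#'
#' `MBV_i = sum_j (Z_ij - center_j) * u_j`, with the centering vector
#' learned on the training animals. Predictions are invariant to the
#' genotype coding dialect once `coding` declares the convention the
#' effects were estimated in (effects scale by 1/10 between dosage and
#' the -10/0/10 convention).
#'
#' @param geno a `geno_matrix` for the animals to predict.
#' @param effects numeric vector of marker effects, named by snp id (or
#'   in `geno` column order).
#' @param centers numeric centering vector on the same coding scale as
#'   `effects` (0 = no centering).
#' @param coding coding convention `effects` were estimated in; must be
#'   declared so dialect mismatches convert rather than corrupt.
#' @return Tibble `animal`, `mbv`.
#' @export
predict_mbv <- function(geno, effects, centers = 0,
                        coding = c("dosage012", "gensel_pm10")) {
  if (missing(coding)) {
    stop("declare the coding convention the effects were estimated in")
  }
  coding <- match.arg(coding)
  stopifnot(inherits(geno, "geno_matrix"))
  Z <- convert_coding(geno, coding)$calls
  if (!is.null(names(effects))) {
    missing_snps <- setdiff(names(effects), colnames(Z))
    if (length(missing_snps) > 0) {
      stop("effect(s) for SNPs absent from genotypes: ",
           paste(utils::head(missing_snps, 5), collapse = ", "))
    }
    Z <- Z[, names(effects), drop = FALSE]
  } else if (length(effects) != ncol(Z)) {
    stop("effect vector length ", length(effects),
         " does not match SNP count ", ncol(Z))
  }
  Zc <- sweep(Z, 2, centers)
  tibble::tibble(animal = rownames(Z), mbv = unname(drop(Zc %*% effects)))
}

#' @export
#' @rdname predict_mbv
#' @param object a `bayes_fit`.
#' @param newdata a `geno_matrix`; defaults to predicting nothing
#'   without it.
#' @param ... unused.
predict.bayes_fit <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "geno_matrix"))
  eff <- stats::setNames(object$effects$posterior_mean,
                         object$effects$snp_id)
  predict_mbv(newdata, eff, centers = object$centers,
              coding = "dosage012")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
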