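#' Pedigree numerator relationship matrix
#'
#' Henderson's tabular recursion with inbreeding: off-diagonals are the
#' mean of the parental relationships,
#' `a_ij = (a_{s(i),j} + a_{d(i),j}) / 2`, and diagonals are
#' `1 + F_i = 1 + a_{s(i),d(i)} / 2`. Values are exact rational numbers
#' on toy pedigrees (e.g. parent-offspring 0.5, full sibs 0.5, an
#' offspring of full sibs has F = 0.25).
#'
#' @param ped a `pedigree` (topological sort is guaranteed by the
#'   constructor; plain data frames are re-sorted with a warning).
#' @return Symmetric numeric matrix with animal ids as dimnames.
#' @export
build_nrm <- function(ped) {
  if (!inherits(ped, "pedigree")) {
    warning("input re-sorted topologically via pedigree()")
    ped <- pedigree(ped)
  }
  idx <- stats::setNames(seq_len(nrow(ped)), ped$animal)
  s <- ifelse(is.na(ped$sire), -1L, idx[ped$sire] - 1L)
  d <- ifelse(is.na(ped$dam), -1L, idx[ped$dam] - 1L)
  A <- nrm_tabular(as.integer(s), as.integer(d))
  dimnames(A) <- list(ped$animal, ped$animal)
  A
}

#' Inbreeding coefficients from a relationship matrix
#' @param A numerator relationship matrix.
#' @return Named numeric vector `F = diag(A) - 1`.
#' @export
inbreeding <- function(A) diag(A) - 1

#' Relatedness-minimizing K-means cross-validation folds
#'
#' The relationship matrix is turned into the distance
#' `d_ij = 1 - a_ij / sqrt(a_ii a_jj)` (the normalization keeps inbred
#' diagonals from distorting distances), embedded by classical
#' multidimensional scaling (top components covering at least
#' `var_mass` of the positive eigenvalue mass, capped at `max_dim`),
#' and clustered with Lloyd-style K-means over `restarts` restarts,
#' keeping the best inertia. Animals with zero distance (e.g.
#' relationship 1) always co-cluster; the assignment is deterministic
#' under a fixed seed.
#'
#' @param A relationship matrix over the reference animals (dimnames =
#'   animal ids).
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @param restarts K-means restarts (default 25).
#' @param var_mass eigenvalue mass the embedding must cover
#'   (default 0.9).
#' @param max_dim embedding dimension cap (default 20).
#' @return Tibble of class `cv_folds`: `animal`, `fold`; per-fold sizes
#'   in attribute `"sizes"`.
#' @export
kmeans_folds <- function(A, k = 5, seed = 1, restarts = 25,
                         var_mass = 0.9, max_dim = 20) {
  n <- nrow(A)
  if (k < 2) stop("k must be at least 2")
  if (k > n) stop("more folds than animals")
  if (is.null(rownames(A))) rownames(A) <- paste0("animal_", seq_len(n))
  dd <- sqrt(diag(A))
  D <- 1 - A / outer(dd, dd)
  D[D < 0] <- 0
  # cmdscale warns when fewer positive eigenvalues than asked-for axes;
  # the dimension is re-capped right below, so that is expected
  mds <- suppressWarnings(
    stats::cmdscale(stats::as.dist(D), k = min(n - 1, max_dim), eig = TRUE))
  ev <- mds$eig[mds$eig > 1e-12]
  m <- if (length(ev) == 0) 1 else {
    min(max(which(cumsum(ev) / sum(ev) >= var_mass)[1], 1, na.rm = TRUE),
        ncol(mds$points))
  }
  m <- max(m, min(2, ncol(mds$points)))
  X <- mds$points[, seq_len(m), drop = FALSE]
  km <- with_seed(seed,
    stats::kmeans(X, centers = k, nstart = restarts, iter.max = 100))
  out <- tibble::tibble(animal = rownames(A), fold = as.integer(km$cluster))
  class(out) <- c("cv_folds", class(out))
  attr(out, "sizes") <- as.integer(table(out$fold))
  attr(out, "inertia") <- km$tot.withinss
  out
}

#' Within- and between-fold relatedness diagnostics
#'
#' Per fold: `inBreC` (mean inbreeding coefficient of members),
#' `a_max_within` (mean over members of each member's maximum
#' relationship to another member), `a_max_between` (mean over members
#' of the maximum relationship to any non-member), `a_ij_within` (mean
#' pairwise relationship within the fold) and `a_ij_between` (mean
#' relationship of member/non-member pairs). A final `"Avg."` row holds
#' the unweighted mean of the per-fold values. Well-separated folds show
#' between-fold values clearly below the within-fold ones.
#'
#' @param A relationship matrix.
#' @param folds a `cv_folds` assignment covering the matrix animals.
#' @return Tibble `fold`, `n_animals`, `inBreC`, `a_max_within`,
#'   `a_max_between`, `a_ij_within`, `a_ij_between`. Singleton folds get
#'   `NA` within-fold statistics.
#' @export
cluster_relatedness_stats <- function(A, folds) {
  stopifnot(inherits(folds, "cv_folds") || is.data.frame(folds))
  ids <- rownames(A)
  miss <- setdiff(ids, folds$animal)
  if (length(miss) > 0) {
    stop("fold assignment missing animal(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  f <- folds$fold[match(ids, folds$animal)]
  Fi <- diag(A) - 1
  per_fold <- purrr::map_dfr(sort(unique(f)), function(cl) {
    inside <- which(f == cl); outside <- which(f != cl)
    Aw <- A[inside, inside, drop = FALSE]
    diag(Aw) <- NA
    off <- Aw[upper.tri(Aw)]
    tibble::tibble(
      fold = as.character(cl),
      n_animals = length(inside),
      inBreC = mean(Fi[inside]),
      a_max_within = if (length(inside) > 1)
        mean(apply(Aw, 1, max, na.rm = TRUE)) else NA_real_,
      a_max_between = if (length(outside) > 0)
        mean(apply(A[inside, outside, drop = FALSE], 1, max)) else NA_real_,
      a_ij_within = if (length(off) > 0) mean(off) else NA_real_,
      a_ij_between = if (length(outside) > 0)
        mean(A[inside, outside, drop = FALSE]) else NA_real_)
  })
  avg <- dplyr::summarise(per_fold, fold = "Avg.",
                          n_animals = sum(.data$n_animals),
                          dplyr::across(c("inBreC", "a_max_within",
                                          "a_max_between", "a_ij_within",
                                          "a_ij_between"),
                                        ~ mean(.x, na.rm = TRUE)))
  dplyr::bind_rows(per_fold, avg)
}

#' Cross-validated genomic prediction accuracy
#'
#' For each fold, the model is trained on all animals outside the fold
#' (fold-level seed = base seed + fold index), molecular breeding values
#' are predicted for the fold members, and the fold's accuracy is the
#' Pearson correlation between MBV and the deregressed response within
#' the fold. The summary accuracy is the unweighted mean over folds with
#' standard error `sd / sqrt(k)`. A fold with constant MBV yields `NA`
#' and is excluded from the mean with a warning. With
#' `scale = "reliability"` each fold's correlation is divided by the
#' square root of the fold's mean record reliability.
#'
#' @param geno a `geno_matrix` covering all response animals.
#' @param debv a `debv_table` (needs `animal`, `debv`, `weight`;
#'   `rel` if `scale = "reliability"`).
#' @param folds a `cv_folds` assignment (animals outside `debv` are
#'   ignored).
#' @param config a [bayes_config()]; `store_samples` is forced off for
#'   the fold fits.
#' @param scale `"none"` (default) or `"reliability"`.
#' @return Tibble of class `cv_accuracy`: `fold`, `n_train`,
#'   `n_validate`, `accuracy`. Summary via [glance()] (columns
#'   `mean_accuracy`, `se`, `k`).
#' @export
run_cv <- function(geno, debv, folds, config = bayes_config(),
                   scale = c("none", "reliability")) {
  scale <- match.arg(scale)
  stopifnot(inherits(geno, "geno_matrix"), inherits(config, "bayes_config"))
  dv <- debv[debv$animal %in% folds$animal, , drop = FALSE]
  f <- folds$fold[match(dv$animal, folds$animal)]
  fold_ids <- sort(unique(f))
  if (any(table(f) == nrow(dv))) stop("a fold contains every animal")
  res <- purrr::map_dfr(fold_ids, function(cl) {
    train <- dv[f != cl, , drop = FALSE]
    valid <- dv[f == cl, , drop = FALSE]
    cfg <- config
    cfg$seed <- config$seed + cl
    cfg$store_samples <- FALSE
    fit <- fit_bayes(geno, train, cfg)
    mbv <- predict(fit, newdata = geno)
    mbv <- mbv$mbv[match(valid$animal, mbv$animal)]
    acc <- if (stats::sd(mbv) == 0 || stats::sd(valid$debv) == 0) {
      warning("constant MBV or response in fold ", cl,
              "; accuracy set to NA")
      NA_real_
    } else {
      a <- stats::cor(mbv, valid$debv)
      if (scale == "reliability") a / sqrt(mean(valid$rel)) else a
    }
    tibble::tibble(fold = cl, n_train = nrow(train),
                   n_validate = nrow(valid), accuracy = acc)
  })
  class(res) <- c("cv_accuracy", class(res))
  res
}

#' @export
#' @method glance cv_accuracy
#' @rdname run_cv
#' @param x a `cv_accuracy`.
#' @param ... unused.
glance.cv_accuracy <- function(x, ...) {
  acc <- x$accuracy[!is.na(x$accuracy)]
  tibble::tibble(mean_accuracy = mean(acc),
                 se = stats::sd(acc) / sqrt(length(acc)),
                 k = length(acc))
}
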