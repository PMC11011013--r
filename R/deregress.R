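#' Reliability-based record weight
#'
#' Weight applied to a deregressed breeding-value record to account for
#' its heterogeneous residual variance:
#' \deqn{w = \frac{1 - h^2}{\left[c + (1 - r^2)/r^2\right] h^2}}
#' with \eqn{h^2} the trait heritability, \eqn{r^2} the record's
#' reliability and \eqn{c} the fraction of genetic variance not captured
#' by the markers. Under this form more reliable records weigh more.
#' The alternative reading of the same expression with the bracket in
#' the numerator, \eqn{w = (1 - h^2)[c + (1 - r^2)/r^2]/h^2}, is
#' available via `form = "flat"`; it is not the default because it
#' down-weights reliable records.
#'
#' @param h2 heritability, in (0, 1).
#' @param r2 record reliability, in (0, 1).
#' @param c marker-shortfall fraction, >= 0 (default 0.4).
#' @param form `"garrick"` (default) or `"flat"`.
#' @return Positive finite weight (vectorized over `r2`).
#' @export
garrick_weight <- function(h2, r2, c = 0.4, form = c("garrick", "flat")) {
  form <- match.arg(form)
  if (any(h2 <= 0 | h2 >= 1)) stop("h2 must lie strictly in (0, 1)")
  if (any(r2 <= 0 | r2 >= 1)) stop("r2 must lie strictly in (0, 1)")
  if (any(c < 0)) stop("c must be non-negative")
  bracket <- c + (1 - r2) / r2
  if (form == "garrick") (1 - h2) / (bracket * h2)
  else (1 - h2) * bracket / h2
}

#' Deregress EBVs into response variables for whole-genome regression
#'
#' Removes the shrinkage from estimated breeding values so that records
#' can serve as quasi-independent responses, in two modes:
#'
#' \describe{
#'   \item{`incPA`}{Full-information deregression: `DEBV = EBV / r2`,
#'     reliability unchanged. Re-shrinking by `r2` recovers the input
#'     EBV exactly (round-trip identity).}
#'   \item{`excPA`}{Removes the parent-average contribution first by
#'     absorbing a parent-average effect in the two-trait mixed-model
#'     equations
#'     \deqn{\begin{pmatrix} Z'_{PA}Z_{PA} + 4\lambda & -2\lambda \\
#'           -2\lambda & Z'_iZ_i + 2\lambda \end{pmatrix}
#'           \begin{pmatrix}\hat g_{PA}\\ \hat g_i\end{pmatrix} =
#'           \begin{pmatrix}y_{PA}\\ y_i\end{pmatrix}}
#'     with \eqn{\lambda = (1 - h^2)/h^2}. The parent average carries
#'     prior variance \eqn{\sigma_a^2/2}, so its effective reliability
#'     is \eqn{r^2_{PA,eff} = (r^2_s + r^2_d)/2}, twice the usual
#'     predictor reliability \eqn{r^2_{PA} = (r^2_s + r^2_d)/4}.
#'     Equating the reported reliabilities to the inverse of the
#'     coefficient matrix gives a quadratic in
#'     \eqn{b = Z'_iZ_i + 2\lambda}:
#'     \deqn{b = \frac{\lambda\left(1 +
#'       \sqrt{1 + 8(1 - r^2)(1 - r^2_{PA,eff})}\right)}{2(1 - r^2)}}
#'     hence the own-plus-progeny effective record contribution
#'     \eqn{Z'_iZ_i = b - 2\lambda}. The information-corrected right-hand
#'     side \eqn{y_i = -2\lambda\,PA + (Z'_iZ_i + 2\lambda)\,EBV} yields
#'     `DEBV = y_i / Z'_iZ_i` with reliability
#'     \eqn{r^2_* = Z'_iZ_i / (Z'_iZ_i + \lambda)}. The boundary
#'     \eqn{Z'_iZ_i = 0} corresponds exactly to \eqn{r^2 = r^2_{PA}}:
#'     an EBV made of parent average only.}
#' }
#'
#' Animals whose reliability does not exceed the parent-average
#' reliability carry no own information and are dropped in `excPA` mode
#' (reported in the `"dropped"` attribute with a reason), as are animals
#' without a computable parent average.
#'
#' @param ebv an `ebv_table` (or data frame with its columns; `excPA`
#'   needs `sire_rel`/`dam_rel` for the parent-average reliability).
#' @param params a `trait_params` row supplying `h2` and `c`.
#' @param mode `"incPA"` or `"excPA"`.
#' @param weight_form passed to [garrick_weight()].
#' @return Tibble of class `debv_table`: `animal`, `debv`, `rel`
#'   (reliability of the deregressed record), `weight`, `mode`. Dropped
#'   animals (excPA) are listed in attribute `"dropped"`.
#' @export
deregress <- function(ebv, params, mode = c("incPA", "excPA"),
                      weight_form = "garrick") {
  mode <- match.arg(mode)
  if (!inherits(ebv, "ebv_table")) ebv <- ebv_table(ebv)
  stopifnot(inherits(params, "trait_params"), nrow(params) == 1)
  h2 <- params$h2; cc <- params$c
  lambda <- (1 - h2) / h2

  if (mode == "incPA") {
    out <- tibble::tibble(animal = ebv$animal,
                          debv = ebv$ebv / ebv$rel,
                          rel = ebv$rel)
    dropped <- tibble::tibble(animal = character(0), reason = character(0))
  } else {
    r2_pa <- (ebv$sire_rel + ebv$dam_rel) / 4   # predictor reliability
    reason <- rep(NA_character_, nrow(ebv))
    reason[is.na(ebv$parent_average) | is.na(r2_pa)] <- "no parent average"
    ok <- is.na(reason) & ebv$rel > r2_pa
    reason[is.na(reason) & !ok] <- "no own information beyond parent average"
    keep <- which(ok)
    r2 <- ebv$rel[keep]
    r2_pa_eff <- 2 * r2_pa[keep]                # PA effect has variance sigma_a^2/2
    b <- lambda * (1 + sqrt(1 + 8 * (1 - r2) * (1 - r2_pa_eff))) /
      (2 * (1 - r2))
    zi <- b - 2 * lambda
    bad <- zi <= 0
    if (any(bad)) {
      reason[keep[bad]] <- "no own information beyond parent average"
      keep <- keep[!bad]; zi <- zi[!bad]
    }
    yi <- -2 * lambda * ebv$parent_average[keep] +
      (zi + 2 * lambda) * ebv$ebv[keep]
    out <- tibble::tibble(animal = ebv$animal[keep],
                          debv = yi / zi,
                          rel = zi / (zi + lambda))
    dropped <- tibble::tibble(animal = ebv$animal[!is.na(reason)],
                              reason = reason[!is.na(reason)])
  }
  out$weight <- garrick_weight(h2, out$rel, cc, form = weight_form)
  out$mode <- mode
  class(out) <- c("debv_table", class(out))
  attr(out, "dropped") <- dropped
  out
}
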