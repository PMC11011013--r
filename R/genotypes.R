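#' Marker map constructor
#'
#' Builds and validates a marker map: one row per SNP with its identifier,
#' autosome and 1-based physical position. The map is sorted by
#' (chromosome, position) on construction, which downstream window
#' assignment relies on.
#'
#' @param df data frame with columns `snp_id`, `chr`, `pos_bp`.
#' @param autosomes integer vector of admissible autosome labels
#'   (default `1:29`, the bovine autosomes).
#' @return A tibble of class `marker_map`, sorted by `(chr, pos_bp)`.
#' @export
marker_map <- function(df, autosomes = 1:29) {
  stopifnot(is.data.frame(df))
  need <- c("snp_id", "chr", "pos_bp")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("marker map is missing column(s): ", paste(miss, collapse = ", "))
  }
  map <- tibble::as_tibble(df[need])
  map$snp_id <- as.character(map$snp_id)
  map$chr <- as.integer(map$chr)
  map$pos_bp <- as.integer(map$pos_bp)
  if (anyDuplicated(map$snp_id)) {
    stop("duplicated snp_id in marker map: ",
         paste(utils::head(map$snp_id[duplicated(map$snp_id)], 5), collapse = ", "))
  }
  if (any(is.na(map$pos_bp)) || any(map$pos_bp < 1)) {
    stop("marker positions must be 1-based integers >= 1")
  }
  bad <- !map$chr %in% autosomes
  if (any(bad)) {
    stop("marker(s) outside the declared autosome set: ",
         paste(utils::head(map$snp_id[bad], 5), collapse = ", "))
  }
  map <- dplyr::arrange(map, .data$chr, .data$pos_bp)
  class(map) <- c("marker_map", class(map))
  map
}

#' Read a marker map from a TSV file
#'
#' Expects columns `snp_id`, `chr`, `pos_bp` (header required).
#'
#' @inheritParams marker_map
#' @param path file path.
#' @return A `marker_map` tibble.
#' @export
read_marker_map <- function(path, autosomes = 1:29) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  marker_map(df, autosomes = autosomes)
}

#' Genotype matrix constructor
#'
#' Couples an animals-by-SNPs call matrix with its marker map and records
#' the allele-coding convention. The canonical internal coding is
#' `dosage012` (count of the alternate allele); the GenSel-style
#' \{-10, 0, 10\} convention is accepted as a dialect and converts to and
#' from dosages through the exact affine map `g -> 10 * (g - 1)`.
#'
#' @param calls numeric matrix, animals in rows (rownames = animal ids),
#'   SNPs in columns (colnames = snp ids). Missing calls are `NA`.
#' @param map `marker_map` (or coercible data frame) covering exactly the
#'   matrix columns.
#' @param coding `"dosage012"` or `"gensel_pm10"`.
#' @return An object of class `geno_matrix`: a list with elements
#'   `calls`, `map`, `coding`.
#' @export
geno_matrix <- function(calls, map, coding = c("dosage012", "gensel_pm10")) {
  coding <- match.arg(coding)
  stopifnot(is.matrix(calls))
  if (!inherits(map, "marker_map")) map <- marker_map(map)
  if (is.null(rownames(calls))) {
    rownames(calls) <- paste0("animal_", seq_len(nrow(calls)))
  }
  if (is.null(colnames(calls))) {
    if (ncol(calls) != nrow(map)) {
      stop("genotype matrix has ", ncol(calls), " columns but map has ",
           nrow(map), " SNPs")
    }
    colnames(calls) <- map$snp_id
  }
  unknown <- setdiff(colnames(calls), map$snp_id)
  if (length(unknown) > 0) {
    stop("SNP id(s) in genotype matrix absent from map: ",
         paste(utils::head(unknown, 5), collapse = ", "),
         if (length(unknown) > 5) sprintf(" (+%d more)", length(unknown) - 5) else "")
  }
  map <- map[map$snp_id %in% colnames(calls), , drop = FALSE]
  calls <- calls[, map$snp_id, drop = FALSE]
  valid <- if (coding == "dosage012") c(0, 1, 2) else c(-10, 0, 10)
  bad <- !(calls %in% valid | is.na(calls))
  if (any(bad)) {
    idx <- which(bad)[1]
    stop("invalid genotype call ", calls[idx], " (coding ", coding, ") at row ",
         (idx - 1) %% nrow(calls) + 1, ", column ", (idx - 1) %/% nrow(calls) + 1)
  }
  structure(list(calls = calls, map = map, coding = coding),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", nrow(x$calls), " animals x ", ncol(x$calls),
      " SNPs [", x$coding, "], ",
      sum(is.na(x$calls)), " missing calls\n", sep = "")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Animal identifiers of a genotype matrix
#' @param x a `geno_matrix`.
#' @return Character vector of animal ids (row order).
#' @export
animal_ids <- function(x) {
  stopifnot(inherits(x, "geno_matrix"))
  rownames(x$calls)
}

#' Convert between genotype coding conventions
#'
#' `dosage012 -> gensel_pm10` applies `g -> 10 * (g - 1)`; the reverse
#' applies `g -> g / 10 + 1`. The map is an exact bijection on
#' \{0, 1, 2\} and round-trips without loss. Marker-effect estimates
#' scale by 1/10 between the conventions; predicted breeding-value
#' rankings are invariant.
#'
#' @param geno a `geno_matrix`.
#' @param to target coding.
#' @return A `geno_matrix` in the requested coding.
#' @export
convert_coding <- function(geno, to = c("dosage012", "gensel_pm10")) {
  to <- match.arg(to)
  stopifnot(inherits(geno, "geno_matrix"))
  if (geno$coding == to) return(geno)
  calls <- geno$calls
  calls <- if (to == "gensel_pm10") 10 * (calls - 1) else calls / 10 + 1
  geno_matrix(calls, geno$map, coding = to)
}

#' Dosage-coded call matrix
#'
#' Returns the call matrix in 0/1/2 dosage coding regardless of the
#' stored dialect.
#'
#' @param geno a `geno_matrix`.
#' @return Numeric matrix of dosages with `NA` for missing calls.
#' @export
dosage_calls <- function(geno) {
  convert_coding(geno, "dosage012")$calls
}

#' Read a genotype matrix
#'
#' Supports two text formats:
#' \describe{
#'   \item{`matrix`}{A TSV with animal ids in the first column and one
#'     column per SNP id; cells in \{0, 1, 2\} or `NA`.}
#'   \item{`plink_raw`}{The PLINK `--recode A` additive dialect:
#'     whitespace-separated with columns `FID IID PAT MAT SEX PHENOTYPE`
#'     followed by one allele-count column per SNP. Animal ids are taken
#'     from `IID`; trailing `_A`-style allele suffixes on SNP column
#'     names are stripped.}
#' }
#'
#' @param path file path.
#' @param map `marker_map` the columns must match.
#' @param format `"auto"` (sniff the header), `"matrix"` or `"plink_raw"`.
#' @param coding coding convention of the cells (matrix format only;
#'   PLINK raw is always additive dosages).
#' @return A `geno_matrix`.
#' @export
read_genotypes <- function(path, map,
                           format = c("auto", "matrix", "plink_raw"),
                           coding = "dosage012") {
  format <- match.arg(format)
  header <- strsplit(readLines(path, n = 1), "[ \t]+")[[1]]
  if (format == "auto") {
    format <- if (identical(header[1:6],
                            c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")))
      "plink_raw" else "matrix"
  }
  if (format == "plink_raw") {
    df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                            check.names = FALSE)
    ids <- as.character(df$IID)
    snp_cols <- setdiff(names(df), c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"))
    calls <- as.matrix(df[snp_cols])
    colnames(calls) <- sub("_[ACGT0-9]+$", "", snp_cols)
    coding <- "dosage012"
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
    ids <- as.character(df[[1]])
    calls <- as.matrix(df[-1])
  }
  storage.mode(calls) <- "double"
  rownames(calls) <- ids
  bad_cells <- !(calls %in% (if (coding == "dosage012") c(0, 1, 2) else c(-10, 0, 10)) |
                   is.na(calls))
  if (any(bad_cells)) {
    row <- (which(bad_cells)[1] - 1) %% nrow(calls) + 1
    stop("non-genotype cell in ", path, " at data line ", row,
         " (expected 0/1/2 or NA)")
  }
  geno_matrix(calls, map, coding = coding)
}

#' Write a genotype matrix as TSV
#'
#' Inverse of [read_genotypes()] (matrix format): animal ids in the
#' first column, one column per SNP, `NA` for missing.
#'
#' @param geno a `geno_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path) {
  stopifnot(inherits(geno, "geno_matrix"))
  df <- data.frame(animal = rownames(geno$calls), geno$calls,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Trait variance components
#'
#' Bundles the additive-genetic and residual variance of a trait and
#' derives its heritability `h2 = sigma_a2 / (sigma_a2 + sigma_e2)`.
#' `c` is the fraction of genetic variance assumed not captured by the
#' marker panel, used by the deregression record weights (default 0.4).
#'
#' @param trait_code short trait label (e.g. `"STA"` for stature).
#' @param sigma_a2 additive genetic variance (> 0).
#' @param sigma_e2 residual variance (> 0).
#' @param c fraction of genetic variance not explained by markers, in
#'   \[0, 1\].
#' @return One-row tibble of class `trait_params` with columns
#'   `trait_code`, `sigma_a2`, `sigma_e2`, `h2`, `c`.
#' @export
trait_params <- function(trait_code, sigma_a2, sigma_e2, c = 0.4) {
  stopifnot(sigma_a2 > 0, sigma_e2 > 0, c >= 0, c <= 1)
  h2 <- sigma_a2 / (sigma_a2 + sigma_e2)
  out <- tibble::tibble(trait_code = as.character(trait_code),
                        sigma_a2 = sigma_a2, sigma_e2 = sigma_e2,
                        h2 = h2, c = c)
  class(out) <- c("trait_params", class(out))
  out
}

#' Read trait variance components from YAML or TSV
#'
#' YAML layout: a list of records each with `trait_code`, `sigma_a2`,
#' `sigma_e2` and optionally `c`. TSV layout: the same fields as columns.
#'
#' @param path file path (`.yaml`/`.yml` or `.tsv`).
#' @param c default marker-shortfall fraction used when the file omits it.
#' @return A `trait_params` tibble, one row per trait.
#' @export
read_trait_params <- function(path, c = 0.4) {
  if (grepl("\\.ya?ml$", path)) {
    recs <- yaml::read_yaml(path)
    df <- purrr::map_dfr(recs, tibble::as_tibble)
  } else {
    df <- tibble::as_tibble(
      utils::read.table(path, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE))
  }
  if (!"c" %in% names(df)) df$c <- c
  purrr::pmap_dfr(df[c("trait_code", "sigma_a2", "sigma_e2", "c")], trait_params)
}

#' Breeding-value record table
#'
#' Validates per-animal EBV records and computes the parent average where
#' both parent EBVs are present. Reliabilities are the squared
#' correlation between the EBV and the true breeding value and must lie
#' strictly inside (0, 1).
#'
#' @param df data frame with columns `animal`, `ebv`, `rel` and
#'   optionally `sire_ebv`, `dam_ebv`, `sire_rel`, `dam_rel`.
#' @return Tibble of class `ebv_table` with a `parent_average` column
#'   (`NA` unless both parent EBVs are known).
#' @export
ebv_table <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("animal", "ebv", "rel")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("EBV table missing column(s): ",
                             paste(miss, collapse = ", "))
  out <- tibble::as_tibble(df)
  out$animal <- as.character(out$animal)
  if (any(out$rel <= 0 | out$rel >= 1, na.rm = TRUE)) {
    stop("reliabilities must lie strictly in (0, 1)")
  }
  for (col in c("sire_ebv", "dam_ebv", "sire_rel", "dam_rel")) {
    if (!col %in% names(out)) out[[col]] <- NA_real_
  }
  out$parent_average <- ifelse(
    !is.na(out$sire_ebv) & !is.na(out$dam_ebv),
    (out$sire_ebv + out$dam_ebv) / 2, NA_real_)
  class(out) <- c("ebv_table", class(out))
  out
}

#' Read an EBV table from TSV
#'
#' Columns: `animal`, `ebv`, `rel`, optionally `sire_ebv`, `dam_ebv`,
#' `sire_rel`, `dam_rel`.
#'
#' @param path file path.
#' @return An `ebv_table` tibble.
#' @export
read_ebv_table <- function(path) {
  ebv_table(utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE))
}
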