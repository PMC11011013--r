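#' Pedigree constructor
#'
#' Validates a three-column pedigree (animal, sire, dam), resolves the
#' unknown-parent sentinel (`0`, `""` or `NA`), adds parents that are
#' referenced but never defined as founders (with a warning), and sorts
#' records topologically so every parent precedes its offspring. A cycle
#' (an animal among its own ancestors) is an error that names the
#' offending animals.
#'
#' @param df data frame with columns `animal`, `sire`, `dam`.
#' @return Tibble of class `pedigree`, topologically sorted, with `NA`
#'   for unknown parents.
#' @export
pedigree <- function(df) {
  stopifnot(is.data.frame(df))
  miss <- setdiff(c("animal", "sire", "dam"), names(df))
  if (length(miss) > 0) stop("pedigree missing column(s): ",
                             paste(miss, collapse = ", "))
  ped <- tibble::tibble(animal = as.character(df$animal),
                        sire = as.character(df$sire),
                        dam = as.character(df$dam))
  ped$sire[ped$sire %in% c("0", "") | is.na(ped$sire)] <- NA_character_
  ped$dam[ped$dam %in% c("0", "") | is.na(ped$dam)] <- NA_character_
  if (anyDuplicated(ped$animal)) {
    stop("duplicated animal id(s) in pedigree: ",
         paste(unique(ped$animal[duplicated(ped$animal)]), collapse = ", "))
  }
  parents <- stats::na.omit(unique(c(ped$sire, ped$dam)))
  phantom <- setdiff(parents, ped$animal)
  if (length(phantom) > 0) {
    warning("parent(s) never defined as animals, added as founders: ",
            paste(phantom, collapse = ", "))
    ped <- dplyr::bind_rows(
      tibble::tibble(animal = phantom, sire = NA_character_,
                     dam = NA_character_),
      ped)
  }

  # Kahn topological sort over the parent -> offspring DAG
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$animal)
  n_pending <- (!is.na(ped$sire)) + (!is.na(ped$dam))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(ped$sire[i], ped$dam[i])) {
      if (!is.na(p)) children[[idx[p]]] <- c(children[[idx[p]]], i)
    }
  }
  order <- integer(0)
  ready <- which(n_pending == 0)
  while (length(ready) > 0) {
    i <- ready[1]; ready <- ready[-1]
    order <- c(order, i)
    for (ch in children[[i]]) {
      n_pending[ch] <- n_pending[ch] - 1
      if (n_pending[ch] == 0) ready <- c(ready, ch)
    }
  }
  if (length(order) < n) {
    cyc <- ped$animal[setdiff(seq_len(n), order)]
    stop("pedigree contains a cycle involving: ",
         paste(cyc, collapse = ", "))
  }
  ped <- ped[order, ]
  class(ped) <- c("pedigree", class(ped))
  ped
}

#' Read a pedigree from CSV
#'
#' Three columns `animal,sire,dam`; unknown parents coded `0` or empty.
#'
#' @param path file path.
#' @return A topologically sorted `pedigree` tibble.
#' @export
read_pedigree <- function(path) {
  pedigree(utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character"))
}

#' Founders of a pedigree
#' @param ped a `pedigree`.
#' @return Character vector of animals with both parents unknown.
#' @export
founders <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  ped$animal[is.na(ped$sire) & is.na(ped$dam)]
}
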