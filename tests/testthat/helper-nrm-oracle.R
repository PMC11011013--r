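# Independent relationship-matrix oracle: Wright's path-counting rule.
# a_ij = sum over common ancestors A and pairs of ancestor paths meeting
# only at A of (1/2)^(links) * (1 + F_A); inbreeding F_i is the kinship
# of the parents, computed the same way in topological order. This never
# touches the tabular recursion the package uses.
path_nrm <- function(sire, dam) {
  n <- length(sire)
  paths_up <- function(x) {
    res <- list(c(x))
    for (p in c(sire[x], dam[x])) if (p > 0)
      for (pp in paths_up(p)) res <- c(res, list(c(x, pp)))
    res
  }
  Fc <- numeric(n)
  kin <- function(i, j) {
    s <- 0
    for (p1 in paths_up(i)) for (p2 in paths_up(j)) {
      A <- p1[length(p1)]
      if (A != p2[length(p2)]) next
      if (length(intersect(p1, p2)) != 1L) next
      s <- s + 0.5^(length(p1) + length(p2) - 1) * (1 + Fc[A])
    }
    s
  }
  for (i in seq_len(n))
    Fc[i] <- if (sire[i] > 0 && dam[i] > 0) kin(sire[i], dam[i]) else 0
  A <- diag(1 + Fc)
  for (i in seq_len(n)) for (j in seq_len(i - 1))
    A[i, j] <- A[j, i] <- 2 * kin(i, j)
  A
}

# every valid parent assignment for animals 1..n (parents precede
# offspring, no selfing); 0 = unknown
enum_peds <- function(n) {
  opts <- function(i) {
    o <- list(c(0L, 0L))
    for (j in seq_len(i - 1)) o <- c(o, list(c(j, 0L)), list(c(0L, j)))
    if (i > 2) for (j in seq_len(i - 1)) for (kk in seq_len(i - 1))
      if (j != kk) o <- c(o, list(c(j, kk)))
    o
  }
  peds <- list(list(sire = integer(0), dam = integer(0)))
  for (i in seq_len(n)) {
    new <- vector("list", 0)
    for (p in peds) for (o in opts(i))
      new <- c(new, list(list(sire = c(p$sire, o[1]), dam = c(p$dam, o[2]))))
    peds <- new
  }
  peds
}

rand_ped_idx <- function(n) {
  sire <- dam <- integer(n)
  for (i in seq_len(n)) {
    prev <- seq_len(i - 1)
    if (length(prev) > 0 && stats::runif(1) < 0.7) {
      pr <- sample(prev, min(2, length(prev)))
      sire[i] <- pr[1]
      if (length(pr) > 1 && stats::runif(1) < 0.9) dam[i] <- pr[2]
    }
  }
  list(sire = sire, dam = dam)
}

# run the package's tabular NRM on an index-coded pedigree, rows back in
# the original 1..n order
tabular_nrm_idx <- function(sire, dam) {
  ids <- paste0("P", seq_along(sire))
  ped <- pedigree(data.frame(
    animal = ids,
    sire = ifelse(sire > 0, paste0("P", pmax(sire, 1)), "0"),
    dam = ifelse(dam > 0, paste0("P", pmax(dam, 1)), "0")))
  A <- build_nrm(ped)
  unname(A[ids, ids])
}
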