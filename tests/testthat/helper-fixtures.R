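# Small constructors used across the suite. All fixtures are built in
# code; file-based ones are written to tempfiles by the tests.

# genotype matrix with a sequential map laid over n_chr chromosomes
make_geno <- function(calls, n_chr = 1, spacing_bp = 1000,
                      coding = "dosage012") {
  k <- ncol(calls)
  if (is.null(rownames(calls))) rownames(calls) <- paste0("a", seq_len(nrow(calls)))
  if (is.null(colnames(calls))) colnames(calls) <- paste0("s", seq_len(k))
  per_chr <- ceiling(k / n_chr)
  map <- marker_map(data.frame(
    snp_id = colnames(calls),
    chr = rep(seq_len(n_chr), each = per_chr)[seq_len(k)],
    pos_bp = (((seq_len(k) - 1) %% per_chr) * spacing_bp) + 1),
    autosomes = seq_len(max(n_chr, 29)))
  geno_matrix(calls, map, coding = coding)
}

# one-SNP column realizing exact genotype counts (order shuffle-free)
col_from_counts <- function(n0, n1, n2, n_na = 0) {
  c(rep(0, n0), rep(1, n1), rep(2, n2), rep(NA, n_na))
}

# simulated population shared by several mid-size checks
sim_population <- function(n_founders = 200, n_gen = 1, opm = 2,
                           n_snps = 400, seed = 42, n_chr = 4,
                           spacing_bp = 100000) {
  ped <- simulate_pedigree(n_founders, n_gen, opm, seed = seed)
  g <- gene_drop_genotypes(ped, n_snps, seed = seed + 1, n_chr = n_chr,
                           spacing_bp = spacing_bp)
  list(ped = ped, geno = g)
}
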