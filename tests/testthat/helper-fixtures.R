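# Small programmatic fixtures shared across test files.

small_params <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(n_sites = 3000L, n_sites_chrx = 300L,
                   chrom_lengths_mb = c(chr1 = 100, chr2 = 80, chrX = 60),
                   seed = seed)
  do.call(sim_params, utils::modifyList(defaults, args))
}

# A hand-built sim_truth with full control over genotypes and transmission:
# every site on one autosome, constant parental genotypes and fetal alleles.
manual_truth <- function(n, mother_alleles, father_alleles,
                         fetus_pat, fetus_mat,
                         ref = "A", alt = "G", chrom = "chr1",
                         f = 0.0569, mean_depth = 33.6, eps = 0,
                         fixed_depth = TRUE, seed = 1) {
  params <- sim_params(f = f, mean_depth = mean_depth, eps = eps,
                       chrom_lengths_mb = setNames(max(1, n * 100 / 1e6), chrom),
                       n_sites = n, fixed_depth = fixed_depth, seed = seed)
  sites <- new_sites(rep(chrom, n), seq_len(n) * 100L, rep(ref, n), rep(alt, n))
  mother <- new_phased_parent("mother", sites,
                              rep(mother_alleles[1], n), rep(mother_alleles[2], n))
  father <- new_phased_parent("father", sites,
                              rep(father_alleles[1], n), rep(father_alleles[2], n))
  structure(list(params = params, sites = sites, mother = mother,
                 father = father,
                 fetus = list(pat_allele = rep(fetus_pat, n),
                              mat_allele = rep(fetus_mat, n),
                              path_pat = rep(0L, n), path_mat = rep(0L, n)),
                 crossovers = data.frame(parent = character(0),
                                         chrom = character(0), pos = numeric(0)),
                 grandparents = NULL),
            class = "sim_truth")
}
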