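# cff-DNA fraction estimation from discordant homozygous sites: where the
# parents are homozygous for different alleles, the paternal allele (which
# the mother lacks) appears in plasma only through fetal DNA, at expected
# fraction f/2. A method-of-moments estimator on the pooled counts inverts
# this, with an optional correction for symmetric sequencing error.

#' Estimate the cff-DNA fraction from plasma counts
#'
#' Pools reads over `DISCORDANT_HOM` sites (mother homozygous, father
#' homozygous for the other allele). With `p_hat` the pooled fraction of
#' reads carrying the paternal-specific allele, returns
#' `f_hat = 2 (p_hat - eps) / (1 - 2 eps)`, clipped to `[0, 1]`
#' (`eps = 0` disables the error correction). Per-chromosome estimates use
#' the same pooled estimator within each chromosome.
#'
#' @param counts plasma count table aligned with the parental sites.
#' @param classes per-site classes from [classify_sites()].
#' @param mother the mother's `phased_parent` (identifies which allele at
#'   each discordant site is the paternal-specific one).
#' @param eps symmetric per-read error probability (default 0).
#' @param min_depth minimum per-site depth for a site to be pooled.
#' @return a [new_fetal_fraction_estimate()] object.
#' @export
estimate_ff <- function(counts, classes, mother, eps = 0, min_depth = 1) {
  stopifnot(inherits(mother, "phased_parent"), eps >= 0, eps < 0.5)
  check_counts_aligned(counts, mother$sites)
  depth <- counts$n_ref + counts$n_alt
  use <- which(classes == "DISCORDANT_HOM" & depth >= min_depth)
  if (length(use) == 0) {
    stop("no discordant homozygous sites with depth >= ", min_depth, call. = FALSE)
  }
  # the paternal-specific allele is the one the mother lacks
  mother_is_ref <- mother$hap0[use] == counts$ref[use]
  pat_reads <- ifelse(mother_is_ref, counts$n_alt[use], counts$n_ref[use])
  tot <- depth[use]
  if (sum(tot) == 0) stop("all qualifying sites have zero depth", call. = FALSE)
  mom_est <- function(k, n) {
    p_hat <- sum(k) / sum(n)
    min(1, max(0, 2 * (p_hat - eps) / (1 - 2 * eps)))
  }
  f_hat <- mom_est(pat_reads, tot)
  per_chrom <- vapply(split(seq_along(use), counts$chrom[use]),
                      function(ii) mom_est(pat_reads[ii], tot[ii]),
                      numeric(1))
  new_fetal_fraction_estimate(f_hat, length(use), per_chrom)
}
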