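# The site-by-site strategy (SBSS) baseline: call every site independently
# from its own reads, without haplotype context. Its failure modes at low
# cff-DNA fraction and moderate depth -- absent paternal-specific alleles,
# opposite allelic imbalance at maternal-only heterozygous sites -- are what
# motivate the HMM. Also the naive de-novo scan over uninformative sites.

#' Paternal-specific allele detection and absence rate
#'
#' At paternal-only heterozygous sites, SBSS takes `threshold` or more reads
#' matching the paternal-specific allele (the father's allele absent from
#' the maternal genotype) as evidence of its transmission. The absence rate
#' is the fraction of truly transmitted paternal-specific alleles (or, with
#' no truth, of all paternal-only sites) with fewer than `threshold`
#' supporting reads.
#'
#' @param counts plasma count table.
#' @param classes per-site classes from [classify_sites()].
#' @param mother,father `phased_parent` objects.
#' @param threshold detection read threshold (default 1).
#' @param truth optional `sim_truth` restricting the rate to sites where the
#'   paternal-specific allele was truly transmitted.
#' @return list with `absence_rate`, `n_sites` and `calls` (per-site table
#'   with the paternal-specific read count and a `detected` flag).
#' @export
paternal_absence_rate <- function(counts, classes, mother, father,
                                  threshold = 1, truth = NULL) {
  check_counts_aligned(counts, mother$sites)
  idx <- which(classes == "PATERNAL_ONLY_HET")
  if (length(idx) == 0) stop("no paternal-only heterozygous sites", call. = FALSE)
  mother_is_ref <- mother$hap0[idx] == counts$ref[idx]
  pat_reads <- ifelse(mother_is_ref, counts$n_alt[idx], counts$n_ref[idx])
  pat_allele <- ifelse(mother_is_ref, counts$alt[idx], counts$ref[idx])
  calls <- data.frame(counts[idx, c("chrom", "pos")],
                      paternal_allele = pat_allele,
                      paternal_reads = pat_reads,
                      detected = pat_reads >= threshold,
                      stringsAsFactors = FALSE)
  eval_idx <- seq_along(idx)
  if (!is.null(truth)) {
    transmitted <- truth$fetus$pat_allele[idx] == pat_allele
    eval_idx <- which(transmitted)
    calls$transmitted <- transmitted
  }
  list(absence_rate = mean(!calls$detected[eval_idx]),
       n_sites = length(eval_idx), calls = calls)
}

#' Maternal transmission calls by allelic imbalance
#'
#' At each maternal-only heterozygous site, SBSS calls the maternal allele
#' with the higher read count as transmitted (equal counts: tie, no call).
#' With truth available, reports the opposite-imbalance rate: the fraction
#' of non-tie sites whose call contradicts the truly transmitted allele.
#'
#' @inheritParams paternal_absence_rate
#' @return list with `calls` (per-site called allele or NA on ties),
#'   `n_called`, `n_tie`, and (given truth) `opposite_rate` and `accuracy`.
#' @export
maternal_imbalance_call <- function(counts, classes, mother, truth = NULL) {
  check_counts_aligned(counts, mother$sites)
  idx <- which(classes == "MATERNAL_ONLY_HET")
  if (length(idx) == 0) stop("no maternal-only heterozygous sites", call. = FALSE)
  # read counts for each maternal haplotype allele
  h0_is_ref <- mother$hap0[idx] == counts$ref[idx]
  k0 <- ifelse(h0_is_ref, counts$n_ref[idx], counts$n_alt[idx])
  k1 <- ifelse(h0_is_ref, counts$n_alt[idx], counts$n_ref[idx])
  call <- ifelse(k0 > k1, mother$hap0[idx],
                 ifelse(k1 > k0, mother$hap1[idx], NA_character_))
  calls <- data.frame(counts[idx, c("chrom", "pos")],
                      reads_hap0 = k0, reads_hap1 = k1, call = call,
                      stringsAsFactors = FALSE)
  out <- list(calls = calls, n_called = sum(!is.na(call)),
              n_tie = sum(is.na(call)))
  if (!is.null(truth)) {
    informative <- !is.na(call)
    wrong <- call[informative] != truth$fetus$mat_allele[idx][informative]
    out$opposite_rate <- mean(wrong)
    out$accuracy <- mean(!wrong)
  }
  out
}

#' Naive de-novo mutation scan
#'
#' Flags biparentally uninformative sites (both parents homozygous for the
#' same allele) carrying `min_reads` or more reads of the non-parental
#' allele. With spiked truth, reports sensitivity = detected / spiked.
#'
#' @inheritParams paternal_absence_rate
#' @param min_reads detection threshold (default 1).
#' @param mutations optional mutation table from [spike_denovo()].
#' @return list with `candidates` (flagged sites), `n_candidates`, and
#'   (given `mutations`) `sensitivity`, `n_detected`, `n_spiked`.
#' @export
denovo_scan <- function(counts, classes, mother, min_reads = 1,
                        mutations = NULL) {
  check_counts_aligned(counts, mother$sites)
  idx <- which(classes == "UNINFORMATIVE" & !is_chrx(counts$chrom))
  parents_ref <- mother$hap0[idx] == counts$ref[idx]
  nonpar_reads <- ifelse(parents_ref, counts$n_alt[idx], counts$n_ref[idx])
  hit <- nonpar_reads >= min_reads
  candidates <- data.frame(counts[idx[hit], c("chrom", "pos")],
                           allele = ifelse(parents_ref, counts$alt[idx],
                                           counts$ref[idx])[hit],
                           reads = nonpar_reads[hit],
                           stringsAsFactors = FALSE)
  out <- list(candidates = candidates, n_candidates = nrow(candidates))
  if (!is.null(mutations)) {
    if (nrow(mutations) == 0) {
      out$sensitivity <- NA_real_
      out$n_detected <- 0L
      out$n_spiked <- 0L
    } else {
      key_c <- paste(candidates$chrom, candidates$pos)
      key_m <- paste(mutations$chrom, mutations$pos)
      out$n_detected <- sum(key_m %in% key_c)
      out$n_spiked <- nrow(mutations)
      out$sensitivity <- out$n_detected / out$n_spiked
    }
  }
  out
}

#' Per-allele plasma concentration by maximum likelihood
#'
#' Under the per-site binomial read model, the maximum-likelihood
#' concentration of an allele is its read fraction `k / n`. Reports the
#' per-site MLEs for ref and alt, aggregated as per-chromosome means
#' (sites with zero depth are skipped).
#'
#' @param counts plasma count table.
#' @return list with `per_site` (chrom, pos, conc_ref, conc_alt) and
#'   `per_chromosome` (mean concentrations by chromosome).
#' @export
allele_concentration_mle <- function(counts) {
  depth <- counts$n_ref + counts$n_alt
  keep <- depth > 0
  per_site <- data.frame(counts[keep, c("chrom", "pos")],
                         conc_ref = counts$n_ref[keep] / depth[keep],
                         conc_alt = counts$n_alt[keep] / depth[keep])
  agg <- do.call(rbind, lapply(split(per_site, per_site$chrom), function(d) {
    data.frame(chrom = d$chrom[1], mean_conc_ref = mean(d$conc_ref),
               mean_conc_alt = mean(d$conc_alt), n_sites = nrow(d))
  }))
  rownames(agg) <- NULL
  list(per_site = per_site, per_chromosome = agg)
}
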