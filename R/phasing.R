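# Parental haplotype construction from trio genotypes (a parent plus that
# parent's own parents), with a windowed panel-vote resolver for the sites
# Mendelian logic cannot orient. The resolver is a desk-scale stand-in for
# statistical phasing against a reference panel: it completes a partial trio
# phase by majority vote of panel haplotypes over flanking phased sites.

#' Phase a parent from its own parents' genotypes (trio phasing)
#'
#' At each site, the parent's two alleles are oriented as
#' (transmitted-from-grandfather | transmitted-from-grandmother) whenever
#' Mendelian transmission forces a unique assignment. Sites where both
#' orientations are Mendelian-consistent (e.g. all three individuals
#' heterozygous) are flagged `AMBIGUOUS`; Mendelian-impossible sites are
#' flagged `INCONSISTENT` and excluded downstream.
#'
#' @param sites site table shared by the three genotype matrices.
#' @param parent_gt,grandfather_gt,grandmother_gt 2-column character
#'   matrices of unordered alleles, one row per site.
#' @return object of class `partial_phase`: the site table plus columns
#'   `allele_gf`, `allele_gm` (NA unless phased) and
#'   `status` in `{PHASED, AMBIGUOUS, INCONSISTENT}`.
#' @export
trio_phase <- function(sites, parent_gt, grandfather_gt, grandmother_gt) {
  validate_sites(sites)
  n <- nrow(sites)
  for (g in list(parent_gt, grandfather_gt, grandmother_gt)) {
    if (!is.matrix(g) || nrow(g) != n || ncol(g) != 2) {
      stop("genotypes must be 2-column matrices over the shared site list",
           call. = FALSE)
    }
  }
  allele_gf <- allele_gm <- rep(NA_character_, n)
  status <- rep(NA_character_, n)
  in_gt <- function(a, g) a == g[, 1] | a == g[, 2]
  p1 <- parent_gt[, 1]; p2 <- parent_gt[, 2]
  # orientation A: p1 from grandfather, p2 from grandmother; B: the reverse
  okA <- in_gt(p1, grandfather_gt) & in_gt(p2, grandmother_gt)
  okB <- in_gt(p2, grandfather_gt) & in_gt(p1, grandmother_gt)
  hom <- p1 == p2
  status[!okA & !okB] <- "INCONSISTENT"
  amb <- okA & okB & !hom
  status[amb] <- "AMBIGUOUS"
  forced <- is.na(status)
  useA <- forced & okA
  useB <- forced & !okA
  allele_gf[useA] <- p1[useA]; allele_gm[useA] <- p2[useA]
  allele_gf[useB] <- p2[useB]; allele_gm[useB] <- p1[useB]
  status[forced] <- "PHASED"
  out <- sites
  out$allele_gf <- allele_gf
  out$allele_gm <- allele_gm
  out$status <- status
  class(out) <- c("partial_phase", "data.frame")
  out
}

#' Resolve remaining phase ambiguity with a haplotype panel
#'
#' Each ambiguous heterozygous site is oriented by a majority vote of panel
#' haplotypes: a panel haplotype is matched to the grandfather- or
#' grandmother-derived haplotype over the nearest `window` trio-phased
#' heterozygous sites on each side, and votes its own allele at the
#' ambiguous site onto the matched side. Ties, and ambiguity left by an
#' empty panel, are resolved by a seeded coin flip with a warning.
#'
#' @param partial a [trio_phase()] result.
#' @param panel character matrix of panel haplotypes (sites x haplotypes),
#'   or `NULL` for no panel.
#' @param role `"mother"` or `"father"` for the output object.
#' @param window number of flanking phased heterozygous sites per side.
#' @param seed optional integer seed for coin flips.
#' @return list with `parent` (a fully phased [new_phased_parent()] object
#'   over the Mendelian-consistent sites, hap0 = grandfather-derived),
#'   `inferred_rate_before` and `inferred_rate_after` (fraction of
#'   consistent sites phased), `source` (per-site `TRIO`/`PANEL`/`RANDOM`),
#'   and `n_inconsistent`.
#' @export
panel_resolve <- function(partial, panel = NULL, role = "mother",
                          window = 10, seed = NULL) {
  stopifnot(inherits(partial, "partial_phase"))
  if (!is.null(seed)) set.seed(seed)
  keep <- partial$status != "INCONSISTENT"
  n_inc <- sum(!keep)
  if (n_inc > 0) {
    message("excluding ", n_inc, " Mendelian-inconsistent site(s)")
  }
  pp <- partial[keep, , drop = FALSE]
  if (!is.null(panel)) panel <- panel[keep, , drop = FALSE]
  n <- nrow(pp)
  rate_before <- mean(pp$status == "PHASED")
  source <- ifelse(pp$status == "PHASED", "TRIO", NA_character_)
  a_gf <- pp$allele_gf
  a_gm <- pp$allele_gm
  amb <- which(pp$status == "AMBIGUOUS")
  phased_het <- which(pp$status == "PHASED" & pp$allele_gf != pp$allele_gm)
  no_panel_warned <- FALSE
  for (i in amb) {
    het_alleles <- c(pp$ref[i], pp$alt[i])
    votes <- c(0, 0)  # weighted votes for allele_gf[i] == het_alleles[1] vs [2]
    if (!is.null(panel) && ncol(panel) > 0 && length(phased_het) > 0) {
      before <- tail(phased_het[phased_het < i], window)
      after <- head(phased_het[phased_het > i], window)
      anchors <- c(before, after)
      if (length(anchors) > 0) {
        # weight each panel haplotype by its match margin: locally IBD
        # haplotypes match one side at nearly every anchor, unrelated ones
        # hover near half and would otherwise drown out the signal
        for (h in seq_len(ncol(panel))) {
          a0 <- sum(panel[anchors, h] == a_gf[anchors])
          a1 <- sum(panel[anchors, h] == a_gm[anchors])
          margin <- abs(a0 - a1)
          if (margin < 2) next
          side_allele <- panel[i, h]
          if (!side_allele %in% het_alleles) next
          k <- match(side_allele, het_alleles)
          if (a0 > a1) votes[k] <- votes[k] + margin
          else votes[3L - k] <- votes[3L - k] + margin
        }
      }
    }
    if (votes[1] != votes[2]) {
      pick <- which.max(votes)
      source[i] <- "PANEL"
    } else {
      if ((is.null(panel) || ncol(panel) == 0) && !no_panel_warned) {
        warning("no panel available; resolving remaining ambiguous sites by coin flip",
                call. = FALSE)
        no_panel_warned <- TRUE
      }
      pick <- sample(1:2, 1)
      source[i] <- "RANDOM"
    }
    a_gf[i] <- het_alleles[pick]
    a_gm[i] <- het_alleles[3L - pick]
  }
  parent <- new_phased_parent(role, pp[c("chrom", "pos", "ref", "alt")],
                              a_gf, a_gm)
  list(parent = parent,
       inferred_rate_before = rate_before,
       inferred_rate_after = 1.0,
       source = source,
       n_inconsistent = n_inc)
}

#' Switch-error rate between an inferred and a true phasing
#'
#' Fraction of consecutive heterozygous site pairs (within a chromosome)
#' whose relative phase disagrees between the inferred and true haplotypes.
#' The statistic is invariant under a global hap0/hap1 relabeling, so it is
#' automatically minimized over the labeling.
#'
#' @param inferred,truth `phased_parent` objects over identical sites, both
#'   fully phased.
#' @return list with `rate`, `n_switches`, `n_pairs`; `rate` is `NA` (with
#'   `defined = FALSE`) when fewer than 2 heterozygous sites exist.
#' @export
switch_error_rate <- function(inferred, truth) {
  stopifnot(inherits(inferred, "phased_parent"), inherits(truth, "phased_parent"))
  if (!identical(inferred$sites[c("chrom", "pos")], truth$sites[c("chrom", "pos")])) {
    stop("inferred and truth must cover identical sites", call. = FALSE)
  }
  het <- parent_is_het(truth)
  if (any(het != parent_is_het(inferred))) {
    stop("inferred genotypes disagree with truth at some heterozygous sites",
         call. = FALSE)
  }
  n_sw <- 0L; n_pairs <- 0L
  for (ch in unique(truth$sites$chrom)) {
    sel <- which(het & truth$sites$chrom == ch)
    if (length(sel) < 2) next
    o <- inferred$hap0[sel] == truth$hap0[sel]
    n_sw <- n_sw + sum(o[-1] != o[-length(o)])
    n_pairs <- n_pairs + length(sel) - 1L
  }
  if (n_pairs == 0) {
    return(list(rate = NA_real_, n_switches = 0L, n_pairs = 0L, defined = FALSE))
  }
  list(rate = n_sw / n_pairs, n_switches = n_sw, n_pairs = n_pairs,
       defined = TRUE)
}
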