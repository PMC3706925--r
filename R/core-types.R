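# Shared genomic data model: sites, phased parents, plasma counts,
# and the five-way informativeness classification that drives everything else.

DNA_BASES <- c("A", "C", "G", "T")

#' Site-class labels
#'
#' The five informativeness classes of a biallelic site given the two
#' parental genotypes. `PATERNAL_ONLY_HET`, `MATERNAL_ONLY_HET` and
#' `BIPARENTAL_HET` are the classes the HMM decodes; `DISCORDANT_HOM`
#' (parents homozygous for different alleles) drives fetal-fraction
#' estimation; `UNINFORMATIVE` sites carry no transmission signal.
#'
#' @export
SITE_CLASSES <- c("PATERNAL_ONLY_HET", "MATERNAL_ONLY_HET", "BIPARENTAL_HET",
                  "DISCORDANT_HOM", "UNINFORMATIVE")

VALID_CHROMS <- c(paste0("chr", 1:22), "chrX")

#' Normalize and validate chromosome names
#'
#' Accepts `"1"`..`"22"`, `"X"` with or without a `"chr"` prefix and returns
#' the canonical `"chr*"` form. chrY and mitochondrial contigs are not part
#' of the model (the method reconstructs autosomes plus the maternally
#' transmitted X) and are rejected, as is anything unrecognized.
#'
#' @param chrom character vector of chromosome names.
#' @return character vector of canonical names.
#' @export
normalize_chrom <- function(chrom) {
  x <- as.character(chrom)
  x <- ifelse(grepl("^chr", x), x, paste0("chr", x))
  bad <- unique(x[!x %in% VALID_CHROMS])
  if (length(bad) > 0) {
    stop("unsupported chromosome name(s): ", paste(bad, collapse = ", "),
         " (autosomes chr1..chr22 and chrX are supported)", call. = FALSE)
  }
  x
}

is_chrx <- function(chrom) chrom == "chrX"

#' Construct a validated site table
#'
#' @param chrom,pos,ref,alt vectors describing biallelic SNVs; `pos` is
#'   1-based and must be strictly increasing within each chromosome.
#' @return `data.frame` with columns chrom, pos, ref, alt.
#' @export
new_sites <- function(chrom, pos, ref, alt) {
  df <- data.frame(chrom = normalize_chrom(chrom), pos = as.integer(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   stringsAsFactors = FALSE)
  validate_sites(df)
  df
}

validate_sites <- function(sites) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  if (!all(sites$ref %in% DNA_BASES) || !all(sites$alt %in% DNA_BASES)) {
    stop("ref/alt must be single bases in {A,C,G,T} (biallelic SNVs only)",
         call. = FALSE)
  }
  if (any(sites$ref == sites$alt)) stop("ref must differ from alt", call. = FALSE)
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("positions must be strictly increasing within ", ch, call. = FALSE)
    }
  }
  invisible(sites)
}

#' Construct a phased parent
#'
#' A parent is two ordered haplotype allele sequences (`hap0`, `hap1`) over a
#' shared site list. For the father on chrX (male-fetus model) the genotype
#' is haploid: `hap1` is `NA` at chrX rows.
#'
#' @param role `"mother"` or `"father"`.
#' @param sites site table as from [new_sites()].
#' @param hap0,hap1 character vectors of alleles, each element equal to the
#'   site's ref or alt allele (`hap1` may be `NA` on chrX for the father).
#' @return object of class `phased_parent`.
#' @export
new_phased_parent <- function(role, sites, hap0, hap1) {
  role <- match.arg(role, c("mother", "father"))
  validate_sites(sites)
  n <- nrow(sites)
  stopifnot(length(hap0) == n, length(hap1) == n)
  ok0 <- hap0 == sites$ref | hap0 == sites$alt
  ok1 <- is.na(hap1) | hap1 == sites$ref | hap1 == sites$alt
  if (!all(ok0) || !all(ok1)) {
    stop("haplotype alleles must match each site's ref or alt allele",
         call. = FALSE)
  }
  if (any(is.na(hap1)) && !(role == "father" && all(is_chrx(sites$chrom[is.na(hap1)])))) {
    stop("haploid (NA hap1) sites are only allowed for the father on chrX",
         call. = FALSE)
  }
  structure(list(role = role, sites = sites,
                 hap0 = as.character(hap0), hap1 = as.character(hap1)),
            class = "phased_parent")
}

#' @export
print.phased_parent <- function(x, ...) {
  cat(sprintf("<phased_parent: %s, %d sites on %d chromosome(s)>\n",
              x$role, nrow(x$sites), length(unique(x$sites$chrom))))
  invisible(x)
}

# Unordered genotype of a parent as a 2-column allele matrix (col2 NA = haploid)
parent_gt <- function(parent) cbind(parent$hap0, parent$hap1)

parent_is_het <- function(parent) {
  !is.na(parent$hap1) & parent$hap0 != parent$hap1
}

#' Construct a plasma count table
#'
#' Per-site non-duplicate ref/alt read counts from maternal plasma; the HMM
#' observation sequence. Rows align 1:1 with a parental site list.
#'
#' @param sites site table.
#' @param n_ref,n_alt non-negative integer read counts.
#' @return `data.frame` with columns chrom, pos, ref, alt, n_ref, n_alt.
#' @export
new_plasma_counts <- function(sites, n_ref, n_alt) {
  validate_sites(sites)
  stopifnot(length(n_ref) == nrow(sites), length(n_alt) == nrow(sites))
  if (any(n_ref < 0) || any(n_alt < 0)) stop("counts must be >= 0", call. = FALSE)
  df <- sites
  df$n_ref <- as.integer(n_ref)
  df$n_alt <- as.integer(n_alt)
  df
}

check_counts_aligned <- function(counts, sites) {
  if (nrow(counts) != nrow(sites) ||
      !all(counts$chrom == sites$chrom & counts$pos == sites$pos &
           counts$ref == sites$ref & counts$alt == sites$alt)) {
    stop("plasma counts do not align 1:1 with the parental site list",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Classify a single site by parental heterozygosity
#'
#' @param mother_gt unordered maternal genotype: character vector of 2 alleles.
#' @param father_gt unordered paternal genotype: 2 alleles, or a single allele
#'   on chrX when the fetus is male (the father transmits Y, not X).
#' @param chrom chromosome name.
#' @param fetal_sex `"male"` or `"female"`.
#' @return one of [SITE_CLASSES]. For a male fetus on chrX, only
#'   `MATERNAL_ONLY_HET` (mother heterozygous) or `UNINFORMATIVE` can be
#'   returned, since the father contributes no X allele to the mixture's
#'   fetal component.
#' @export
classify_site <- function(mother_gt, father_gt, chrom,
                          fetal_sex = c("male", "female")) {
  fetal_sex <- match.arg(fetal_sex)
  chrom <- normalize_chrom(chrom)
  mother_gt <- as.character(mother_gt)
  father_gt <- as.character(father_gt)
  if (length(mother_gt) != 2) stop("mother genotype must have 2 alleles", call. = FALSE)
  if (!length(father_gt) %in% 1:2) stop("father genotype must have 1 or 2 alleles", call. = FALSE)
  alleles <- unique(c(mother_gt, father_gt))
  if (!all(alleles %in% DNA_BASES)) stop("alleles must be single bases", call. = FALSE)
  if (length(alleles) > 2) {
    stop("non-biallelic genotype combination (", paste(alleles, collapse = "/"),
         "); only biallelic sites are modeled", call. = FALSE)
  }
  m_het <- mother_gt[1] != mother_gt[2]
  if (is_chrx(chrom) && fetal_sex == "male") {
    return(if (m_het) "MATERNAL_ONLY_HET" else "UNINFORMATIVE")
  }
  f_het <- length(father_gt) == 2 && father_gt[1] != father_gt[2]
  if (m_het && f_het) return("BIPARENTAL_HET")
  if (m_het) return("MATERNAL_ONLY_HET")
  if (f_het) return("PATERNAL_ONLY_HET")
  if (mother_gt[1] == father_gt[1]) "UNINFORMATIVE" else "DISCORDANT_HOM"
}

#' Classify every shared site of a parental pair
#'
#' Vectorized site classification over the common site list of a phased
#' mother/father pair.
#'
#' @param mother,father `phased_parent` objects over identical sites.
#' @param fetal_sex `"male"` or `"female"`.
#' @return factor with levels [SITE_CLASSES], one element per site.
#' @export
classify_sites <- function(mother, father, fetal_sex = c("male", "female")) {
  fetal_sex <- match.arg(fetal_sex)
  stopifnot(inherits(mother, "phased_parent"), inherits(father, "phased_parent"))
  if (!identical(mother$sites[c("chrom", "pos", "ref", "alt")],
                 father$sites[c("chrom", "pos", "ref", "alt")])) {
    stop("mother and father must share an identical site list", call. = FALSE)
  }
  m_het <- parent_is_het(mother)
  f_het <- parent_is_het(father)
  cls <- ifelse(m_het & f_het, "BIPARENTAL_HET",
         ifelse(m_het, "MATERNAL_ONLY_HET",
         ifelse(f_het, "PATERNAL_ONLY_HET",
         ifelse(mother$hap0 == father$hap0, "UNINFORMATIVE", "DISCORDANT_HOM"))))
  x <- is_chrx(mother$sites$chrom)
  if (fetal_sex == "male" && any(x)) {
    cls[x] <- ifelse(m_het[x], "MATERNAL_ONLY_HET", "UNINFORMATIVE")
  }
  factor(cls, levels = SITE_CLASSES)
}

#' Fetal-fraction estimate container
#'
#' @param f_hat genome-wide cff-DNA fraction in `[0, 1]`.
#' @param n_sites_used number of discordant homozygous sites pooled.
#' @param per_chromosome named numeric vector of per-chromosome estimates.
#' @return object of class `fetal_fraction_estimate`.
#' @export
new_fetal_fraction_estimate <- function(f_hat, n_sites_used, per_chromosome) {
  stopifnot(f_hat >= 0, f_hat <= 1, all(per_chromosome >= 0 & per_chromosome <= 1))
  structure(list(f_hat = f_hat, n_sites_used = as.integer(n_sites_used),
                 per_chromosome = per_chromosome),
            class = "fetal_fraction_estimate")
}

#' @export
print.fetal_fraction_estimate <- function(x, ...) {
  cat(sprintf("cff-DNA fraction estimate: %.4f (%.2f%%) from %d discordant-hom sites\n",
              x$f_hat, 100 * x$f_hat, x$n_sites_used))
  invisible(x)
}
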