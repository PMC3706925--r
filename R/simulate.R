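# Synthetic-data generator: a three-generation pedigree with recombination on
# a Haldane map, and maternal-plasma read counts whose mixture law is exactly
# the one the HMM inverts. The defaults emulate the study regime this package
# targets: cff-DNA fraction 5.69%, non-duplicate depth 33.6X, ~375k markers,
# male fetus.

#' Default chromosome lengths (Mb)
#'
#' Approximate GRCh37 lengths for chr1..chr22 and chrX, used to scale marker
#' counts and genetic maps.
#'
#' @return named numeric vector of lengths in Mb.
#' @export
default_chrom_lengths_mb <- function() {
  c(chr1 = 249, chr2 = 243, chr3 = 198, chr4 = 191, chr5 = 181, chr6 = 171,
    chr7 = 159, chr8 = 146, chr9 = 141, chr10 = 136, chr11 = 135, chr12 = 134,
    chr13 = 115, chr14 = 107, chr15 = 102, chr16 = 90, chr17 = 81, chr18 = 78,
    chr19 = 59, chr20 = 63, chr21 = 48, chr22 = 51, chrX = 155)
}

#' Simulation parameters
#'
#' The defaults are the operating point of the study this package models:
#' true fetal fraction 5.69%, mean non-duplicate autosomal depth 33.6X,
#' ~375,000 markers genome-wide, symmetric per-read error 0.005, sex-averaged
#' recombination 1.2 cM/Mb per parent (Haldane, no interference), male fetus.
#' chrX carries its own marker budget (default 5,300, so that roughly 1,900
#' maternal-heterozygous X sites arise, matching the study's chrX marker
#' count in magnitude) because array-ascertained X markers are sparser than
#' length-proportional scaling would give.
#'
#' @param f true cff-DNA fraction, in (0, 1).
#' @param mean_depth expected non-duplicate autosomal depth; chrX (male
#'   fetus) is simulated at `mean_depth * (2 - f) / 2`.
#' @param eps symmetric per-read allele flip probability, in `[0, 0.5)`.
#' @param r_maternal,r_paternal recombination rates in cM/Mb.
#' @param fetal_sex `"male"` or `"female"`.
#' @param n_sites total marker count genome-wide (autosomes get
#'   `n_sites - n_sites_chrx`, split proportionally to length).
#' @param n_sites_chrx marker count on chrX (ignored if chrX absent from
#'   `chrom_lengths_mb`).
#' @param chrom_lengths_mb named vector of chromosome lengths in Mb.
#' @param af_range range of the per-site uniform alt-allele frequency law.
#' @param fixed_depth if `TRUE`, every site gets exactly its (rounded)
#'   expected depth instead of a Poisson draw -- useful for analytic tests.
#' @param seed optional integer seed applied by the generators.
#' @return list of validated parameters, class `sim_params`.
#' @export
sim_params <- function(f = 0.0569, mean_depth = 33.6, eps = 0.005,
                       r_maternal = 1.2, r_paternal = 1.2,
                       fetal_sex = c("male", "female"),
                       n_sites = 375000L, n_sites_chrx = 5300L,
                       chrom_lengths_mb = default_chrom_lengths_mb(),
                       af_range = c(0.05, 0.95),
                       fixed_depth = FALSE, seed = NULL) {
  fetal_sex <- match.arg(fetal_sex)
  stopifnot(f > 0, f < 1, mean_depth > 0, eps >= 0, eps < 0.5,
            r_maternal >= 0, r_paternal >= 0,
            length(af_range) == 2, af_range[1] > 0, af_range[2] < 1)
  if (is.null(names(chrom_lengths_mb)) || any(chrom_lengths_mb <= 0)) {
    stop("chrom_lengths_mb must be a named vector of positive lengths", call. = FALSE)
  }
  names(chrom_lengths_mb) <- normalize_chrom(names(chrom_lengths_mb))
  n_sites <- as.integer(n_sites)
  if (n_sites <= 0) stop("n_sites must be positive", call. = FALSE)
  has_x <- "chrX" %in% names(chrom_lengths_mb)
  auto <- setdiff(names(chrom_lengths_mb), "chrX")
  n_auto_total <- if (has_x) n_sites - as.integer(n_sites_chrx) else n_sites
  if (length(auto) > 0 && n_auto_total <= 0) {
    stop("n_sites leaves no autosomal markers after the chrX budget", call. = FALSE)
  }
  per_chrom <- integer(0)
  if (length(auto) > 0) {
    w <- chrom_lengths_mb[auto] / sum(chrom_lengths_mb[auto])
    per_chrom <- setNames(pmax(1L, as.integer(round(n_auto_total * w))), auto)
  }
  if (has_x) per_chrom <- c(per_chrom, chrX = as.integer(n_sites_chrx))
  structure(list(f = f, mean_depth = mean_depth, eps = eps,
                 r_maternal = r_maternal, r_paternal = r_paternal,
                 fetal_sex = fetal_sex,
                 chrom_lengths_mb = chrom_lengths_mb,
                 n_sites_per_chrom = per_chrom,
                 af_range = af_range, fixed_depth = fixed_depth, seed = seed),
            class = "sim_params")
}

# One meiosis over a site list: Poisson crossover count (Haldane/no
# interference), uniform positions, random starting haplotype. hapA is
# transmitted where path == 0.
meiosis <- function(hapA, hapB, pos, length_bp, rate_cm_mb) {
  k <- rpois(1, length_bp / 1e6 * rate_cm_mb / 100)
  xo <- sort(runif(k, min = 0, max = length_bp))
  start <- sample(0:1, 1)
  path <- as.integer((start + findInterval(pos, xo)) %% 2)
  list(allele = ifelse(path == 0L, hapA, hapB), path = path,
       crossovers = xo, start = start)
}

random_biallelic_alleles <- function(n) {
  ref <- sample(DNA_BASES, n, replace = TRUE)
  alt <- sample(DNA_BASES, n, replace = TRUE)
  while (any(clash <- alt == ref)) {
    alt[clash] <- sample(DNA_BASES, sum(clash), replace = TRUE)
  }
  list(ref = ref, alt = alt)
}

#' Simulate a three-generation pedigree with recombination
#'
#' Draws four grandparental haplotype pairs site-independently from the
#' allele-frequency law, forms each parent by one meiosis per grandparent
#' (Poisson crossovers under the Haldane map, uniform positions, no
#' interference), and forms the fetus by one meiosis per parent. On chrX the
#' male grandparents and (for a male fetus) the father are haploid; a male
#' fetus receives one maternal recombinant X and no paternal X.
#'
#' @param params a [sim_params()] object.
#' @return object of class `sim_truth`: a list with elements `params`,
#'   `sites` (marker table with the drawn alt-allele frequency `af`),
#'   `mother` and `father` (`phased_parent`), `fetus` (`pat_allele`,
#'   `mat_allele`, `path_pat`, `path_mat`; paternal entries `NA` on chrX for
#'   a male fetus), `crossovers` (data frame: parent, chrom, pos -- the
#'   fetal meioses only) and `grandparents`.
#' @export
simulate_pedigree <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  chroms <- names(params$n_sites_per_chrom)
  male <- params$fetal_sex == "male"

  site_list <- list(); gp_list <- list()
  mo0 <- mo1 <- fa0 <- fa1 <- character(0)
  pat_allele <- mat_allele <- character(0)
  path_pat <- path_mat <- integer(0)
  xo_rows <- list()

  for (ch in chroms) {
    n <- params$n_sites_per_chrom[[ch]]
    if (n <= 0) stop("zero sites requested on ", ch, call. = FALSE)
    L <- params$chrom_lengths_mb[[ch]] * 1e6
    pos <- sort(sample.int(as.integer(L), n))
    al <- random_biallelic_alleles(n)
    af <- runif(n, params$af_range[1], params$af_range[2])
    draw_hap <- function() ifelse(runif(n) < af, al$alt, al$ref)
    x <- ch == "chrX"

    # grandparents: ff/mf are male (haploid X), fm/mm female
    gp <- list(
      ff = list(hap0 = draw_hap(), hap1 = if (x) NULL else draw_hap()),
      fm = list(hap0 = draw_hap(), hap1 = draw_hap()),
      mf = list(hap0 = draw_hap(), hap1 = if (x) NULL else draw_hap()),
      mm = list(hap0 = draw_hap(), hap1 = draw_hap()))

    if (!x) {
      f0 <- meiosis(gp$ff$hap0, gp$ff$hap1, pos, L, params$r_paternal)$allele
      f1 <- meiosis(gp$fm$hap0, gp$fm$hap1, pos, L, params$r_maternal)$allele
      m0 <- meiosis(gp$mf$hap0, gp$mf$hap1, pos, L, params$r_paternal)$allele
      m1 <- meiosis(gp$mm$hap0, gp$mm$hap1, pos, L, params$r_maternal)$allele
    } else {
      # father's X comes (recombined) from his mother; mother's hap0 is her
      # father's single X verbatim, hap1 a recombinant of her mother's pair
      f0 <- meiosis(gp$fm$hap0, gp$fm$hap1, pos, L, params$r_maternal)$allele
      f1 <- rep(NA_character_, n)
      m0 <- gp$mf$hap0
      m1 <- meiosis(gp$mm$hap0, gp$mm$hap1, pos, L, params$r_maternal)$allele
    }

    mm_mei <- meiosis(m0, m1, pos, L, params$r_maternal)
    mat_allele <- c(mat_allele, mm_mei$allele)
    path_mat <- c(path_mat, mm_mei$path)
    if (length(mm_mei$crossovers) > 0) {
      xo_rows[[length(xo_rows) + 1]] <-
        data.frame(parent = "maternal", chrom = ch, pos = mm_mei$crossovers)
    }
    if (!x) {
      fp_mei <- meiosis(f0, f1, pos, L, params$r_paternal)
      pat_allele <- c(pat_allele, fp_mei$allele)
      path_pat <- c(path_pat, fp_mei$path)
      if (length(fp_mei$crossovers) > 0) {
        xo_rows[[length(xo_rows) + 1]] <-
          data.frame(parent = "paternal", chrom = ch, pos = fp_mei$crossovers)
      }
    } else if (male) {
      pat_allele <- c(pat_allele, rep(NA_character_, n))
      path_pat <- c(path_pat, rep(NA_integer_, n))
    } else {
      # female fetus: father's single X transmitted without recombination
      pat_allele <- c(pat_allele, f0)
      path_pat <- c(path_pat, rep(0L, n))
    }

    site_list[[ch]] <- data.frame(chrom = ch, pos = pos, ref = al$ref,
                                  alt = al$alt, af = af,
                                  stringsAsFactors = FALSE)
    gp_list[[ch]] <- gp
    fa0 <- c(fa0, f0); fa1 <- c(fa1, f1)
    mo0 <- c(mo0, m0); mo1 <- c(mo1, m1)
  }

  sites <- do.call(rbind, site_list)
  rownames(sites) <- NULL
  core <- sites[c("chrom", "pos", "ref", "alt")]
  mother <- new_phased_parent("mother", core, mo0, mo1)
  father <- new_phased_parent("father", core, fa0, fa1)
  crossovers <- if (length(xo_rows) > 0) do.call(rbind, xo_rows) else
    data.frame(parent = character(0), chrom = character(0), pos = numeric(0))
  structure(list(params = params, sites = sites, mother = mother,
                 father = father,
                 fetus = list(pat_allele = pat_allele, mat_allele = mat_allele,
                              path_pat = path_pat, path_mat = path_mat),
                 crossovers = crossovers, grandparents = gp_list),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth: %d sites, %d chromosomes, f = %.4f, %s fetus, %d fetal crossovers>\n",
              nrow(x$sites), length(unique(x$sites$chrom)), x$params$f,
              x$params$fetal_sex, nrow(x$crossovers)))
  invisible(x)
}

# Expected alt-read probability in plasma given maternal/fetal alt dosages.
# Autosome: theta = (1-f) gM/2 + f gF/2. chrX, male fetus: the fetal
# contribution is a single maternal-derived allele, so
# theta = ((1-f) gM + f 1[transmitted allele is alt]) / (2 - f).
plasma_theta <- function(g_m, g_f, f, chrx_male) {
  ifelse(chrx_male,
         ((1 - f) * g_m + f * g_f) / (2 - f),
         (1 - f) * g_m / 2 + f * g_f / 2)
}

apply_error <- function(theta, eps) theta * (1 - eps) + (1 - theta) * eps

#' Simulate maternal plasma read counts
#'
#' Per autosomal site: depth `n ~ Poisson(mean_depth)` and alt count
#' `k ~ Binomial(n, theta_err)` with
#' `theta = (1-f) g_M/2 + f g_F/2` (`g_M`, `g_F` the maternal and fetal
#' alt dosages) and `theta_err = theta (1-eps) + (1-theta) eps`. Per chrX
#' site with a male fetus the fetus contributes one maternal-derived allele:
#' depth `n ~ Poisson(mean_depth (2-f)/2)` and
#' `theta = ((1-f) g_M + f 1[transmitted maternal allele is alt]) / (2-f)`.
#'
#' @param truth a [simulate_pedigree()] result (possibly after
#'   [spike_denovo()]).
#' @param params simulation parameters; defaults to `truth$params`.
#' @return plasma count table as from [new_plasma_counts()].
#' @export
simulate_plasma <- function(truth, params = truth$params) {
  stopifnot(inherits(truth, "sim_truth"), inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed + 1L)
  sites <- truth$sites
  n_sites <- nrow(sites)
  alt <- sites$alt
  g_m <- (truth$mother$hap0 == alt) + (truth$mother$hap1 == alt)
  xm <- is_chrx(sites$chrom) & params$fetal_sex == "male"
  g_f <- ifelse(xm, as.integer(truth$fetus$mat_allele == alt),
                ifelse(is.na(truth$fetus$pat_allele), NA_integer_,
                       (truth$fetus$pat_allele == alt)) +
                  (truth$fetus$mat_allele == alt))
  mu <- ifelse(xm, params$mean_depth * (2 - params$f) / 2, params$mean_depth)
  n <- if (params$fixed_depth) as.integer(round(mu)) else rpois(n_sites, mu)
  theta <- apply_error(plasma_theta(g_m, g_f, params$f, xm), params$eps)
  k_alt <- rbinom(n_sites, n, theta)
  new_plasma_counts(sites[c("chrom", "pos", "ref", "alt")], n - k_alt, k_alt)
}

#' Spike fetal de-novo mutations into a simulated truth
#'
#' Selects biparentally uninformative sites (both parents homozygous for the
#' same allele) and flips one fetal allele to the allele neither parent
#' carries, so the mutant reads in plasma can only come from the fetus.
#' Supports sensitivity evaluation of the naive site-by-site de-novo scan.
#'
#' @param truth a `sim_truth`.
#' @param n_mutations number of sites to mutate.
#' @param seed optional integer seed.
#' @return list with the modified `truth` and `mutations`, a data frame of
#'   chrom, pos, mutant allele and parental origin of the flipped allele.
#' @export
spike_denovo <- function(truth, n_mutations, seed = NULL) {
  stopifnot(inherits(truth, "sim_truth"), n_mutations >= 0)
  if (!is.null(seed)) set.seed(seed)
  cls <- classify_sites(truth$mother, truth$father, truth$params$fetal_sex)
  elig <- which(cls == "UNINFORMATIVE" & !is_chrx(truth$sites$chrom))
  if (n_mutations > length(elig)) {
    stop("only ", length(elig), " uninformative sites available for ",
         n_mutations, " mutations", call. = FALSE)
  }
  if (n_mutations == 0) {
    return(list(truth = truth,
                mutations = data.frame(chrom = character(0), pos = integer(0),
                                       allele = character(0), origin = character(0))))
  }
  idx <- sort(sample(elig, n_mutations))
  sites <- truth$sites
  # parents are homozygous and identical here; the mutant allele is the other one
  mut_allele <- ifelse(truth$mother$hap0[idx] == sites$ref[idx],
                       sites$alt[idx], sites$ref[idx])
  xm <- is_chrx(sites$chrom[idx]) & truth$params$fetal_sex == "male"
  origin <- ifelse(xm, "maternal",
                   ifelse(runif(length(idx)) < 0.5, "paternal", "maternal"))
  pat <- truth$fetus$pat_allele
  mat <- truth$fetus$mat_allele
  pat[idx[origin == "paternal"]] <- mut_allele[origin == "paternal"]
  mat[idx[origin == "maternal"]] <- mut_allele[origin == "maternal"]
  truth$fetus$pat_allele <- pat
  truth$fetus$mat_allele <- mat
  list(truth = truth,
       mutations = data.frame(chrom = sites$chrom[idx], pos = sites$pos[idx],
                              allele = mut_allele, origin = origin,
                              stringsAsFactors = FALSE))
}

#' Simulate a phasing reference panel with pedigree-consistent LD
#'
#' Panel haplotypes are fresh meioses of random pairs drawn from the pool of
#' grandparental haplotypes, so they share long stretches with the parental
#' haplotypes -- the linkage structure [panel_resolve()] exploits.
#'
#' @param truth a `sim_truth`.
#' @param n_haps panel size.
#' @param rate recombination rate (cM/Mb) used for the panel meioses.
#' @param seed optional integer seed.
#' @return character matrix, `nrow(truth$sites)` rows x `n_haps` columns.
#' @export
simulate_panel <- function(truth, n_haps = 20, rate = 1.2, seed = NULL) {
  stopifnot(inherits(truth, "sim_truth"), n_haps >= 1)
  if (!is.null(seed)) set.seed(seed)
  sites <- truth$sites
  panel <- matrix(NA_character_, nrow(sites), n_haps)
  for (ch in unique(sites$chrom)) {
    sel <- sites$chrom == ch
    pos <- sites$pos[sel]
    L <- truth$params$chrom_lengths_mb[[ch]] * 1e6
    gp <- truth$grandparents[[ch]]
    pool <- list(gp$ff$hap0, gp$fm$hap0, gp$fm$hap1, gp$mf$hap0,
                 gp$mm$hap0, gp$mm$hap1)
    if (!is.null(gp$ff$hap1)) pool <- c(pool, list(gp$ff$hap1))
    if (!is.null(gp$mf$hap1)) pool <- c(pool, list(gp$mf$hap1))
    for (h in seq_len(n_haps)) {
      pick <- sample(length(pool), 2)
      panel[sel, h] <- meiosis(pool[[pick[1]]], pool[[pick[2]]], pos, L, rate)$allele
    }
  }
  panel
}
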