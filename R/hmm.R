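# The core method: a hidden Markov model over parentally transmitted
# haplotypes. Hidden state = which haplotype (0/1) each parent passed to the
# fetus at a site; 4 states on autosomes, 2 on chrX for a male fetus (the
# father transmits Y). Emissions are binomial on plasma alt-read counts with
# the mixture probability theta of the plasma model; transitions follow a
# Haldane map with independent parental meioses. All arithmetic is in
# natural-log space.

# Autosomal state order: s = 1..4 <-> (hp, hm) = (0,0), (1,0), (0,1), (1,1).
# Ties in Viterbi prefer no-switch, then the lowest state index.
STATE_HP <- c(0L, 1L, 0L, 1L)
STATE_HM <- c(0L, 0L, 1L, 1L)

#' Haldane map: switch probability between adjacent sites
#'
#' `rho = (1 - exp(-2 d)) / 2` for genetic distance `d` in Morgans, with
#' `d = delta_bp * rate / 1e8` under a constant cM/Mb map (no interference).
#'
#' @param delta_bp physical distance in bp (>= 0).
#' @param rate_cm_mb recombination rate in cM/Mb.
#' @return switch probability in `[0, 0.5)`.
#' @export
haldane_rho <- function(delta_bp, rate_cm_mb) {
  if (any(delta_bp < 0)) stop("negative inter-site distance", call. = FALSE)
  0.5 * (1 - exp(-2 * delta_bp * rate_cm_mb / 1e8))
}

# n x S matrix of per-state alt-read probabilities (before sequencing error).
# mX_alt / fX_alt are logical: is the parent's hap X allele the alt allele.
state_thetas <- function(f, m0_alt, m1_alt, f0_alt, f1_alt, chrx_male = FALSE) {
  if (f <= 0 || f >= 1) stop("f must be in (0, 1)", call. = FALSE)
  g_m <- m0_alt + m1_alt
  if (chrx_male) {
    cbind(((1 - f) * g_m + f * m0_alt) / (2 - f),
          ((1 - f) * g_m + f * m1_alt) / (2 - f))
  } else {
    cbind((1 - f) * g_m / 2 + f * (f0_alt + m0_alt) / 2,
          (1 - f) * g_m / 2 + f * (f1_alt + m0_alt) / 2,
          (1 - f) * g_m / 2 + f * (f0_alt + m1_alt) / 2,
          (1 - f) * g_m / 2 + f * (f1_alt + m1_alt) / 2)
  }
}

# Vectorized emission log-probability matrix (sites x states). n = 0 rows
# give log(1) = 0 for every state: no data, no information.
emission_matrix <- function(k_alt, depth, f, eps, m0_alt, m1_alt,
                            f0_alt = NULL, f1_alt = NULL, chrx_male = FALSE) {
  th <- apply_error(state_thetas(f, m0_alt, m1_alt, f0_alt, f1_alt, chrx_male), eps)
  matrix(dbinom(k_alt, depth, as.vector(th), log = TRUE),
         nrow = length(k_alt), ncol = ncol(th))
}

#' Emission log-probability of one HMM state at one site
#'
#' Computes `log Binomial(k; n, theta_err(state))` where `theta` follows the
#' plasma mixture law (autosomal or male-fetus chrX form) selected by the
#' transmitted-haplotype state, and `theta_err` applies the symmetric
#' per-read error.
#'
#' @param state list with `hp` and `hm` (transmitted haplotype index, 0 or
#'   1, per parent); `hp` is ignored on chrX with a male fetus.
#' @param site list with `chrom`, `alt`, `mother` (the mother's ordered
#'   hap0/hap1 alleles), `father` (hap0/hap1, or a single allele on chrX),
#'   `n_ref`, `n_alt`.
#' @param model list with `f` (fetal fraction) and `eps` (error rate).
#' @param fetal_sex `"male"` or `"female"`.
#' @return emission log-probability (0 when `n_ref + n_alt == 0`).
#' @export
emission_logprob <- function(state, site, model, fetal_sex = "male") {
  chrxm <- is_chrx(normalize_chrom(site$chrom)) && fetal_sex == "male"
  m0 <- site$mother[1] == site$alt
  m1 <- site$mother[2] == site$alt
  f0 <- site$father[1] == site$alt
  f1 <- if (length(site$father) > 1) site$father[2] == site$alt else f0
  E <- emission_matrix(site$n_alt, site$n_ref + site$n_alt, model$f, model$eps,
                       m0, m1, f0, f1, chrx_male = chrxm)
  s <- if (chrxm) state$hm + 1L else state$hp * 1L + state$hm * 2L + 1L
  E[1, s]
}

# (n-1) x S x S array of log transition matrices for consecutive chain sites.
trans_log_array <- function(delta_bp, r_paternal, r_maternal, chrx_male = FALSE) {
  if (any(delta_bp < 0)) stop("negative inter-site distance", call. = FALSE)
  rho_m <- haldane_rho(delta_bp, r_maternal)
  n1 <- length(delta_bp)
  if (chrx_male) {
    arr <- array(0, c(n1, 2, 2))
    for (a in 1:2) for (b in 1:2) {
      arr[, a, b] <- if (a == b) log1p(-rho_m) else log(rho_m)
    }
  } else {
    rho_p <- haldane_rho(delta_bp, r_paternal)
    arr <- array(0, c(n1, 4, 4))
    for (a in 1:4) for (b in 1:4) {
      lp <- if (STATE_HP[a] == STATE_HP[b]) log1p(-rho_p) else log(rho_p)
      lm <- if (STATE_HM[a] == STATE_HM[b]) log1p(-rho_m) else log(rho_m)
      arr[, a, b] <- lp + lm
    }
  }
  arr
}

#' Log transition matrix between two adjacent sites
#'
#' Per-parent switch probability from the Haldane map
#' ([haldane_rho()]); the joint autosomal transition is the product over the
#' two independent parental meioses. Rows sum to 1 in probability space.
#'
#' @param delta_bp inter-site distance in bp (> 0 in normal use; 0 gives the
#'   identity in the `delta_bp -> 0` limit).
#' @param model list with `r_maternal` and `r_paternal` (cM/Mb).
#' @param chrx_male if `TRUE`, the 2-state male-fetus chrX model (maternal
#'   meiosis only).
#' @return S x S matrix of log transition probabilities (rows = from-state).
#' @export
transition_logmatrix <- function(delta_bp, model, chrx_male = FALSE) {
  stopifnot(length(delta_bp) == 1)
  arr <- trans_log_array(delta_bp, model$r_paternal, model$r_maternal, chrx_male)
  arr[1, , ]
}

# --- log-space machinery -----------------------------------------------------

lse2 <- function(x, y) {
  m <- pmax(x, y)
  out <- m + log1p(exp(-abs(x - y)))
  out[is.infinite(m)] <- m[is.infinite(m)]
  out
}

row_lse <- function(M) {
  m <- M[, 1]
  for (j in seq_len(ncol(M))[-1]) m <- pmax(m, M[, j])
  r <- m + log(rowSums(exp(M - m)))
  r[is.infinite(m)] <- m[is.infinite(m)]
  r
}

# Accept a single S x S log matrix or an (n-1) x S x S array.
trans_accessor <- function(log_transitions, n, S) {
  if (n == 1) return(NULL)
  if (is.matrix(log_transitions)) {
    stopifnot(nrow(log_transitions) == S, ncol(log_transitions) == S)
    function(i) log_transitions
  } else if (is.array(log_transitions) && length(dim(log_transitions)) == 3) {
    stopifnot(dim(log_transitions)[1] == n - 1, dim(log_transitions)[2] == S)
    function(i) log_transitions[i, , ]
  } else {
    stop("log_transitions must be an S x S matrix or an (n-1) x S x S array",
         call. = FALSE)
  }
}

#' Viterbi decoding of a transmitted-haplotype chain
#'
#' Maximum-probability state path under a uniform initial distribution.
#' Ties are broken toward no-switch (keep the previous state), then toward
#' the lowest state index, making decoding deterministic.
#'
#' @param emissions n x S matrix of per-site per-state emission
#'   log-probabilities.
#' @param log_transitions S x S log transition matrix, or an
#'   (n-1) x S x S array with one matrix per adjacent site pair.
#' @return list with `path` (integer states in 1..S) and `loglik` (the
#'   decoded path's log joint probability).
#' @export
viterbi <- function(emissions, log_transitions = NULL) {
  E <- as.matrix(emissions)
  n <- nrow(E); S <- ncol(E)
  if (n == 0) stop("empty chain", call. = FALSE)
  v <- -log(S) + E[1, ]
  if (n == 1) {
    s <- which.max(v)
    return(list(path = s, loglik = v[s]))
  }
  TR <- trans_accessor(log_transitions, n, S)
  ptr <- matrix(0L, n, S)
  sq <- seq_len(S)
  for (i in 2:n) {
    cand <- v + TR(i - 1)                       # rows: from-state, cols: to-state
    j <- max.col(t(cand), ties.method = "first")
    mx <- cand[cbind(j, sq)]
    stay <- diag(cand) >= mx                    # exact tie with no-switch wins
    j[stay] <- sq[stay]
    ptr[i, ] <- j
    v <- mx + E[i, ]
  }
  path <- integer(n)
  path[n] <- which.max(v)
  for (i in n:2) path[i - 1] <- ptr[i, path[i]]
  list(path = path, loglik = v[path[n]])
}

#' Forward-backward posteriors and transmission log-odds
#'
#' Per-site posterior state probabilities (normalized to sum 1) computed in
#' log space with log-sum-exp, plus the per-parent logarithmic odds ratio
#' between transmission of haplotype 1 and haplotype 0,
#' `L = log P(h = 1 | data) - log P(h = 0 | data)` (natural log).
#'
#' @inheritParams viterbi
#' @return list with `log_posterior` (n x S), `posterior` (n x S, rows sum
#'   to 1), `lod_paternal` and `lod_maternal` (length-n; `lod_paternal` is
#'   `NULL` for a 2-state chain), and `loglik` (the data log-likelihood).
#' @export
forward_backward <- function(emissions, log_transitions = NULL) {
  E <- as.matrix(emissions)
  n <- nrow(E); S <- ncol(E)
  if (n == 0) stop("empty chain", call. = FALSE)
  A <- matrix(0, n, S); B <- matrix(0, n, S)
  a <- -log(S) + E[1, ]
  A[1, ] <- a
  if (n > 1) {
    TR <- trans_accessor(log_transitions, n, S)
    for (i in 2:n) {
      P <- exp(TR(i - 1))
      m <- max(a)
      a <- m + log(as.vector(crossprod(P, exp(a - m)))) + E[i, ]
      A[i, ] <- a
    }
    b <- rep(0, S)
    B[n, ] <- b
    for (i in (n - 1):1) {
      P <- exp(TR(i))
      u <- b + E[i + 1, ]
      m <- max(u)
      b <- m + log(as.vector(P %*% exp(u - m)))
      B[i, ] <- b
    }
  }
  LP <- A + B
  norm <- row_lse(LP)
  LP <- LP - norm
  if (S == 4) {
    lod_pat <- lse2(LP[, 2], LP[, 4]) - lse2(LP[, 1], LP[, 3])
    lod_mat <- lse2(LP[, 3], LP[, 4]) - lse2(LP[, 1], LP[, 2])
  } else {
    lod_pat <- NULL
    lod_mat <- LP[, 2] - LP[, 1]
  }
  ll_m <- max(A[n, ])
  list(log_posterior = LP, posterior = exp(LP),
       lod_paternal = lod_pat, lod_maternal = lod_mat,
       loglik = ll_m + log(sum(exp(A[n, ] - ll_m))))
}

# breakpoint intervals from a decoded per-parent path over chain positions:
# (pos of last site before the switch, pos of first site after it]
switch_intervals <- function(pos, path) {
  sw <- which(diff(path) != 0)
  data.frame(left_pos = pos[sw], right_pos = pos[sw + 1])
}

#' Recover the fetal genome from plasma counts and phased parents
#'
#' Runs, per chromosome, the transmitted-haplotype HMM over the informative
#' sites (paternal-only, maternal-only and biparentally heterozygous;
#' maternal-heterozygous only on chrX for a male fetus): Viterbi decoding
#' for the calls, forward-backward for per-site transmission log-odds, and
#' breakpoint extraction where the decoded per-parent path switches.
#' Uninformative and discordant homozygous sites need no inference -- their
#' fetal genotype is implied by the parental genotypes.
#'
#' @param mother,father `phased_parent` objects over identical sites.
#' @param counts plasma count table aligned 1:1 with the parental sites.
#' @param f fetal fraction (from [estimate_ff()] or known truth).
#' @param eps symmetric per-read error probability.
#' @param r_maternal,r_paternal recombination rates in cM/Mb.
#' @param fetal_sex `"male"` or `"female"`.
#' @return object of class `fetal_call`: list with `sites` (per-site class,
#'   decoded transmitted-haplotype indices `hp`/`hm`, fetal alleles,
#'   genotype, per-parent log-odds, and whether the site was HMM-inferred),
#'   `breakpoints` (parent, chrom, left_pos, right_pos), `f`, `config`, and
#'   `chrom_loglik`.
#' @export
call_fetal_genome <- function(mother, father, counts, f, eps = 0.005,
                              r_maternal = 1.2, r_paternal = 1.2,
                              fetal_sex = c("male", "female")) {
  fetal_sex <- match.arg(fetal_sex)
  if (missing(f) || is.null(f) || is.na(f)) {
    stop("fetal fraction f is required (estimate it with estimate_ff())",
         call. = FALSE)
  }
  if (f <= 0 || f >= 1) stop("f must be in (0, 1)", call. = FALSE)
  stopifnot(inherits(mother, "phased_parent"), inherits(father, "phased_parent"))
  sites <- mother$sites
  check_counts_aligned(counts, sites)
  cls <- classify_sites(mother, father, fetal_sex)

  n_all <- nrow(sites)
  hp <- hm <- rep(NA_integer_, n_all)
  lod_pat <- lod_mat <- rep(NA_real_, n_all)
  pat_allele <- mat_allele <- rep(NA_character_, n_all)
  bp_rows <- list()
  ll_rows <- list()

  alt <- sites$alt
  m0_alt <- mother$hap0 == alt
  m1_alt <- mother$hap1 == alt
  f0_alt <- father$hap0 == alt
  f1_alt <- father$hap1 == alt
  depth <- counts$n_ref + counts$n_alt

  for (ch in unique(sites$chrom)) {
    in_ch <- sites$chrom == ch
    chrxm <- is_chrx(ch) && fetal_sex == "male"
    info_cls <- if (chrxm) "MATERNAL_ONLY_HET" else
      c("PATERNAL_ONLY_HET", "MATERNAL_ONLY_HET", "BIPARENTAL_HET")
    idx <- which(in_ch & cls %in% info_cls)
    if (length(idx) > 0) {
      E <- emission_matrix(counts$n_alt[idx], depth[idx], f, eps,
                           m0_alt[idx], m1_alt[idx],
                           f0_alt[idx], f1_alt[idx], chrx_male = chrxm)
      arr <- if (length(idx) > 1) {
        trans_log_array(diff(sites$pos[idx]), r_paternal, r_maternal, chrxm)
      } else NULL
      vit <- viterbi(E, arr)
      fb <- forward_backward(E, arr)
      if (chrxm) {
        hm_path <- vit$path - 1L
        hm[idx] <- hm_path
        mat_allele[idx] <- ifelse(hm_path == 0L, mother$hap0[idx], mother$hap1[idx])
        lod_mat[idx] <- fb$lod_maternal
        bim <- switch_intervals(sites$pos[idx], hm_path)
        if (nrow(bim) > 0) {
          bp_rows[[length(bp_rows) + 1]] <-
            cbind(parent = "maternal", chrom = ch, bim)
        }
      } else {
        hp_path <- STATE_HP[vit$path]
        hm_path <- STATE_HM[vit$path]
        hp[idx] <- hp_path; hm[idx] <- hm_path
        pat_allele[idx] <- ifelse(hp_path == 0L, father$hap0[idx], father$hap1[idx])
        mat_allele[idx] <- ifelse(hm_path == 0L, mother$hap0[idx], mother$hap1[idx])
        lod_pat[idx] <- fb$lod_paternal
        lod_mat[idx] <- fb$lod_maternal
        bip <- switch_intervals(sites$pos[idx], hp_path)
        bim <- switch_intervals(sites$pos[idx], hm_path)
        if (nrow(bip) > 0) bp_rows[[length(bp_rows) + 1]] <-
          cbind(parent = "paternal", chrom = ch, bip)
        if (nrow(bim) > 0) bp_rows[[length(bp_rows) + 1]] <-
          cbind(parent = "maternal", chrom = ch, bim)
      }
      ll_rows[[length(ll_rows) + 1]] <-
        data.frame(chrom = ch, n_informative = length(idx),
                   viterbi_loglik = vit$loglik, loglik = fb$loglik)
    }
    # sites needing no inference: both parents homozygous (or chrX mother-hom)
    imp <- which(in_ch & is.na(mat_allele) & !(cls %in% info_cls))
    if (length(imp) > 0) {
      mat_allele[imp] <- mother$hap0[imp]
      pat_allele[imp] <- if (chrxm) NA_character_ else father$hap0[imp]
    }
  }

  gt <- ifelse(is.na(pat_allele), mat_allele,
               paste(pmin(pat_allele, mat_allele),
                     pmax(pat_allele, mat_allele), sep = "/"))
  call_df <- data.frame(sites[c("chrom", "pos", "ref", "alt")],
                        class = cls, inferred = !is.na(hm) | !is.na(hp),
                        hp = hp, hm = hm,
                        pat_allele = pat_allele, mat_allele = mat_allele,
                        gt = gt, lod_pat = lod_pat, lod_mat = lod_mat,
                        stringsAsFactors = FALSE)
  breakpoints <- if (length(bp_rows) > 0) do.call(rbind, bp_rows) else
    data.frame(parent = character(0), chrom = character(0),
               left_pos = integer(0), right_pos = integer(0))
  rownames(breakpoints) <- NULL
  structure(list(sites = call_df, breakpoints = breakpoints, f = f,
                 config = list(eps = eps, r_maternal = r_maternal,
                               r_paternal = r_paternal, fetal_sex = fetal_sex),
                 chrom_loglik = if (length(ll_rows) > 0) do.call(rbind, ll_rows)
                                else NULL),
            class = "fetal_call")
}

#' @export
print.fetal_call <- function(x, ...) {
  cat(sprintf("<fetal_call: %d sites (%d HMM-inferred), %d breakpoints, f = %.4f>\n",
              nrow(x$sites), sum(x$sites$inferred), nrow(x$breakpoints), x$f))
  invisible(x)
}
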