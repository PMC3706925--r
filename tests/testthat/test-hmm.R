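test_that("the Haldane map evaluates correctly, with sane limits", {
  expect_equal(haldane_rho(1e6, 1.2), 0.5 * (1 - exp(-0.024)))
  expect_equal(haldane_rho(1e6, 1.2), 0.0118571, tolerance = 1e-5)
  expect_equal(haldane_rho(0, 1.2), 0)
  expect_lte(haldane_rho(1e12, 1.2), 0.5)
  expect_error(haldane_rho(-5, 1.2), "negative")
})

test_that("transition matrices are stochastic and reach their limits", {
  model <- list(r_maternal = 1.2, r_paternal = 1.2)
  M <- transition_logmatrix(1e6, model)
  expect_equal(dim(M), c(4, 4))
  expect_equal(rowSums(exp(M)), rep(1, 4))
  # delta -> 0: identity
  M0 <- transition_logmatrix(0, model)
  expect_equal(diag(exp(M0)), rep(1, 4))
  expect_true(all(exp(M0)[row(M0) != col(M0)] == 0))
  # huge distance: all states equally likely
  Minf <- transition_logmatrix(1e13, model)
  expect_equal(as.vector(exp(Minf)), rep(0.25, 16), tolerance = 1e-6)
  # male-fetus chrX: 2 states, maternal meiosis only
  X <- transition_logmatrix(1e6, model, chrx_male = TRUE)
  expect_equal(dim(X), c(2, 2))
  expect_equal(exp(X[1, 2]), haldane_rho(1e6, 1.2))
})

test_that("emission probabilities implement the mixture law per state", {
  f <- 0.0569
  model <- list(f = f, eps = 0)
  site <- list(chrom = "chr2", alt = "G", mother = c("A", "G"),
               father = c("A", "A"), n_ref = 20, n_alt = 14)
  # maternal hap1 = G transmitted: balanced mixture, theta = 0.5
  e1 <- emission_logprob(list(hp = 0, hm = 1), site, model)
  expect_equal(e1, dbinom(14, 34, 0.5, log = TRUE))
  # maternal hap0 = A transmitted: theta = 0.5 - f/2
  e0 <- emission_logprob(list(hp = 0, hm = 0), site, model)
  expect_equal(e0, dbinom(14, 34, 0.5 - f / 2, log = TRUE))
  # no reads: log-probability 0 for every state
  empty <- site; empty$n_ref <- 0; empty$n_alt <- 0
  for (hp in 0:1) for (hm in 0:1) {
    expect_equal(emission_logprob(list(hp = hp, hm = hm), empty, model), 0)
  }
  # symmetric counts k = n/2: the two maternal states differ by the
  # algebraic identity (n/2) log[ th1 (1-th1) / (th0 (1-th0)) ]
  sym <- site; sym$n_ref <- 17; sym$n_alt <- 17
  d <- emission_logprob(list(hp = 0, hm = 1), sym, model) -
       emission_logprob(list(hp = 0, hm = 0), sym, model)
  th1 <- 0.5; th0 <- 0.5 - f / 2
  expect_equal(d, 17 * log(th1 * (1 - th1) / (th0 * (1 - th0))))
  expect_error(emission_logprob(list(hp = 0, hm = 0), site, list(f = 1.2, eps = 0)),
               "f must be")
})

test_that("chrX male emissions use the hemizygous mixture", {
  f <- 0.0569
  site <- list(chrom = "chrX", alt = "G", mother = c("A", "G"),
               father = c("A"), n_ref = 15, n_alt = 18)
  e1 <- emission_logprob(list(hm = 1), site, list(f = f, eps = 0))
  theta <- ((1 - f) * 1 + f) / (2 - f)
  expect_equal(e1, dbinom(18, 33, theta, log = TRUE))
})

test_that("Viterbi and forward-backward match exhaustive enumeration", {
  set.seed(2024)
  for (rep in 1:25) {
    S <- sample(c(2, 4), 1)
    n <- sample(2:6, 1)
    inst <- random_hmm_instance(n, S)
    oracle <- enum_decode(inst$E, inst$arr)
    vit <- viterbi(inst$E, inst$arr)
    fb <- forward_backward(inst$E, inst$arr)
    expect_equal(vit$loglik, oracle$best_loglik, tolerance = 1e-9)
    expect_equal(fb$posterior, oracle$posterior, tolerance = 1e-9)
    expect_equal(fb$loglik, oracle$loglik, tolerance = 1e-9)
    expect_equal(rowSums(fb$posterior), rep(1, n), tolerance = 1e-9)
  }
})

test_that("flat emissions decode to a constant path and flat posteriors", {
  model <- list(r_maternal = 1.2, r_paternal = 1.2)
  E <- matrix(0, 5, 4)   # n = 0 everywhere
  arr <- fetalhap:::trans_log_array(rep(5e6, 4), 1.2, 1.2)
  vit <- viterbi(E, arr)
  expect_equal(vit$path, rep(vit$path[1], 5))  # no-switch tie-break
  expect_equal(vit$path[1], 1)                 # then lowest state index
  # a single constant matrix is accepted in place of the per-interval array
  M <- transition_logmatrix(5e6, model)
  vit2 <- viterbi(E, M)
  expect_equal(vit2$path, vit$path)
  expect_equal(vit2$loglik, vit$loglik)
  fb <- forward_backward(matrix(0, 1, 4))
  expect_equal(fb$posterior[1, ], rep(0.25, 4))
  expect_equal(fb$lod_maternal, 0)
  expect_equal(fb$lod_paternal, 0)
  expect_error(viterbi(matrix(0, 0, 4)), "empty")
})

test_that("decoded fetal alleles are invariant under haplotype relabeling", {
  p <- small_params(seed = 23, n_sites = 2000, n_sites_chrx = 200)
  tr <- simulate_pedigree(p)
  pc <- simulate_plasma(tr)
  call1 <- call_fetal_genome(tr$mother, tr$father, pc, f = p$f, eps = p$eps)
  mother2 <- new_phased_parent("mother", tr$mother$sites,
                               tr$mother$hap1, tr$mother$hap0)
  # father swap must keep chrX NA in hap1: swap autosome labels only
  xrow <- is.na(tr$father$hap1)
  f0 <- ifelse(xrow, tr$father$hap0, tr$father$hap1)
  f1 <- ifelse(xrow, tr$father$hap1, tr$father$hap0)
  father2 <- new_phased_parent("father", tr$father$sites, f0, f1)
  call2 <- call_fetal_genome(mother2, father2, pc, f = p$f, eps = p$eps)
  expect_identical(call1$sites$mat_allele, call2$sites$mat_allele)
  expect_identical(call1$sites$pat_allele, call2$sites$pat_allele)
  expect_identical(call1$sites$gt, call2$sites$gt)
})

test_that("high depth without recombination recovers the fetus exactly", {
  p <- small_params(seed = 29, r_maternal = 0, r_paternal = 0,
                    mean_depth = 200, fixed_depth = TRUE,
                    n_sites = 1500, n_sites_chrx = 150)
  tr <- simulate_pedigree(p)
  pc <- simulate_plasma(tr)
  call <- call_fetal_genome(tr$mother, tr$father, pc, f = p$f, eps = p$eps,
                            r_maternal = 1e-6, r_paternal = 1e-6)
  acc <- allele_accuracy(call, tr)$report
  expect_equal(acc$accuracy[acc$metric == "paternal_allele_autosome"], 1)
  expect_equal(acc$accuracy[acc$metric == "maternal_allele_autosome"], 1)
  expect_equal(acc$accuracy[acc$metric == "maternal_allele_chrX"], 1)
  expect_equal(nrow(call$breakpoints), 0)
})

test_that("recovery is robust to using the estimated fetal fraction", {
  p <- sim_params(seed = 37, chrom_lengths_mb = c(chr1 = 150), n_sites = 20000)
  tr <- simulate_pedigree(p)
  pc <- simulate_plasma(tr)
  cls <- classify_sites(tr$mother, tr$father, "male")
  f_hat <- estimate_ff(pc, cls, tr$mother, eps = p$eps)$f_hat
  expect_lt(abs(f_hat - p$f), 0.01)
  acc_true <- allele_accuracy(call_fetal_genome(tr$mother, tr$father, pc,
                                                f = p$f, eps = p$eps), tr)
  acc_est <- allele_accuracy(call_fetal_genome(tr$mother, tr$father, pc,
                                               f = f_hat, eps = p$eps), tr)
  d <- abs(acc_true$report$accuracy[2] - acc_est$report$accuracy[2])
  expect_lt(d, 0.005)
})

test_that("breakpoint intervals span the flanking informative sites", {
  pos <- c(100L, 250L, 400L)
  path <- c(0L, 1L, 1L)
  iv <- fetalhap:::switch_intervals(pos, path)
  expect_equal(iv$left_pos, 100)
  expect_equal(iv$right_pos, 250)
  expect_error(call_fetal_genome(list(), list(), NULL, f = NA), "required")
})
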