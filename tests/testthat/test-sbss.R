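# The site-by-site baseline has closed-form behavior under fixed depth:
# paternal-specific absence is a binomial zero count, opposite imbalance is
# an exact binomial tail. These oracles anchor the Monte-Carlo checks.

test_that("paternal-specific absence matches the binomial zero-count law", {
  # mother A/A, father A/G with hap0 = G transmitted: paternal-specific = G
  tr <- manual_truth(1e5, c("A", "A"), c("G", "A"), "G", "A",
                     mean_depth = 2, eps = 0, fixed_depth = TRUE, seed = 8)
  pc <- simulate_plasma(tr)
  cls <- classify_sites(tr$mother, tr$father)
  expect_true(all(cls == "PATERNAL_ONLY_HET"))
  res <- paternal_absence_rate(pc, cls, tr$mother, tr$father, truth = tr)
  p_absent <- (1 - 0.0569 / 2)^2   # no paternal read in n = 2 draws: 0.9439
  se <- sqrt(p_absent * (1 - p_absent) / 1e5)
  expect_lt(abs(res$absence_rate - p_absent), 3 * se)
  # threshold 0: every site trivially "detected"
  expect_equal(paternal_absence_rate(pc, cls, tr$mother, tr$father,
                                     threshold = 0)$absence_rate, 0)
})

test_that("every detected site drives the absence rate to zero", {
  n <- 50
  sites <- new_sites(rep("chr1", n), seq_len(n) * 10L, rep("A", n), rep("G", n))
  mother <- new_phased_parent("mother", sites, rep("A", n), rep("A", n))
  father <- new_phased_parent("father", sites, rep("A", n), rep("G", n))
  counts <- new_plasma_counts(sites, rep(30L, n), rep(2L, n))
  cls <- classify_sites(mother, father)
  expect_equal(paternal_absence_rate(counts, cls, mother, father)$absence_rate, 0)
})

test_that("imbalance calls follow the sign rule, with ties uncalled", {
  n <- 3
  sites <- new_sites(rep("chr1", n), seq_len(n) * 10L, rep("A", n), rep("G", n))
  mother <- new_phased_parent("mother", sites, rep("A", n), rep("G", n))
  father <- new_phased_parent("father", sites, rep("A", n), rep("A", n))
  counts <- new_plasma_counts(sites, c(10L, 2L, 5L), c(2L, 10L, 5L))
  cls <- classify_sites(mother, father)
  res <- maternal_imbalance_call(counts, cls, mother)
  expect_identical(res$calls$call, c("A", "G", NA))
  expect_equal(res$n_tie, 1)
})

test_that("opposite-imbalance rate matches the exact binomial tail", {
  # mother A/G, father A/A, fetus inherits maternal A: the transmitted
  # allele's expected read fraction is 0.5 + f/2, fixed depth 34
  f <- 0.0569
  tr <- manual_truth(1e5, c("A", "G"), c("A", "A"), "A", "A",
                     mean_depth = 34, eps = 0, fixed_depth = TRUE, seed = 12)
  pc <- simulate_plasma(tr)
  cls <- classify_sites(tr$mother, tr$father)
  res <- maternal_imbalance_call(pc, cls, tr$mother, truth = tr)
  theta_t <- 0.5 + f / 2              # transmitted-allele read fraction
  k <- 0:34
  pk <- dbinom(k, 34, theta_t)
  p_opp <- sum(pk[k < 17]) / (1 - pk[k == 17][1])
  se <- sqrt(p_opp * (1 - p_opp) / res$n_called)
  expect_lt(abs(res$opposite_rate - p_opp), 3 * se)
})

test_that("imbalance-call accuracy tracks the binomial oracle across depths", {
  f <- 0.0569
  for (depth in c(2, 34, 200)) {
    tr <- manual_truth(4e4, c("A", "G"), c("A", "A"), "A", "A",
                       mean_depth = depth, eps = 0, fixed_depth = TRUE,
                       seed = depth)
    pc <- simulate_plasma(tr)
    cls <- classify_sites(tr$mother, tr$father)
    res <- maternal_imbalance_call(pc, cls, tr$mother, truth = tr)
    k <- 0:depth
    pk <- dbinom(k, depth, 0.5 + f / 2)
    half <- depth / 2
    p_acc <- sum(pk[k > half]) / (1 - if (depth %% 2 == 0) pk[k == half][1] else 0)
    se <- sqrt(p_acc * (1 - p_acc) / res$n_called)
    expect_lt(abs(res$accuracy - p_acc), 3 * se)
  }
})

test_that("the naive de-novo scan has binomial detection sensitivity", {
  p <- small_params(seed = 19, eps = 0, mean_depth = 34, fixed_depth = TRUE,
                    n_sites = 8000, n_sites_chrx = 400)
  tr <- simulate_pedigree(p)
  sp <- spike_denovo(tr, 1000, seed = 7)
  pc <- simulate_plasma(sp$truth)
  cls <- classify_sites(tr$mother, tr$father, "male")
  scan <- denovo_scan(pc, cls, tr$mother, mutations = sp$mutations)
  p_det <- 1 - (1 - 0.0569 / 2)^34
  se <- sqrt(p_det * (1 - p_det) / 1000)
  expect_lt(abs(scan$sensitivity - p_det), 3 * se)
  # no non-parental reads anywhere -> empty candidate list
  quiet <- pc
  parents_ref <- tr$mother$hap0 == pc$ref
  quiet$n_alt[parents_ref] <- 0L
  quiet$n_ref[!parents_ref] <- 0L
  expect_equal(denovo_scan(quiet, cls, tr$mother)$n_candidates, 0)
})
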