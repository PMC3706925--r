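toy_sites <- function(n) new_sites(rep("chr1", n), seq_len(n) * 1000L,
                                   rep("A", n), rep("G", n))

gt_mat <- function(...) matrix(c(...), ncol = 2, byrow = TRUE)

test_that("trio phasing orients forced sites and flags the rest", {
  s <- toy_sites(3)
  out <- trio_phase(s,
                    parent_gt = gt_mat("A", "G", "A", "G", "A", "A"),
                    grandfather_gt = gt_mat("A", "A", "A", "G", "G", "G"),
                    grandmother_gt = gt_mat("G", "G", "A", "G", "G", "G"))
  # grandfather hom A, grandmother hom G -> forced (A|G)
  expect_identical(out$status[1], "PHASED")
  expect_identical(c(out$allele_gf[1], out$allele_gm[1]), c("A", "G"))
  # all three het -> ambiguous
  expect_identical(out$status[2], "AMBIGUOUS")
  # parent hom A impossible from two hom-G grandparents
  expect_identical(out$status[3], "INCONSISTENT")
})

test_that("trio phasing never contradicts the parent genotype", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 200
    s <- toy_sites(n)
    draw <- function() matrix(sample(c("A", "G"), 2 * n, TRUE), ncol = 2)
    pg <- draw()
    out <- trio_phase(s, pg, draw(), draw())
    ph <- out$status == "PHASED"
    reord <- cbind(pmin(out$allele_gf[ph], out$allele_gm[ph]),
                   pmax(out$allele_gf[ph], out$allele_gm[ph]))
    orig <- cbind(pmin(pg[ph, 1], pg[ph, 2]), pmax(pg[ph, 1], pg[ph, 2]))
    expect_identical(reord, orig)
  }
})

test_that("a unanimous panel vote orients an ambiguous site", {
  s <- toy_sites(3)
  partial <- trio_phase(s,
                        parent_gt = gt_mat("A", "G", "A", "G", "A", "G"),
                        grandfather_gt = gt_mat("A", "A", "A", "G", "A", "A"),
                        grandmother_gt = gt_mat("G", "G", "A", "G", "G", "G"))
  expect_identical(partial$status, c("PHASED", "AMBIGUOUS", "PHASED"))
  # hap0 (grandfather side) carries A at sites 1 and 3; every panel
  # haplotype pairs A-at-flanks with G at the middle site
  panel <- matrix(rep(c("A", "G", "A"), 10), nrow = 3)
  res <- panel_resolve(partial, panel, role = "mother", seed = 1)
  expect_identical(res$parent$hap0[2], "G")
  expect_identical(res$source[2], "PANEL")
  expect_equal(res$inferred_rate_after, 1.0)
})

test_that("resolution without ambiguity is the identity", {
  s <- toy_sites(2)
  partial <- trio_phase(s, gt_mat("A", "G", "A", "A"),
                        gt_mat("A", "A", "A", "A"), gt_mat("G", "G", "A", "A"))
  res <- panel_resolve(partial, NULL, role = "mother")
  expect_equal(res$inferred_rate_before, 1.0)
  expect_identical(res$parent$hap0, c("A", "A"))
  expect_identical(res$parent$hap1, c("G", "A"))
})

test_that("empty panel falls back to seeded coin flips with a warning", {
  s <- toy_sites(1)
  partial <- trio_phase(s, gt_mat("A", "G"), gt_mat("A", "G"), gt_mat("A", "G"))
  expect_warning(res <- panel_resolve(partial, NULL, seed = 4), "coin flip")
  expect_identical(res$source, "RANDOM")
})

test_that("switch-error rate counts relative-phase disagreements", {
  n <- 101
  s <- toy_sites(n)
  h0 <- rep(c("A", "G"), length.out = n)
  h1 <- ifelse(h0 == "A", "G", "A")
  truth <- new_phased_parent("mother", s, h0, h1)
  expect_equal(switch_error_rate(truth, truth)$rate, 0)
  swapped <- new_phased_parent("mother", s, h1, h0)
  expect_equal(switch_error_rate(swapped, truth)$rate, 0)
  # one isolated flipped site among 101 het sites: enters and exits
  h0b <- h0; h1b <- h1
  h0b[50] <- h1[50]; h1b[50] <- h0[50]
  one_flip <- new_phased_parent("mother", s, h0b, h1b)
  expect_equal(switch_error_rate(one_flip, truth)$rate, 2 / 100)
  # fewer than two het sites: undefined, flagged
  hom <- new_phased_parent("mother", toy_sites(2), c("A", "A"), c("A", "A"))
  expect_false(switch_error_rate(hom, hom)$defined)
})

test_that("trio + LD panel recovers simulated parental phase", {
  # without recombination the grandfather-transmitted haplotype IS hap0,
  # so trio-phased sites must match truth exactly
  p0 <- small_params(seed = 17, r_maternal = 0, r_paternal = 0,
                     chrom_lengths_mb = c(chr1 = 50), n_sites = 1500)
  tr0 <- simulate_pedigree(p0)
  gp <- tr0$grandparents$chr1
  partial <- trio_phase(tr0$sites[c("chrom", "pos", "ref", "alt")],
                        cbind(tr0$mother$hap0, tr0$mother$hap1),
                        cbind(gp$mf$hap0, gp$mf$hap1),
                        cbind(gp$mm$hap0, gp$mm$hap1))
  ph <- partial$status == "PHASED"
  expect_gt(mean(ph), 0.5)
  expect_identical(partial$allele_gf[ph], tr0$mother$hap0[ph])
  expect_identical(partial$allele_gm[ph], tr0$mother$hap1[ph])

  # with recombination and an LD panel, resolved-site error stays low
  errs <- 0L; tot <- 0L
  for (seed in 1:10) {
    p <- small_params(seed = seed, chrom_lengths_mb = c(chr1 = 50),
                      n_sites = 1200)
    tr <- simulate_pedigree(p)
    gp <- tr$grandparents$chr1
    partial <- trio_phase(tr$sites[c("chrom", "pos", "ref", "alt")],
                          cbind(tr$mother$hap0, tr$mother$hap1),
                          cbind(gp$mf$hap0, gp$mf$hap1),
                          cbind(gp$mm$hap0, gp$mm$hap1))
    panel <- simulate_panel(tr, n_haps = 30, seed = seed + 100)
    res <- panel_resolve(partial, panel, role = "mother", seed = seed)
    resolved <- which(res$source == "PANEL")
    if (length(resolved) > 0) {
      errs <- errs + sum(res$parent$hap0[resolved] != tr$mother$hap0[resolved])
      tot <- tot + length(resolved)
    }
  }
  expect_gt(tot, 50)
  expect_lt(errs / tot, 0.05)
})
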