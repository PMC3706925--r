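# Accuracy metrics against a simulated (or sequenced) fetal truth: allele
# and genotype accuracy by site class, an error taxonomy (haplotype noise /
# breakpoint-related / centromere-edge), and depth-downsampling curves.

#' Allele and genotype accuracy of a fetal call against truth
#'
#' Paternal-allele accuracy is computed over paternal-only plus biparental
#' heterozygous autosomal sites; maternal-allele accuracy over maternal-only
#' plus biparental heterozygous autosomal sites; chrX maternal-allele
#' accuracy separately. Genotype accuracy (unordered allele pair) is
#' reported per heterozygosity class.
#'
#' @param call a [call_fetal_genome()] result.
#' @param truth a `sim_truth` over the same sites.
#' @return object of class `accuracy_report`: list with `report` (metric,
#'   n_sites, n_correct, accuracy) and `errors` (per-site mismatches with
#'   the parent concerned).
#' @export
allele_accuracy <- function(call, truth) {
  stopifnot(inherits(call, "fetal_call"), inherits(truth, "sim_truth"))
  cs <- call$sites
  if (!identical(cs[c("chrom", "pos")], truth$sites[c("chrom", "pos")])) {
    stop("call and truth site lists differ", call. = FALSE)
  }
  auto <- !is_chrx(cs$chrom)
  cls <- as.character(cs$class)
  pat_ok <- cs$pat_allele == truth$fetus$pat_allele
  mat_ok <- cs$mat_allele == truth$fetus$mat_allele
  true_gt <- ifelse(is.na(truth$fetus$pat_allele), truth$fetus$mat_allele,
                    paste(pmin(truth$fetus$pat_allele, truth$fetus$mat_allele),
                          pmax(truth$fetus$pat_allele, truth$fetus$mat_allele),
                          sep = "/"))
  gt_ok <- cs$gt == true_gt

  row_of <- function(metric, sel, ok) {
    n <- sum(sel)
    nc <- sum(ok[sel], na.rm = TRUE)
    data.frame(metric = metric, n_sites = n, n_correct = nc,
               accuracy = if (n > 0) nc / n else NA_real_)
  }
  sel_pat <- auto & cls %in% c("PATERNAL_ONLY_HET", "BIPARENTAL_HET")
  sel_mat <- auto & cls %in% c("MATERNAL_ONLY_HET", "BIPARENTAL_HET")
  sel_x <- !auto & cls == "MATERNAL_ONLY_HET"
  report <- rbind(
    row_of("paternal_allele_autosome", sel_pat, pat_ok),
    row_of("maternal_allele_autosome", sel_mat, mat_ok),
    row_of("maternal_allele_chrX", sel_x, mat_ok),
    row_of("genotype_paternal_only_het", auto & cls == "PATERNAL_ONLY_HET", gt_ok),
    row_of("genotype_maternal_only_het", auto & cls == "MATERNAL_ONLY_HET", gt_ok),
    row_of("genotype_biparental_het", auto & cls == "BIPARENTAL_HET", gt_ok),
    row_of("genotype_chrX_maternal_het", sel_x, gt_ok))

  err_pat <- which(sel_pat & !pat_ok)
  err_mat <- which((sel_mat | sel_x) & !mat_ok)
  errors <- rbind(
    if (length(err_pat) > 0)
      data.frame(cs[err_pat, c("chrom", "pos")], parent = "paternal"),
    if (length(err_mat) > 0)
      data.frame(cs[err_mat, c("chrom", "pos")], parent = "maternal"))
  if (is.null(errors)) {
    errors <- data.frame(chrom = character(0), pos = integer(0),
                         parent = character(0))
  }
  rownames(errors) <- NULL
  structure(list(report = report, errors = errors), class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("Fetal recovery accuracy by site class:\n")
  r <- x$report
  for (i in seq_len(nrow(r))) {
    cat(sprintf("  %-28s %7d sites  %s\n", r$metric[i], r$n_sites[i],
                if (is.na(r$accuracy[i])) "NA" else
                  sprintf("%6.2f%%", 100 * r$accuracy[i])))
  }
  invisible(x)
}

#' Default centromere/edge annotation for simulated chromosomes
#'
#' Simulated chromosomes have no real heterochromatin, so the default
#' annotation marks the first and last `edge_mb` of each chromosome.
#'
#' @param chrom_lengths_mb named vector of chromosome lengths in Mb.
#' @param edge_mb edge width in Mb (default 1).
#' @return data frame chrom, start, end (1-based inclusive).
#' @export
default_edge_regions <- function(chrom_lengths_mb, edge_mb = 1) {
  ch <- names(chrom_lengths_mb)
  L <- chrom_lengths_mb * 1e6
  w <- edge_mb * 1e6
  rbind(data.frame(chrom = ch, start = 1, end = w),
        data.frame(chrom = ch, start = L - w + 1, end = L))
}

#' Classify recovery errors into types I/II/III
#'
#' Type III: the error site lies in an annotated centromere/edge region
#' (takes precedence). Type II: within `window_bp` of any true crossover or
#' inferred breakpoint interval. Type I: everything else (attributed to
#' haplotype-inference noise).
#'
#' @param errors data frame with chrom, pos (e.g. from [allele_accuracy()]).
#' @param true_crossovers data frame with chrom, pos (points).
#' @param inferred_breakpoints data frame with chrom, left_pos, right_pos.
#' @param regions centromere/edge annotation: data frame chrom, start, end
#'   (1-based inclusive), e.g. [default_edge_regions()].
#' @param window_bp breakpoint proximity window (default 1 Mb).
#' @return character vector of `"I"`, `"II"`, `"III"` per error row.
#' @export
classify_errors <- function(errors, true_crossovers, inferred_breakpoints,
                            regions, window_bp = 1e6) {
  n <- nrow(errors)
  if (n == 0) return(character(0))
  type <- rep("I", n)
  for (i in seq_len(n)) {
    ch <- errors$chrom[i]; p <- errors$pos[i]
    reg <- regions[regions$chrom == ch, , drop = FALSE]
    if (nrow(reg) > 0 && any(p >= reg$start & p <= reg$end)) {
      type[i] <- "III"
      next
    }
    near <- FALSE
    tc <- true_crossovers[true_crossovers$chrom == ch, , drop = FALSE]
    if (nrow(tc) > 0 && any(abs(tc$pos - p) <= window_bp)) near <- TRUE
    if (!near) {
      ib <- inferred_breakpoints[inferred_breakpoints$chrom == ch, , drop = FALSE]
      if (nrow(ib) > 0 &&
          any(p >= ib$left_pos - window_bp & p <= ib$right_pos + window_bp)) {
        near <- TRUE
      }
    }
    if (near) type[i] <- "II"
  }
  type
}

#' Accuracy-versus-depth downsampling curve
#'
#' Binomially thins each site's ref and alt counts by each retention
#' fraction, reruns the full recovery, and reports accuracy per metric per
#' retained depth, together with a Spearman monotone-trend statistic per
#' metric.
#'
#' @param counts full-depth plasma count table.
#' @param fractions retention fractions in (0, 1].
#' @param mother,father phased parents.
#' @param truth `sim_truth` for scoring.
#' @param f fetal fraction supplied to the caller.
#' @param eps,r_maternal,r_paternal,fetal_sex passed to
#'   [call_fetal_genome()].
#' @param seed integer seed for the thinning draws.
#' @return list with `curve` (fraction, mean_depth, metric, n_sites,
#'   accuracy) and `trend` (Spearman correlation of accuracy with fraction,
#'   per metric).
#' @export
downsample_curve <- function(counts, fractions, mother, father, truth, f,
                             eps = 0.005, r_maternal = 1.2, r_paternal = 1.2,
                             fetal_sex = "male", seed = 1) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  rows <- list()
  for (fr in fractions) {
    set.seed(seed + round(1e6 * fr))
    thinned <- counts
    if (fr < 1) {
      thinned$n_ref <- rbinom(nrow(counts), counts$n_ref, fr)
      thinned$n_alt <- rbinom(nrow(counts), counts$n_alt, fr)
    }
    call <- call_fetal_genome(mother, father, thinned, f, eps = eps,
                              r_maternal = r_maternal, r_paternal = r_paternal,
                              fetal_sex = fetal_sex)
    rep <- allele_accuracy(call, truth)$report
    rep$fraction <- fr
    rep$mean_depth <- mean(thinned$n_ref + thinned$n_alt)
    rows[[length(rows) + 1]] <- rep
  }
  curve <- do.call(rbind, rows)
  rownames(curve) <- NULL
  trend <- vapply(split(curve, curve$metric), function(d) {
    if (nrow(d) < 2 || all(is.na(d$accuracy))) return(NA_real_)
    suppressWarnings(cor(d$fraction, d$accuracy, method = "spearman"))
  }, numeric(1))
  list(curve = curve[c("fraction", "mean_depth", "metric", "n_sites",
                       "n_correct", "accuracy")],
       trend = trend)
}
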