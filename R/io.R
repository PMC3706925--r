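# Readers/writers for the standard interchange formats. The method consumes
# per-site allele counts; producing counts from BAM (alignment, duplicate
# marking, pileup) is upstream of this package. Coordinates are 1-based at
# every interface except BED, which follows the 0-based half-open standard.

vcf_header_lines <- function(chroms, info_lines = character(0),
                             sample_name = "SAMPLE") {
  c("##fileformat=VCFv4.2",
    paste0("##contig=<ID=", chroms, ">"),
    info_lines,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t"))
}

allele_code <- function(allele, ref) ifelse(is.na(allele), NA, ifelse(allele == ref, "0", "1"))

#' Write a phased parent to VCF
#'
#' Phased genotypes are written as `hap0|hap1`; haploid chrX father sites
#' are written as a single allele.
#'
#' @param parent a `phased_parent`.
#' @param path output path.
#' @param sample_name VCF sample column name (default the parent's role).
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(parent, path, sample_name = parent$role) {
  stopifnot(inherits(parent, "phased_parent"))
  s <- parent$sites
  c0 <- allele_code(parent$hap0, s$ref)
  c1 <- allele_code(parent$hap1, s$ref)
  gt <- ifelse(is.na(c1), c0, paste0(c0, "|", c1))
  lines <- c(vcf_header_lines(unique(s$chrom), sample_name = sample_name),
             paste(s$chrom, s$pos, ".", s$ref, s$alt, ".", "PASS", ".",
                   "GT", gt, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

# Parse one sample's worth of a VCF into sites + allele matrix. Biallelic
# SNVs only; multi-allelic / indel / missing-genotype records are dropped
# with a logged count.
read_vcf_genotypes <- function(path, sample = 1) {
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path, genome = "unknown"))
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(altl)
  gt_all <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt_all)) stop("VCF has no GT field: ", path, call. = FALSE)
  if (is.numeric(sample)) {
    if (sample > ncol(gt_all)) stop("sample index out of range in ", path, call. = FALSE)
  } else if (!sample %in% colnames(gt_all)) {
    stop("sample '", sample, "' not found in ", path, call. = FALSE)
  }
  gt <- gt_all[, sample]
  alt1 <- rep(NA_character_, length(ref))
  alt1[n_alt == 1] <- as.character(unlist(altl[n_alt == 1]))
  snv <- n_alt == 1 & nchar(ref) == 1 & !is.na(alt1) & nchar(alt1) == 1
  called <- !gt %in% c(".", "./.", ".|.")
  keep <- snv & called
  n_drop_snv <- sum(!snv)
  n_drop_gt <- sum(snv & !called)
  if (n_drop_snv > 0) message("dropped ", n_drop_snv,
                              " multi-allelic/indel record(s) from ", path)
  if (n_drop_gt > 0) message("dropped ", n_drop_gt,
                             " missing-genotype record(s) from ", path)
  chrom <- normalize_chrom(as.character(GenomicRanges::seqnames(rr)[keep]))
  sites <- data.frame(chrom = chrom,
                      pos = GenomicRanges::start(rr)[keep],
                      ref = ref[keep], alt = alt1[keep],
                      stringsAsFactors = FALSE)
  g <- gt[keep]
  phased <- grepl("\\|", g) | !grepl("/", g)
  parts <- strsplit(g, "[/|]")
  a1 <- vapply(parts, `[`, character(1), 1)
  a2 <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
               character(1))
  decode <- function(code) ifelse(is.na(code), NA_character_,
                                  ifelse(code == "0", sites$ref, sites$alt))
  list(sites = sites,
       gt = cbind(decode(a1), decode(a2)),
       phased = phased)
}

#' Read a phased parent from VCF
#'
#' All retained records must be phased (`|`-separated GT, or haploid).
#'
#' @param path VCF path.
#' @param role `"mother"` or `"father"`.
#' @param sample sample name or index (default first sample).
#' @return a `phased_parent`.
#' @export
read_phased_vcf <- function(path, role, sample = 1) {
  g <- read_vcf_genotypes(path, sample)
  if (!all(g$phased)) {
    stop(sum(!g$phased), " unphased genotype(s) in ", path,
         "; phase the input first (trio_phase + panel_resolve)", call. = FALSE)
  }
  new_phased_parent(role, g$sites, g$gt[, 1], g$gt[, 2])
}

#' Write a fetal call to VCF
#'
#' The phased GT encodes (paternal|maternal) transmitted alleles; chrX
#' sites of a male fetus are hemizygous (single maternal allele). Per-site
#' per-parent transmission log-odds and decoded transmitted-haplotype
#' indices are stored as INFO keys `LODP`, `LODM`, `HP`, `HM`.
#'
#' @param call a `fetal_call`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fetal_vcf <- function(call, path) {
  stopifnot(inherits(call, "fetal_call"))
  s <- call$sites
  cp <- allele_code(s$pat_allele, s$ref)
  cm <- allele_code(s$mat_allele, s$ref)
  gt <- ifelse(is.na(cp), cm, paste0(cp, "|", cm))
  fmt_num <- function(x) ifelse(is.na(x), NA_character_, sprintf("%.6g", x))
  info_field <- function(key, val) ifelse(is.na(val), NA_character_,
                                          paste0(key, "=", val))
  parts <- cbind(info_field("HP", s$hp), info_field("HM", s$hm),
                 info_field("LODP", fmt_num(s$lod_pat)),
                 info_field("LODM", fmt_num(s$lod_mat)))
  info <- apply(parts, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) == 0) "." else paste(r, collapse = ";")
  })
  info_lines <- c(
    "##INFO=<ID=HP,Number=1,Type=Integer,Description=\"Decoded paternal transmitted haplotype index\">",
    "##INFO=<ID=HM,Number=1,Type=Integer,Description=\"Decoded maternal transmitted haplotype index\">",
    "##INFO=<ID=LODP,Number=1,Type=Float,Description=\"Paternal transmission log-odds, natural log\">",
    "##INFO=<ID=LODM,Number=1,Type=Float,Description=\"Maternal transmission log-odds, natural log\">",
    "##fetalhapGT=paternal|maternal transmitted alleles; hemizygous chrX sites carry the maternal allele only")
  lines <- c(vcf_header_lines(unique(s$chrom), info_lines, "FETUS"),
             paste(s$chrom, s$pos, ".", s$ref, s$alt, ".", "PASS", info,
                   "GT", gt, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a fetal call VCF back into a site table
#'
#' Recovers the per-site transmitted alleles and log-odds written by
#' [write_fetal_vcf()] (as a plain data frame, not a full `fetal_call`).
#'
#' @param path VCF path.
#' @return data frame chrom, pos, ref, alt, pat_allele, mat_allele, gt,
#'   lod_pat, lod_mat.
#' @export
read_fetal_vcf <- function(path) {
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path, genome = "unknown"))
  g <- read_vcf_genotypes(path, 1)
  pat <- g$gt[, 1]
  mat <- g$gt[, 2]
  hemi <- is.na(mat)
  mat[hemi] <- pat[hemi]
  pat[hemi] <- NA_character_
  inf <- VariantAnnotation::info(vcf)
  gt <- ifelse(is.na(pat), mat, paste(pmin(pat, mat), pmax(pat, mat), sep = "/"))
  data.frame(g$sites, pat_allele = pat, mat_allele = mat, gt = gt,
             lod_pat = as.numeric(inf$LODP), lod_mat = as.numeric(inf$LODM),
             stringsAsFactors = FALSE)
}

#' Read plasma allele counts from TSV
#'
#' Expects a header `chrom, pos, ref, alt, n_ref, n_alt` with 1-based
#' positions. When a parental site table is supplied the counts are aligned
#' to it: sites missing from the TSV get zero counts (logged); a shared
#' position with mismatched ref/alt alleles is a hard error (it almost
#' always means shifted coordinates or a swapped allele convention).
#'
#' @param path TSV path.
#' @param sites optional parental site table to align against.
#' @return plasma count table.
#' @export
read_counts_tsv <- function(path, sites = NULL) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  need <- c("chrom", "pos", "ref", "alt", "n_ref", "n_alt")
  if (!all(need %in% names(df))) {
    stop("counts TSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df$chrom <- normalize_chrom(df$chrom)
  if (is.null(sites)) return(df[need])
  key_s <- paste(sites$chrom, sites$pos)
  key_c <- paste(df$chrom, df$pos)
  hit <- match(key_s, key_c)
  shared <- !is.na(hit)
  bad <- shared & (df$ref[hit] != sites$ref | df$alt[hit] != sites$alt)
  if (any(bad, na.rm = TRUE)) {
    i <- which(bad)[1]
    stop("ref/alt mismatch between counts TSV and site list at ",
         sites$chrom[i], ":", sites$pos[i],
         " (", df$ref[hit[i]], "/", df$alt[hit[i]], " vs ",
         sites$ref[i], "/", sites$alt[i], ")", call. = FALSE)
  }
  if (any(!shared)) {
    message(sum(!shared), " site(s) absent from counts TSV; assigned zero depth")
  }
  n_ref <- ifelse(shared, df$n_ref[hit], 0L)
  n_alt <- ifelse(shared, df$n_alt[hit], 0L)
  new_plasma_counts(sites[c("chrom", "pos", "ref", "alt")], n_ref, n_alt)
}

#' Write plasma allele counts to TSV
#'
#' @param counts plasma count table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(counts, path) {
  data.table::fwrite(counts[c("chrom", "pos", "ref", "alt", "n_ref", "n_alt")],
                     path, sep = "\t")
  invisible(path)
}

#' Write recombination breakpoint intervals to BED
#'
#' One 0-based half-open interval per decoded switch, spanning the two
#' flanking informative sites, with the name column `MATERNAL`/`PATERNAL`.
#'
#' @param call a `fetal_call` (or any data frame with parent, chrom,
#'   left_pos, right_pos).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_breakpoints_bed <- function(call, path) {
  bp <- if (inherits(call, "fetal_call")) call$breakpoints else call
  if (nrow(bp) == 0) {
    writeLines("# no recombination breakpoints detected", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(bp$chrom,
                               IRanges::IRanges(start = bp$left_pos,
                                                end = bp$right_pos))
  names(gr) <- toupper(bp$parent)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read breakpoint intervals from BED
#'
#' @param path BED path as written by [write_breakpoints_bed()].
#' @return data frame parent, chrom, left_pos, right_pos (1-based closed,
#'   i.e. the flanking informative site positions).
#' @export
read_breakpoints_bed <- function(path) {
  first <- readLines(path, n = 1)
  if (length(first) == 0 || grepl("^#", first)) {
    return(data.frame(parent = character(0), chrom = character(0),
                      left_pos = integer(0), right_pos = integer(0)))
  }
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(parent = tolower(gr$name),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             left_pos = GenomicRanges::start(gr),
             right_pos = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Write a JSON run manifest
#'
#' Records the run configuration (including the seed -- always) so a run
#' can be reproduced exactly.
#'
#' @param config named list of run parameters; must include `seed`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path) {
  if (is.null(config$seed)) stop("manifest config must record a seed", call. = FALSE)
  config$package_version <- as.character(utils::packageVersion("fetalhap"))
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
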