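#' Construct a genotype matrix
#'
#' Container for diploid biallelic genotypes coded as counts of the coded
#' allele (0, 1 or 2). The coded allele is the allele whose homozygote is
#' coded 2; for VCF input this is the ALT allele.
#'
#' @param calls integer matrix, individuals in rows, variants in columns,
#'   entries in \{0, 1, 2\}.
#' @param sample_ids character vector of unique individual identifiers
#'   (defaults to rownames of `calls`).
#' @param variant_ids character vector of unique variant identifiers
#'   (defaults to colnames of `calls`).
#' @param chrom,pos optional per-variant coordinates (1-based, VCF style).
#' @param variant_class optional per-variant label, `"SNP"` or `"INDEL"`.
#' @return An object of class `genotype_matrix`: the integer call matrix with
#'   a `variants` attribute (data frame of per-variant metadata).
#' @export
genotype_matrix <- function(calls, sample_ids = rownames(calls),
                            variant_ids = colnames(calls),
                            chrom = NULL, pos = NULL, variant_class = NULL) {
  calls <- as.matrix(calls)
  if (is.null(sample_ids)) sample_ids <- paste0("ind", seq_len(nrow(calls)))
  if (is.null(variant_ids)) variant_ids <- paste0("var", seq_len(ncol(calls)))
  sample_ids <- as.character(sample_ids)
  variant_ids <- as.character(variant_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (anyDuplicated(variant_ids)) stop("duplicate variant ids")
  if (length(sample_ids) != nrow(calls) || length(variant_ids) != ncol(calls))
    stop("id lengths do not match call matrix dimensions")
  if (anyNA(calls)) stop("missing calls are not allowed in a genotype_matrix")
  storage.mode(calls) <- "integer"
  bad <- which(!(calls %in% 0:2))
  if (length(bad))
    stop("calls must be 0, 1 or 2; first offending entry at position ", bad[1])
  dimnames(calls) <- list(sample_ids, variant_ids)
  variants <- data.frame(variant_id = variant_ids, stringsAsFactors = FALSE)
  if (!is.null(chrom)) variants$chrom <- as.character(chrom)
  if (!is.null(pos)) variants$pos <- as.integer(pos)
  if (!is.null(variant_class)) {
    variant_class <- as.character(variant_class)
    stopifnot(all(variant_class %in% c("SNP", "INDEL")))
    variants$class <- variant_class
  }
  structure(calls, variants = variants, class = c("genotype_matrix", "matrix", "array"))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d variants\n", nrow(x), ncol(x)))
  if (ncol(x) > 0 && nrow(x) > 0) {
    show <- unclass(x)[seq_len(min(5L, nrow(x))), seq_len(min(8L, ncol(x))), drop = FALSE]
    print(show)
    if (nrow(x) > 5L || ncol(x) > 8L) cat("...\n")
  }
  invisible(x)
}

#' @export
summary.genotype_matrix <- function(object, ...) {
  vs <- variant_stats(object)
  cat(sprintf("genotype_matrix: %d individuals x %d variants\n",
              nrow(object), ncol(object)))
  cat("MAF distribution:\n")
  print(summary(vs$maf))
  invisible(vs)
}

variant_meta <- function(g) attr(g, "variants")

# subset helper preserving metadata; j indexes variants, i individuals
subset_genotypes <- function(g, i = NULL, j = NULL) {
  v <- variant_meta(g)
  m <- unclass(g)
  if (!is.null(i)) m <- m[i, , drop = FALSE]
  if (!is.null(j)) {
    m <- m[, j, drop = FALSE]
    v <- v[j, , drop = FALSE]
  }
  structure(m, variants = v, class = c("genotype_matrix", "matrix", "array"))
}

#' Read genotypes from VCF or plain-matrix file
#'
#' VCF input uses only the GT field; multi-allelic records are skipped with a
#' warning. The plain-matrix format is a TSV with a header row naming the
#' columns: `variant_id`, optionally `chrom`, `pos`, `class`, followed by one
#' column per sample; cells hold 0/1/2 or `.` for missing.
#'
#' @param path file path (VCF may be plain or gzipped).
#' @param format `"vcf"`, `"matrix"`, or `"auto"` (by file extension).
#' @param missing_policy what to do with missing genotypes: `"fail"` (default;
#'   the expected upstream input is fully imputed), `"drop_variant"`, or
#'   `"mean_impute"` (variant mean rounded to the nearest integer call).
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "matrix"),
                           missing_policy = c("fail", "drop_variant", "mean_impute")) {
  format <- match.arg(format)
  missing_policy <- match.arg(missing_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "matrix"
  }
  if (format == "vcf") read_genotypes_vcf(path, missing_policy)
  else read_genotypes_matrix(path, missing_policy)
}

read_genotypes_vcf <- function(path, missing_policy) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"]) | is.na(fix[, "ALT"])
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix), dimnames = list(NULL, names(gt)))
  keep <- !multi
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], ":", fix[noid, "POS"])
  # count ALT alleles in GT strings like 0/1, 1|1, ./.
  alt_count <- function(s) {
    if (is.na(s) || grepl("\\.", s)) return(NA_integer_)
    sum(as.integer(strsplit(s, "[/|]")[[1]]))
  }
  calls <- apply(gt, c(1, 2), alt_count)
  vclass <- ifelse(nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L, "SNP", "INDEL")
  build_from_calls(t(calls), colnames(gt), ids, fix[, "CHROM"], as.integer(fix[, "POS"]),
                   vclass, missing_policy)
}

read_genotypes_matrix <- function(path, missing_policy) {
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                      colClasses = "character", comment.char = ""),
    error = function(e) stop("malformed matrix file ", path, ": ", conditionMessage(e)))
  if (!"variant_id" %in% names(tab))
    stop("malformed matrix file: no 'variant_id' column in header")
  meta_cols <- intersect(c("variant_id", "chrom", "pos", "class"), names(tab))
  samp_cols <- setdiff(names(tab), meta_cols)
  if (!length(samp_cols)) stop("malformed matrix file: no sample columns")
  cells <- as.matrix(tab[, samp_cols, drop = FALSE])
  cells[cells == "."] <- NA
  suppressWarnings(calls <- matrix(as.integer(cells), nrow = nrow(cells)))
  bad <- which(!is.na(cells) & is.na(calls))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(cells))
    stop("malformed matrix file: non-numeric cell at data line ", rc[1])
  }
  bad_val <- which(!is.na(calls) & !(calls %in% 0:2))
  if (length(bad_val)) {
    rc <- arrayInd(bad_val[1], dim(calls))
    stop("invalid genotype call ", calls[bad_val[1]], " at data line ", rc[1],
         " (must be 0, 1, 2 or '.')")
  }
  build_from_calls(t(calls), samp_cols, tab$variant_id,
                   if ("chrom" %in% names(tab)) tab$chrom else NULL,
                   if ("pos" %in% names(tab)) as.integer(tab$pos) else NULL,
                   if ("class" %in% names(tab)) tab$class else NULL,
                   missing_policy)
}

# calls: individuals x variants, may contain NA; applies missing policy
build_from_calls <- function(calls, sample_ids, variant_ids, chrom, pos,
                             vclass, missing_policy) {
  if (anyNA(calls)) {
    miss_var <- colSums(is.na(calls)) > 0
    if (missing_policy == "fail") {
      stop("missing genotype(s) at variant ",
           variant_ids[which(miss_var)[1]], " (missing_policy = 'fail')")
    } else if (missing_policy == "drop_variant") {
      keep <- !miss_var
      calls <- calls[, keep, drop = FALSE]
      variant_ids <- variant_ids[keep]
      chrom <- chrom[keep]; pos <- pos[keep]; vclass <- vclass[keep]
      message(sum(miss_var), " variant(s) with missing calls dropped")
    } else { # mean_impute
      for (j in which(miss_var)) {
        m <- mean(calls[, j], na.rm = TRUE)
        calls[is.na(calls[, j]), j] <- as.integer(round(m))
      }
      message(sum(miss_var), " variant(s) mean-imputed (rounded)")
    }
  }
  genotype_matrix(calls, sample_ids, variant_ids, chrom, pos, vclass)
}

#' Write a genotype matrix in the plain-matrix TSV format
#'
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  v <- variant_meta(g)
  out <- cbind(v, as.data.frame(t(unclass(g)), check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-variant allele statistics
#'
#' @param g a [genotype_matrix()].
#' @return Data frame with one row per variant: `p` (frequency of the coded
#'   allele), `maf`, `mac` (minor allele count) and `n_obs` (diploid sample
#'   size).
#' @export
variant_stats <- function(g) {
  if (nrow(g) == 0 || ncol(g) == 0) stop("empty genotype matrix")
  n <- nrow(g)
  p <- colMeans(unclass(g)) / 2
  maf <- pmin(p, 1 - p)
  mac <- as.integer(round(2 * n * maf))
  data.frame(variant_id = variant_meta(g)$variant_id, p = p, maf = maf,
             mac = mac, n_obs = n, row.names = NULL, stringsAsFactors = FALSE)
}

#' Define a MAF-restriction scenario
#'
#' The three named scenarios mirror the usual common/rare split: `"5+"` keeps
#' MAF >= 5%, `"1+"` keeps MAF >= 1%, and `"1_5"` keeps 1% <= MAF < 5%.
#' Intervals are half-open `[maf_low, maf_high)` except that the top value 0.5
#' is always kept, so `1+` is the exact disjoint union of `5+` and `1_5`.
#'
#' @param name `"5+"`, `"1+"`, `"1_5"`, or `"custom"`.
#' @param maf_low,maf_high custom bounds, required when `name = "custom"`.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name = c("5+", "1+", "1_5", "custom"),
                          maf_low = NULL, maf_high = NULL) {
  name <- match.arg(name)
  bounds <- switch(name,
    "5+" = c(0.05, 0.5),
    "1+" = c(0.01, 0.5),
    "1_5" = c(0.01, 0.05),
    custom = c(maf_low, maf_high))
  if (length(bounds) != 2 || is.null(bounds))
    stop("custom scenario requires maf_low and maf_high")
  if (!(bounds[1] >= 0 && bounds[1] < bounds[2] && bounds[2] <= 0.5))
    stop("require 0 <= maf_low < maf_high <= 0.5")
  structure(list(name = name, maf_low = bounds[1], maf_high = bounds[2]),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  top <- if (x$maf_high == 0.5) "0.5]" else paste0(x$maf_high, ")")
  cat(sprintf("scenario '%s': MAF in [%g, %s\n", x$name, x$maf_low, top))
  invisible(x)
}

#' Filter variants by a MAF scenario
#'
#' Keeps variants with `maf_low <= maf < maf_high`; MAF exactly 0.5 is kept
#' whenever `maf_high` is 0.5. Monomorphic variants (MAF 0) never pass.
#'
#' @param g a [genotype_matrix()].
#' @param spec a [scenario_spec()] (or a scenario name, coerced).
#' @return The filtered `genotype_matrix`; the numbers kept and removed are
#'   stored in its `filter_log` attribute.
#' @export
apply_maf_scenario <- function(g, spec) {
  if (is.character(spec)) spec <- scenario_spec(spec)
  stopifnot(inherits(spec, "scenario_spec"))
  maf <- variant_stats(g)$maf
  keep <- maf >= spec$maf_low & (maf < spec$maf_high |
                                   (spec$maf_high == 0.5 & maf == 0.5))
  keep <- keep & maf > 0
  if (!any(keep)) warning("no variants pass scenario '", spec$name, "'")
  out <- subset_genotypes(g, j = which(keep))
  attr(out, "filter_log") <- list(scenario = spec$name,
                                  kept = sum(keep), removed = sum(!keep))
  attr(out, "scenario") <- spec
  out
}

#' Subset a genotype matrix to a chip variant list
#'
#' The id list is treated as a set (duplicates collapsed); ids not present in
#' the matrix are reported, not an error.
#'
#' @param g a [genotype_matrix()].
#' @param variant_ids character vector of variant ids to keep.
#' @return A `genotype_matrix` with the matching variants in their original
#'   order; missing ids are stored in the `ids_not_found` attribute.
#' @export
subset_chip <- function(g, variant_ids) {
  ids <- unique(as.character(variant_ids))
  present <- variant_meta(g)$variant_id %in% ids
  missing_ids <- setdiff(ids, variant_meta(g)$variant_id)
  if (!any(present)) warning("no listed variant ids found in the matrix")
  if (length(missing_ids))
    message(length(missing_ids), " listed id(s) not present in the matrix")
  out <- subset_genotypes(g, j = which(present))
  attr(out, "ids_not_found") <- missing_ids
  out
}
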