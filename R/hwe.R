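#' Exact test for departure from Hardy-Weinberg proportions
#'
#' Conditional exact test on genotype counts: given the sample size and the
#' minor allele count, the null probability of observing `h` heterozygotes is
#' proportional to `n! / (n_aa! h! n_AA!) * 2^h`. The p-value sums the
#' probabilities of all heterozygote counts whose probability does not exceed
#' that of the observed configuration (ties included), which is the standard
#' exact construction and remains valid at low minor allele frequency where
#' the chi-square approximation breaks down.
#'
#' @param counts genotype counts: a length-3 vector or list with elements
#'   `n_hom_minor`, `n_het`, `n_hom_major` (in that order if unnamed). The
#'   minor/major labelling is rechecked internally, so orientation does not
#'   matter.
#' @param alpha significance level for the departure flag.
#' @param midp if `TRUE`, use the mid-p variant (half weight on the observed
#'   configuration). Default `FALSE`.
#' @return List of class `hwe_result`: `p_value`, `departing`, `alpha`,
#'   `n_het_observed`, `n`, `n_minor`.
#' @export
hwe_exact_pvalue <- function(counts, alpha = 0.05, midp = FALSE) {
  if (is.list(counts)) counts <- unlist(counts)
  if (!is.null(names(counts)) && all(c("n_hom_minor", "n_het", "n_hom_major") %in% names(counts)))
    counts <- counts[c("n_hom_minor", "n_het", "n_hom_major")]
  counts <- as.integer(counts)
  if (length(counts) != 3 || any(counts < 0)) stop("counts must be 3 non-negative integers")
  n <- sum(counts)
  if (n < 1) stop("empty sample")
  n_minor <- 2L * counts[1] + counts[2]
  if (n_minor > n) { # relabel so the first class is the minor homozygote
    counts <- rev(counts)
    n_minor <- 2L * counts[1] + counts[2]
  }
  if (n_minor == 0L || n_minor == 2L * n)
    stop("monomorphic variant: exact HWE test undefined")
  dist <- hwe_het_distribution(n, n_minor)
  obs <- counts[2]
  if (!obs %in% dist$het) stop("heterozygote count inconsistent with allele count parity")
  p_obs <- dist$prob[dist$het == obs]
  # tolerance guards equal-probability ties computed in floating point
  le <- dist$prob <= p_obs * (1 + 1e-10)
  p <- sum(dist$prob[le])
  if (midp) p <- p - 0.5 * p_obs
  p <- min(1, p)
  structure(list(p_value = p, departing = p <= alpha, alpha = alpha,
                 n_het_observed = obs, n = n, n_minor = n_minor),
            class = "hwe_result")
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("HWE exact test: n = %d, minor alleles = %d, het = %d\n",
              x$n, x$n_minor, x$n_het_observed))
  cat(sprintf("p-value = %.6g (%sdeparting at alpha = %g)\n",
              x$p_value, if (x$departing) "" else "not ", x$alpha))
  invisible(x)
}

# Null distribution of the heterozygote count conditional on (n, n_minor).
# Feasible counts share the parity of n_minor; weights computed in log space.
hwe_het_distribution <- function(n, n_minor) {
  het <- seq.int(n_minor %% 2L, min(n_minor, 2L * n - n_minor), by = 2L)
  hom_minor <- (n_minor - het) / 2L
  hom_major <- n - hom_minor - het
  logw <- lfactorial(n) - lfactorial(hom_minor) - lfactorial(het) -
    lfactorial(hom_major) + het * log(2)
  w <- exp(logw - max(logw))
  list(het = het, prob = w / sum(w))
}

#' Fraction of variants departing from Hardy-Weinberg proportions
#'
#' Applies the exact test to every variant and reports the departing fraction
#' at the given significance level, alongside the raw counts.
#'
#' @param g a [genotype_matrix()]; all variants must be polymorphic (run after
#'   MAF filtering).
#' @param alpha significance level (default 0.05).
#' @param midp passed to [hwe_exact_pvalue()].
#' @return List of class `hwe_summary`: `n_variants`, `n_departing`,
#'   `percent_departing`, `alpha`, and `per_variant` (data frame of p-values).
#' @export
hwe_departure_fraction <- function(g, alpha = 0.05, midp = FALSE) {
  if (nrow(g) == 0 || ncol(g) == 0) stop("empty genotype matrix")
  m <- unclass(g)
  mono <- colSums(m) %in% c(0L, 2L * nrow(m))
  if (any(mono))
    stop(sum(mono), " monomorphic variant(s) present; apply a MAF filter first")
  pvals <- vapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    hwe_exact_pvalue(c(sum(x == 2L), sum(x == 1L), sum(x == 0L)),
                     alpha = alpha, midp = midp)$p_value
  }, numeric(1))
  dep <- pvals <= alpha
  structure(list(
    n_variants = ncol(m),
    n_departing = sum(dep),
    fraction_departing = mean(dep),
    percent_departing = 100 * mean(dep),
    alpha = alpha,
    per_variant = data.frame(variant_id = variant_meta(g)$variant_id,
                             p_value = pvals, departing = dep,
                             stringsAsFactors = FALSE)),
    class = "hwe_summary")
}

#' @export
print.hwe_summary <- function(x, ...) {
  cat("Hardy-Weinberg proportions analysis\n")
  cat(sprintf("  Total variants:     %d\n", x$n_variants))
  cat(sprintf("  Departing variants: %d\n", x$n_departing))
  cat(sprintf("  %% departing:        %.3f (alpha = %g)\n",
              x$percent_departing, x$alpha))
  invisible(x)
}
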