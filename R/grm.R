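#' Relationship matrix container
#'
#' Symmetric matrix of pairwise additive-relationship estimates tagged by the
#' method that produced it and, optionally, the MAF scenario of its variants.
#'
#' @param values symmetric numeric matrix with id dimnames.
#' @param method `"A_ped"`, `"G_yang"` or `"G_sim"`.
#' @param scenario optional [scenario_spec()].
#' @param n_variants optional number of variants used.
#' @return Object of class `rel_matrix`.
#' @export
rel_matrix <- function(values, method = c("A_ped", "G_yang", "G_sim"),
                       scenario = NULL, n_variants = NULL) {
  method <- match.arg(method)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("relationship matrix must be square")
  if (max(abs(values - t(values))) > 1e-8) stop("relationship matrix not symmetric")
  values <- (values + t(values)) / 2
  if (is.null(rownames(values)))
    dimnames(values) <- list(paste0("ind", seq_len(nrow(values))),
                             paste0("ind", seq_len(nrow(values))))
  structure(values, method = method, scenario = scenario,
            n_variants = n_variants, class = c("rel_matrix", "matrix", "array"))
}

#' @export
print.rel_matrix <- function(x, ...) {
  sc <- attr(x, "scenario")
  cat(sprintf("rel_matrix (%s%s): %d individuals\n", attr(x, "method"),
              if (!is.null(sc)) paste0(", scenario ", sc$name) else "", nrow(x)))
  if (!is.null(attr(x, "n_variants")))
    cat(sprintf("  variants used: %d\n", attr(x, "n_variants")))
  k <- min(6L, nrow(x))
  print(round(unclass(x)[seq_len(k), seq_len(k), drop = FALSE], 4))
  if (nrow(x) > k) cat("...\n")
  invisible(x)
}

#' @export
summary.rel_matrix <- function(object, ...) {
  off <- unclass(object)[upper.tri(object)]
  cat(sprintf("rel_matrix (%s): %d individuals\n", attr(object, "method"), nrow(object)))
  cat("off-diagonal:\n"); print(summary(off))
  cat("diagonal:\n"); print(summary(diag(unclass(object))))
  invisible(object)
}

# variants monomorphic at the frequencies in use cannot be standardised
drop_monomorphic <- function(g, label) {
  p <- colMeans(unclass(g)) / 2
  mono <- p <= 0 | p >= 1
  if (any(mono)) {
    message(sum(mono), " monomorphic variant(s) removed before the ", label,
            " estimator")
    g <- subset_genotypes(g, j = which(!mono))
  }
  g
}

#' Allele-frequency-weighted (Yang) genomic relationship matrix
#'
#' Off-diagonal entries average, over variants, the products of centred
#' genotypes scaled by the variant's heterozygosity:
#' `G[j,k] = mean_i (x[i,j] - 2p[i]) (x[i,k] - 2p[i]) / (2 p[i] (1 - p[i]))`.
#' The diagonal uses its own formula,
#' `G[j,j] = 1 + mean_i (x^2 - (1 + 2p) x + 2 p^2) / (2 p (1 - p))`,
#' which corrects the self-estimate for the sampling of the individual's own
#' alleles. Scaling by `2p(1-p)` gives low-MAF variants relatively more
#' weight.
#'
#' @param g a [genotype_matrix()]; variants monomorphic in the frequency set
#'   used must be removed (done automatically for sample frequencies, an error
#'   for user-supplied ones).
#' @param freqs optional per-variant frequencies of the coded allele, strictly
#'   inside (0,1); defaults to the sample estimate `colMeans(g)/2`.
#' @param block_size number of variants accumulated per block; the genotype
#'   matrix is processed in variant blocks so only one block of standardised
#'   genotypes is held at a time.
#' @return A [rel_matrix()] with method `"G_yang"`.
#' @export
grm_yang <- function(g, freqs = NULL, block_size = 10000L) {
  if (is.null(freqs)) {
    g <- drop_monomorphic(g, "Yang")
    freqs <- colMeans(unclass(g)) / 2
  } else {
    if (length(freqs) != ncol(g))
      stop("freqs must have one value per variant")
    bad <- which(freqs <= 0 | freqs >= 1)
    if (length(bad))
      stop("frequency not in (0,1) for variant ",
           variant_meta(g)$variant_id[bad[1]], "; filter first")
  }
  m <- unclass(g)
  N <- ncol(m)
  if (N == 0) stop("no variants left for the Yang estimator")
  n <- nrow(m)
  S <- matrix(0, n, n)
  D <- numeric(n)
  for (start in seq(1L, N, by = block_size)) {
    j <- start:min(N, start + block_size - 1L)
    X <- m[, j, drop = FALSE]
    storage.mode(X) <- "double"
    p <- freqs[j]
    het <- 2 * p * (1 - p)
    Z <- sweep(X, 2L, 2 * p) # x - 2p
    Z <- sweep(Z, 2L, sqrt(het), "/")
    S <- S + tcrossprod(Z)
    # diagonal numerator: x^2 - (1 + 2p) x + 2 p^2, per variant
    Dnum <- X * X - sweep(X, 2L, 1 + 2 * p, "*")
    Dnum <- sweep(Dnum, 2L, 2 * p * p, "+")
    D <- D + rowSums(sweep(Dnum, 2L, het, "/"))
  }
  G <- S / N
  diag(G) <- 1 + D / N
  G <- (G + t(G)) / 2
  dimnames(G) <- list(rownames(m), rownames(m))
  rel_matrix(G, method = "G_yang", scenario = attr(g, "scenario"),
             n_variants = N)
}

#' Similarity (allele-sharing) genomic relationship matrix
#'
#' Counts shared alleles without allele-frequency weighting:
#' `G = (M - 1)(M - 1)' / (N / 2)` on 0/1/2 genotypes, equivalent to the
#' frequency-weighted estimator with all frequencies set to 0.5. Entries lie
#' in `[-2, 2]`: -2 for a pair with opposing homozygous genotypes at every
#' variant, 2 for identical homozygotes throughout; an individual's diagonal
#' equals twice its fraction of homozygous variants.
#'
#' @param g a [genotype_matrix()].
#' @param keep_monomorphic keep variants with no variation in the sample
#'   (default `FALSE`: only segregating variants enter the estimate).
#' @param block_size variants per accumulation block.
#' @return A [rel_matrix()] with method `"G_sim"`.
#' @export
grm_similarity <- function(g, keep_monomorphic = FALSE, block_size = 10000L) {
  if (!keep_monomorphic) g <- drop_monomorphic(g, "similarity")
  m <- unclass(g)
  N <- ncol(m)
  if (N == 0) stop("no variants left for the similarity estimator")
  n <- nrow(m)
  S <- matrix(0, n, n)
  for (start in seq(1L, N, by = block_size)) {
    j <- start:min(N, start + block_size - 1L)
    X <- m[, j, drop = FALSE]
    storage.mode(X) <- "double"
    S <- S + tcrossprod(X - 1)
  }
  G <- S / (N / 2)
  dimnames(G) <- list(rownames(m), rownames(m))
  rel_matrix(G, method = "G_sim", scenario = attr(g, "scenario"),
             n_variants = N)
}

#' Genomic inbreeding coefficients
#'
#' Self-relationship minus 1 for every individual. Interpretable as the
#' correlation between uniting gametes; can be negative when an individual is
#' more heterozygous than expected at the frequencies used.
#'
#' @param G a [rel_matrix()].
#' @return Data frame of class `inbreeding_table` with columns `id`, `F`.
#' @export
genomic_inbreeding <- function(G) {
  stopifnot(inherits(G, "rel_matrix"))
  structure(data.frame(id = rownames(G), F = diag(unclass(G)) - 1,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("inbreeding_table", "data.frame"))
}

#' Write a relationship matrix as TSV
#'
#' @param G a [rel_matrix()].
#' @param path output path for the square form (header row of ids).
#' @param long_path optional path for the long form (id1, id2, value; upper
#'   triangle including the diagonal).
#' @return `path`, invisibly.
#' @export
write_rel_matrix <- function(G, path, long_path = NULL) {
  m <- unclass(G)
  utils::write.table(data.frame(id = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(long_path)) {
    ut <- which(upper.tri(m, diag = TRUE), arr.ind = TRUE)
    long <- data.frame(id1 = rownames(m)[ut[, 1]], id2 = colnames(m)[ut[, 2]],
                       value = m[ut])
    utils::write.table(long, long_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
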