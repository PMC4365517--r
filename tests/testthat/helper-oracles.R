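# Independent oracles used across the suite. These deliberately use
# different algorithms from the package: plain (unmemoised) recursive
# kinship instead of the tabular method, and exhaustive allele-placement
# enumeration instead of the conditional-distribution HWE formula.

# recursion depth of each individual (founders = 0); parents always shallower
oracle_depths <- function(ped) {
  idx <- seq_len(nrow(ped)); names(idx) <- ped$id
  d <- rep(NA_integer_, nrow(ped))
  dep <- function(i) {
    if (!is.na(d[i])) return(d[i])
    s <- ped$sire[i]; dm <- ped$dam[i]
    v <- 0L
    if (!is.na(s)) v <- max(v, dep(idx[[s]]) + 1L)
    if (!is.na(dm)) v <- max(v, dep(idx[[dm]]) + 1L)
    d[i] <<- v
    v
  }
  for (i in idx) dep(i)
  d
}

# plain recursive kinship phi; A = 2 * phi
oracle_a_matrix <- function(ped) {
  idx <- seq_len(nrow(ped)); names(idx) <- ped$id
  depth <- oracle_depths(ped)
  pidx <- function(p) if (is.na(p)) 0L else idx[[p]]
  si <- vapply(ped$sire, pidx, integer(1))
  di <- vapply(ped$dam, pidx, integer(1))
  phi <- function(a, b) {
    if (a == 0L || b == 0L) return(0)
    if (a == b) return(0.5 * (1 + phi(si[a], di[a])))
    # recurse on the (weakly) deeper individual; it cannot be the other's
    # ancestor because ancestors are strictly shallower
    if (depth[a] < depth[b]) { t <- a; a <- b; b <- t }
    0.5 * (phi(si[a], b) + phi(di[a], b))
  }
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (a in seq_len(n)) for (b in a:n) A[a, b] <- A[b, a] <- 2 * phi(a, b)
  A
}

# random valid pedigree data frame (parents drawn among earlier individuals)
random_pedigree_df <- function(n, p_parent = 0.7) {
  id <- paste0("i", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i >= 3 && stats::runif(1) < p_parent) {
      pr <- sample(i - 1L, 2L)
      sire[i] <- id[pr[1]]
      dam[i] <- id[pr[2]]
    }
  }
  list(id = id, sire = sire, dam = dam)
}

# exhaustive HWE oracle: place n_minor alleles into 2n ordered slots, count
# heterozygous individuals per placement, and sum the probabilities of all
# heterozygote counts no more likely than the observed one
oracle_hwe_pvalue <- function(n_hom_minor, n_het, n_hom_major) {
  n <- n_hom_minor + n_het + n_hom_major
  n_minor <- 2L * n_hom_minor + n_het
  if (n_minor > n) { # relabel
    tmp <- n_hom_minor; n_hom_minor <- n_hom_major; n_hom_major <- tmp
    n_minor <- 2L * n_hom_minor + n_het
  }
  slots <- 2L * n
  placements <- utils::combn(slots, n_minor)
  het_of <- apply(placements, 2, function(pos) {
    carrier <- tabulate((pos + 1L) %/% 2L, nbins = n)
    sum(carrier == 1L)
  })
  tab <- table(het_of) / ncol(placements)
  p_obs <- tab[[as.character(n_het)]]
  sum(tab[tab <= p_obs * (1 + 1e-10)])
}

# small genotype matrix from a variants-in-rows literal
gm <- function(...) {
  rows <- list(...)
  genotype_matrix(t(do.call(rbind, rows)))
}
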