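# Synthetic cohorts with known ground truth: pedigree simulation, gene
# dropping with tracked founder alleles (exact IBD), allele-frequency spectra
# and the allele-frequency resampling sensitivity analysis.

# run expr with a fixed seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) stop("an explicit integer seed is required")
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Simulation configuration
#'
#' Defaults emulate the study cohort the package's analyses are designed for:
#' a dairy-cattle-like set of ~118 genotyped individuals containing
#' parent-offspring pairs, full-sib pairs and half-sib families of 2-5, with
#' partial pedigree recording so that complete-generation depth varies.
#'
#' @param n_founders number of unrelated, non-inbred founders.
#' @param n_generations number of descendant generations.
#' @param offspring_per_gen offspring counts per generation (recycled).
#' @param half_sib_range range of offspring per sire family (half-sib family
#'   sizes).
#' @param full_sib_pairs_per_gen number of matings per generation repeated to
#'   produce a full-sib pair.
#' @param p_inbred_mating probability that a dam related to the sire (sharing
#'   a parent) is chosen, producing inbred offspring.
#' @param n_genotyped number of (most recent) individuals treated as the
#'   genotyped cohort.
#' @param record_loss probability that a non-genotyped ancestor's parent
#'   records are missing in the *observed* pedigree (the true pedigree is
#'   always complete); genotyped individuals always have both parents
#'   recorded, so observed depth is at least 1 and varies above that.
#' @param n_variants number of unlinked variants to gene-drop.
#' @param spectrum founder MAF spectrum: `"l_shaped"` (density proportional to
#'   1/p, sequence-like) or `"uniform"` (chip-like).
#' @param maf_min lower truncation of the founder MAF spectrum (default 0.01).
#' @param seed integer seed; mandatory, no implicit entropy.
#' @param track_founder_alleles record founder-allele labels during gene drop
#'   and return the exact IBD relationship matrix.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_founders = 40L, n_generations = 5L,
                       offspring_per_gen = c(40L, 45L, 50L, 55L, 60L),
                       half_sib_range = c(2L, 5L),
                       full_sib_pairs_per_gen = 1L,
                       p_inbred_mating = 0.08,
                       n_genotyped = 118L,
                       record_loss = 0.15,
                       n_variants = 10000L,
                       spectrum = c("l_shaped", "uniform"),
                       maf_min = 0.01,
                       seed = NULL,
                       track_founder_alleles = FALSE) {
  spectrum <- match.arg(spectrum)
  if (maf_min <= 0) stop("maf_min must be positive")
  if (is.null(seed)) stop("seed is mandatory")
  offspring_per_gen <- rep_len(as.integer(offspring_per_gen), n_generations)
  structure(list(n_founders = as.integer(n_founders),
                 n_generations = as.integer(n_generations),
                 offspring_per_gen = offspring_per_gen,
                 half_sib_range = as.integer(half_sib_range),
                 full_sib_pairs_per_gen = as.integer(full_sib_pairs_per_gen),
                 p_inbred_mating = p_inbred_mating,
                 n_genotyped = as.integer(n_genotyped),
                 record_loss = record_loss,
                 n_variants = as.integer(n_variants),
                 spectrum = spectrum, maf_min = maf_min,
                 seed = as.integer(seed),
                 track_founder_alleles = isTRUE(track_founder_alleles)),
            class = "sim_config")
}

#' Draw a founder allele-frequency spectrum
#'
#' `"uniform"` draws MAF uniformly on `[maf_min, 0.5]` (the flat spectrum
#' typical of ascertained SNP chips); `"l_shaped"` draws from a density
#' proportional to `1/p` truncated to the same interval (the rare-allele-heavy
#' spectrum of sequence variants). The orientation of the coded allele is
#' randomised, so returned frequencies live in `[maf_min, 1 - maf_min]`.
#'
#' @param n_variants number of variants.
#' @param spectrum `"l_shaped"` or `"uniform"`.
#' @param maf_min lower truncation (> 0).
#' @param seed integer seed.
#' @return Numeric vector of coded-allele frequencies.
#' @export
draw_frequency_spectrum <- function(n_variants, spectrum = c("l_shaped", "uniform"),
                                    maf_min = 0.01, seed) {
  spectrum <- match.arg(spectrum)
  stopifnot(maf_min > 0, maf_min < 0.5)
  if (n_variants == 0) return(numeric(0))
  with_seed(seed, {
    u <- stats::runif(n_variants)
    maf <- switch(spectrum,
      uniform = maf_min + u * (0.5 - maf_min),
      # inverse CDF of density 1/p on [maf_min, 0.5]
      l_shaped = maf_min * (0.5 / maf_min)^u)
    flip <- stats::runif(n_variants) < 0.5
    ifelse(flip, 1 - maf, maf)
  })
}

#' Simulate a pedigree with half-sib, full-sib and inbred matings
#'
#' Generates founders and the requested descendant generations. Each sire in
#' a generation founds a half-sib family of `half_sib_range` offspring with
#' (mostly) distinct dams; a configurable number of matings per generation is
#' repeated to yield full-sib pairs; with probability `p_inbred_mating` a dam
#' sharing a parent with the sire is chosen, producing inbred offspring.
#' Deterministic per seed.
#'
#' @param config a [sim_config()].
#' @return A [pedigree()] (the complete, true pedigree) with attributes:
#'   `sex`, `generation` (named vectors), `genotyped` (the `n_genotyped` most
#'   recent ids), and `observed` (a [pedigree()] with ancestor parent records
#'   masked at rate `record_loss`).
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    nf <- config$n_founders
    if (nf < 2) stop("infeasible design: need at least 2 founders")
    id <- paste0("F", seq_len(nf))
    sire <- rep(NA_character_, nf)
    dam <- rep(NA_character_, nf)
    sex <- rep(c("M", "F"), length.out = nf)
    gen <- rep(0L, nf)
    counter <- 0L
    for (g in seq_len(config$n_generations)) {
      males <- id[sex == "M" & gen == g - 1L]
      females <- id[sex == "F" & gen == g - 1L]
      if (!length(males) || !length(females))
        stop("infeasible design: no available ",
             if (!length(males)) "sires" else "dams", " for generation ", g)
      n_off <- config$offspring_per_gen[g]
      fs_left <- config$full_sib_pairs_per_gen
      made <- 0L
      while (made < n_off) {
        s <- sample(males, 1L)
        fam <- min(n_off - made,
                   sample(seq(config$half_sib_range[1], config$half_sib_range[2]), 1L))
        # dams for this sire family: distinct where the pool allows
        dams_used <- character(0)
        for (k in seq_len(fam)) {
          rel_f <- related_females(id, sire, dam, sex, gen, s, g - 1L)
          d <- if (length(rel_f) && stats::runif(1) < config$p_inbred_mating) {
            sample(rel_f, 1L)
          } else {
            pool <- setdiff(females, dams_used)
            if (!length(pool)) pool <- females
            sample(pool, 1L)
          }
          if (fs_left > 0L && k == 2L) { # repeat the first mating -> full sibs
            d <- dams_used[1]
            fs_left <- fs_left - 1L
          }
          dams_used <- c(dams_used, d)
          counter <- counter + 1L
          id <- c(id, paste0("G", g, "_", counter))
          sire <- c(sire, s)
          dam <- c(dam, d)
          sex <- c(sex, sample(c("M", "F"), 1L))
          gen <- c(gen, g)
          made <- made + 1L
        }
      }
    }
    ped <- pedigree(id, sire, dam)
    names(sex) <- id; names(gen) <- id
    # genotyped cohort: non-founders sampled with recency weighting, so it
    # spans several generations and many of its members' parents fall
    # outside the cohort (as in real sequenced-sire panels)
    cand <- id[gen >= 1L]
    if (!length(cand)) cand <- id
    ng <- min(config$n_genotyped, length(cand))
    genotyped <- if (ng == length(cand)) cand else
      sample(cand, ng, prob = 2^gen[cand])
    genotyped <- genotyped[order(match(genotyped, id))]
    # observed pedigree: mask ancestor records to create depth variation
    osire <- sire; odam <- dam
    maskable <- which(gen >= 1L & !(id %in% genotyped))
    if (length(maskable) && config$record_loss > 0) {
      mask <- maskable[stats::runif(length(maskable)) < config$record_loss]
      osire[mask] <- NA; odam[mask] <- NA
    }
    observed <- pedigree(id, osire, odam)
    attr(ped, "sex") <- sex
    attr(ped, "generation") <- gen
    attr(ped, "genotyped") <- genotyped
    attr(ped, "observed") <- observed
    ped
  })
}

# females of generation g sharing a recorded parent with sire s
related_females <- function(id, sire, dam, sex, gen, s, g) {
  i <- match(s, id)
  ps <- c(sire[i], dam[i])
  ps <- ps[!is.na(ps)]
  if (!length(ps)) return(character(0))
  sel <- sex == "F" & gen == g & (sire %in% ps | dam %in% ps)
  id[sel]
}

#' Gene-drop genotypes through a pedigree
#'
#' Founder alleles are drawn independently per variant from the founder
#' frequency of the coded allele; every non-founder inherits one uniformly
#' chosen allele from each parent per variant (unlinked loci). With
#' `track_founder_alleles = TRUE`, each founder allele carries a unique label
#' and the exact identity-by-descent relationship matrix is returned on the
#' additive-relationship scale: for a pair, the average over variants of half
#' the number of label matches among the four allele comparisons; for an
#' individual with itself, `1 +` the fraction of variants where its two
#' labels coincide. The expectation of this matrix over replicate drops is
#' the pedigree additive relationship matrix.
#'
#' @param ped a [pedigree()].
#' @param freqs per-variant founder frequencies of the coded allele, strictly
#'   in (0,1).
#' @param seed integer seed.
#' @param track_founder_alleles return ground truth (default `FALSE`).
#' @return A [genotype_matrix()] over all pedigree members; when tracking, a
#'   list with elements `genotypes`, `ibd` (matrix), `founder_frequencies`
#'   and `pedigree`.
#' @export
gene_drop <- function(ped, freqs, seed, track_founder_alleles = FALSE) {
  stopifnot(all(freqs > 0), all(freqs < 1))
  nv <- length(freqs)
  ord <- topological_order(ped)
  n <- length(ord)
  pos <- seq_len(n); names(pos) <- ord
  si <- di <- rep(0L, n)
  si[pos[ped$id]] <- ifelse(is.na(ped$sire), 0L, pos[ped$sire])
  di[pos[ped$id]] <- ifelse(is.na(ped$dam), 0L, pos[ped$dam])
  founders <- which(si == 0L & di == 0L)
  if (any(xor(si == 0L, di == 0L)))
    stop("gene_drop requires both parents known or both unknown (true pedigree)")
  fidx <- integer(n); fidx[founders] <- seq_along(founders)
  with_seed(seed, {
    # founder allele states: one Bernoulli(p) draw per variant per founder allele
    nlab <- 2L * length(founders)
    S <- matrix(stats::rbinom(nv * nlab, 1L, rep(freqs, nlab)), nrow = nv)
    L1 <- matrix(0L, nv, n)
    L2 <- matrix(0L, nv, n)
    for (x in seq_len(n)) {
      if (si[x] == 0L) {
        L1[, x] <- 2L * fidx[x] - 1L
        L2[, x] <- 2L * fidx[x]
      } else {
        pick <- stats::runif(nv) < 0.5
        L1[, x] <- ifelse(pick, L1[, si[x]], L2[, si[x]])
        pick <- stats::runif(nv) < 0.5
        L2[, x] <- ifelse(pick, L1[, di[x]], L2[, di[x]])
      }
    }
    rows <- seq_len(nv)
    calls <- matrix(0L, n, nv, dimnames = list(ord, paste0("v", rows)))
    for (x in seq_len(n))
      calls[x, ] <- S[cbind(rows, L1[, x])] + S[cbind(rows, L2[, x])]
    g <- genotype_matrix(calls[ped$id, , drop = FALSE])
    if (!track_founder_alleles) return(g)
    ibd <- matrix(0, n, n, dimnames = list(ord, ord))
    for (j in seq_len(n)) {
      for (k in j:n) {
        if (j == k) {
          ibd[j, j] <- 1 + mean(L1[, j] == L2[, j])
        } else {
          sh <- (L1[, j] == L1[, k]) + (L1[, j] == L2[, k]) +
                (L2[, j] == L1[, k]) + (L2[, j] == L2[, k])
          ibd[j, k] <- ibd[k, j] <- mean(sh) / 2
        }
      }
    }
    list(genotypes = g, ibd = ibd[ped$id, ped$id, drop = FALSE],
         founder_frequencies = freqs, pedigree = ped)
  })
}

#' Resample allele frequencies with binomial sampling error
#'
#' Emulates the estimation error of allele frequencies computed from a finite
#' diploid sample: each variant's frequency is redrawn from a normal with
#' mean `p` and standard deviation `sqrt(p (1 - p) / (2 n))`, truncated
#' (clamped) to `[1/(2n), 1 - 1/(2n)]`.
#'
#' @param freqs per-variant frequencies in (0,1).
#' @param n_diploid diploid sample size whose sampling error is emulated.
#' @param n_replicates number of replicate frequency sets.
#' @param seed integer seed.
#' @return Matrix, variants x replicates.
#' @export
resample_frequencies <- function(freqs, n_diploid, n_replicates, seed) {
  stopifnot(all(freqs > 0), all(freqs < 1), n_diploid >= 1)
  nv <- length(freqs)
  sd <- sqrt(freqs * (1 - freqs) / (2 * n_diploid))
  lo <- 1 / (2 * n_diploid)
  with_seed(seed, {
    draws <- matrix(stats::rnorm(nv * n_replicates, mean = freqs, sd = sd),
                    nrow = nv)
    pmin(pmax(draws, lo), 1 - lo)
  })
}

#' Sensitivity of the Yang estimator to allele-frequency estimation error
#'
#' Computes the Yang relationship matrix with sample-estimated frequencies,
#' then recomputes it with each of `n_replicates` resampled frequency sets
#' (see [resample_frequencies()]) and reports the Pearson correlation between
#' each replicate's entries (diagonal plus upper triangle) and the baseline.
#'
#' @param g a [genotype_matrix()], polymorphic throughout.
#' @param n_replicates number of resampling replicates (default 20).
#' @param seed integer seed.
#' @param n_diploid diploid sample size for the sampling error (default
#'   `nrow(g)`).
#' @return List: `correlations` (per replicate), `min`, `mean`.
#' @export
frequency_sensitivity <- function(g, n_replicates = 20L, seed,
                                  n_diploid = nrow(g)) {
  g <- drop_monomorphic(g, "Yang")
  p_hat <- colMeans(unclass(g)) / 2
  base <- unclass(grm_yang(g, freqs = p_hat))
  ut <- upper.tri(base, diag = TRUE)
  base_v <- base[ut]
  reps <- resample_frequencies(p_hat, n_diploid, n_replicates, seed)
  cors <- vapply(seq_len(n_replicates), function(r) {
    Gr <- unclass(grm_yang(g, freqs = reps[, r]))
    stats::cor(base_v, Gr[ut])
  }, numeric(1))
  list(correlations = cors, min = min(cors), mean = mean(cors))
}
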