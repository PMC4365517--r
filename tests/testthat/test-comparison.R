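test_that("degree groups follow the pedigree cut-offs and partition pairs", {
  m <- matrix(0.01, 4, 4)
  m[1, 2] <- m[2, 1] <- 0.503
  m[1, 3] <- m[3, 1] <- 0.30
  m[3, 4] <- m[4, 3] <- 0.25 # inclusive lower bound of second degree
  diag(m) <- 1
  dimnames(m) <- list(letters[1:4], letters[1:4])
  gr <- group_pairs(rel_matrix(m, "A_ped"))
  val <- function(g) gr$pairs$a_value[gr$pairs$group == g]
  expect_setequal(val("first"), 0.503)
  expect_setequal(val("second"), c(0.30, 0.25))
  expect_identical(nrow(gr$pairs), 6L) # 4 choose 2
  expect_identical(nrow(gr$self), 4L)
})

test_that("a single parent-offspring pair yields 1 first and 5 less pairs", {
  # C has one recorded parent only, so exactly one parent-offspring pair
  p <- pedigree(c("A", "B", "C", "D"), c(NA, NA, "A", NA), c(NA, NA, NA, NA))
  gr <- group_pairs(a_matrix(p))
  expect_identical(unname(table(gr$pairs$group)["first"]), 1L)
  expect_identical(unname(table(gr$pairs$group)["second"]), 0L)
  expect_identical(unname(table(gr$pairs$group)["less"]), 5L)
})

test_that("off-diagonal values at or above 1 are binned with a warning", {
  m <- matrix(c(1, 1.01, 1.01, 1.2), 2, 2)
  expect_warning(gr <- group_pairs(rel_matrix(m, "A_ped")), ">= 1")
  expect_identical(as.character(gr$pairs$group), "first")
})

test_that("descriptive statistics use the n-1 variance", {
  expect_equal(describe_estimates(c(0.5, 0.5)),
               c(min = 0.5, mean = 0.5, max = 0.5, var = 0, n = 2))
  expect_equal(describe_estimates(c(0, 1))[["var"]], 0.5)
  expect_error(describe_estimates(0.3), "single value")
})

test_that("pearson_test matches brute-force covariance arithmetic", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    x <- stats::rnorm(n); y <- stats::rnorm(n) + 0.5 * x
    res <- pearson_test(x, y)
    r_brute <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(res$r, r_brute, tolerance = 1e-12)
    t_brute <- r_brute * sqrt((n - 2) / (1 - r_brute^2))
    expect_equal(res$p_vs_zero, 2 * stats::pt(-abs(t_brute), n - 2),
                 tolerance = 1e-10)
  }
})

test_that("difference-from-one flag spares near-perfect correlations", {
  x <- seq_len(20)
  res <- pearson_test(x, x + 1) # r exactly 1
  expect_equal(res$r, 1)
  expect_false(res$different_from_one)
  # r ~ 0.999 at thousands of pairs: overwhelmingly different from 0
  set.seed(8)
  n <- 4000
  xx <- stats::rnorm(n)
  yy <- xx + stats::rnorm(n, sd = sqrt(1 / 0.999^2 - 1))
  res2 <- pearson_test(xx, yy)
  expect_gt(res2$r, 0.995)
  expect_true(res2$different_from_zero)
  expect_lt(res2$p_vs_zero, 1e-100)
  # at modest n the same r is statistically indistinguishable from 1
  res2b <- pearson_test(xx[1:30], yy[1:30])
  expect_false(res2b$different_from_one)
  # a clearly imperfect correlation is flagged different from 1
  res3 <- pearson_test(xx, xx + stats::rnorm(n))
  expect_true(res3$different_from_one)
  # orthogonal contrast: r = 0, not different from 0
  x0 <- rep(c(-1, 1), 5)
  y0 <- unname(stats::residuals(stats::lm(stats::rnorm(10) ~ x0)))
  res4 <- pearson_test(x0, y0)
  expect_lt(abs(res4$r), 1e-10)
  expect_false(res4$different_from_zero)
  expect_error(pearson_test(rep(1, 5), 1:5), "zero variance")
})

test_that("wilcoxon exact p matches full sign enumeration", {
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3), c(2, 3, 4))$p_value, 0.25)
  # brute force over all sign assignments, n <= 12, with ties
  set.seed(41)
  for (i in 1:8) {
    n <- sample(4:12, 1)
    d <- sample(c(-3:-1, 1:3), n, replace = TRUE)
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Wall <- signs %*% r
    pW <- table(Wall) / length(Wall)
    p_le <- sum(pW[as.numeric(names(pW)) <= W + 1e-9])
    p_ge <- sum(pW[as.numeric(names(pW)) >= W - 1e-9])
    want <- min(1, 2 * min(p_le, p_ge))
    got <- wilcoxon_signed_rank(d, rep(0, n))$p_value
    expect_equal(got, want, tolerance = 1e-12, label = paste("case", i))
  }
})

test_that("wilcoxon agrees with stats::wilcox.test in the tie-free exact case", {
  set.seed(43)
  x <- stats::rnorm(15); y <- stats::rnorm(15)
  got <- wilcoxon_signed_rank(x, y)
  want <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
  expect_equal(got$p_value, want$p.value, tolerance = 1e-12)
})

test_that("wilcoxon handles degenerate and large-sample inputs", {
  expect_warning(res <- wilcoxon_signed_rank(1:5, 1:5), "zero")
  expect_equal(res$p_value, 1)
  set.seed(47)
  x <- stats::rnorm(500)
  y <- x - 1 # shift of one sd
  res2 <- wilcoxon_signed_rank(x, y)
  expect_lt(res2$p_value, 1e-6)
  expect_match(res2$method, "normal approximation")
})

test_that("comparing correlations uses the Fisher-z closed form", {
  expect_equal(compare_correlations(0.5, 50, 0.5, 80)$p_value, 1)
  res <- compare_correlations(0.395, 118, 0.721, 44)
  expect_gt(res$p_value, 0.001)
  expect_lt(res$p_value, 0.05)
  z_brute <- (atanh(0.9) - atanh(0.1)) / sqrt(1 / 997 + 1 / 997)
  res2 <- compare_correlations(0.9, 1000, 0.1, 1000)
  expect_equal(res2$z, z_brute, tolerance = 1e-12)
  expect_lt(res2$p_value, 1e-10)
  expect_error(compare_correlations(1, 10, 0.5, 10), "degenerate")
})

test_that("depth-stratified inbreeding correlations behave at the extremes", {
  Fp <- data.frame(id = letters[1:10], F = seq(0, 0.45, by = 0.05))
  groups <- list(depth1 = letters[1:10], depth2 = letters[1:6],
                 depth4 = letters[1:2])
  expect_warning(tab <- depth_correlation_table(Fp, Fp, groups), "fewer than 3")
  expect_identical(tab$group, c("depth1", "depth2"))
  expect_equal(tab$r, c(1, 1))
  set.seed(53)
  Fg <- Fp; Fg$F <- sample(Fg$F)
  tab2 <- suppressWarnings(depth_correlation_table(Fp, Fg, groups))
  expect_lt(abs(tab2$r[tab2$group == "depth1"]), 0.6)
})

test_that("scenario_report assembles consistent, deterministic tables", {
  set.seed(59)
  ped <- simulate_pedigree(sim_config(n_founders = 10, n_generations = 2,
                                      offspring_per_gen = c(12, 14),
                                      n_genotyped = 20, seed = 4))
  ids <- attr(ped, "genotyped")
  freqs <- draw_frequency_spectrum(400, "uniform", seed = 5)
  g_all <- gene_drop(ped, freqs, seed = 6)
  g <- genotype_matrix(unclass(g_all)[match(ids, rownames(g_all)), , drop = FALSE])
  A <- a_matrix(ped, ids = ids)
  G1 <- grm_yang(g)
  G2 <- grm_similarity(g)
  rep1 <- scenario_report(A, list(yang = G1, sim = G2), ped = ped)
  expect_s3_class(rep1, "comparison_report")
  # off-diagonal pairs partition into the three degree groups
  expect_identical(sum(table(rep1$groups$pairs$group)),
                   as.integer(length(ids) * (length(ids) - 1L) / 2))
  expect_identical(nrow(rep1$scenario_table), 3L)
  expect_true(all(c("A_ped", "yang", "sim") %in% rep1$descriptive$matrix))
  rep2 <- scenario_report(A, list(yang = G1, sim = G2), ped = ped)
  expect_identical(rep1$correlations, rep2$correlations)
  expect_identical(rep1$wilcoxon, rep2$wilcoxon)
  # id mismatch errors
  bad <- rel_matrix(unclass(G1)[1:10, 1:10], "G_yang")
  expect_error(scenario_report(A, list(bad = bad)), "id mismatch")
})
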