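# Grouping, descriptive statistics and the statistical comparisons between
# pedigree-based and genomic relationship/inbreeding estimates.

#' Group pairs by pedigree relationship degree
#'
#' Off-diagonal pairs are partitioned by the pedigree additive relationship:
#' first degree (`[0.5, 1)`, e.g. parent-offspring, full sibs), second degree
#' (`[0.25, 0.5)`, e.g. half sibs, grandparent-offspring), and less related
#' (`[0, 0.25)`). Self-relationships (the diagonal) are routed to the
#' inbreeding analysis, not to a degree group. Values at or above 1
#' off-diagonal are assigned to first degree with a warning.
#'
#' @param A the pedigree [rel_matrix()] over the genotyped individuals.
#' @return List of class `degree_groups`: `pairs` (data frame id1, id2,
#'   a_value, group), `self` (data frame id, a_value), and `levels`.
#' @export
group_pairs <- function(A) {
  stopifnot(inherits(A, "rel_matrix"))
  m <- unclass(A)
  ut <- which(upper.tri(m), arr.ind = TRUE)
  val <- m[ut]
  grp <- ifelse(val >= 0.5, "first", ifelse(val >= 0.25, "second", "less"))
  if (any(val >= 1)) warning(sum(val >= 1),
    " off-diagonal value(s) >= 1 assigned to the first-degree group")
  pairs <- data.frame(id1 = rownames(m)[ut[, 1]], id2 = colnames(m)[ut[, 2]],
                      a_value = val,
                      group = factor(grp, levels = c("first", "second", "less")),
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs,
                 self = data.frame(id = rownames(m), a_value = diag(m),
                                   stringsAsFactors = FALSE),
                 levels = c("first", "second", "less")),
            class = "degree_groups")
}

#' @export
print.degree_groups <- function(x, ...) {
  cat("degree_groups:\n")
  print(table(x$pairs$group))
  invisible(x)
}

#' Descriptive statistics of a set of estimates
#'
#' @param values numeric vector (at least 2 values, so the variance is
#'   defined).
#' @return Named vector: `min`, `mean`, `max`, `var` (n-1 denominator), `n`.
#' @export
describe_estimates <- function(values) {
  values <- as.numeric(values)
  if (!length(values)) stop("no values to describe")
  if (length(values) == 1) stop("variance undefined for a single value")
  c(min = min(values), mean = mean(values), max = max(values),
    var = stats::var(values), n = length(values))
}

#' Pearson correlation with tests against 0 and against 1
#'
#' The coefficient and the two-sided t-test against zero come from
#' [stats::cor.test()]. Because a Fisher-z test against exactly 1 is
#' degenerate, "significantly different from 1" is declared when the upper
#' bound of the Fisher-z confidence interval falls below `1 - epsilon_one`;
#' the method is recorded in the result.
#'
#' @param x,y paired numeric vectors, length >= 3.
#' @param conf_level confidence level for the Fisher-z interval.
#' @param epsilon_one near-unity boundary (default 5e-4, so r = 0.999 at
#'   large pair counts is not flagged as different from 1).
#' @return List of class `correlation_result`: `r`, `n`, `p_vs_zero`,
#'   `different_from_zero`, `different_from_one`, `ci`, `method_note`.
#' @export
pearson_test <- function(x, y, conf_level = 0.95, epsilon_one = 5e-4) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance in input")
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  if (abs(r) < 1) {
    z <- atanh(r)
    se <- 1 / sqrt(n - 3)
    q <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci <- tanh(c(z - q * se, z + q * se))
  } else {
    ci <- c(r, r)
  }
  structure(list(r = r, n = n, p_vs_zero = ct$p.value,
                 different_from_zero = ct$p.value <= 0.05,
                 different_from_one = ci[2] < 1 - epsilon_one,
                 ci = ci, conf_level = conf_level,
                 method_note = sprintf(
                   "t-test vs 0; 'different from 1' = Fisher-z %g%% CI upper bound < 1 - %g",
                   100 * conf_level, epsilon_one)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.4f (n = %d), p vs 0 = %.3g%s%s\n", x$r, x$n, x$p_vs_zero,
              if (x$different_from_zero) ", different from 0" else "",
              if (x$different_from_one) ", different from 1" else ""))
  invisible(x)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test on paired differences. Zero differences are dropped. For 25
#' or fewer non-zero differences the exact null distribution of the positive
#' rank sum is computed by dynamic programming over the (midrank-resolved)
#' ranks, which stays exact in the presence of ties; above that a normal
#' approximation with continuity and tie correction is used.
#'
#' @param x,y paired numeric vectors.
#' @param exact_limit maximum n for the exact distribution (default 25).
#' @return List of class `wilcoxon_result`: `statistic` (positive rank sum
#'   W+), `n` (non-zero differences), `p_value`, `method`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_limit = 25L) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; test degenerate")
    return(structure(list(statistic = 0, n = 0L, p_value = 1,
                          method = "degenerate"), class = "wilcoxon_result"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_limit) {
    # exact distribution of 2*W+ by generating-function DP; doubling the
    # midranks makes every rank an integer even under ties
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    f <- numeric(total + 1L) # f[w+1] = #assignments with doubled rank sum w
    f[1] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), f[seq_len(total + 1L - ri)])
      f <- f + shifted
    }
    probs <- f / sum(f)
    w2 <- as.integer(round(2 * W))
    p_le <- sum(probs[seq_len(w2 + 1L)])
    p_ge <- sum(probs[(w2 + 1L):(total + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact (DP over signed midranks)"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation with continuity correction"
  }
  structure(list(statistic = W, n = n, p_value = p, method = method),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: W+ = %g, n = %d, p = %.4g (%s)\n",
              x$statistic, x$n, x$p_value, x$method))
  invisible(x)
}

#' Compare two correlation coefficients (independent samples)
#'
#' Two-sided z-test on Fisher-transformed correlations. The independence
#' assumption is noted in the result: nested groups (as with pedigree-depth
#' subsets) violate it, making the p-value approximate.
#'
#' @param r1,n1,r2,n2 the two coefficients and their sample sizes.
#' @return List: `z`, `p_value`, `note`.
#' @export
compare_correlations <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("degenerate correlation (|r| >= 1)")
  if (n1 < 4 || n2 < 4) stop("need n >= 4 in each sample")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)),
       note = "independence assumed between the two samples")
}

#' Depth-stratified inbreeding correlations
#'
#' Correlates pedigree and genomic inbreeding coefficients within each
#' pedigree-depth group.
#'
#' @param F_ped,F_gen inbreeding tables (data frames with columns `id`, `F`).
#' @param groups named list of id vectors, as from [depth_groups()].
#' @param ... passed to [pearson_test()].
#' @return Data frame: group, n, r, p_vs_zero, different_from_one. Groups
#'   with fewer than 3 usable ids are skipped with a warning.
#' @export
depth_correlation_table <- function(F_ped, F_gen, groups, ...) {
  rows <- lapply(names(groups), function(gname) {
    ids <- intersect(intersect(groups[[gname]], F_ped$id), F_gen$id)
    if (length(ids) < 3) {
      warning("group ", gname, " has fewer than 3 individuals; skipped")
      return(NULL)
    }
    xp <- F_ped$F[match(ids, F_ped$id)]
    xg <- F_gen$F[match(ids, F_gen$id)]
    res <- tryCatch(pearson_test(xp, xg, ...), error = function(e) NULL)
    if (is.null(res)) {
      warning("correlation undefined in group ", gname, "; skipped")
      return(NULL)
    }
    data.frame(group = gname, n = res$n, r = res$r, p_vs_zero = res$p_vs_zero,
               different_from_one = res$different_from_one,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full comparison report across scenarios and estimators
#'
#' Assembles the whole comparison analysis for a set of relationship
#' matrices sharing an id set: scenario variant counts, descriptive
#' statistics per matrix and degree group (plus inbreeding coefficients),
#' pairwise correlations (overall and within groups) with significance
#' against 0 and 1, paired Wilcoxon tests between matrices on the pooled
#' off-diagonal estimates, and depth-stratified pedigree-vs-genomic
#' inbreeding correlations.
#'
#' @param A pedigree [rel_matrix()] over the genotyped individuals.
#' @param G_list named list of genomic [rel_matrix()] objects with identical
#'   ids (in any order; they are aligned to `A`).
#' @param ped optional [pedigree()] for depth groups (defaults to skipping
#'   the depth analysis).
#' @param depth_thresholds integer thresholds for [depth_groups()].
#' @param epsilon_one passed to [pearson_test()].
#' @return Object of class `comparison_report` with elements
#'   `scenario_table`, `descriptive`, `correlations`, `wilcoxon`,
#'   `inbreeding_depth`, `groups`.
#' @export
scenario_report <- function(A, G_list, ped = NULL,
                            depth_thresholds = c(1L, 2L, 4L),
                            epsilon_one = 5e-4) {
  stopifnot(inherits(A, "rel_matrix"), length(G_list) >= 1)
  if (is.null(names(G_list)) || any(names(G_list) == ""))
    stop("G_list must be a fully named list")
  ids <- rownames(A)
  for (nm in names(G_list)) {
    bad <- c(setdiff(ids, rownames(G_list[[nm]])),
             setdiff(rownames(G_list[[nm]]), ids))
    if (length(bad))
      stop("id mismatch with matrix '", nm, "': ",
           paste(utils::head(bad, 5), collapse = ", "))
    G_list[[nm]] <- rel_matrix(unclass(G_list[[nm]])[ids, ids],
                               method = attr(G_list[[nm]], "method"),
                               scenario = attr(G_list[[nm]], "scenario"),
                               n_variants = attr(G_list[[nm]], "n_variants"))
  }
  mats <- c(list(A_ped = A), G_list)
  groups <- group_pairs(A)
  pr <- groups$pairs
  iu <- cbind(match(pr$id1, ids), match(pr$id2, ids))

  scenario_table <- data.frame(
    matrix = names(mats),
    method = vapply(mats, function(m) attr(m, "method"), character(1)),
    scenario = vapply(mats, function(m) {
      sc <- attr(m, "scenario"); if (is.null(sc)) "none" else sc$name
    }, character(1)),
    n_variants = vapply(mats, function(m) {
      nv <- attr(m, "n_variants"); if (is.null(nv)) NA_integer_ else as.integer(nv)
    }, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)

  # descriptive statistics per matrix x group, plus inbreeding (diag - 1)
  desc <- list()
  for (nm in names(mats)) {
    v <- unclass(mats[[nm]])[iu]
    for (gl in groups$levels) {
      sel <- pr$group == gl
      if (sum(sel) >= 2) {
        d <- describe_estimates(v[sel])
        desc[[length(desc) + 1]] <- data.frame(
          matrix = nm, group = gl, min = d["min"], mean = d["mean"],
          max = d["max"], var = d["var"], n = d["n"], row.names = NULL)
      }
    }
    f <- diag(unclass(mats[[nm]])) - 1
    d <- describe_estimates(f)
    desc[[length(desc) + 1]] <- data.frame(
      matrix = nm, group = "inbreeding", min = d["min"], mean = d["mean"],
      max = d["max"], var = d["var"], n = d["n"], row.names = NULL)
  }
  descriptive <- do.call(rbind, desc)

  # pairwise correlations: overall and within degree groups
  cors <- list()
  nms <- names(mats)
  for (a in seq_along(nms)) for (b in seq_along(nms)) {
    if (a >= b) next
    va <- unclass(mats[[nms[a]]])[iu]
    vb <- unclass(mats[[nms[b]]])[iu]
    for (gl in c("all", groups$levels)) {
      sel <- if (gl == "all") rep(TRUE, nrow(pr)) else pr$group == gl
      if (sum(sel) < 3) next
      res <- tryCatch(pearson_test(va[sel], vb[sel], epsilon_one = epsilon_one),
                      error = function(e) NULL)
      if (is.null(res)) next
      cors[[length(cors) + 1]] <- data.frame(
        matrix1 = nms[a], matrix2 = nms[b], group = gl, n = res$n, r = res$r,
        p_vs_zero = res$p_vs_zero,
        different_from_zero = res$different_from_zero,
        different_from_one = res$different_from_one,
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  correlations <- do.call(rbind, cors)

  # paired Wilcoxon between matrices on pooled off-diagonal estimates
  wil <- list()
  for (a in seq_along(nms)) for (b in seq_along(nms)) {
    if (a >= b) next
    va <- unclass(mats[[nms[a]]])[iu]
    vb <- unclass(mats[[nms[b]]])[iu]
    res <- suppressWarnings(wilcoxon_signed_rank(va, vb))
    wil[[length(wil) + 1]] <- data.frame(
      matrix1 = nms[a], matrix2 = nms[b], n = res$n, statistic = res$statistic,
      p_value = res$p_value, method = res$method,
      row.names = NULL, stringsAsFactors = FALSE)
  }
  wilcoxon <- do.call(rbind, wil)

  inbreeding_depth <- NULL
  if (!is.null(ped)) {
    F_ped <- pedigree_inbreeding(ped)
    F_ped <- F_ped[F_ped$id %in% ids, ]
    grp <- depth_groups(ped, ids = ids, thresholds = depth_thresholds)
    tabs <- lapply(names(G_list), function(nm) {
      tb <- suppressWarnings(
        depth_correlation_table(F_ped, genomic_inbreeding(G_list[[nm]]), grp))
      if (!is.null(tb)) tb$matrix <- nm
      tb
    })
    inbreeding_depth <- do.call(rbind, tabs)
  }

  structure(list(scenario_table = scenario_table, descriptive = descriptive,
                 correlations = correlations, wilcoxon = wilcoxon,
                 inbreeding_depth = inbreeding_depth, groups = groups),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("== Scenario overview ==\n"); print(x$scenario_table)
  cat("\n== Degree groups ==\n"); print(table(x$groups$pairs$group))
  cat("\n== Descriptive statistics ==\n")
  print(x$descriptive, digits = 4, row.names = FALSE)
  cat("\n== Correlations ==\n")
  print(x$correlations, digits = 4, row.names = FALSE)
  cat("\n== Wilcoxon signed-rank (pooled pairs) ==\n")
  print(x$wilcoxon, digits = 4, row.names = FALSE)
  if (!is.null(x$inbreeding_depth)) {
    cat("\n== Inbreeding correlations by pedigree depth ==\n")
    print(x$inbreeding_depth, digits = 4, row.names = FALSE)
  }
  invisible(x)
}
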