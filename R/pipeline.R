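# End-to-end orchestration: build sequence-like and chip-like datasets (real
# or simulated), run every scenario x estimator combination, and write the
# comparison report tables.

#' Thin variants to a chip-like uniform-MAF subset
#'
#' SNP chips are ascertained towards common variants, giving them a roughly
#' flat MAF spectrum, whereas sequence data are rare-allele-heavy. This
#' emulates chip ascertainment by stratified sampling over 1%-wide MAF bins
#' so the selected subset's MAF histogram is approximately uniform on
#' `[maf_min, 0.5]`. Bins with too few variants are topped up from the
#' remaining variants closest in MAF, with a warning.
#'
#' @param g a [genotype_matrix()].
#' @param n_target number of variants to select (`<=` variants available).
#' @param seed integer seed.
#' @param maf_min lower edge of the binning range (default 0.01).
#' @param bin_width MAF bin width (default 0.01).
#' @return A `genotype_matrix` with the selected variants in their original
#'   order.
#' @export
chip_thinning <- function(g, n_target, seed, maf_min = 0.01, bin_width = 0.01) {
  maf <- variant_stats(g)$maf
  if (n_target > ncol(g)) stop("n_target exceeds the number of variants")
  if (n_target == ncol(g)) return(g)
  breaks <- seq(maf_min, 0.5, by = bin_width)
  if (breaks[length(breaks)] < 0.5) breaks <- c(breaks, 0.5)
  eligible <- which(maf >= maf_min)
  bin <- cut(maf[eligible], breaks, include.lowest = TRUE, labels = FALSE)
  nbins <- length(breaks) - 1L
  quota <- rep(n_target %/% nbins, nbins)
  extra <- n_target - sum(quota)
  if (extra > 0) quota[seq_len(extra)] <- quota[seq_len(extra)] + 1L
  with_seed(seed, {
    chosen <- integer(0)
    short <- 0L
    for (b in seq_len(nbins)) {
      in_bin <- eligible[bin == b]
      take <- min(quota[b], length(in_bin))
      short <- short + quota[b] - take
      if (take > 0)
        chosen <- c(chosen, in_bin[sample.int(length(in_bin), take)])
    }
    if (short > 0) {
      warning(short, " variant(s) reassigned from under-filled MAF bins")
      left <- setdiff(eligible, chosen)
      # fill from neighbours: prefer the rarest remaining (adjacent bins)
      left <- left[order(maf[left])]
      chosen <- c(chosen, left[seq_len(min(short, length(left)))])
    }
    subset_genotypes(g, j = sort(chosen))
  })
}

#' Pipeline configuration
#'
#' @param sim a [sim_config()] for a simulated cohort, or `NULL` when reading
#'   real inputs.
#' @param genotype_path,pedigree_path input files (used when `sim` is NULL).
#' @param chip_ids optional variant-id list file or character vector defining
#'   the chip subset of real data; for simulated data chip emulation uses
#'   [chip_thinning()].
#' @param n_chip target chip size for thinning (default 10% of variants,
#'   capped at 5000).
#' @param scenarios scenario names to run (default the three MAF scenarios).
#' @param estimators `"yang"`, `"similarity"` or both.
#' @param alpha HWE significance level.
#' @param depth_thresholds pedigree-depth thresholds.
#' @param seed integer seed.
#' @param out_dir output directory.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, genotype_path = NULL,
                            pedigree_path = NULL, chip_ids = NULL,
                            n_chip = NULL,
                            scenarios = c("5+", "1+", "1_5"),
                            estimators = c("yang", "similarity"),
                            alpha = 0.05, depth_thresholds = c(1L, 2L, 4L),
                            seed = NULL, out_dir = NULL) {
  estimators <- match.arg(estimators, several.ok = TRUE)
  if (is.null(sim) && (is.null(genotype_path) || is.null(pedigree_path)))
    stop("provide either a sim_config or genotype and pedigree paths")
  if (!is.null(sim)) stopifnot(inherits(sim, "sim_config"))
  if (is.null(seed)) seed <- if (!is.null(sim)) sim$seed else
    stop("seed is required")
  stopifnot(all(scenarios %in% c("5+", "1+", "1_5")))
  structure(list(sim = sim, genotype_path = genotype_path,
                 pedigree_path = pedigree_path, chip_ids = chip_ids,
                 n_chip = n_chip, scenarios = scenarios,
                 estimators = estimators, alpha = alpha,
                 depth_thresholds = as.integer(depth_thresholds),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full relationship-comparison pipeline
#'
#' Builds (or reads) a sequence-like genotype set and a chip-like subset,
#' applies every MAF scenario to both, computes the pedigree A matrix and the
#' requested genomic estimators per scenario, runs the Hardy-Weinberg
#' analysis, and assembles the comparison report. When `out_dir` is set, all
#' tables are written as TSV plus a JSON run manifest.
#'
#' @param config a [pipeline_config()].
#' @return List of class `pipeline_result`: `report` (a
#'   [scenario_report()] object), `hwe` (per scenario x source), `matrices`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }

  if (!is.null(config$sim)) {
    ped <- run_stage("simulate_pedigree", simulate_pedigree(config$sim))
    genotyped <- attr(ped, "genotyped")
    obs_ped <- attr(ped, "observed")
    freqs <- run_stage("spectrum", draw_frequency_spectrum(
      config$sim$n_variants, config$sim$spectrum, config$sim$maf_min,
      seed = config$seed + 1L))
    g_all <- run_stage("gene_drop",
                       gene_drop(ped, freqs, seed = config$seed + 2L))
    g_wgs <- subset_genotypes(g_all, i = match(genotyped, rownames(g_all)))
    note("simulated %d individuals (%d genotyped), %d variants",
         nrow(ped), length(genotyped), ncol(g_wgs))
    n_chip <- config$n_chip
    if (is.null(n_chip)) n_chip <- min(5000L, max(2L, ncol(g_wgs) %/% 10L))
    g_chip <- run_stage("chip_thinning", {
      keep <- which(variant_stats(g_wgs)$maf >= config$sim$maf_min)
      chip_thinning(subset_genotypes(g_wgs, j = keep),
                    min(n_chip, length(keep)), seed = config$seed + 3L,
                    maf_min = config$sim$maf_min)
    })
  } else {
    g_wgs <- run_stage("read_genotypes", read_genotypes(config$genotype_path))
    obs_ped <- ped <- run_stage("read_pedigree",
                                read_pedigree(config$pedigree_path))
    genotyped <- intersect(ped$id, rownames(g_wgs))
    g_wgs <- subset_genotypes(g_wgs, i = match(genotyped, rownames(g_wgs)))
    if (is.null(config$chip_ids)) stop("chip_ids required for real data")
    ids <- if (length(config$chip_ids) == 1 && file.exists(config$chip_ids))
      readLines(config$chip_ids) else config$chip_ids
    g_chip <- run_stage("subset_chip", subset_chip(g_wgs, ids))
  }
  note("chip subset: %d variants", ncol(g_chip))

  sources <- list(WGS = g_wgs, SNP = g_chip)
  scen <- lapply(config$scenarios, scenario_spec)
  names(scen) <- config$scenarios

  A <- run_stage("a_matrix", a_matrix(obs_ped, ids = genotyped))

  G_list <- list()
  hwe_rows <- list()
  for (src in names(sources)) {
    for (sc in names(scen)) {
      gs <- run_stage("apply_maf_scenario",
                      apply_maf_scenario(sources[[src]], scen[[sc]]))
      if (ncol(gs) < 2) {
        note("scenario %s/%s empty; skipped", src, sc)
        next
      }
      hw <- run_stage("hwe", hwe_departure_fraction(gs, alpha = config$alpha))
      hwe_rows[[paste(src, sc)]] <- data.frame(
        source = src, scenario = sc, n_variants = hw$n_variants,
        n_departing = hw$n_departing,
        percent_departing = hw$percent_departing, stringsAsFactors = FALSE)
      if ("yang" %in% config$estimators)
        G_list[[paste0("G_", src, "_", sc, "_yang")]] <-
          run_stage("grm_yang", grm_yang(gs))
      if ("similarity" %in% config$estimators)
        G_list[[paste0("G_", src, "_", sc, "_sim")]] <-
          run_stage("grm_similarity", grm_similarity(gs))
      note("scenario %s/%s: %d variants", src, sc, ncol(gs))
    }
  }
  hwe_table <- do.call(rbind, c(hwe_rows, list(make.row.names = FALSE)))

  report <- run_stage("scenario_report",
                      scenario_report(A, G_list, ped = obs_ped,
                                      depth_thresholds = config$depth_thresholds))

  manifest <- list(seed = config$seed, scenarios = config$scenarios,
                   estimators = config$estimators, alpha = config$alpha,
                   n_genotyped = length(genotyped),
                   version = as.character(utils::packageVersion("relkit")),
                   log = log)

  result <- structure(list(report = report, hwe = hwe_table,
                           matrices = c(list(A_ped = A), G_list),
                           manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_result(result, config$out_dir)
  result
}

write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  rep <- result$report
  wt(rep$scenario_table, "scenario_counts.tsv")
  wt(rep$descriptive, "descriptive.tsv")
  wt(rep$correlations, "correlations.tsv")
  wt(rep$wilcoxon, "wilcoxon.tsv")
  if (!is.null(rep$inbreeding_depth))
    wt(rep$inbreeding_depth, "inbreeding_depth.tsv")
  wt(result$hwe, "hwe_summary.tsv")
  for (nm in names(result$matrices))
    write_rel_matrix(result$matrices[[nm]],
                     file.path(out_dir, paste0(nm, ".tsv")))
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  cat("HWE summary:\n"); print(x$hwe, row.names = FALSE)
  cat("\n")
  print(x$report)
  invisible(x)
}
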