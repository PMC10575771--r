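# Full analysis pipeline: per region x metabolite x measure pooling,
# sensitivity subsets, meta-regressions with follow-ups, FDR, and export.

#' Analysis configuration
#'
#' @param measures Effect-size measures to pool.
#' @param method Between-study variance estimator for [remeta()].
#' @param min_k_regression Minimum studies for a meta-regression.
#' @param fdr_q False discovery rate for the per-measure x metabolite
#'   families across brain regions.
#' @param alpha Significance level used to trigger follow-up regressions.
#' @param g_variance Hedges' g variance flavour.
#' @param control_n_mode Shared-control adjustment mode (see
#'   [adjust_control_n()]).
#' @param dip_scheme Normalisation for the modality analysis.
#' @param dip_n_sim Null replicates for the Monte-Carlo dip calibration.
#' @param seed Seed for the dip calibration (required when individual-level
#'   data are analysed).
#' @return List of class `glumeta_config`.
#' @export
analysis_config <- function(measures = c("lnCVR", "lnVR", "SMD"),
                            method = "REML",
                            min_k_regression = 5L,
                            fdr_q = 0.10,
                            alpha = 0.05,
                            g_variance = "LS",
                            control_n_mode = "fractional",
                            dip_scheme = "divide_by_mean",
                            dip_n_sim = 2000L,
                            seed = NULL) {
  out <- as.list(environment())
  class(out) <- "glumeta_config"
  out
}

.read_config <- function(config) {
  if (is.character(config)) {
    vals <- yaml::read_yaml(config)
    config <- do.call(analysis_config, vals)
  }
  if (!inherits(config, "glumeta_config")) config <- do.call(analysis_config, config)
  config
}

.tiny_digest <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  v <- as.double(raw)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 2^31)
}

.moderators_primary <- c("mean_age", "prop_male", "panss_total", "cpz")
.moderator_sd_map <- c(mean_age = "age_sd", panss_total = "panss_total_sd")
.quality_mods <- c("snr_ratio", "fwhm_ratio")

#' Run the full variability-and-magnitude meta-analysis
#'
#' For every brain region x metabolite cell with at least two studies, pools
#' lnCVR, lnVR and Hedges' g effect sizes for all patients and for the
#' antipsychotic-naive and medicated sensitivity subsets; compares the
#' subsets in Wald tests where both are estimable; runs moderator
#' meta-regressions (combined mean age, proportion male, PANSS total, CPZ
#' dose) where at least `min_k_regression` studies carry the moderator;
#' follows up significant lnCVR meta-regressions with the moderator-SD
#' regressions, and FDR-significant lnCVR pooled results with the 1H-MRS
#' quality-ratio regressions (SNR, FWHM); applies Benjamini-Hochberg FDR per
#' measure x metabolite across regions; and computes the weighted mean-SD
#' correlation diagnostic.  Individual-level data, when supplied, are dip
#' tested per metabolite x reference-scheme stratum via [pool_and_test()].
#'
#' Cells that cannot be analysed are logged in `skipped`, never dropped
#' silently.
#'
#' @param study A file path, data frame, or `study_table` of study-level
#'   records.
#' @param individual Optional long-format individual-level data frame
#'   (columns `study_id`, `group`, `metabolite`, `reference_scheme`,
#'   `value`).
#' @param config An [analysis_config()], a YAML file path, or a list.
#' @return Object of class `glumeta_results`.
#' @export
run_full_analysis <- function(study, individual = NULL,
                              config = analysis_config()) {
  config <- .read_config(config)
  st <- if (inherits(study, "study_table")) study
        else read_study_table(study, control_n_mode = config$control_n_mode)
  rec <- st$records
  if (!nrow(rec)) stop("no valid records to analyse", call. = FALSE)

  skipped <- list()
  skip <- function(...) skipped[[length(skipped) + 1L]] <<- data.frame(...)

  pooled <- list(); fits <- list(); waldt <- list()
  for (measure in config$measures) {
    es <- effect_sizes(rec, measure = measure, g_variance = config$g_variance)
    for (region in unique(es$region)) for (metab in unique(es$metabolite)) {
      cell <- es[es$region == region & es$metabolite == metab, , drop = FALSE]
      if (!nrow(cell)) next
      subsets <- list(all = cell,
                      antipsychotic_naive =
                        cell[cell$medication_status == "antipsychotic_naive", ],
                      medicated = cell[cell$medication_status == "medicated", ])
      for (sub in names(subsets)) {
        dsub <- subsets[[sub]]
        if (nrow(dsub) < 2) {
          skip(stage = "pooling", measure = measure, region = region,
               metabolite = metab, subset = sub,
               reason = paste0("k = ", nrow(dsub), " < 2"))
          next
        }
        fit <- remeta(dsub$yi, dsub$vi, data = dsub, method = config$method)
        key <- paste(measure, region, metab, sub, sep = "|")
        fits[[key]] <- fit
        pooled[[key]] <- data.frame(
          measure = measure, region = region, metabolite = metab,
          subset = sub, k = fit$k, estimate = fit$b[[1]], se = fit$se[[1]],
          ci_low = fit$ci.lb[[1]], ci_high = fit$ci.ub[[1]],
          z = fit$zval[[1]], p = fit$pval[[1]],
          tau2 = fit$tau2, i2 = fit$i2,
          study_ids = paste(dsub$study_id, collapse = ";"),
          stringsAsFactors = FALSE)
      }
      ka <- paste(measure, region, metab, "antipsychotic_naive", sep = "|")
      km <- paste(measure, region, metab, "medicated", sep = "|")
      if (!is.null(fits[[ka]]) && !is.null(fits[[km]])) {
        wt <- compare_subgroups(fits[[ka]], fits[[km]])
        waldt[[paste(measure, region, metab, sep = "|")]] <- data.frame(
          measure = measure, region = region, metabolite = metab,
          comparison = "antipsychotic_naive_vs_medicated",
          estimate_a = wt$estimate_a, estimate_b = wt$estimate_b,
          z = wt$z, p = wt$p, stringsAsFactors = FALSE)
      }
    }
  }
  pooled <- if (length(pooled)) do.call(rbind, c(pooled, make.row.names = FALSE))
            else data.frame()
  waldt <- if (length(waldt)) do.call(rbind, c(waldt, make.row.names = FALSE))
           else data.frame()

  # FDR per measure x metabolite across regions (the region family)
  fdr <- list()
  if (nrow(pooled)) {
    pall <- pooled[pooled$subset == "all", , drop = FALSE]
    for (measure in unique(pall$measure)) for (metab in unique(pall$metabolite)) {
      fam <- pall[pall$measure == measure & pall$metabolite == metab, , drop = FALSE]
      if (!nrow(fam)) next
      fl <- bh_fdr(fam$p, q = config$fdr_q)
      fdr[[paste(measure, metab, sep = "|")]] <- data.frame(
        measure = measure, metabolite = metab, region = fam$region,
        p = fam$p, p_adjusted = fl$p_adjusted, reject = fl$reject,
        q = config$fdr_q, stringsAsFactors = FALSE)
    }
  }
  fdr <- if (length(fdr)) do.call(rbind, c(fdr, make.row.names = FALSE))
         else data.frame()

  # moderator meta-regressions (primary), on lnCVR and SMD
  regress <- list()
  run_regression <- function(measure, region, metab, moderator, type) {
    es <- effect_sizes(rec[rec$region == region & rec$metabolite == metab, ],
                       measure = measure, g_variance = config$g_variance)
    es <- es[is.finite(es[[moderator]]), , drop = FALSE]
    if (nrow(es) < config$min_k_regression) {
      skip(stage = "meta_regression", measure = measure, region = region,
           metabolite = metab, subset = moderator,
           reason = paste0("k = ", nrow(es), " < ", config$min_k_regression))
      return(NULL)
    }
    if (length(unique(es[[moderator]])) < 2) {
      skip(stage = "meta_regression", measure = measure, region = region,
           metabolite = metab, subset = moderator, reason = "constant moderator")
      return(NULL)
    }
    fit <- remeta(es$yi, es$vi, mods = stats::as.formula(paste("~", moderator)),
                  data = es, method = config$method,
                  min_k = config$min_k_regression)
    data.frame(measure = measure, region = region, metabolite = metab,
               moderator = moderator, type = type, k = fit$k,
               slope = fit$b[[2]], se = fit$se[[2]], z = fit$zval[[2]],
               p = fit$pval[[2]], tau2_residual = fit$tau2,
               stringsAsFactors = FALSE)
  }
  cells <- unique(rec[c("region", "metabolite")])
  for (measure in intersect(c("lnCVR", "SMD"), config$measures))
    for (ci in seq_len(nrow(cells))) for (m in .moderators_primary) {
      rr <- run_regression(measure, cells$region[ci], cells$metabolite[ci],
                           m, "primary")
      if (!is.null(rr)) regress[[length(regress) + 1L]] <- rr
    }
  regress_df <- if (length(regress)) do.call(rbind, c(regress, make.row.names = FALSE))
                else data.frame()

  # follow-ups: moderator-SD regressions for significant primary lnCVR
  # meta-regressions; data-quality regressions for FDR-significant lnCVR cells
  if (nrow(regress_df)) {
    sig <- regress_df[regress_df$measure == "lnCVR" &
                      regress_df$type == "primary" &
                      regress_df$p < config$alpha, , drop = FALSE]
    fu <- list()
    for (i in seq_len(nrow(sig))) {
      mod_sd <- .moderator_sd_map[sig$moderator[i]]
      if (is.na(mod_sd)) next
      rr <- run_regression("lnCVR", sig$region[i], sig$metabolite[i],
                           unname(mod_sd), "moderator_sd")
      if (!is.null(rr)) fu[[length(fu) + 1L]] <- rr
    }
    if (nrow(fdr)) {
      sig_cells <- fdr[fdr$measure == "lnCVR" & fdr$reject, , drop = FALSE]
      for (i in seq_len(nrow(sig_cells))) for (qm in .quality_mods) {
        rr <- run_regression("lnCVR", sig_cells$region[i],
                             sig_cells$metabolite[i], qm, "quality")
        if (!is.null(rr)) fu[[length(fu) + 1L]] <- rr
      }
    }
    if (length(fu))
      regress_df <- rbind(regress_df,
                          do.call(rbind, c(fu, make.row.names = FALSE)))
  }

  # weighted mean-SD correlation across study arms (weights: combined n)
  correlation <- tryCatch(
    weighted_pearson(c(rec$mean_p, rec$mean_c), c(rec$sd_p, rec$sd_c),
                     rep(rec$n_p + rec$n_c, 2)),
    error = function(e) NA_real_)

  # modality analysis on individual-level data
  dip_results <- NULL
  if (!is.null(individual)) {
    if (is.null(config$seed))
      stop("config$seed is required for the Monte-Carlo dip calibration",
           call. = FALSE)
    stopifnot(all(c("study_id", "group", "value") %in% names(individual)))
    pat <- individual[individual$group == "patient", , drop = FALSE]
    if (is.null(pat$metabolite)) pat$metabolite <- "glutamate"
    if (is.null(pat$reference_scheme)) pat$reference_scheme <- "other"
    dip_results <- list()
    for (metab in unique(pat$metabolite))
      for (rs in unique(pat$reference_scheme)) {
        sl <- pat[pat$metabolite == metab & pat$reference_scheme == rs, ]
        if (!nrow(sl)) next
        keep <- names(which(table(sl$study_id) >= 2))
        sl <- sl[sl$study_id %in% keep, ]
        if (!nrow(sl)) {
          skip(stage = "modality", measure = "dip", region = "",
               metabolite = metab, subset = rs, reason = "no study with n >= 2")
          next
        }
        dip_results[[paste(metab, rs, sep = "|")]] <-
          pool_and_test(sl, scheme = config$dip_scheme,
                        n_sim = config$dip_n_sim, seed = config$seed)
      }
  }

  skipped <- if (length(skipped)) do.call(rbind, c(skipped, make.row.names = FALSE))
             else data.frame()

  out <- list(pooled = pooled, regressions = regress_df,
              subgroup_tests = waldt, fdr = fdr,
              correlation = correlation, dip = dip_results,
              skipped = skipped,
              provenance = list(
                n_records = nrow(rec),
                input_digest = .tiny_digest(rec),
                seed = config$seed,
                config = unclass(config)[setdiff(names(config), "")],
                package_version = as.character(utils::packageVersion("glumeta")),
                variance_note = paste(
                  "lnCVR/lnVR sampling variances use the standard",
                  "independent-groups approximation without a mean-SD",
                  "correlation term (assumption)")))
  class(out) <- "glumeta_results"
  out
}

#' @export
print.glumeta_results <- function(x, ...) {
  cat("glumeta analysis:", x$provenance$n_records, "records\n")
  if (nrow(x$pooled)) {
    cat("Pooled results (subset = all):\n")
    pa <- x$pooled[x$pooled$subset == "all",
                   c("measure", "region", "metabolite", "k", "estimate",
                     "ci_low", "ci_high", "p", "i2")]
    pa[5:9] <- lapply(pa[5:9], function(v) round(v, 3))
    print(pa, row.names = FALSE)
  }
  if (is.finite(x$correlation))
    cat("Weighted mean-SD correlation:", round(x$correlation, 3), "\n")
  if (nrow(x$regressions))
    cat(nrow(x$regressions), "meta-regressions (",
        sum(x$regressions$p < 0.05), "with p < 0.05 )\n")
  if (!is.null(x$dip))
    for (nm in names(x$dip)) {
      cat("Dip [", nm, "]: ")
      print(x$dip[[nm]]$pooled)
    }
  invisible(x)
}

#' @export
summary.glumeta_results <- function(object, ...) print(object, ...)

#' Export forest-style tables and a JSON result set
#'
#' One TSV per measure (columns `region`, `metabolite`, `subset`, `k`,
#' `estimate`, `ci_low`, `ci_high`, `p`, `i2`; rows only for estimable
#' cells), plus `results.json` with the complete result set.  Output is
#' byte-stable across runs with the same inputs and seed (no timestamps).
#'
#' @param results A `glumeta_results`.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of paths written, invisibly.
#' @export
export_forest_tables <- function(results, out_dir) {
  stopifnot(inherits(results, "glumeta_results"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir))
      stop("cannot create output directory ", out_dir, call. = FALSE)
  }
  paths <- character(0)
  for (measure in unique(results$pooled$measure)) {
    tab <- results$pooled[results$pooled$measure == measure,
                          c("region", "metabolite", "subset", "k", "estimate",
                            "ci_low", "ci_high", "p", "i2")]
    p <- file.path(out_dir, paste0("forest_", measure, ".tsv"))
    num <- vapply(tab, is.numeric, TRUE)
    tab[num] <- lapply(tab[num], function(v) format(v, digits = 15, trim = TRUE,
                                                    scientific = FALSE))
    utils::write.table(tab, p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  pj <- file.path(out_dir, "results.json")
  ser <- results
  ser$dip <- lapply(ser$dip, function(d) list(
    pooled = unclass(d$pooled),
    per_study = lapply(d$per_study, unclass), scheme = d$scheme))
  jsonlite::write_json(unclass(ser), pj, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  paths <- c(paths, pj)
  invisible(paths)
}
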