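# End-to-end orchestration: simulate -> clean -> transfer -> GMM/SOM ->
# reference intervals -> bias assessment, as a single reproducible run.

#' Pipeline run configuration
#'
#' Collects every tunable of a full run. A run is a pure function of this
#' configuration: rerunning with the same config reproduces the same report.
#'
#' @param seed Integer master seed (direct sample uses \code{seed}, LIS
#'   sample \code{seed + 1}, bootstrap fallbacks \code{seed + 2}).
#' @param spec Simulation spec, see \code{\link{default_simulation_spec}}.
#' @param n_direct Direct-sample size(s) per stratum; defaults to the
#'   published per-stratum counts (3167, 4469, 1455, 1594).
#' @param n_lis LIS subjects per stratum.
#' @param strategy Outlier strategy, "per_analyte" or "radical".
#' @param analytes Analytes to report RIs for.
#' @param maps Transference maps applied to the direct sample.
#' @param bounds Plausibility bounds for cleaning.
#' @param skew_threshold Normality screen for Box-Cox in cleaning.
#' @param gmm_tol,gmm_max_iter EM controls.
#' @param som_kernel_width,som_max_iter Batch-SOM controls.
#' @param conf Confidence level for RI limit CIs.
#' @param out_dir Optional directory; when set, \code{\link{run_indirect_ri}}
#'   writes CSV tables and a JSON report there.
#' @return List of class \code{"ri_config"}.
#' @export
ri_config <- function(seed = 1L, spec = default_simulation_spec(),
                      n_direct = c(3167L, 4469L, 1455L, 1594L),
                      n_lis = 5000L,
                      strategy = c("per_analyte", "radical"),
                      analytes = c("creatinine", "urea"),
                      maps = default_transfer_maps(),
                      bounds = default_bounds(), skew_threshold = 0.5,
                      gmm_tol = 1e-8, gmm_max_iter = 500L,
                      som_kernel_width = 1, som_max_iter = 200L,
                      conf = 0.90, out_dir = NULL) {
  strategy <- match.arg(strategy)
  structure(as.list(environment()), class = "ri_config")
}

#' @export
print.ri_config <- function(x, ...) {
  cat(sprintf("indirect-RI run config: seed %d, %d strata, n_lis %s/stratum, %s outliers\n",
              x$seed, length(x$spec), paste(unique(x$n_lis), collapse = "/"),
              x$strategy))
  invisible(x)
}

#' Run the full indirect reference-interval pipeline
#'
#' Executes every stage in order on synthetic data: generate a direct
#' (healthy, Roche-scale) sample and a mixed LIS (Beckman-scale) population;
#' clean both (missing/extreme deletion, earliest-record deduplication, age
#' filter 1 to <17 years, per-stratum Box-Cox + Tukey outlier removal, with
#' the configured strategy on the LIS side); transfer the direct sample to
#' the LIS platform; partition potential healthy LIS children per analyte and
#' stratum by GMM (initialized from the transferred direct sample) and by a
#' 3x1 batch SOM on the joint renal triple; estimate nonparametric RIs for
#' the direct and both indirect populations; and assess each indirect limit's
#' bias ratio against the direct one.
#'
#' @param config A \code{\link{ri_config}}.
#' @return Object of class \code{"indirect_ri_run"}: per-analyte
#'   \code{reports} (see \code{\link{compare_populations}}), selected
#'   \code{fractions} per method and analyte, per-stratum \code{gmm} /
#'   \code{som} fits, stage-wise record \code{counts}, the cleaning reports,
#'   \code{truth}, and the \code{config}.
#' @export
run_indirect_ri <- function(config = ri_config()) {
  stopifnot(inherits(config, "ri_config"))
  spec <- config$spec
  schemes <- list(creatinine = default_strata("creatinine"),
                  urea = default_strata("urea"),
                  uric_acid = default_strata("uric_acid"))

  direct <- generate_direct(spec, config$n_direct, seed = config$seed)
  lis <- generate_lis(spec, config$n_lis, seed = config$seed + 1L)
  counts <- list(direct_raw = nrow(direct$records),
                 lis_raw = nrow(lis$records))

  dir_clean <- clean_records(direct$records, schemes, config$bounds,
                             skew_threshold = config$skew_threshold)
  lis_clean <- clean_records(lis$records, schemes, config$bounds,
                             skew_threshold = config$skew_threshold,
                             strategy = config$strategy)
  counts$direct_cleaning <- dir_clean$report$counts
  counts$lis_cleaning <- lis_clean$report$counts

  dir_recs <- transfer_records(dir_clean$records, config$maps)
  lis_recs <- lis_clean$records

  gmm_runs <- list(); som_runs <- list()
  reports <- list()
  fractions <- list()
  for (a in config$analytes) {
    scheme <- schemes[[a]]
    lis_a <- lis_recs[lis_recs$analyte == a, , drop = FALSE]
    dir_a <- dir_recs[dir_recs$analyte == a, , drop = FALSE]
    gmm_runs[[a]] <- gmm_partition(lis_a, dir_a, scheme,
                                   tol = config$gmm_tol,
                                   max_iter = config$gmm_max_iter)
    som_runs[[a]] <- som_partition(lis_recs, scheme,
                                   kernel_width = config$som_kernel_width,
                                   max_iter = config$som_max_iter)
    gmm_sel <- do.call(rbind, lapply(gmm_runs[[a]], `[[`, "records"))
    som_ids <- unlist(lapply(som_runs[[a]], `[[`, "subjects"), use.names = FALSE)
    som_sel <- lis_a[lis_a$subject_id %in% som_ids, , drop = FALSE]
    # fractions use the full cleaned record count of the analyte as the
    # common denominator (matching the published arithmetic, where subjects
    # without a complete renal triple can never be SOM-selected)
    n_lis_a <- sum(!is.na(assign_stratum(lis_a$age, lis_a$sex, scheme)))
    fractions[[a]] <- c(
      gmm = sum(vapply(gmm_runs[[a]], function(r) length(r$selected), 0L)) /
        n_lis_a,
      som = nrow(som_sel) / n_lis_a
    )
    reports[[a]] <- compare_populations(
      list(direct = dir_a, gmm = gmm_sel, som = som_sel),
      scheme, conf = config$conf, boot_seed = config$seed + 2L)
    counts[[paste0(a, "_partition")]] <- c(
      lis = nrow(lis_a), gmm_selected = nrow(gmm_sel),
      som_clustered = sum(vapply(som_runs[[a]], `[[`, 0L, "n_total")),
      som_selected = nrow(som_sel))
  }

  run <- structure(list(reports = reports, fractions = fractions,
                        gmm = gmm_runs, som = som_runs, counts = counts,
                        cleaning = list(direct = dir_clean$report,
                                        lis = lis_clean$report),
                        truth = list(direct = direct$truth, lis = lis$truth),
                        config = config),
                   class = "indirect_ri_run")
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

#' @export
print.indirect_ri_run <- function(x, ...) {
  cat("Indirect reference-interval run (seed ", x$config$seed, ", ",
      x$config$strategy, " outliers)\n\n", sep = "")
  for (a in names(x$reports)) {
    cat("== ", a, " ==  selected fractions: GMM ",
        sprintf("%.1f%%", 100 * x$fractions[[a]]["gmm"]), ", SOM ",
        sprintf("%.1f%%", 100 * x$fractions[[a]]["som"]), "\n", sep = "")
    print(x$reports[[a]])
    cat("\n")
  }
  invisible(x)
}

#' @export
plot.indirect_ri_run <- function(x, analyte = names(x$reports)[1], ...) {
  d <- x$reports[[analyte]]$densities
  strata <- unique(d$stratum)
  old <- graphics::par(mfrow = c(length(strata), 1), mar = c(3, 3, 2, 1))
  on.exit(graphics::par(old))
  for (s in strata) {
    ds <- d[d$stratum == s, ]
    pops <- unique(ds$population)
    graphics::plot(NA, xlim = range(ds$x), ylim = range(ds$y), main = s,
                   xlab = analyte, ylab = "density", ...)
    for (i in seq_along(pops)) {
      dp <- ds[ds$population == pops[i], ]
      graphics::lines(dp$x, dp$y, col = i, lwd = 2)
    }
    graphics::legend("topright", legend = pops, col = seq_along(pops),
                     lwd = 2, bty = "n", cex = 0.8)
  }
  invisible(x)
}

# write tables and a machine-readable report bundle
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (a in names(run$reports)) {
    rep <- run$reports[[a]]
    utils::write.csv(rep$summaries, file.path(out_dir, paste0(a, "_summaries.csv")),
                     row.names = FALSE)
    utils::write.csv(rep$intervals, file.path(out_dir, paste0(a, "_intervals.csv")),
                     row.names = FALSE)
    if (!is.null(rep$bias)) {
      utils::write.csv(rep$bias, file.path(out_dir, paste0(a, "_bias.csv")),
                       row.names = FALSE)
    }
    utils::write.csv(rep$densities, file.path(out_dir, paste0(a, "_densities.csv")),
                     row.names = FALSE)
  }
  report <- list(seed = run$config$seed, strategy = run$config$strategy,
                 counts = lapply(run$counts, as.list),
                 fractions = lapply(run$fractions, as.list))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
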