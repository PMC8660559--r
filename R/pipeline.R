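#' Run the end-to-end mapping pipeline on a simulated experiment
#'
#' Executes the full workflow on synthetic data: simulate the experiment,
#' derive senescence metrics and classify every line against the parents
#' each season, select phenotype-based bulks, run the bulk segregant scan,
#' detect candidate regions, and perform single-marker association plus
#' inheritance classification at the peak marker. Stage failures are
#' recorded in the report while upstream results are preserved. Given the
#' same configuration and seed the report is identical.
#'
#' @param config a named list, or a path to a YAML file, with elements:
#'   `seed` (integer), `sim` (list of [sim_config()] overrides),
#'   `n_years`, `preset`, `varietal_threshold`, `delta_exact`,
#'   `bulk_source` (`"truth"` for the simulator's homozygous-only bulks,
#'   `"phenotype"` to pool the phenotype-classified selection),
#'   `n_markers`, `alpha`, `min_years`, `out_dir` (optional; report JSON
#'   written there).
#' @return object of class `pipeline_report` (a list).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(seed = 1L, sim = list(), n_years = 2, preset = "results",
                   varietal_threshold = 0.9, delta_exact = 1,
                   bulk_source = "truth", n_markers = 7, alpha = 0.05,
                   min_years = NULL, out_dir = NULL)
  config <- utils::modifyList(defaults, config)
  if (is.null(config$min_years)) config$min_years <- min(2, config$n_years)
  scfg <- do.call(sim_config, config$sim)
  set.seed(config$seed)

  report <- list(seed = config$seed, stages = list())
  run <- function(name, f) {
    res <- tryCatch(list(ok = TRUE, value = f()),
                    error = function(e) list(ok = FALSE,
                                             value = conditionMessage(e)))
    report$stages[[name]] <<- if (res$ok) "ok" else paste("failed:", res$value)
    if (res$ok) res$value else NULL
  }

  sim <- run("simulate", function() simulate_experiment(scfg, config$n_years))
  if (is.null(sim)) return(.finish_report(report, config))

  metrics <- run("metrics", function() {
    out <- list()
    for (year in names(sim$timecourses)) {
      tc <- sim$timecourses[[year]]
      # noiseless parental reference curves, dosage 0 and 2
      parents <- simulate_parent_curves(sim, year)
      per_ril <- lapply(split(tc, tc$plot), derive_metrics)
      out[[year]] <- list(per_ril = per_ril, parents = parents)
    }
    out
  })
  if (is.null(metrics)) return(.finish_report(report, config))

  classifications <- run("classify", function() {
    rows <- list()
    for (year in names(metrics)) {
      m <- metrics[[year]]
      for (ril in names(m$per_ril)) {
        cl <- classify_ril(m$per_ril[[ril]], m$parents$wt, m$parents$sg)
        rows[[length(rows) + 1L]] <- data.frame(
          ril = ril, year = year, class = cl$class,
          tt70 = unname(m$per_ril[[ril]]$tt_scores["TT70"]),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })

  pheno_bulks <- if (!is.null(classifications)) {
    run("bulks", function() {
      suppressWarnings(select_bulks(
        classifications, min_years = config$min_years,
        bulk_caps = c(sg = scfg$bulk_size_sg, nsg = scfg$bulk_size_nsg)))
    })
  } else NULL

  records <- run("readcounts", function() {
    if (config$bulk_source == "phenotype") {
      if (is.null(pheno_bulks) || length(pheno_bulks$sg) == 0 ||
          length(pheno_bulks$nsg) == 0)
        stop("phenotype-based bulk selection produced an empty bulk")
      simulate_bulk_readcounts(sim$truth, sim$genotypes,
                               list(sg = pheno_bulks$sg,
                                    nsg = pheno_bulks$nsg), scfg)
    } else sim$records
  })
  if (is.null(records)) return(.finish_report(report, config))

  scan <- run("bsa", function()
    bsa_scan(records, preset = config$preset,
             varietal_threshold = config$varietal_threshold,
             delta_exact = config$delta_exact))
  if (is.null(scan)) return(.finish_report(report, config))

  assoc <- run("assoc", function() {
    markers <- .pick_markers(sim, config$n_markers)
    tt70 <- vapply(rownames(sim$genotypes), function(r) {
      m <- metrics[[1]]$per_ril[[r]]
      if (is.null(m)) NA_real_ else unname(m$tt_scores["TT70"])
    }, numeric(1))
    a <- single_marker_assoc(markers$calls, data.frame(TT70 = tt70))
    peak <- attr(a, "peaks")[["TT70"]]
    inh <- tryCatch(
      classify_inheritance(tt70, markers$calls[, peak], config$alpha),
      error = function(e) list(mode = "ambiguous",
                               note = conditionMessage(e)))
    list(table = a, peak = peak, inheritance = inh, markers = markers$info)
  })

  causal <- sim$truth[sim$truth$class == "ems_causal", , drop = FALSE]
  top <- if (nrow(scan$regions) > 0) scan$regions[1, ] else NULL
  report$causal <- list(chrom = causal$chrom, pos = causal$pos)
  report$top_region <- if (!is.null(top)) {
    list(chrom = top$chrom, start = top$start, end = top$end,
         span_bp = top$span_bp, n_members = top$n_members)
  } else NULL
  report$causal_in_top_region <- !is.null(top) &&
    top$chrom == causal$chrom && top$start <= causal$pos &&
    top$end >= causal$pos
  report$n_enriched <- nrow(scan$enriched)
  report$n_varietal_removed <- nrow(scan$varietal)
  if (!is.null(classifications)) {
    truth_cls <- sim$phenotype_class[classifications$ril]
    comparable <- truth_cls != "intermediate" &
      classifications$class != "ambiguous"
    report$classification_accuracy <- if (any(comparable)) {
      mean(classifications$class[comparable] == truth_cls[comparable])
    } else NA
  }
  if (!is.null(assoc)) {
    report$peak_marker <- assoc$peak
    report$inheritance <- assoc$inheritance$mode
  }
  report$scan <- scan
  report$assoc <- assoc
  .finish_report(report, config)
}

# noiseless parental senescence curves for one season (dosage 0 and 2)
simulate_parent_curves <- function(sim, year) {
  cfg0 <- sim$config
  cfg0$t50_noise_sd <- 0
  temps <- sim$temps[[year]]
  tc <- simulate_senescence_timecourse(
    c(wt_parent = 0L, mutant_parent = 2L), NULL, cfg0, temps)
  list(wt = derive_metrics(tc[tc$plot == "wt_parent", ]),
       sg = derive_metrics(tc[tc$plot == "mutant_parent", ]))
}

# KASP-like marker panel: EMS SNPs spanning the causal chromosome
.pick_markers <- function(sim, n_markers) {
  causal_chrom <- sim$truth$chrom[sim$truth$class == "ems_causal"]
  idx <- which(sim$truth$chrom == causal_chrom &
                 sim$truth$class != "varietal")
  if (length(idx) > n_markers) {
    qs <- unique(round(stats::quantile(seq_along(idx),
                                       probs = seq(0, 1,
                                                   length.out = n_markers))))
    idx <- idx[qs]
  }
  # always include the causal SNP itself
  causal_idx <- which(sim$truth$class == "ems_causal")
  idx <- sort(unique(c(idx, causal_idx)))
  calls <- sim$genotypes[, idx, drop = FALSE]
  calls[] <- c("A", "H", "B")[sim$genotypes[, idx, drop = FALSE] + 1L]
  info <- data.frame(marker = colnames(calls),
                     chrom = sim$truth$chrom[idx], bp = sim$truth$pos[idx],
                     causal = idx == causal_idx, stringsAsFactors = FALSE)
  list(calls = calls, info = info)
}

.finish_report <- function(report, config) {
  class(report) <- "pipeline_report"
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    slim <- report[setdiff(names(report), c("scan", "assoc"))]
    jsonlite::write_json(slim, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Staygreen mapping pipeline report (seed", x$seed, ")\n")
  for (s in names(x$stages)) cat(sprintf("  %-12s %s\n", s, x$stages[[s]]))
  if (!is.null(x$top_region))
    cat(sprintf("  top region : %s:%.0f-%.0f (%d SNPs)%s\n",
                x$top_region$chrom, x$top_region$start, x$top_region$end,
                x$top_region$n_members,
                if (isTRUE(x$causal_in_top_region)) " [contains causal]"
                else ""))
  if (!is.null(x$peak_marker))
    cat(sprintf("  peak marker: %s, inheritance %s\n", x$peak_marker,
                x$inheritance))
  invisible(x)
}
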