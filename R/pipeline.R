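## Orchestration: bins -> richness -> rates -> ASR -> colonization ->
## regressions -> hypothesis tally, for one or more climate variables.

.collect_warnings <- function(expr) {
  ws <- character(0)
  val <- withCallingHandlers(expr, warning = function(w) {
    ws <<- c(ws, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  list(value = val, warnings = ws)
}

.default_config <- function(config) {
  utils::modifyList(list(
    n_bins = c(map = 17, mat = 14),
    epsilon = 0.5,
    richness_source = "region",
    dr_exclude = NULL,
    asr_model = "LA",
    tip_mode = "range",
    alpha = 0.05
  ), config)
}

#' Analyze one climate variable through the full pipeline
#'
#' Runs the complete chain for a single variable: species climatic
#' summaries, bin construction, local/regional richness and area, DR-based
#' (and optionally clade-based method-of-moments) per-bin rates, phylogenetic
#' signal, trait-model selection, ancestral reconstruction, per-bin first
#' colonization times, and the regression battery (climate~richness linear
#' and quadratic with AIC comparison, rate~richness, time~richness).
#'
#' @param phy the species-level `"phylo"` object.
#' @param cells grid-cell table with `cell_id` and the column `var`.
#' @param occurrences species-by-cell table.
#' @param var climate column name in `cells` (e.g. `"map_mm"`).
#' @param n_bins number of bins for this variable.
#' @param config list of options (see [run_pipeline()]).
#' @param clades optional list with `records` and `membership` for
#'   method-of-moments clade rates.
#' @return a list with the intermediate tables (`summaries`, `bins`,
#'   `membership`, `rates`), the model results (`signal`, `model_fits`,
#'   `best_model`, `asr`), `colonization`, `time_richness`, the fitted
#'   regressions (`fits`), per-stage row `counts`, and collected `warnings`.
#' @export
analyze_variable <- function(phy, cells, occurrences, var, n_bins = 17,
                             config = list(), clades = NULL) {
  config <- .default_config(config)
  warnings <- character(0)
  note <- function(w) warnings <<- c(warnings, w)

  sw <- .collect_warnings(species_climate_summary(occurrences, cells, vars = var))
  summaries <- sw$value
  warnings <- c(warnings, sw$warnings)

  not_in_tree <- setdiff(summaries$species, phy$tip.label)
  no_climate <- setdiff(phy$tip.label, summaries$species)
  if (length(not_in_tree)) {
    note(paste0(length(not_in_tree), " species with occurrences absent from tree"))
  }
  if (length(no_climate)) {
    note(paste0(length(no_climate), " tree tips without occurrence data"))
  }

  bins <- make_bins(cells[[var]], n_bins = n_bins, variable = var)
  mw <- .collect_warnings(assign_species_to_bins(summaries, bins, var))
  membership <- mw$value
  warnings <- c(warnings, mw$warnings)
  bins <- bin_richness(bins, membership, cells, occurrences, var)

  dr <- dr_statistic(phy)
  rates <- list(dr = dr)
  bin_rates <- list(dr = bin_rate_summary(membership, dr,
                                          exclude_above = config$dr_exclude))
  if (!is.null(clades)) {
    for (eps in config$epsilon) {
      cw <- .collect_warnings(clade_rates(clades$records, clades$membership,
                                          epsilon = eps,
                                          richness_source = config$richness_source))
      warnings <- c(warnings, cw$warnings)
      key <- paste0("ms_eps", eps)
      rates[[key]] <- cw$value
      bin_rates[[key]] <- bin_rate_summary(membership, cw$value)
    }
  }

  # tree-based analyses on the tips with climate data
  with_clim <- intersect(phy$tip.label, summaries$species)
  signal <- model_fits <- best <- rec <- colonization <- NULL
  time_rich <- NULL
  if (length(with_clim) >= 4L) {
    sub <- if (length(with_clim) == length(phy$tip.label)) phy else {
      ape::keep.tip(phy, with_clim)
    }
    trait <- stats::setNames(
      summaries[[paste0("mean_", var)]][match(sub$tip.label, summaries$species)],
      sub$tip.label)
    signal <- pagel_lambda(sub, trait)
    model_fits <- list()
    for (m in c("BM", "LA", "OU", "WN")) {
      model_fits[[m]] <- tryCatch(fit_trait_model(sub, trait, m),
                                  error = function(e) NULL)
    }
    model_fits <- Filter(Negate(is.null), model_fits)
    if (length(model_fits) >= 2L) best <- best_model(model_fits)
    rec <- asr(sub, trait, model = config$asr_model)
    term <- match(seq_along(sub$tip.label), sub$edge[, 2])
    tipdf <- data.frame(
      tip = sub$tip.label,
      min = summaries[[paste0("min_", var)]][match(sub$tip.label, summaries$species)],
      max = summaries[[paste0("max_", var)]][match(sub$tip.label, summaries$species)],
      terminal = sub$edge.length[term],
      age = 0,
      stringsAsFactors = FALSE)
    colonization <- first_colonization_times(rec, tipdf, bins,
                                             tip_mode = config$tip_mode)
    tw <- .collect_warnings(time_richness_table(colonization, bins))
    time_rich <- tw$value
    warnings <- c(warnings, tw$warnings)
  } else {
    note("fewer than 4 tips with climate data; tree-based stages skipped")
  }

  fits <- list()
  mid <- bin_midpoints(bins)
  for (scale in c("local", "regional")) {
    richcol <- paste0(scale, "_richness")
    ok <- !is.na(bins[[richcol]])
    if (sum(ok) >= 4L) {
      lf <- linfit(mid[ok], bins[[richcol]][ok])
      qf <- quadfit(mid[ok], bins[[richcol]][ok])
      fits[[paste0("climate_", scale)]] <-
        list(linear = lf, quadratic = qf, comparison = compare_aic(lf, qf))
    }
    for (rk in names(bin_rates)) {
      br <- bin_rates[[rk]]
      m2 <- merge(data.frame(bin = seq_len(nrow(bins)),
                             richness = bins[[richcol]]),
                  br[, c("bin", "mean_rate", "median_rate")], by = "bin")
      for (agg in c("mean", "median")) {
        rr <- m2[[paste0(agg, "_rate")]]
        ok2 <- !is.na(rr) & !is.na(m2$richness)
        if (sum(ok2) >= 3L && stats::var(rr[ok2]) > 0) {
          fits[[paste0("rate_", rk, "_", agg, "_", scale)]] <-
            linfit(rr[ok2], m2$richness[ok2])
        }
      }
    }
    if (!is.null(time_rich) && nrow(time_rich) >= 3L &&
        sum(!is.na(time_rich[[richcol]])) >= 3L) {
      ok3 <- !is.na(time_rich[[richcol]])
      if (stats::var(time_rich$time[ok3]) > 0) {
        fits[[paste0("time_", scale)]] <-
          linfit(time_rich$time[ok3], time_rich[[richcol]][ok3])
      }
    }
  }

  list(variable = var,
       summaries = summaries,
       bins = bins,
       membership = membership,
       rates = rates,
       bin_rates = bin_rates,
       signal = signal,
       model_fits = model_fits,
       best_model = best,
       asr = rec,
       colonization = colonization,
       time_richness = time_rich,
       fits = fits,
       counts = list(n_species = nrow(summaries), n_cells = nrow(cells),
                     n_bins = nrow(bins), n_tips = length(phy$tip.label)),
       warnings = warnings)
}

#' Run the full analysis over all climate variables
#'
#' Deterministic given its inputs: loops [analyze_variable()] over the
#' supplied variables and assembles an analysis report. `data` is a named
#' list (one entry per variable, e.g. `"map"`, `"mat"`) whose entries carry
#' `cells`, `occurrences` and `value_col` -- exactly the shape produced by
#' [make_scenario()]. A single shared cell/occurrence table can be passed by
#' repeating it per variable with different `value_col`s.
#'
#' @param phy the species-level `"phylo"` object.
#' @param data named per-variable list (see above).
#' @param config list of options: `n_bins` (named vector, default
#'   `c(map = 17, mat = 14)`), `epsilon` (vector of relative extinction
#'   fractions, default 0.5), `richness_source` (`"region"`/`"global"`),
#'   `dr_exclude` (DR exclusion threshold, default none), `asr_model`
#'   (`"LA"`/`"BM"`), `tip_mode` (`"range"`/`"mean"`), `alpha`.
#' @param clades optional list with `records` and `membership` for
#'   method-of-moments rates.
#' @return object of class `"analysis_report"`: list with `variables` (one
#'   [analyze_variable()] result per variable), the echoed `config`, and
#'   pooled `warnings`.
#' @export
run_pipeline <- function(phy, data, config = list(), clades = NULL) {
  config <- .default_config(config)
  stopifnot(length(data) >= 1L, !is.null(names(data)))
  out <- list()
  for (v in names(data)) {
    d <- data[[v]]
    nb <- if (v %in% names(config$n_bins)) config$n_bins[[v]] else config$n_bins[[1]]
    out[[v]] <- tryCatch(
      analyze_variable(phy, d$cells, d$occurrences, var = d$value_col,
                       n_bins = nb, config = config, clades = clades),
      error = function(e) {
        stop("pipeline stage failed for variable '", v, "': ",
             conditionMessage(e), call. = FALSE)
      })
  }
  structure(list(variables = out, config = config,
                 warnings = unlist(lapply(out, `[[`, "warnings"),
                                   use.names = FALSE)),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Analysis report (", length(x$variables), " variable(s) )\n", sep = "")
  for (v in names(x$variables)) {
    av <- x$variables[[v]]
    cat("--", v, ":", av$counts$n_species, "species,",
        av$counts$n_bins, "bins\n")
    if (!is.null(av$signal)) {
      cat(sprintf("   lambda = %.3f (p[lambda=0] = %.3g)\n",
                  av$signal$lambda, av$signal$p))
    }
    for (nm in names(av$fits)) {
      f <- av$fits[[nm]]
      if (inherits(f, "reg_fit")) {
        cat(sprintf("   %-30s r2 = %.3f, p = %.3g, slope = %+.3g\n", nm,
                    f$r2, f$p, f$coefficients[["x"]]))
      } else {
        cat(sprintf("   %-30s r2 = %.3f, p = %.3g (%s preferred by AIC)\n",
                    paste0(nm, "_linear"), f$linear$r2, f$linear$p,
                    f$comparison$preferred))
      }
    }
  }
  invisible(x)
}

#' Per-clade pipeline runs for within-family replication
#'
#' Extracts each clade's subtree and species, re-runs [analyze_variable()]
#' inside it, and collects the time~richness and rate~richness regression
#' p-values and slopes -- the per-clade rows that [clade_tally()] counts.
#'
#' @param phy full tree.
#' @param membership data frame `tip`, `clade` defining the clades (e.g.
#'   families).
#' @param cells,occurrences,var as in [analyze_variable()].
#' @param n_bins bins built inside each clade over the same variable.
#' @param scale `"local"` or `"regional"` richness for the tally.
#' @param rate_key which rate summary to use (default `"dr"`).
#' @param config pipeline options.
#' @param min_tips clades with fewer tips in the tree are skipped.
#' @return data frame with one row per analyzed clade: `clade`, `n_tips`,
#'   `p_time`, `slope_time`, `p_rate`, `slope_rate` (NA where a fit was not
#'   estimable).
#' @export
analyze_subclades <- function(phy, membership, cells, occurrences, var,
                              n_bins = 10, scale = "local", rate_key = "dr",
                              config = list(), min_tips = 10) {
  clades <- unique(membership$clade)
  rows <- list()
  for (cl in clades) {
    tips <- intersect(membership$tip[membership$clade == cl], phy$tip.label)
    if (length(tips) < min_tips) next
    sub <- ape::keep.tip(phy, tips)
    occ <- occurrences[occurrences$species %in% tips, , drop = FALSE]
    if (!nrow(occ)) next
    av <- suppressWarnings(
      analyze_variable(sub, cells, occ, var = var, n_bins = n_bins,
                       config = config))
    ft <- av$fits[[paste0("time_", scale)]]
    fr <- av$fits[[paste0("rate_", rate_key, "_mean_", scale)]]
    rows[[cl]] <- data.frame(
      clade = cl, n_tips = length(tips),
      p_time = if (is.null(ft)) NA_real_ else ft$p,
      slope_time = if (is.null(ft)) NA_real_ else ft$coefficients[["x"]],
      p_rate = if (is.null(fr)) NA_real_ else fr$p,
      slope_rate = if (is.null(fr)) NA_real_ else fr$coefficients[["x"]],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tally which hypothesis each clade supports
#'
#' Classifies each clade into four mutually exclusive categories from the
#' p-values of its time~richness and rate~richness regressions: time not
#' rate, rate not time, both, neither. The default classification follows
#' the raw `p < alpha` rule (sign-agnostic); a second tally requiring a
#' positive slope for "support" is reported alongside. Clades missing either
#' p-value are dropped and counted.
#'
#' @param reports data frame with columns `clade`, `p_time`, `p_rate` and
#'   (for the signed tally) `slope_time`, `slope_rate`.
#' @param alpha significance level.
#' @return list with `counts` and `signed_counts` (named integer vectors
#'   over `time_not_rate`, `rate_not_time`, `both`, `neither`), `n` clades
#'   tallied, and `n_dropped`.
#' @export
clade_tally <- function(reports, alpha = 0.05) {
  ok <- !is.na(reports$p_time) & !is.na(reports$p_rate)
  r <- reports[ok, , drop = FALSE]
  tally <- function(sig_t, sig_r) {
    c(time_not_rate = sum(sig_t & !sig_r),
      rate_not_time = sum(!sig_t & sig_r),
      both = sum(sig_t & sig_r),
      neither = sum(!sig_t & !sig_r))
  }
  sig_t <- r$p_time < alpha
  sig_r <- r$p_rate < alpha
  counts <- tally(sig_t, sig_r)
  signed <- if (all(c("slope_time", "slope_rate") %in% names(r))) {
    tally(sig_t & r$slope_time > 0, sig_r & r$slope_rate > 0)
  } else NULL
  list(counts = counts, signed_counts = signed, n = nrow(r),
       n_dropped = sum(!ok))
}

#' Write the analysis report's tables to disk
#'
#' Writes, per variable, the bin report (richness, area, rates,
#' colonization time merged in) and the colonization records as CSV, and a
#' JSON summary of the regression fits, signal and model selection.
#'
#' @param report an `"analysis_report"`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_analysis_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  js <- list(config = report$config, variables = list())
  for (v in names(report$variables)) {
    av <- report$variables[[v]]
    bins <- as.data.frame(av$bins)
    if (!is.null(av$colonization)) {
      bins$colonization_time <- av$colonization$time
    }
    utils::write.csv(bins, file.path(dir, paste0("bins_", v, ".csv")),
                     row.names = FALSE)
    if (!is.null(av$colonization)) {
      write_colonization(av$colonization,
                         file.path(dir, paste0("colonization_", v, ".csv")))
    }
    utils::write.csv(av$rates$dr, file.path(dir, paste0("rates_dr_", v, ".csv")),
                     row.names = FALSE)
    fits <- lapply(av$fits, function(f) {
      if (inherits(f, "reg_fit")) {
        list(kind = f$kind, coefficients = as.list(f$coefficients), r2 = f$r2,
             p = f$p, AIC = f$AIC, n = f$n)
      } else {
        list(linear = list(r2 = f$linear$r2, p = f$linear$p, AIC = f$linear$AIC),
             quadratic = list(r2 = f$quadratic$r2, p = f$quadratic$p,
                              AIC = f$quadratic$AIC),
             preferred = f$comparison$preferred)
      }
    })
    js$variables[[v]] <- list(
      fits = fits,
      signal = if (!is.null(av$signal)) {
        list(lambda = av$signal$lambda, LRT = av$signal$LRT, p = av$signal$p)
      },
      best_model = if (!is.null(av$best_model)) av$best_model$best,
      warnings = av$warnings)
  }
  jsonlite::write_json(js, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(dir)
}
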