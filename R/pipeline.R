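# one exposure table against one outcome table: select instruments,
# harmonize, fit; the workhorse behind screen_layer and the mediation legs
fit_edge <- function(exposure_stats, outcome_stats, panel = NULL,
                     criteria = instrument_criteria(),
                     methods = c("ivw", "egger", "weighted_median",
                                 "simple_mode", "weighted_mode"),
                     n_boot = 1000, seed = 1L,
                     exposure = NULL, outcome = NULL) {
  sel <- select_instruments(exposure_stats, panel, criteria)
  if (length(sel$selected) == 0)
    return(list(status = "untestable", reason = "no_instruments",
                selection = sel, exposure = exposure, outcome = outcome))
  exp_sub <- exposure_stats[exposure_stats$snp_id %in% sel$selected, ,
                            drop = FALSE]
  pairs <- suppressWarnings(harmonize(exp_sub, outcome_stats))
  usable <- usable_pairs(pairs)
  if (nrow(usable) == 0)
    return(list(status = "untestable", reason = "no_overlapping_snps",
                selection = sel, pairs = pairs,
                exposure = exposure, outcome = outcome))
  fit <- mr_fit(usable, methods = methods, n_boot = n_boot, seed = seed,
                exposure = exposure, outcome = outcome)
  list(status = "tested", selection = sel, pairs = pairs, fit = fit,
       exposure = exposure, outcome = outcome)
}

ivw_of <- function(edge) {
  e <- edge$fit$estimates
  e[e$method == "ivw", , drop = FALSE]
}

#' Screen a layer of exposures against one outcome
#'
#' For every exposure table: select instruments, harmonize against the
#' outcome, fit the five MR estimators and run the full sensitivity
#' suite. An edge passes when the IVW p-value is below `significance`,
#' the sensitivity gate is satisfied, and the Steiger direction is TRUE.
#' Exposures with zero surviving instruments (or no overlapping
#' variants) are reported as untestable, never silently skipped.
#'
#' @param exposures Named list of summary-statistics data frames.
#' @param outcome Outcome summary-statistics data frame.
#' @param panel Optional [ld_panel()].
#' @param criteria [instrument_criteria()].
#' @param gate [gate_config()].
#' @param significance IVW p threshold for "significantly associated"
#'   (default 0.05).
#' @param n_boot Bootstrap resamples for the median/mode estimators.
#' @param presso_n_sim MR-PRESSO simulations.
#' @param seed Integer seed (fanned out per exposure).
#' @param methods Estimators fitted per edge (all five by default).
#' @return Object of class `mr_layer`: list with `edges` (per-exposure
#'   records: `status`, `fit`, `sensitivity`, `passed_gate`, `passed`)
#'   and `summary` (one row per exposure).
#' @export
screen_layer <- function(exposures, outcome, panel = NULL,
                         criteria = instrument_criteria(),
                         gate = gate_config(), significance = 0.05,
                         n_boot = 1000, presso_n_sim = 1000, seed = 1L,
                         methods = c("ivw", "egger", "weighted_median",
                                     "simple_mode", "weighted_mode")) {
  if (is.null(names(exposures)) || any(names(exposures) == ""))
    names(exposures) <- sprintf("exposure_%d", seq_along(exposures))
  nm <- sort(names(exposures))  # order-invariant output
  edges <- list()
  for (i in seq_along(nm)) {
    ed <- fit_edge(exposures[[nm[i]]], outcome, panel, criteria,
                   methods = methods, n_boot = n_boot,
                   seed = child_seed(seed, i),
                   exposure = nm[i], outcome = "outcome")
    if (ed$status == "tested") {
      ivw <- ivw_of(ed)
      sens <- mr_sensitivity(ed$fit, presso_n_sim = presso_n_sim,
                             presso_seed = child_seed(seed, i),
                             run_presso = gate$presso)
      ed$sensitivity <- sens
      ed$ivw_p <- ivw$pval
      ed$ivw_beta <- ivw$beta
      ed$passed_gate <- sensitivity_gate(sens, gate,
                                         ivw_model = ed$fit$ivw_model,
                                         ivw_beta = ivw$beta)
      ed$passed <- ed$ivw_p < significance && ed$passed_gate &&
        isTRUE(sens$steiger$direction)
    } else {
      ed$passed_gate <- NA
      ed$passed <- FALSE
      ed$ivw_p <- NA_real_
      ed$ivw_beta <- NA_real_
    }
    edges[[nm[i]]] <- ed
  }
  summary <- do.call(rbind, lapply(edges, function(e)
    data.frame(exposure = e$exposure, status = e$status,
               nsnp = if (e$status == "tested") e$fit$nsnp else 0L,
               ivw_beta = e$ivw_beta, ivw_p = e$ivw_p,
               passed_gate = e$passed_gate, passed = e$passed,
               stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  structure(list(edges = edges, summary = summary, gate = gate,
                 significance = significance), class = "mr_layer")
}

#' @export
print.mr_layer <- function(x, ...) {
  cat("MR layer screen:", nrow(x$summary), "exposures;",
      sum(x$summary$passed), "passed,",
      sum(x$summary$status != "tested"), "untestable\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# IVW beta/se for one mediation leg (exposure table -> outcome table)
leg_ivw <- function(exposure_stats, outcome_stats, panel, criteria, seed) {
  ed <- fit_edge(exposure_stats, outcome_stats, panel, criteria,
                 methods = "ivw", seed = seed)
  if (ed$status != "tested") return(NULL)
  ivw_of(ed)
}

#' Discover regulatory axes by combined upstream and downstream mediation
#'
#' Implements the three-layer screening strategy: (1) screen upstream
#' proteins, downstream proteins and metabolites against the outcome;
#' (2) for every upstream/downstream pair where both pass, run the
#' two-step upstream mediation (beta_all = upstream -> outcome, beta1 =
#' upstream -> downstream, beta2 = downstream -> outcome, all IVW) and
#' screen it; (3) for survivors, run the downstream mediation through
#' each passing metabolite (beta1 = downstream protein -> metabolite,
#' beta2 = metabolite -> outcome) and screen. An axis is retained only
#' when its upstream mediation passes AND at least one downstream
#' metabolite mediation passes - pairs lacking a downstream mechanism
#' are excluded.
#'
#' @param upstream,downstream,metabolites Named lists of
#'   summary-statistics data frames.
#' @param outcome Outcome summary-statistics data frame.
#' @param panel Optional [ld_panel()].
#' @param criteria [instrument_criteria()].
#' @param gate [gate_config()].
#' @param significance Layer IVW p threshold.
#' @param p_max,proportion_min Mediation screen thresholds (defaults
#'   0.05 and 0.15).
#' @param n_boot,presso_n_sim,seed Simulation settings.
#' @param methods Estimators fitted per layer edge.
#' @return Object of class `mr_axes`: list with `axes` (each holding
#'   `upstream_mediation` and the screened `downstream_mediations`),
#'   `layers`, `candidates` (all upstream mediations tried) and
#'   `report` (per-stage counts for provenance).
#' @export
discover_axes <- function(upstream, downstream, metabolites, outcome,
                          panel = NULL, criteria = instrument_criteria(),
                          gate = gate_config(), significance = 0.05,
                          p_max = 0.05, proportion_min = 0.15,
                          n_boot = 1000, presso_n_sim = 1000, seed = 1L,
                          methods = c("ivw", "egger", "weighted_median",
                                      "simple_mode", "weighted_mode")) {
  up_layer <- screen_layer(upstream, outcome, panel, criteria, gate,
                           significance, n_boot, presso_n_sim,
                           child_seed(seed, 101L), methods = methods)
  down_layer <- screen_layer(downstream, outcome, panel, criteria, gate,
                             significance, n_boot, presso_n_sim,
                             child_seed(seed, 102L), methods = methods)
  met_layer <- screen_layer(metabolites, outcome, panel, criteria, gate,
                            significance, n_boot, presso_n_sim,
                            child_seed(seed, 103L), methods = methods)
  up_pass <- names(which(vapply(up_layer$edges, function(e)
    isTRUE(e$passed), logical(1))))
  down_pass <- names(which(vapply(down_layer$edges, function(e)
    isTRUE(e$passed), logical(1))))
  met_pass <- names(which(vapply(met_layer$edges, function(e)
    isTRUE(e$passed), logical(1))))

  candidates <- list()
  axes <- list()
  kk <- 0L
  for (u in up_pass) {
    for (d in down_pass) {
      kk <- kk + 1L
      b_all <- ivw_of(up_layer$edges[[u]])
      b2 <- ivw_of(down_layer$edges[[d]])
      b1 <- leg_ivw(upstream[[u]], downstream[[d]], panel, criteria,
                    child_seed(seed, 200L + kk))
      if (is.null(b1)) next
      med <- mr_mediation(b_all$beta, b_all$se, b1$beta, b1$se,
                          b2$beta, b2$se,
                          exposure = u, mediator = d, outcome = "outcome")
      candidates[[length(candidates) + 1L]] <- med
      if (nrow(screen_mediators(med, p_max, proportion_min)) == 0) next
      # downstream mechanism: metabolite mediations of the d -> outcome leg
      down_meds <- list()
      for (mt in met_pass) {
        kk <- kk + 1L
        mb2 <- ivw_of(met_layer$edges[[mt]])
        mb1 <- leg_ivw(downstream[[d]], metabolites[[mt]], panel, criteria,
                       child_seed(seed, 200L + kk))
        if (is.null(mb1)) next
        dm <- mr_mediation(b2$beta, b2$se, mb1$beta, mb1$se,
                           mb2$beta, mb2$se,
                           exposure = d, mediator = mt,
                           outcome = "outcome")
        if (nrow(screen_mediators(dm, p_max, proportion_min)) > 0)
          down_meds[[length(down_meds) + 1L]] <- dm
      }
      if (length(down_meds) > 0)
        axes[[length(axes) + 1L]] <- list(
          upstream_id = u, mediator_id = d, outcome_id = "outcome",
          upstream_mediation = med,
          downstream_mediations = do.call(rbind, down_meds))
    }
  }
  report <- list(
    n_upstream = length(upstream), n_upstream_passed = length(up_pass),
    n_downstream = length(downstream),
    n_downstream_passed = length(down_pass),
    n_metabolites = length(metabolites),
    n_metabolites_passed = length(met_pass),
    n_candidate_pairs = length(candidates),
    n_axes = length(axes),
    thresholds = list(significance = significance, p_max = p_max,
                      proportion_min = proportion_min,
                      criteria = unclass(criteria), gate = unclass(gate)),
    version = as.character(utils::packageVersion("mraxis")))
  structure(list(axes = axes,
                 layers = list(upstream = up_layer, downstream = down_layer,
                               metabolites = met_layer),
                 candidates = if (length(candidates))
                   do.call(rbind, candidates) else NULL,
                 report = report),
            class = "mr_axes")
}

#' @export
print.mr_axes <- function(x, ...) {
  r <- x$report
  cat("Regulatory-axis discovery\n")
  cat(sprintf("  layers passed: upstream %d/%d, downstream %d/%d, metabolites %d/%d\n",
              r$n_upstream_passed, r$n_upstream, r$n_downstream_passed,
              r$n_downstream, r$n_metabolites_passed, r$n_metabolites))
  cat(sprintf("  axes retained: %d\n", r$n_axes))
  for (a in x$axes) {
    cat(sprintf("  %s -> %s -> outcome (upstream proportion %.1f%%; %d metabolite mediator(s))\n",
                a$upstream_id, a$mediator_id,
                100 * a$upstream_mediation$proportion,
                nrow(a$downstream_mediations)))
  }
  invisible(x)
}

#' Write pipeline outputs
#'
#' Emits the Table-1-shaped estimates TSV, the Table-2-shaped
#' sensitivity TSV, the axes TSV and a JSON run report into a directory.
#'
#' @param axes An `mr_axes` object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_axes_output <- function(axes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  est_rows <- list()
  sens <- list()
  for (lname in names(axes$layers)) {
    layer <- axes$layers[[lname]]
    for (e in layer$edges) {
      if (e$status != "tested") next
      est <- e$fit$estimates
      est_rows[[length(est_rows) + 1L]] <-
        cbind(data.frame(exposure = e$exposure, outcome = e$outcome,
                         layer = lname, stringsAsFactors = FALSE),
              est[, c("method", "nsnp", "pval", "beta", "or",
                      "or_ci_low", "or_ci_high")])
      sens[[paste(lname, e$exposure, sep = ":")]] <- e$sensitivity
    }
  }
  write.table(do.call(rbind, est_rows), file.path(dir, "estimates.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_sensitivity_table(sens, file.path(dir, "sensitivity.tsv"))
  if (length(axes$axes)) {
    ax <- do.call(rbind, lapply(axes$axes, function(a) {
      m <- a$upstream_mediation
      data.frame(upstream = a$upstream_id, mediator = a$mediator_id,
                 beta_all = m$beta_all, beta1 = m$beta1, beta2 = m$beta2,
                 proportion = sprintf("%.1f%%", 100 * m$proportion),
                 p = m$p12,
                 metabolite_mediators =
                   paste(a$downstream_mediations$mediator_id,
                         collapse = ","),
                 stringsAsFactors = FALSE)
    }))
    write.table(ax, file.path(dir, "axes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(axes$candidates))
    write_mediation_table(axes$candidates,
                          file.path(dir, "mediation_candidates.tsv"))
  writeLines(jsonlite::toJSON(axes$report, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(dir, "run_report.json"))
  invisible(dir)
}
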