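#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end analysis with the study's
#' canonical defaults: 20% edge density, 20% hub fraction, 100-network null
#' ensembles, 100 permutations in the motion test, alpha = 0.05.
#'
#' @param design a [cohort_design()] used to simulate each condition.
#' @param parcellation a `parcellation`, or `NULL` for the packaged
#'   258-node stand-in.
#' @param conditions character vector of condition labels; each is an
#'   independent simulation pass sharing the group assignment.
#' @param filter a [filter_spec()].
#' @param density proportional threshold density.
#' @param hub_fraction hub fraction.
#' @param n_null null-ensemble size per subject (0 skips normalisation).
#' @param n_perm permutations in the motion QC test.
#' @param motion_scalar subject-level motion scalar for QC.
#' @param mean_mode whole-brain connectivity mode (see
#'   [mean_connectivity()]).
#' @param alpha significance level for pattern classification.
#' @param compare_lowpass additionally run the pipeline without the
#'   low-pass filter and report both result sets side by side.
#' @param seed master seed; every random stage derives its own seed from it
#'   via [stage_seed()].
#' @param output_dir directory for TSV/JSON outputs, or `NULL` to skip
#'   writing.
#' @return a `run_config` list.
#' @export
run_config <- function(design = cohort_design(), parcellation = NULL,
                       conditions = "rest", filter = filter_spec(),
                       density = 0.2, hub_fraction = 0.2, n_null = 100,
                       n_perm = 100, motion_scalar = "max_fd",
                       mean_mode = "retained", alpha = 0.05,
                       compare_lowpass = FALSE, seed = 1,
                       output_dir = NULL) {
  structure(list(design = design, parcellation = parcellation,
                 conditions = conditions, filter = filter, density = density,
                 hub_fraction = hub_fraction, n_null = n_null,
                 n_perm = n_perm, motion_scalar = motion_scalar,
                 mean_mode = mean_mode, alpha = alpha,
                 compare_lowpass = compare_lowpass, seed = seed,
                 output_dir = output_dir),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Top-level keys mirror the arguments of [run_config()]; `design`,
#' `design$motion` and `filter` are nested maps passed to
#' [cohort_design()], [motion_design()] and [filter_spec()].  A YAML
#' `lowpass_hz: null` disables the low-pass.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- raw
  if (!is.null(raw$design)) {
    d <- raw$design
    if (!is.null(d$motion)) d$motion <- do.call(motion_design, d$motion)
    if (!is.null(d$global_coupling)) d$global_coupling <- unlist(d$global_coupling)
    args$design <- do.call(cohort_design, d)
  }
  if (!is.null(raw$filter)) args$filter <- do.call(filter_spec, raw$filter)
  if (!is.null(raw$parcellation))
    args$parcellation <- read_parcellation(raw$parcellation)
  do.call(run_config, args)
}

#' Per-subject network metrics for one preprocessed cohort
#'
#' Thresholds each subject's correlation matrix, computes whole-brain
#' connectivity, raw and null-normalised clustering and efficiency, node
#' strengths, hub counts per analyzed network, intra/inter-network block
#' weights, and the node disruption index against the control-group
#' template.
#'
#' @param cohort a (preprocessed) `cohort`.
#' @param density,hub_fraction,n_null,mean_mode see [run_config()].
#' @param seed master seed for the per-subject null ensembles.
#' @param ndi_template group whose average strengths form the NDI template
#'   (default `"CON"`).
#' @return list with `table` (one row per subject), `strengths` (`S x N`),
#'   `fc_stack` (`S x M` unthresholded edge stack), `networks` (list of
#'   `weighted_network`).
#' @export
compute_subject_metrics <- function(cohort, density = 0.2,
                                    hub_fraction = 0.2, n_null = 100,
                                    mean_mode = "retained", seed = 1,
                                    ndi_template = "CON") {
  stopifnot(inherits(cohort, "cohort"))
  parc <- cohort$parcellation
  n <- nrow(parc)
  m <- n * (n - 1) / 2
  subs <- cohort$subjects
  s_count <- length(subs)

  fc_stack <- matrix(NA_real_, s_count, m)
  strengths <- matrix(NA_real_, s_count, n)
  networks <- vector("list", s_count)
  rows <- vector("list", s_count)
  for (i in seq_len(s_count)) {
    sub <- subs[[i]]
    fc <- correlation_matrix(sub$timeseries)
    fc_stack[i, ] <- upper_tri_values(fc)
    net <- proportional_threshold(fc, density)
    networks[[i]] <- net
    strengths[i, ] <- node_strengths(net)

    c_raw <- clustering_coefficient(net)
    e_raw <- global_efficiency(net)
    c_norm <- e_norm <- NA_real_
    if (n_null > 0) {
      ens <- null_ensemble(net, n = n_null,
                           seed = stage_seed(seed, paste0("null_", sub$subject_id)))
      c_norm <- normalize_metric(clustering_coefficient, net, ens)$normalized
      e_norm <- normalize_metric(global_efficiency, net, ens)$normalized
    }
    hubs <- identify_hubs(strengths[i, ], parc, hub_fraction)
    blocks <- network_block_weights(net, parc)
    row <- data.frame(subject_id = sub$subject_id, group = sub$group,
                      condition = sub$condition,
                      mean_connectivity = mean_connectivity(net, mean_mode),
                      C_raw = c_raw, C_norm = c_norm,
                      E_raw = e_raw, E_norm = e_norm)
    hub_cols <- setNames(as.list(hubs$counts),
                         paste0("hubs_", names(hubs$counts)))
    intra_cols <- setNames(as.list(blocks$intra),
                           paste0("intra_", blocks$network))
    inter_cols <- setNames(as.list(blocks$inter),
                           paste0("inter_", blocks$network))
    rows[[i]] <- cbind(row, as.data.frame(hub_cols),
                       as.data.frame(intra_cols), as.data.frame(inter_cols))
  }
  table <- do.call(rbind, rows)

  groups <- table$group
  tmpl_rows <- which(groups == ndi_template)
  if (length(tmpl_rows) >= 2) {
    tmpl <- group_template(strengths[tmpl_rows, , drop = FALSE])
    table$ndi <- vapply(seq_len(s_count), function(i)
      node_disruption_index(strengths[i, ], tmpl, ndi_template)$slope,
      numeric(1))
  } else {
    table$ndi <- NA_real_
  }
  list(table = table, strengths = strengths, fc_stack = fc_stack,
       networks = networks)
}

# One group-statistics row for a metric column.
metric_group_stats <- function(values, groups, metric, alpha = 0.05) {
  sample <- split(values, groups)[c("CON", "SIB", "ASC")]
  pat <- endophenotype_pattern(sample, alpha)
  data.frame(metric = metric,
             F = pat$anova$F, df_between = pat$anova$df_between,
             df_within = pat$anova$df_within, p = pat$anova$p,
             t_ASC_CON = pat$t_asc_con$t, p_ASC_CON = pat$t_asc_con$p,
             t_SIB_CON = pat$t_sib_con$t, p_SIB_CON = pat$t_sib_con$p,
             mean_CON = pat$means["CON"], mean_SIB = pat$means["SIB"],
             mean_ASC = pat$means["ASC"], pattern = pat$pattern,
             row.names = NULL)
}

#' Group statistics table for a metrics table
#'
#' Runs the three-group ANOVA, planned t-tests and pattern classification
#' for each requested metric column.  No multiple-comparison correction is
#' applied; the number of tests performed is recorded in the
#' `"n_tests"` attribute.
#'
#' @param table per-subject metrics table (see
#'   [compute_subject_metrics()]).
#' @param metrics columns to test (defaults to the global metrics plus all
#'   hub-count columns).
#' @param alpha significance level.
#' @return data frame, one row per metric.
#' @export
group_stats_table <- function(table, metrics = NULL, alpha = 0.05) {
  if (is.null(metrics)) {
    metrics <- intersect(c("mean_connectivity", "C_raw", "C_norm",
                           "E_raw", "E_norm", "ndi"), names(table))
    metrics <- c(metrics, grep("^hubs_", names(table), value = TRUE))
  }
  metrics <- metrics[vapply(metrics, function(mm) !anyNA(table[[mm]]),
                            logical(1))]
  out <- do.call(rbind, lapply(metrics, function(mm)
    metric_group_stats(table[[mm]], table$group, mm, alpha)))
  attr(out, "n_tests") <- 3L * length(metrics)
  out
}

#' Run the full analysis pipeline
#'
#' simulate -> preprocess -> connectivity -> graph metrics -> motion QC ->
#' group statistics, per condition, from one configuration.  Every random
#' stage consumes a seed derived deterministically from the master seed and
#' the stage name, so identical configurations give identical reports.
#' When the filter has a low-pass and `compare_lowpass = TRUE`, a paired
#' pass without the low-pass runs on the same cohorts and both result sets
#' are reported side by side.
#'
#' @param config a [run_config()].
#' @param cohorts optional named list of pre-generated cohorts (one per
#'   condition); supplied cohorts skip simulation, so cached runs reproduce
#'   downstream results exactly.
#' @return a `pipeline_report` list: `config` (fully resolved), per
#'   condition the subject metrics table, group statistics, QC results, and
#'   (optionally) `collapsed` and `no_lowpass` sections.  Written to
#'   `config$output_dir` as TSV + JSON when set.
#' @export
run_pipeline <- function(config = run_config(), cohorts = NULL) {
  stopifnot(inherits(config, "run_config"))
  parc <- config$parcellation %||% load_packaged_parcellation()

  run_pass <- function(filter) {
    conds <- list()
    for (cond in config$conditions) {
      cohort <- cohorts[[cond]] %||% {
        d <- config$design
        d$condition <- cond
        d$seed <- stage_seed(config$seed, paste0("cohort_", cond))
        generate_cohort(parc, d)
      }
      pre <- preprocess_cohort(cohort, filter)
      met <- compute_subject_metrics(
        pre, density = config$density, hub_fraction = config$hub_fraction,
        n_null = config$n_null, mean_mode = config$mean_mode,
        seed = stage_seed(config$seed, paste0("metrics_", cond)))
      qc <- motion_qc(cohort, fc_stack = met$fc_stack,
                      scalar = config$motion_scalar, n_perm = config$n_perm,
                      seed = stage_seed(config$seed, paste0("qc_", cond)))
      stats <- group_stats_table(met$table, alpha = config$alpha)
      conds[[cond]] <- list(metrics = met$table, stats = stats,
                            qc = list(subjects = qc$subjects,
                                      scalar = qc$scalar,
                                      mean_r = qc$test$mean_r,
                                      slope = qc$test$slope,
                                      p_mean = qc$test$p_mean,
                                      p_slope = qc$test$p_slope,
                                      moving_average = data.frame(
                                        distance = qc$profile$distance,
                                        moving_average = qc$profile$moving_average)))
    }
    collapsed <- NULL
    if (length(config$conditions) > 1) {
      mats <- vapply(conds, function(cc) cc$metrics$mean_connectivity,
                     numeric(nrow(conds[[1]]$metrics)))
      collapsed_vals <- rowMeans(mats)
      collapsed <- list(
        stats = metric_group_stats(collapsed_vals,
                                   conds[[1]]$metrics$group,
                                   "mean_connectivity_collapsed",
                                   config$alpha),
        condition_correlation = condition_correlation(mats))
    }
    list(conditions = conds, collapsed = collapsed)
  }

  report <- run_pass(config$filter)
  if (isTRUE(config$compare_lowpass) && !is.null(config$filter$lowpass_hz)) {
    no_lp <- config$filter
    no_lp$lowpass_hz <- NULL
    report$no_lowpass <- run_pass(no_lp)
  }
  report$config <- config
  class(report) <- "pipeline_report"
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' Write a pipeline report to disk
#'
#' Per condition: the subject metrics table and group-statistics table as
#' TSV and the QC moving-average curve as TSV; the whole report (minus the
#' bulky tables, which the TSVs hold) as `report.json`, including the fully
#' resolved configuration.
#'
#' @param report a `pipeline_report`.
#' @param dir output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cond in names(report$conditions)) {
    cc <- report$conditions[[cond]]
    write.table(cc$metrics, file.path(dir, paste0("metrics_", cond, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(cc$stats, file.path(dir, paste0("stats_", cond, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(cc$qc$moving_average,
                file.path(dir, paste0("qc_profile_", cond, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  slim <- report
  slim$config$parcellation <- NULL
  for (cond in names(slim$conditions)) {
    slim$conditions[[cond]]$metrics <- NULL
    slim$conditions[[cond]]$qc$moving_average <- NULL
  }
  jsonlite::write_json(unclass_recursive(slim),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE, na = "null")
  invisible(dir)
}

unclass_recursive <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) {
    x <- lapply(x, unclass_recursive)
    attributes(x) <- list(names = names(x))
  }
  x
}
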