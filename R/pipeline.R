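#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. In
#' `simulate` mode the design/effects and a master seed define the synthetic
#' study; in `load` mode `paths` must name existing delimited-text inputs
#' (`fish`, `cortisol`, and either `curves` or `expression`; optionally
#' `behavior` and `resolution`).
#'
#' @param mode `"simulate"` or `"load"`.
#' @param out_dir base directory under which one fresh run directory is
#'   created per invocation.
#' @param seed master seed (mandatory in simulate mode and whenever QAP runs
#'   in Monte-Carlo mode).
#' @param design,effects simulate-mode generative settings.
#' @param behavior_params,cortisol_params,kinetics simulate-mode parameter
#'   lists.
#' @param paths named list of input files (load mode).
#' @param alpha significance level used throughout.
#' @param n_perm QAP permutation count.
#' @param log_scale analyze expression on the log scale.
#' @param qap_alternative `"greater"` or `"two_sided"`.
#' @param use_curves quantify from raw curves (`TRUE`) or take the
#'   expression table directly (`FALSE`; simulate mode then uses the latent
#'   truth, load mode requires `paths$expression`).
#' @param heatmaps write heatmap images.
#' @param run_name optional fixed name for the run directory.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "load"), out_dir, seed = NULL,
                            design = study_design(),
                            effects = default_effects(design),
                            behavior_params = default_behavior_params(),
                            cortisol_params = default_cortisol_params(),
                            kinetics = default_kinetics(design$genes,
                                                        design$reference_gene),
                            paths = NULL, alpha = 0.05, n_perm = 5000,
                            log_scale = TRUE, qap_alternative = "greater",
                            use_curves = TRUE, heatmaps = FALSE,
                            run_name = NULL) {
  mode <- match.arg(mode)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (mode == "simulate" && is.null(seed))
    stop("simulate mode requires a master seed")
  if (mode == "load") {
    if (is.null(paths$fish) || is.null(paths$cortisol))
      stop("load mode requires paths$fish and paths$cortisol")
    if (is.null(paths$curves) && is.null(paths$expression))
      stop("load mode requires paths$curves or paths$expression")
  }
  structure(list(mode = mode, out_dir = out_dir, seed = seed,
                 design = design, effects = effects,
                 behavior_params = behavior_params,
                 cortisol_params = cortisol_params, kinetics = kinetics,
                 paths = paths, alpha = alpha, n_perm = n_perm,
                 log_scale = log_scale, qap_alternative = qap_alternative,
                 use_curves = use_curves, heatmaps = heatmaps,
                 run_name = run_name),
            class = "pipeline_config")
}

required_columns <- list(
  fish = c("fish_id", "dyad_id", "treatment"),
  behavior = c("fish_id", "time_s", "behavior"),
  resolution = c("dyad_id", "resolution_time_s"),
  cortisol = c("fish_id", "treatment", "cortisol_ng_ml"),
  curves = c("reaction_id", "fish_id", "nucleus", "gene", "cycle",
             "fluorescence"),
  expression = c("fish_id", "dyad_id", "treatment", "nucleus", "gene",
                 "relative_expression"))

read_input_table <- function(path, what) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required_columns[[what]], names(df))
  if (length(missing))
    stop("file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  df
}

#' Validate a set of input tables
#'
#' Schema, range and referential checks on delimited-text inputs: required
#' columns present, numeric columns numeric and in range (non-negative
#' fluorescence, positive expression, event times within a session),
#' every expression/cortisol fish present in the fish table, and
#' winner/loser dyads complete (or explicitly flagged as dropout).
#'
#' @param paths named list of file paths (any subset of `fish`, `behavior`,
#'   `resolution`, `cortisol`, `curves`, `expression`).
#' @return data frame report with columns `file`, `severity`
#'   (`error`/`warning`), `message`; zero rows when everything is clean.
#' @export
validate_tables <- function(paths) {
  report <- list()
  note <- function(file, severity, message)
    report[[length(report) + 1]] <<- data.frame(file = file,
                                                severity = severity,
                                                message = message)
  tabs <- list()
  for (what in names(paths)) {
    path <- paths[[what]]
    if (!file.exists(path)) {
      note(path, "error", "file not found")
      next
    }
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    missing <- setdiff(required_columns[[what]] %||% character(0), names(df))
    if (length(missing)) {
      note(path, "error", paste("missing column(s):",
                                paste(missing, collapse = ", ")))
      next
    }
    tabs[[what]] <- df
  }
  if (!is.null(tabs$curves) && any(tabs$curves$fluorescence < 0))
    note(paths$curves, "warning", "negative fluorescence values")
  if (!is.null(tabs$expression) &&
      any(tabs$expression$relative_expression <= 0))
    note(paths$expression, "error", "non-positive relative_expression")
  if (!is.null(tabs$cortisol) && any(tabs$cortisol$cortisol_ng_ml < 0))
    note(paths$cortisol, "error", "negative cortisol")
  if (!is.null(tabs$fish)) {
    if (anyDuplicated(tabs$fish$fish_id))
      note(paths$fish, "error", "duplicate fish_id")
    w <- tabs$fish[tabs$fish$treatment == "winner", ]
    l <- tabs$fish[tabs$fish$treatment == "loser", ]
    unpaired <- setdiff(w$dyad_id, l$dyad_id)
    flagged <- if ("partner_dropout" %in% names(tabs$fish))
      w$dyad_id[w$partner_dropout] else character(0)
    bad <- setdiff(unpaired, flagged)
    if (length(bad))
      note(paths$fish, "error",
           paste("winner dyad(s) without loser partner (and not flagged",
                 "as dropout):", paste(bad, collapse = ", ")))
    for (what in intersect(c("expression", "cortisol", "behavior"),
                           names(tabs))) {
      orphan <- setdiff(tabs[[what]]$fish_id, tabs$fish$fish_id)
      if (length(orphan))
        note(paths[[what]], "error",
             paste("fish_id not in fish table:",
                   paste(utils::head(orphan, 5), collapse = ", ")))
    }
    if (!is.null(tabs$expression)) {
      orphan_dyad <- setdiff(tabs$expression$dyad_id, tabs$fish$dyad_id)
      orphan_dyad <- orphan_dyad[!is.na(orphan_dyad) & orphan_dyad != ""]
      if (length(orphan_dyad))
        note(paths$expression, "error",
             paste("dyad_id not in fish table:",
                   paste(utils::head(orphan_dyad, 5), collapse = ", ")))
    }
  }
  if (length(report)) do.call(rbind, report) else
    data.frame(file = character(0), severity = character(0),
               message = character(0))
}

behavior_summaries <- function(events, fish, resolution, session_s) {
  res_by_dyad <- stats::setNames(resolution$resolution_time_s,
                                 resolution$dyad_id)
  out <- lapply(seq_len(nrow(fish)), function(i) {
    f <- fish[i, ]
    ev <- events[events$fish_id == f$fish_id, , drop = FALSE]
    rt <- if (f$treatment %in% c("winner", "loser"))
      res_by_dyad[[f$dyad_id]] %||% NA_real_ else NA_real_
    cbind(data.frame(fish_id = f$fish_id, treatment = f$treatment,
                     dyad_id = f$dyad_id),
          summarize_behavior(ev, session_s, rt))
  })
  do.call(rbind, out)
}

behavior_tests <- function(summaries, session_s) {
  real <- summaries[summaries$treatment %in% c("winner", "loser"), ]
  mirror <- summaries[summaries$treatment == "mirror", ]
  # latency and resolution are fight-level for real dyads
  lat_real <- tapply(real$latency_first_bite_s, real$dyad_id, min)
  res_real <- tapply(real$resolution_time_s, real$dyad_id,
                     function(x) x[1])
  # unresolved mirror fights enter the resolution comparison at session end
  tests <- list(
    latency_first_bite = two_sample_t(mirror$latency_first_bite_s, lat_real),
    resolution_time = two_sample_t(rep(session_s, nrow(mirror)), res_real),
    aggression_last5 = two_sample_t(
      mirror$aggressive_freq_last5,
      summaries$aggressive_freq_last5[summaries$treatment == "winner"]))
  do.call(rbind, lapply(names(tests), function(nm)
    data.frame(variable = nm, comparison = "mirror vs real",
               t = tests[[nm]]$statistic, df = tests[[nm]]$df,
               p = tests[[nm]]$p)))
}

next_run_dir <- function(out_dir, run_name = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(run_name)) {
    rd <- file.path(out_dir, run_name)
    if (dir.exists(rd)) stop("run directory already exists: ", rd,
                             " (runs are never overwritten)")
    dir.create(rd)
    return(rd)
  }
  i <- 1
  repeat {
    rd <- file.path(out_dir, sprintf("run-%03d", i))
    if (!dir.exists(rd)) { dir.create(rd); return(rd) }
    i <- i + 1
  }
}

#' Run the full analysis pipeline
#'
#' Drives every stage — simulate (or load) raw tables, quantify amplification
#' curves into reference-normalized relative expression, screen outliers per
#' condition, compute behavioral/cortisol/mixed-model statistics, build
#' per-condition co-expression matrices, compare them by QAP and partition
#' them into neurogenomic-state classes — writing every stage's outputs and
#' a JSON manifest (with file checksums) into one fresh run directory.
#' Reruns with the same configuration reproduce identical statistical output
#' tables.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `run_dir`, `manifest`, and the principal
#'   in-memory results (`expression`, `contrasts`, `qap_results`,
#'   `partitions`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  rd <- next_run_dir(config$out_dir, config$run_name)
  design <- config$design
  session_s <- design$interaction_minutes * 60

  # --- stage 1: obtain raw tables ------------------------------------------
  if (config$mode == "simulate") {
    study <- simulate_study(design, config$effects, seed = config$seed,
                            behavior_params = config$behavior_params,
                            cortisol_params = config$cortisol_params,
                            kinetics = config$kinetics,
                            curves = config$use_curves)
    write_study(study, file.path(rd, "raw"))
    fish <- study$fish
    behavior <- study$behavior
    resolution <- study$resolution
    cortisol <- study$cortisol
    curves <- study$curves
    expression0 <- study$expression_true
  } else {
    fish <- read_input_table(config$paths$fish, "fish")
    cortisol <- read_input_table(config$paths$cortisol, "cortisol")
    behavior <- if (!is.null(config$paths$behavior))
      read_input_table(config$paths$behavior, "behavior") else NULL
    resolution <- if (!is.null(config$paths$resolution))
      read_input_table(config$paths$resolution, "resolution") else
        data.frame(dyad_id = character(0), resolution_time_s = numeric(0))
    curves <- if (!is.null(config$paths$curves))
      read_input_table(config$paths$curves, "curves") else NULL
    expression0 <- if (!is.null(config$paths$expression))
      read_input_table(config$paths$expression, "expression") else NULL
  }

  # --- stage 2: quantification ---------------------------------------------
  if (config$use_curves && !is.null(curves)) {
    qc <- quantify_curves(curves)
    write_table_csv(qc, file.path(rd, "qc_report.csv"))
    expression <- normalize_expression(qc, design$reference_gene, fish = fish)
  } else {
    if (is.null(expression0))
      stop("no curves available and no expression table provided")
    expression <- expression0
  }
  write_table_csv(expression, file.path(rd, "expression.csv"))

  # --- stage 3: outlier screening ------------------------------------------
  scr <- screen_dataset(expression, alpha = config$alpha)
  cort_scr <- screen_dataset(cortisol, alpha = config$alpha,
                             value_col = "cortisol_ng_ml",
                             group_cols = "treatment")
  tag_log <- function(stage, log)
    if (nrow(log)) cbind(stage = stage, log) else
      cbind(data.frame(stage = character(0)), log)
  screening_log <- rbind(tag_log("expression", scr$log),
                         tag_log("cortisol", cort_scr$log))
  write_table_csv(screening_log, file.path(rd, "screening_log.csv"))
  expression <- scr$table
  cortisol_s <- cort_scr$table
  write_table_csv(expression, file.path(rd, "expression_screened.csv"))

  # --- stage 4: univariate statistics --------------------------------------
  contrasts <- list(); omnibus <- list(); lmm_notes <- character(0)
  for (gene in design$genes) {
    fitres <- fit_lmm_contrasts(expression, gene,
                                log_scale = config$log_scale)
    contrasts[[gene]] <- fitres$contrasts
    if (!is.null(fitres$omnibus))
      omnibus[[gene]] <- cbind(gene = gene, fitres$omnibus)
    if (length(fitres$notes))
      lmm_notes <- c(lmm_notes, paste0(gene, ": ", fitres$notes))
  }
  contrasts <- do.call(rbind, contrasts)
  rownames(contrasts) <- NULL
  write_table_csv(contrasts, file.path(rd, "contrasts.csv"))
  omnibus <- do.call(rbind, omnibus)
  rownames(omnibus) <- NULL
  write_table_csv(omnibus, file.path(rd, "omnibus.csv"))

  welch <- welch_anova(cortisol_s$cortisol_ng_ml, cortisol_s$treatment)
  cortisol_tests <- data.frame(test = "welch_anova", F = welch$statistic,
                               df1 = welch$df[1], df2 = welch$df[2],
                               p = welch$p)
  write_table_csv(cortisol_tests, file.path(rd, "cortisol_tests.csv"))
  write_table_csv(tukey_hsd(cortisol_s$cortisol_ng_ml, cortisol_s$treatment),
                  file.path(rd, "cortisol_tukey.csv"))

  behavior_out <- NULL
  if (!is.null(behavior) && nrow(behavior)) {
    summaries <- behavior_summaries(behavior, fish, resolution, session_s)
    write_table_csv(summaries, file.path(rd, "behavior_summaries.csv"))
    behavior_out <- behavior_tests(summaries, session_s)
    write_table_csv(behavior_out, file.path(rd, "behavior_tests.csv"))

    # correlation screens: behavior x cortisol x expression
    widew <- merge(summaries[, c("fish_id", "aggressive_freq_last5",
                                 "submissive_freq_last5")],
                   cortisol_s[, c("fish_id", "cortisol_ng_ml")],
                   by = "fish_id", all = TRUE)
    for (k in design$nuclei) for (g in design$genes) {
      sub <- expression[expression$nucleus == k & expression$gene == g,
                        c("fish_id", "relative_expression")]
      names(sub)[2] <- paste0(g, "_", k)
      widew <- merge(widew, sub, by = "fish_id", all = TRUE)
    }
    expr_vars <- setdiff(names(widew),
                         c("fish_id", "aggressive_freq_last5",
                           "submissive_freq_last5", "cortisol_ng_ml"))
    pairs <- rbind(
      data.frame(var1 = "aggressive_freq_last5", var2 = "cortisol_ng_ml"),
      data.frame(var1 = "aggressive_freq_last5", var2 = expr_vars),
      data.frame(var1 = "cortisol_ng_ml", var2 = expr_vars))
    corrs <- corr_with_bh(widew, pairs)
    write_table_csv(corrs$correlations, file.path(rd, "correlations.csv"))
  }

  # --- stage 5: neurogenomic states ----------------------------------------
  matrices <- list()
  for (t in design$treatments) for (k in design$nuclei)
    matrices[[paste(t, k, sep = ":")]] <-
      coexpression_matrix(expression, t, k, genes = design$genes,
                          log_scale = config$log_scale)
  export_heatmaps(matrices, file.path(rd, "matrices"),
                  write_images = config$heatmaps)

  qap_rows <- list(); part_rows <- list()
  for (k in design$nuclei) {
    ms <- stats::setNames(
      lapply(design$treatments, function(t) matrices[[paste(t, k, sep = ":")]]),
      design$treatments)
    part <- partition_states(ms, axis = "treatments", alpha = config$alpha,
                             n_perm = config$n_perm,
                             seed = if (is.null(config$seed)) NULL else
                               substream_seed(config$seed, paste0("nucleus:", k)),
                             alternative = config$qap_alternative)
    qap_rows[[k]] <- cbind(axis = "treatments", within = k, part$edges)
    part_rows[[k]] <- data.frame(axis = "treatments", within = k,
                                 unit = names(part$labels),
                                 label = unname(part$labels))
  }
  for (t in design$treatments) {
    ms <- stats::setNames(
      lapply(design$nuclei, function(k) matrices[[paste(t, k, sep = ":")]]),
      design$nuclei)
    part <- partition_states(ms, axis = "nuclei", alpha = config$alpha,
                             n_perm = config$n_perm,
                             seed = if (is.null(config$seed)) NULL else
                               substream_seed(config$seed,
                                              paste0("treatment:", t)),
                             alternative = config$qap_alternative)
    qap_rows[[paste0("t:", t)]] <- cbind(axis = "nuclei", within = t,
                                         part$edges)
    part_rows[[paste0("t:", t)]] <- data.frame(axis = "nuclei", within = t,
                                               unit = names(part$labels),
                                               label = unname(part$labels))
  }
  qap_results <- do.call(rbind, qap_rows); rownames(qap_results) <- NULL
  partitions <- do.call(rbind, part_rows); rownames(partitions) <- NULL
  write_table_csv(qap_results, file.path(rd, "qap_results.csv"))
  write_table_csv(partitions, file.path(rd, "partitions.csv"))

  # --- manifest -------------------------------------------------------------
  outputs <- sort(list.files(rd, recursive = TRUE))
  outputs <- outputs[outputs != "manifest.json"]
  checksums <- as.list(tools::md5sum(file.path(rd, outputs)))
  names(checksums) <- outputs
  manifest <- list(
    package_version = as.character(utils::packageVersion("neurostates")),
    mode = config$mode, seed = config$seed, alpha = config$alpha,
    n_perm = config$n_perm, log_scale = config$log_scale,
    qap_alternative = config$qap_alternative,
    n_fish = nrow(fish),
    n_coexpression_matrices = length(matrices),
    lmm_notes = lmm_notes,
    files = checksums)
  jsonlite::write_json(manifest, file.path(rd, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(run_dir = rd, manifest = manifest, expression = expression,
                 contrasts = contrasts, qap_results = qap_results,
                 partitions = partitions))
}
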