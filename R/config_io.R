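#' Build a pipeline configuration from a YAML document
#'
#' Reads a single YAML file mirroring [pipeline_config()]: top-level scalars
#' (`mode`, `seed`, `alpha`, `n_perm`, `log_scale`, `qap_alternative`,
#' `use_curves`, `heatmaps`, `out_dir`, `run_name`), a `design` block
#' (`n_control`, `n_mirror`, `n_winner`, `n_loser`, `nuclei`, `genes`,
#' `reference_gene`, `interaction_minutes`), an `effects` block currently
#' supporting the variance components (`sigma_subject`, `sigma_dyad`,
#' `sigma_resid`) and `zero_effects: true` for a null study, and a `paths`
#' block for load mode. Anything omitted falls back to the packaged
#' defaults. The master `seed` is mandatory in simulate mode.
#'
#' @param path YAML file path.
#' @param out_dir overrides the file's `out_dir` when given.
#' @return a [pipeline_config()].
#' @export
pipeline_config_from_yaml <- function(path, out_dir = NULL) {
  doc <- yaml::read_yaml(path)
  dsn <- doc$design %||% list()
  design <- study_design(
    n_control = dsn$n_control %||% 10, n_mirror = dsn$n_mirror %||% 12,
    n_winner = dsn$n_winner %||% 12, n_loser = dsn$n_loser %||% 11,
    nuclei = unlist(dsn$nuclei) %||% c("Dm", "Dl", "Vv", "Vs", "POA"),
    genes = unlist(dsn$genes) %||% c("bdnf", "npas4", "nlgn1", "nlgn2",
                                     "wnt3", "neurod"),
    reference_gene = dsn$reference_gene %||% "eef1a1l1",
    interaction_minutes = dsn$interaction_minutes %||% 30)
  eb <- doc$effects %||% list()
  effects <- default_effects(design, null = isTRUE(eb$zero_effects))
  for (f in c("sigma_subject", "sigma_dyad", "sigma_resid"))
    if (!is.null(eb[[f]])) effects[[f]] <- eb[[f]]
  pipeline_config(
    mode = doc$mode %||% "simulate",
    out_dir = out_dir %||% doc$out_dir %||% "runs",
    seed = doc$seed,
    design = design, effects = effects,
    paths = doc$paths,
    alpha = doc$alpha %||% 0.05,
    n_perm = doc$n_perm %||% 5000,
    log_scale = doc$log_scale %||% TRUE,
    qap_alternative = doc$qap_alternative %||% "greater",
    use_curves = doc$use_curves %||% TRUE,
    heatmaps = doc$heatmaps %||% FALSE,
    run_name = doc$run_name)
}
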