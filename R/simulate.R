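#' Simulate qPCR amplification curves
#'
#' Forward model for raw fluorescence: before the plateau the background-
#' subtracted signal grows exponentially at the reaction's true per-cycle
#' gain, \eqn{F_0 (1+E)^c}, and saturates smoothly into the plateau:
#' \deqn{F(c) = baseline + plateau \cdot x (1+x^h)^{-1/h}, \quad
#'       x = F_0 (1+E)^c / plateau,}
#' with sharpness \eqn{h} (the curve is within a fraction \eqn{x^h/h} of pure
#' exponential growth while \eqn{x \ll 1}). \eqn{F_0} is proportional to the
#' true initial template quantity. Additive Gaussian read noise is applied
#' per cycle.
#'
#' @param true_quantity positive vector, one true template quantity per
#'   reaction (arbitrary units; zero allowed and yields a flat curve).
#' @param kinetics list as from [default_kinetics()] but with scalar `E_true`
#'   (or one value per reaction): fields `E_true`, `plateau`, `baseline`,
#'   `noise_sd`, `f0_scale`, `n_cycles`, `shape_h`.
#' @param seed integer master seed; each reaction gets its own substream.
#' @param reaction_id optional character ids (default `R0001`, ...).
#' @return long data frame: `reaction_id`, `cycle`, `fluorescence`.
#' @examples
#' k <- default_kinetics()
#' k$E_true <- 1; k$noise_sd <- 0
#' curves <- simulate_amplification_curves(c(1, 0.1), k, seed = 1)
#' @export
simulate_amplification_curves <- function(true_quantity, kinetics, seed,
                                          reaction_id = NULL) {
  q <- true_quantity
  if (any(q < 0)) stop("true_quantity must be non-negative")
  if (kinetics$plateau <= 0) stop("plateau must be positive")
  E <- rep_len(unname(kinetics$E_true), length(q))
  if (any(E <= 0) || any(E > 1)) stop("E_true must lie in (0, 1]")
  if (kinetics$n_cycles < 40) stop("need at least 40 cycles")
  if (is.null(reaction_id)) reaction_id <- sprintf("R%04d", seq_along(q))
  cycles <- seq_len(kinetics$n_cycles)
  h <- kinetics$shape_h
  out <- vector("list", length(q))
  for (i in seq_along(q)) {
    x <- kinetics$f0_scale * q[i] * (1 + E[i])^cycles
    fl <- kinetics$baseline + kinetics$plateau * x / (1 + x^h)^(1 / h)
    if (kinetics$noise_sd > 0) {
      fl <- fl + with_substream(seed, paste0("curve:", reaction_id[i]),
                                stats::rnorm(length(cycles),
                                             sd = kinetics$noise_sd))
    }
    out[[i]] <- data.frame(reaction_id = reaction_id[i], cycle = cycles,
                           fluorescence = fl)
  }
  do.call(rbind, out)
}

#' Simulate behavioral event logs for one study
#'
#' Event streams follow the contest phenomenology: both members of a real
#' dyad trade aggressive acts (bite/chase/strike) until the dyad's resolution
#' time, after which only the winner is aggressive and the loser emits only
#' submissive acts (freeze/flee); mirror-fighters are aggressive for the whole
#' session and never submit; isolated controls emit nothing.
#'
#' @param fish data frame with `fish_id`, `dyad_id`, `treatment`.
#' @param design a [study_design()].
#' @param params list from [default_behavior_params()].
#' @param seed integer master seed.
#' @return list with `events` (fish_id, time_s, behavior) and `resolution`
#'   (dyad_id, resolution_time_s; `NA` for unresolved mirror fights).
#' @export
simulate_behavior <- function(fish, design, params = default_behavior_params(),
                              seed) {
  session <- design$interaction_minutes * 60
  aggr <- c("bite", "chase", "strike")
  subm <- c("freeze", "flee")

  # per-dyad latency and resolution for real fights
  real_dyads <- sort(unique(fish$dyad_id[fish$treatment %in%
                                           c("winner", "loser")]))
  resolution <- data.frame(dyad_id = real_dyads, resolution_time_s = NA_real_)
  for (i in seq_along(real_dyads)) {
    resolution$resolution_time_s[i] <- with_substream(
      seed, paste0("resolution:", real_dyads[i]), {
        shape <- (params$resolution_mean_s / params$resolution_sd_s)^2
        stats::rgamma(1, shape = shape,
                      rate = shape / params$resolution_mean_s)
      })
  }
  resolution$resolution_time_s <- pmin(resolution$resolution_time_s, session)

  poisson_times <- function(rate_per_min, from, to) {
    if (to <= from || rate_per_min <= 0) return(numeric(0))
    n <- stats::rpois(1, rate_per_min * (to - from) / 60)
    sort(stats::runif(n, from, to))
  }

  ev <- vector("list", nrow(fish))
  for (i in seq_len(nrow(fish))) {
    f <- fish[i, ]
    ev[[i]] <- with_substream(seed, paste0("behavior:", f$fish_id), {
      if (f$treatment == "control") {
        data.frame(fish_id = character(0), time_s = numeric(0),
                   behavior = character(0))
      } else if (f$treatment == "mirror") {
        lat <- stats::rlnorm(1, params$latency_meanlog_mirror,
                             params$latency_sdlog_mirror)
        lat <- min(lat, session)
        t_a <- c(lat, poisson_times(params$rate_mirror_aggr, lat, session))
        data.frame(fish_id = f$fish_id, time_s = t_a,
                   behavior = c("bite",
                                sample(aggr, length(t_a) - 1, replace = TRUE)))
      } else {
        res <- resolution$resolution_time_s[resolution$dyad_id == f$dyad_id]
        lat <- stats::rlnorm(1, params$latency_meanlog_real,
                             params$latency_sdlog_real)
        lat <- min(lat, res)
        t_pre <- c(lat, poisson_times(params$rate_pre_aggr, lat, res))
        pre <- data.frame(fish_id = f$fish_id, time_s = t_pre,
                          behavior = c("bite", sample(aggr, length(t_pre) - 1,
                                                      replace = TRUE)))
        post <- if (f$treatment == "winner") {
          t_post <- poisson_times(params$rate_post_winner_aggr, res, session)
          data.frame(fish_id = f$fish_id, time_s = t_post,
                     behavior = sample(aggr, length(t_post), replace = TRUE))
        } else {
          t_post <- poisson_times(params$rate_post_loser_subm, res, session)
          data.frame(fish_id = f$fish_id, time_s = t_post,
                     behavior = sample(subm, length(t_post), replace = TRUE))
        }
        rbind(pre, post)
      }
    })
  }
  events <- do.call(rbind, ev)
  events <- events[order(events$fish_id, events$time_s), , drop = FALSE]
  rownames(events) <- NULL
  list(events = events, resolution = resolution)
}

#' Simulate a complete synthetic study
#'
#' Generates everything the analysis pipeline consumes: fish records with
#' dyad pairing and morphometrics, behavioral event logs, plasma cortisol,
#' the latent log-expression truth table (with its subject/dyad/residual
#' decomposition), and optionally raw amplification curves for every
#' fish x nucleus x gene reaction (targets plus reference). Identical
#' `seed` and inputs give byte-identical output; every fish and reaction
#' draws from its own substream, so subsetting a design leaves other units'
#' values unchanged.
#'
#' @param design a [study_design()].
#' @param effects an [effect_spec()].
#' @param seed integer master seed.
#' @param behavior_params list from [default_behavior_params()].
#' @param cortisol_params list from [default_cortisol_params()].
#' @param kinetics list from [default_kinetics()].
#' @param curves if `FALSE`, skip amplification-curve synthesis (the truth
#'   expression table is still produced; much faster for calibration runs).
#' @return object of class `study` with elements `fish`, `behavior`,
#'   `resolution`, `cortisol`, `truth`, `expression_true`, `curves` (or
#'   `NULL`), plus the inputs.
#' @examples
#' s <- simulate_study(study_design(), default_effects(), seed = 1,
#'                     curves = FALSE)
#' nrow(s$fish)  # 45
#' @export
simulate_study <- function(design, effects = default_effects(design), seed,
                           behavior_params = default_behavior_params(),
                           cortisol_params = default_cortisol_params(),
                           kinetics = default_kinetics(design$genes,
                                                       design$reference_gene),
                           curves = TRUE) {
  stopifnot(inherits(design, "study_design"), inherits(effects, "effect_spec"))
  n <- design$n_per_treatment
  nuclei <- design$nuclei; genes <- design$genes
  g <- length(genes)

  # --- fish records with dyad pairing ---------------------------------------
  n_dyads <- n[["winner"]]
  ids <- sprintf("F%02d", seq_len(sum(n)))
  treatment <- rep(c("control", "mirror", "winner", "loser"), n)
  fish <- data.frame(fish_id = ids, treatment = treatment,
                     stringsAsFactors = FALSE)
  fish$dyad_id <- NA_character_
  w_idx <- which(fish$treatment == "winner")
  l_idx <- which(fish$treatment == "loser")
  fish$dyad_id[w_idx] <- sprintf("D%02d", seq_len(n[["winner"]]))
  fish$dyad_id[l_idx] <- sprintf("D%02d", seq_len(n[["loser"]]))
  # housing pairs for mirror and control fish (not a statistical pairing)
  m_idx <- which(fish$treatment == "mirror")
  c_idx <- which(fish$treatment == "control")
  fish$dyad_id[m_idx] <- sprintf("M%02d", ceiling(seq_along(m_idx) / 2))
  fish$dyad_id[c_idx] <- sprintf("I%02d", ceiling(seq_along(c_idx) / 2))
  # dyads whose loser was lost to dropout (unequal winner/loser counts)
  dropout_dyads <- setdiff(fish$dyad_id[w_idx], fish$dyad_id[l_idx])
  fish$partner_dropout <- fish$treatment == "winner" &
    fish$dyad_id %in% dropout_dyads

  morpho <- t(vapply(fish$fish_id, function(id)
    with_substream(seed, paste0("morpho:", id),
                   c(stats::rnorm(1, 3.78, 0.2), stats::rnorm(1, 0.40, 0.03))),
    numeric(2)))
  fish$standard_length_cm <- round(pmax(morpho[, 1], 2.5), 2)
  fish$body_mass_g <- round(pmax(morpho[, 2], 0.2), 3)

  # --- latent expression ----------------------------------------------------
  b_subject <- vapply(fish$fish_id, function(id)
    with_substream(seed, paste0("subject:", id),
                   stats::rnorm(1, 0, effects$sigma_subject)), numeric(1))
  real_dyads <- sort(unique(fish$dyad_id[w_idx]))
  u_dyad <- stats::setNames(vapply(real_dyads, function(d)
    with_substream(seed, paste0("dyad:", d),
                   stats::rnorm(1, 0, effects$sigma_dyad)), numeric(1)),
    real_dyads)

  chol_cache <- list()
  chol_for <- function(t, k) {
    key <- paste(t, k)
    if (is.null(chol_cache[[key]])) {
      C <- effects$coexpression[[t]][[k]]
      # tiny ridge admits exactly singular (PSD) truths
      chol_cache[[key]] <<- chol(C + diag(1e-10, g))
    }
    chol_cache[[key]]
  }

  rows <- vector("list", nrow(fish))
  for (i in seq_len(nrow(fish))) {
    f <- fish[i, ]
    u <- if (f$treatment %in% c("winner", "loser")) u_dyad[[f$dyad_id]] else 0
    # one substream per fish covering all nuclei (columns = nuclei)
    Z <- with_substream(seed, paste0("resid:", f$fish_id),
                        matrix(stats::rnorm(g * length(nuclei)), g))
    e_all <- vapply(seq_along(nuclei), function(ki)
      effects$sigma_resid *
        drop(crossprod(chol_for(f$treatment, nuclei[ki]), Z[, ki])),
      numeric(g))
    if (!is.matrix(e_all)) e_all <- matrix(e_all, nrow = g)
    # delta slice as genes x nuclei (robust to single-nucleus designs)
    dslice <- t(matrix(effects$delta[f$treatment, , , drop = FALSE],
                       nrow = length(nuclei)))
    y_all <- t(effects$mu) + dslice +
      b_subject[[f$fish_id]] + u + e_all
    rows[[i]] <- data.frame(
      fish_id = f$fish_id, dyad_id = f$dyad_id, treatment = f$treatment,
      nucleus = rep(nuclei, each = g), gene = rep(genes, length(nuclei)),
      mu = as.vector(t(effects$mu)),
      delta = as.vector(dslice),
      b_subject = b_subject[[f$fish_id]], b_dyad = u,
      resid = as.vector(e_all), log_expression = as.vector(y_all),
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  expression_true <- truth[, c("fish_id", "dyad_id", "treatment",
                               "nucleus", "gene")]
  expression_true$relative_expression <- exp(truth$log_expression)

  # --- behavior and cortisol ------------------------------------------------
  beh <- simulate_behavior(fish, design, behavior_params, seed)
  cortisol <- data.frame(
    fish_id = fish$fish_id, treatment = fish$treatment,
    cortisol_ng_ml = vapply(seq_len(nrow(fish)), function(i)
      with_substream(seed, paste0("cortisol:", fish$fish_id[i]),
                     stats::rlnorm(1,
                                   cortisol_params$meanlog[[fish$treatment[i]]],
                                   cortisol_params$sdlog)), numeric(1)),
    stringsAsFactors = FALSE)

  # --- amplification curves -------------------------------------------------
  curve_df <- NULL
  if (curves) {
    all_genes <- c(genes, design$reference_gene)
    grid <- expand.grid(fish_id = fish$fish_id, nucleus = nuclei,
                        gene = all_genes, stringsAsFactors = FALSE)
    grid <- grid[order(grid$fish_id, grid$nucleus, grid$gene), ]
    rownames(grid) <- NULL
    grid$reaction_id <- sprintf("R%04d", seq_len(nrow(grid)))
    # reference gene: fixed template level; targets: exp(latent) times it
    key <- paste(expression_true$fish_id, expression_true$nucleus,
                 expression_true$gene)
    rel <- stats::setNames(expression_true$relative_expression, key)
    q <- ifelse(grid$gene == design$reference_gene, 1,
                rel[paste(grid$fish_id, grid$nucleus, grid$gene)])
    kin <- kinetics
    kin$E_true <- unname(kinetics$E_true[grid$gene])
    curve_df <- simulate_amplification_curves(q, kin, seed,
                                              reaction_id = grid$reaction_id)
    curve_df <- merge(curve_df, grid, by = "reaction_id", sort = FALSE)
    curve_df <- curve_df[order(curve_df$reaction_id, curve_df$cycle),
                         c("reaction_id", "fish_id", "nucleus", "gene",
                           "cycle", "fluorescence")]
    rownames(curve_df) <- NULL
  }

  structure(list(fish = fish, behavior = beh$events,
                 resolution = beh$resolution, cortisol = cortisol,
                 truth = truth, expression_true = expression_true,
                 curves = curve_df, design = design, effects = effects,
                 kinetics = kinetics, seed = seed),
            class = "study")
}

#' @export
print.study <- function(x, ...) {
  cat("Synthetic dyadic-contest study (seed ", x$seed, ")\n", sep = "")
  cat("  fish:", nrow(x$fish), "| real dyads:",
      length(unique(x$fish$dyad_id[x$fish$treatment == "loser"])), "\n")
  cat("  behavior events:", nrow(x$behavior), "\n")
  cat("  expression rows:", nrow(x$expression_true),
      if (is.null(x$curves)) "(no curves)" else
        paste0("| curve rows: ", nrow(x$curves)), "\n")
  invisible(x)
}

#' Write a simulated study to delimited text files
#'
#' Emits `fish.csv`, `behavior.csv`, `resolution.csv`, `cortisol.csv`,
#' `truth.csv` and (when present) `curves.csv` into `dir`.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    write_table_csv(study$fish, file.path(dir, "fish.csv")),
    write_table_csv(study$behavior, file.path(dir, "behavior.csv")),
    write_table_csv(study$resolution, file.path(dir, "resolution.csv")),
    write_table_csv(study$cortisol, file.path(dir, "cortisol.csv")),
    write_table_csv(study$truth, file.path(dir, "truth.csv")))
  if (!is.null(study$curves))
    paths <- c(paths, write_table_csv(study$curves,
                                      file.path(dir, "curves.csv")))
  invisible(paths)
}
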