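#' Study design for a dyadic agonistic-contest experiment
#'
#' Describes the layout of a four-treatment social-challenge study: isolated
#' controls, mirror-fighters, and winners/losers of staged real-opponent
#' contests, sampled in several brain nuclei for a panel of target genes plus
#' one reference gene. Winner and loser counts describe dyads: every loser has
#' exactly one winner partner; when `n_winner > n_loser` the surplus winners
#' are retained with a dropout flag on the missing partner (mimicking
#' technical loss of one fish of a pair).
#'
#' @param n_control,n_mirror,n_winner,n_loser group sizes (defaults are the
#'   reference study sizes 10/12/12/11, i.e. 45 fish and 11 complete dyads).
#' @param nuclei ordered character vector of brain nuclei.
#' @param genes ordered character vector of target gene names.
#' @param reference_gene name of the reference (normalization) gene.
#' @param interaction_minutes duration of the staged interaction, minutes.
#' @return An object of class `study_design`.
#' @examples
#' d <- study_design()
#' d$n_per_treatment
#' @export
study_design <- function(n_control = 10, n_mirror = 12, n_winner = 12,
                         n_loser = 11,
                         nuclei = c("Dm", "Dl", "Vv", "Vs", "POA"),
                         genes = c("bdnf", "npas4", "nlgn1", "nlgn2",
                                   "wnt3", "neurod"),
                         reference_gene = "eef1a1l1",
                         interaction_minutes = 30) {
  n <- c(control = n_control, mirror = n_mirror,
         winner = n_winner, loser = n_loser)
  if (any(n < 2)) stop("all treatment counts must be >= 2")
  if (n_loser > n_winner)
    stop("n_loser may not exceed n_winner (each loser needs a winner partner)")
  if (anyDuplicated(genes)) stop("gene names must be unique")
  if (reference_gene %in% genes)
    stop("reference_gene must be disjoint from target genes")
  if (anyDuplicated(nuclei)) stop("nuclei must be unique")
  if (interaction_minutes <= 0) stop("interaction_minutes must be positive")
  structure(list(
    n_per_treatment = n,
    treatments = c("control", "mirror", "winner", "loser"),
    nuclei = nuclei,
    genes = genes,
    reference_gene = reference_gene,
    interaction_minutes = interaction_minutes
  ), class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Dyadic-contest study design\n")
  cat("  fish:", sum(x$n_per_treatment), " (",
      paste(names(x$n_per_treatment), x$n_per_treatment,
            sep = "=", collapse = ", "), ")\n", sep = "")
  cat("  nuclei:", paste(x$nuclei, collapse = ", "), "\n")
  cat("  genes:", paste(x$genes, collapse = ", "),
      "| reference:", x$reference_gene, "\n")
  cat("  interaction:", x$interaction_minutes, "min\n")
  invisible(x)
}

#' Generative effect specification for synthetic expression data
#'
#' Encodes the generative model the downstream mixed-model analysis assumes:
#' latent natural-log expression for fish \eqn{i}, nucleus \eqn{k}, gene
#' \eqn{g} is
#' \deqn{y_{ikg} = \mu_{kg} + \delta_{t(i)kg} + b_i + u_{d(i)} + e_{ikg}}
#' with subject intercept \eqn{b_i \sim N(0, \sigma_s^2)}, a dyad intercept
#' \eqn{u_d \sim N(0, \sigma_d^2)} shared by the winner and loser of a real
#' contest (zero for mirror-fighters and controls), and residual vectors
#' \eqn{e_{ik\cdot} \sim N(0, \sigma_r^2 C_{t,k})} whose correlation matrix
#' \eqn{C_{t,k}} is the per-(treatment, nucleus) co-expression structure.
#' Relative expression is `exp(y)`.
#'
#' @param design a [study_design()].
#' @param mu baseline log-expression matrix, nuclei x genes.
#' @param delta treatment x nucleus x gene array of log-scale mean shifts.
#' @param sigma_subject,sigma_dyad,sigma_resid random-effect and residual SDs
#'   (log scale), all `>= 0`.
#' @param coexpression nested list `coexpression[[treatment]][[nucleus]]` of
#'   gene x gene correlation matrices; each must be symmetric, unit-diagonal
#'   and positive semi-definite.
#' @return An object of class `effect_spec`.
#' @seealso [default_effects()] for the packaged defaults.
#' @export
effect_spec <- function(design, mu, delta, sigma_subject = 0.3,
                        sigma_dyad = 0.2, sigma_resid = 0.5,
                        coexpression = NULL) {
  nuclei <- design$nuclei; genes <- design$genes
  trts <- design$treatments
  stopifnot(is.matrix(mu), identical(dim(mu), c(length(nuclei), length(genes))))
  dimnames(mu) <- list(nuclei, genes)
  stopifnot(length(dim(delta)) == 3,
            identical(dim(delta), c(length(trts), length(nuclei), length(genes))))
  dimnames(delta) <- list(trts, nuclei, genes)
  if (any(c(sigma_subject, sigma_dyad, sigma_resid) < 0))
    stop("all SDs must be >= 0")
  if (is.null(coexpression)) {
    idm <- diag(length(genes)); dimnames(idm) <- list(genes, genes)
    coexpression <- stats::setNames(lapply(trts, function(t)
      stats::setNames(lapply(nuclei, function(n) idm), nuclei)), trts)
  }
  for (t in trts) for (k in nuclei) {
    C <- coexpression[[t]][[k]]
    if (is.null(C)) stop("missing coexpression matrix for (", t, ", ", k, ")")
    check_correlation_matrix(C, sprintf("(%s, %s)", t, k), length(genes))
  }
  structure(list(mu = mu, delta = delta, sigma_subject = sigma_subject,
                 sigma_dyad = sigma_dyad, sigma_resid = sigma_resid,
                 coexpression = coexpression),
            class = "effect_spec")
}

check_correlation_matrix <- function(C, where, g) {
  if (!is.matrix(C) || nrow(C) != g || ncol(C) != g)
    stop("coexpression matrix for ", where, " has wrong dimensions")
  if (max(abs(C - t(C))) > 1e-8)
    stop("coexpression matrix for ", where, " is not symmetric")
  if (max(abs(diag(C) - 1)) > 1e-8)
    stop("coexpression matrix for ", where, " is not unit-diagonal")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("coexpression matrix for ", where,
         " is not positive semi-definite (min eigenvalue ",
         format(min(ev), digits = 3), ")")
  invisible(TRUE)
}

# A generic "strong structure" correlation matrix built deterministically from
# two-factor loadings. Distinct ids give unrelated matrices with no
# non-trivial automorphisms (all off-diagonal values distinct), which keeps
# QAP permutation nulls informative.
#' Deterministic archetype co-expression matrix
#'
#' Builds a generic, strongly structured gene-gene correlation matrix from a
#' small integer id. The same id always yields the same matrix; different ids
#' yield unrelated matrices. Used to compose the default per-condition
#' co-expression truths.
#'
#' @param id small integer selecting the archetype.
#' @param genes character vector of gene names (dimension labels).
#' @return a correlation matrix with `length(genes)` rows.
#' @export
coexpr_archetype <- function(id, genes) {
  g <- length(genes)
  W <- withr::with_seed(100003L + as.integer(id),
                        matrix(stats::rnorm(g * 2, sd = 1), g, 2))
  C <- stats::cov2cor(tcrossprod(W) + diag(0.3, g))
  dimnames(C) <- list(genes, genes)
  C
}

# Archetype id per (nucleus, treatment). Shared ids encode the default truth
# for which conditions share a neurogenomic state: mirror-fighters and losers
# share a state in Dm, Dl and Vs; controls and mirror-fighters share Vv;
# all but losers share POA; winners share one state across Dm and Dl; and
# losers share one across Dm and POA.
default_state_map <- function() {
  m <- rbind(
    Dm  = c(control = 1, mirror = 2,  winner = 3,  loser = 2),
    Dl  = c(control = 4, mirror = 5,  winner = 3,  loser = 5),
    Vv  = c(control = 6, mirror = 6,  winner = 7,  loser = 8),
    Vs  = c(control = 9, mirror = 10, winner = 11, loser = 10),
    POA = c(control = 12, mirror = 12, winner = 12, loser = 2))
  m
}

#' Default generative effects
#'
#' Packaged default [effect_spec()]: nucleus baseline profiles reproducing the
#' qualitative expression ranking of the candidate genes across nuclei (e.g.
#' `bdnf` highest in Dl, `neurod` in Dm/Dl, `nlgn2` in Vs/Vv), treatment
#' shifts on the log scale at the handful of (gene, nucleus, treatment) cells
#' where the contest phenotypes differ from isolated controls, variance
#' components `sigma_subject = 0.3`, `sigma_dyad = 0.2`, `sigma_resid = 0.5`,
#' and per-condition co-expression matrices composed from
#' [coexpr_archetype()]s so that conditions known to share a neurogenomic
#' state share a truth matrix.
#'
#' @param design a [study_design()]; defaults used otherwise.
#' @param null if `TRUE`, return a zero-effect spec (all deltas zero,
#'   identity co-expression) — the calibration condition.
#' @return an [effect_spec()].
#' @export
default_effects <- function(design = study_design(), null = FALSE) {
  nuclei <- design$nuclei; genes <- design$genes
  trts <- design$treatments
  mu <- matrix(log(0.2), length(nuclei), length(genes),
               dimnames = list(nuclei, genes))
  adj <- function(gene, shifts) mu[names(shifts), gene] <<-
    mu[names(shifts), gene] + shifts
  adj("bdnf",   c(Dm = 1.0, Dl = 1.5, Vv = 0, Vs = -1.0, POA = -0.5))
  adj("npas4",  c(Dm = 0.8, Dl = 0.8, Vv = 0.8, Vs = 0, POA = -0.5))
  adj("nlgn1",  c(Dm = 0.6, Dl = 0.6, Vv = 0.6, Vs = 0, POA = -0.1))
  adj("nlgn2",  c(Dm = 0, Dl = 0.1, Vv = 0.8, Vs = 1.4, POA = 0.3))
  adj("wnt3",   c(Dm = 0.4, Dl = 0.3, Vv = 0.3, Vs = -0.2, POA = -0.2))
  adj("neurod", c(Dm = 2.0, Dl = 2.2, Vv = 0, Vs = -0.1, POA = -0.2))

  delta <- array(0, dim = c(length(trts), length(nuclei), length(genes)),
                 dimnames = list(trts, nuclei, genes))
  if (!null) {
    delta["mirror", "Dl", "bdnf"]   <- 0.6
    delta["loser",  "Dl", "bdnf"]   <- 0.6
    delta["mirror", "Dl", "npas4"]  <- -0.6
    delta["winner", "Dm", "npas4"]  <- 0.5
    delta["winner", "Vv", "nlgn1"]  <- 0.6
    delta["loser",  "Vv", "nlgn1"]  <- 0.3
    delta["loser",  "Dl", "nlgn1"]  <- 0.5
    delta["loser",  "Vs", "nlgn2"]  <- -0.7
    delta["winner", "Vs", "nlgn2"]  <- -0.5
    delta["winner", "Dm", "wnt3"]   <- 0.5
    delta["mirror", "Vv", "wnt3"]   <- 0.4
    delta["loser",  "Vv", "wnt3"]   <- 0.4
    delta["winner", "Dm", "neurod"] <- 0.5
  }

  if (null) {
    coex <- NULL  # identity, filled by effect_spec()
  } else {
    map <- default_state_map()
    coex <- stats::setNames(lapply(trts, function(t)
      stats::setNames(lapply(nuclei, function(k)
        coexpr_archetype(map[k, t], genes)), nuclei)), trts)
  }
  effect_spec(design, mu = mu, delta = delta, coexpression = coex)
}

#' Default behavioral event-rate parameters
#'
#' Distributions behind the synthetic event logs: real-opponent first-bite
#' latency is log-normal with median about one minute, mirror-elicited fights
#' start sooner (median ~15 s); real fights resolve after about 7 minutes
#' (gamma-distributed) while mirror fights never resolve; aggressive and
#' submissive acts arrive as Poisson processes at per-minute rates depending
#' on phase and phenotype. Controls emit no events.
#'
#' @param latency_meanlog_real,latency_sdlog_real,latency_meanlog_mirror,latency_sdlog_mirror
#'   log-normal parameters of first-bite latency (seconds).
#' @param resolution_mean_s,resolution_sd_s gamma mean/SD of real-fight
#'   resolution time (seconds).
#' @param rate_pre_aggr,rate_mirror_aggr,rate_post_winner_aggr,rate_post_loser_subm
#'   event rates per minute.
#' @return a named list of parameters.
#' @export
default_behavior_params <- function(latency_meanlog_real = log(55),
                                    latency_sdlog_real = 0.5,
                                    latency_meanlog_mirror = log(15),
                                    latency_sdlog_mirror = 0.4,
                                    resolution_mean_s = 420,
                                    resolution_sd_s = 90,
                                    rate_pre_aggr = 3,
                                    rate_mirror_aggr = 4,
                                    rate_post_winner_aggr = 4,
                                    rate_post_loser_subm = 4) {
  as.list(environment())
}

#' Default plasma cortisol parameters
#'
#' Log-normal per-treatment distributions (ng/ml) ordered
#' mirror ~ winner > loser ~ control, reflecting higher post-fight cortisol in
#' the phenotypes that kept fighting or won.
#'
#' @param meanlog named per-treatment log-means.
#' @param sdlog common log-SD.
#' @return a named list.
#' @export
default_cortisol_params <- function(meanlog = c(control = log(4),
                                                mirror = log(13),
                                                winner = log(12),
                                                loser = log(5)),
                                    sdlog = 0.35) {
  list(meanlog = meanlog, sdlog = sdlog)
}

#' Default qPCR reaction kinetics
#'
#' Forward-model parameters for synthetic amplification curves: per-gene true
#' efficiencies spread over (0.85, 1.0], a shared plateau/baseline in
#' arbitrary fluorescence units, additive Gaussian read noise, and the
#' per-unit-template fluorescence scale that places cycle thresholds in the
#' mid-20s to low-30s.
#'
#' @param genes character vector of target genes (reference gene appended).
#' @param reference_gene reference gene name.
#' @param plateau,baseline,noise_sd,f0_scale,n_cycles,shape_h curve
#'   parameters; `shape_h` controls how sharply the exponential phase
#'   saturates into the plateau (larger = sharper, i.e. exponential growth
#'   holds closer to the plateau).
#' @return a named list with an `E_true` named vector and curve parameters.
#' @export
default_kinetics <- function(genes = study_design()$genes,
                             reference_gene = study_design()$reference_gene,
                             plateau = 100, baseline = 2, noise_sd = 0.3,
                             f0_scale = 1e-8, n_cycles = 40, shape_h = 8) {
  all_genes <- c(genes, reference_gene)
  E_true <- stats::setNames(
    seq(0.86, 1.0, length.out = length(all_genes)), all_genes)
  list(E_true = E_true, plateau = plateau, baseline = baseline,
       noise_sd = noise_sd, f0_scale = f0_scale, n_cycles = n_cycles,
       shape_h = shape_h)
}
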