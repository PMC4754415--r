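# Packaged simulation studies used to validate the statistical machinery.
# These are first-class, documented entry points (not test-only helpers) so
# that calibration evidence can be regenerated by users.

#' Monte-Carlo vs exhaustive QAP agreement study
#'
#' Draws random symmetric matrix pairs and compares the Monte-Carlo QAP
#' p-value against the exact exhaustive p over all `g!` permutations.
#'
#' @param n_pairs number of matrix pairs.
#' @param g matrix dimension (`g <= 8`).
#' @param n_perm Monte-Carlo permutation count.
#' @param seed master seed.
#' @return data frame: `p_mc`, `p_exact`, `abs_diff`, and the binomial
#'   three-sigma band `band = 3 sqrt(p(1-p)/n_perm)` of the exact p.
#' @export
qap_oracle_study <- function(n_pairs = 50, g = 5, n_perm = 5000, seed = 1) {
  rows <- lapply(seq_len(n_pairs), function(i) {
    mats <- with_substream(seed, paste0("qap-oracle:", i), {
      mk <- function() {
        M <- matrix(stats::runif(g * g, -1, 1), g, g)
        M <- (M + t(M)) / 2; diag(M) <- 1
        M
      }
      list(mk(), mk())
    })
    pe <- qap_correlation(mats[[1]], mats[[2]], mode = "exhaustive")$p
    pm <- qap_correlation(mats[[1]], mats[[2]], n_perm = n_perm,
                          seed = substream_seed(seed, paste0("mc:", i)),
                          mode = "monte_carlo")$p
    data.frame(p_mc = pm, p_exact = pe, abs_diff = abs(pm - pe),
               band = 3 * sqrt(pe * (1 - pe) / n_perm))
  })
  do.call(rbind, rows)
}

#' QAP type-I error study
#'
#' Repeatedly simulates two independent groups of fish with uncorrelated
#' genes, builds both sample co-expression matrices and records whether the
#' QAP test (at `alpha`) declares them associated.
#'
#' @param n_rep number of repetitions.
#' @param n_fish fish per matrix.
#' @param n_genes genes per matrix.
#' @param alpha rejection threshold.
#' @param n_perm permutation budget (exhaustive mode engages when
#'   `factorial(n_genes) <= n_perm`).
#' @param seed master seed.
#' @return list: `rejection_rate`, `p_values`.
#' @export
qap_type1_study <- function(n_rep = 1000, n_fish = 12, n_genes = 6,
                            alpha = 0.05, n_perm = 5000, seed = 1) {
  ps <- vapply(seq_len(n_rep), function(i) {
    XY <- with_substream(seed, paste0("qap-null:", i), {
      list(matrix(stats::rnorm(n_fish * n_genes), n_fish),
           matrix(stats::rnorm(n_fish * n_genes), n_fish))
    })
    A <- stats::cor(XY[[1]]); B <- stats::cor(XY[[2]])
    dimnames(A) <- dimnames(B) <- list(paste0("g", seq_len(n_genes)),
                                       paste0("g", seq_len(n_genes)))
    qap_correlation(A, B, n_perm = n_perm,
                    seed = substream_seed(seed, paste0("mc:", i)))$p
  }, numeric(1))
  list(rejection_rate = mean(ps < alpha), p_values = ps)
}

#' qPCR parameter-recovery study
#'
#' Forward-simulates noiseless dilution series at several true efficiencies
#' and measures how well efficiency, cycle-threshold spacing and quantity
#' ratios are recovered by the curve-fitting pipeline.
#'
#' @param E_true efficiencies studied.
#' @param dilution_logs log10 dilution steps (0 = undiluted).
#' @param n_cycles cycles simulated (long enough to reach plateau at the
#'   deepest dilution).
#' @return data frame with one row per reaction: `E_true`, `dilution_log`,
#'   `E_hat`, `CT`, `R0`, `ratio_rel_error` (recovered vs true quantity
#'   ratio to the undiluted reaction), and for E = 1 the CT spacing columns.
#' @export
qpcr_recovery_study <- function(E_true = c(0.8, 0.9, 1.0),
                                dilution_logs = 0:4, n_cycles = 50) {
  rows <- list()
  for (E in E_true) {
    k <- default_kinetics()
    k$E_true <- E; k$noise_sd <- 0; k$n_cycles <- n_cycles
    q <- 10^(-dilution_logs)
    curves <- simulate_amplification_curves(q, k, seed = 1)
    meas <- lapply(split(curves, curves$reaction_id), function(cc) {
      estimate_efficiency_ct(cc, fit_amplification(cc))
    })
    meas <- meas[order(names(meas))]
    R0 <- vapply(meas, `[[`, numeric(1), "R0")
    CT <- vapply(meas, `[[`, numeric(1), "CT")
    Eh <- vapply(meas, `[[`, numeric(1), "E")
    rows[[as.character(E)]] <- data.frame(
      E_true = E, dilution_log = dilution_logs, E_hat = Eh, CT = CT, R0 = R0,
      ratio_rel_error = R0 / R0[1] / (q / q[1]) - 1,
      ct_spacing = c(NA, diff(CT)), row.names = NULL)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Mixed-model contrast calibration study
#'
#' Replicated simulation at the default study conditions (group sizes
#' 12/11/12/10, five nuclei, six genes). One gene is left at zero effect to
#' measure the per-contrast type-I rate of the planned comparisons; another
#' receives a one-residual-SD winner shift in Dm to measure sign recovery
#' and power of the winner-vs-control contrast there.
#'
#' @param n_rep number of replicate studies.
#' @param seed master seed.
#' @param alpha contrast rejection threshold.
#' @param shift_sd injected shift in units of the residual SD.
#' @param null_gene,shift_gene genes carrying the null and shifted effect.
#' @return list: `type1_rate` (pooled over all null-gene contrasts),
#'   `sign_recovery` (fraction of replicates with a positive
#'   winner-minus-control estimate), `power` (correct sign and p < alpha),
#'   `n_rep`.
#' @export
lmm_calibration_study <- function(n_rep = 500, seed = 1, alpha = 0.05,
                                  shift_sd = 1, null_gene = "bdnf",
                                  shift_gene = "npas4") {
  design <- study_design()
  effects <- default_effects(design, null = TRUE)
  effects$delta["winner", "Dm", shift_gene] <-
    shift_sd * effects$sigma_resid
  null_p <- vector("list", n_rep)
  sign_ok <- p_shift <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    tab <- simulate_study(design, effects,
                          seed = substream_seed(seed, paste0("lmm:", i)),
                          curves = FALSE)$expression_true
    f0 <- fit_lmm_contrasts(tab, null_gene, omnibus = FALSE,
                            effect_sizes = FALSE)
    null_p[[i]] <- f0$contrasts$p
    f1 <- fit_lmm_contrasts(tab, shift_gene, omnibus = FALSE,
                            effect_sizes = FALSE)
    cc <- f1$contrasts
    row <- cc[cc$pair == "control vs winner" & cc$nucleus == "Dm", ]
    sign_ok[i] <- row$estimate < 0  # winner above control
    p_shift[i] <- row$p
  }
  list(type1_rate = mean(unlist(null_p) < alpha),
       sign_recovery = mean(sign_ok),
       power = mean(sign_ok & p_shift < alpha),
       n_rep = n_rep)
}

#' Neurogenomic-state recovery study
#'
#' Simulates studies in which two treatments share one strong co-expression
#' truth and a third carries an unrelated one (12 fish per group, six
#' genes), then asks how often [partition_states()] groups the sharing pair
#' together and separates the third.
#'
#' @param n_rep replicate studies.
#' @param seed master seed.
#' @param alpha,n_perm QAP settings.
#' @return list: `recovery_rate`, `n_rep`.
#' @export
state_recovery_study <- function(n_rep = 200, seed = 1, alpha = 0.05,
                                 n_perm = 5000) {
  design <- study_design(n_control = 12, n_mirror = 12, n_winner = 12,
                         n_loser = 2, nuclei = "Dm")
  shared <- coexpr_archetype(21, design$genes)
  distinct <- coexpr_archetype(22, design$genes)
  coex <- list(control = list(Dm = shared), mirror = list(Dm = shared),
               winner = list(Dm = distinct), loser = list(Dm = distinct))
  effects <- effect_spec(design, mu = matrix(0, 1, 6),
                         delta = array(0, c(4, 1, 6)), coexpression = coex)
  hits <- vapply(seq_len(n_rep), function(i) {
    rs <- substream_seed(seed, paste0("state:", i))
    tab <- simulate_study(design, effects, seed = rs,
                          curves = FALSE)$expression_true
    ms <- list(control = coexpression_matrix(tab, "control", "Dm"),
               mirror = coexpression_matrix(tab, "mirror", "Dm"),
               winner = coexpression_matrix(tab, "winner", "Dm"))
    part <- suppressWarnings(
      partition_states(ms, axis = "treatments", alpha = alpha,
                       n_perm = n_perm, seed = rs))
    lab <- part$labels
    length(lab) == 3 && lab[["control"]] == lab[["mirror"]] &&
      lab[["winner"]] != lab[["control"]]
  }, logical(1))
  list(recovery_rate = mean(hits), n_rep = n_rep)
}
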