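# Independent oracles used to validate package implementations. These are
# deliberately written from the definitions, not by calling package code.

# Sequential Grubbs-style brute force for the generalized ESD procedure:
# each iteration recomputed from scratch on the surviving values.
brute_force_esd <- function(x, alpha = 0.05, max_out) {
  n0 <- length(x)
  keep <- rep(TRUE, n0)
  order_removed <- integer(0)
  stats_R <- numeric(0)
  crit <- numeric(0)
  for (step in seq_len(max_out)) {
    xs <- x[keep]
    n <- length(xs)
    if (stats::sd(xs) == 0 || !is.finite(stats::sd(xs))) break
    devs <- abs(xs - mean(xs)) / stats::sd(xs)
    worst_local <- which.max(devs)
    worst_global <- which(keep)[worst_local]
    stats_R <- c(stats_R, devs[worst_local])
    pp <- 1 - alpha / (2 * n)
    tt <- stats::qt(pp, n - 2)
    crit <- c(crit, tt * (n - 1) / sqrt(n * (n - 2 + tt^2)))
    order_removed <- c(order_removed, worst_global)
    keep[worst_global] <- FALSE
  }
  k <- 0
  for (i in seq_along(stats_R)) if (stats_R[i] > crit[i]) k <- i
  list(n_outliers = k, outliers = order_removed[seq_len(k)])
}

# Direct QAP statistic for one permutation, from the definition.
qap_r_for_perm <- function(A, B, perm) {
  Bp <- B[perm, perm]
  ut <- upper.tri(A)
  stats::cor(A[ut], Bp[ut])
}

# Pure four-parameter logistic generator (for fit-recovery tests).
make_logistic_curve <- function(b, L, m, k, cycles = 1:40) {
  data.frame(cycle = cycles,
             fluorescence = b + L / (1 + exp(-k * (cycles - m))))
}

# A small random symmetric "correlation-like" matrix with unit diagonal.
random_symmetric_matrix <- function(g, genes = paste0("g", seq_len(g))) {
  M <- matrix(stats::runif(g * g, -1, 1), g, g)
  M <- (M + t(M)) / 2
  diag(M) <- 1
  dimnames(M) <- list(genes, genes)
  M
}

# Quick latent-only study for statistical tests.
quick_study <- function(seed, design = study_design(),
                        effects = default_effects(design, null = TRUE), ...) {
  simulate_study(design, effects, seed = seed, curves = FALSE, ...)
}
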