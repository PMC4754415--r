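#' Fit a four-parameter logistic to one amplification curve
#'
#' Nonlinear least-squares fit of
#' \eqn{F(c) = b + L / (1 + \exp(-k(c - m)))} with baseline `b`, amplitude
#' `L`, midpoint cycle `m` and rate `k`, using Levenberg–Marquardt with
#' start values anchored on curve quantiles. Curves without usable dynamic
#' range are flagged `no_amplification` and carry no fit values.
#'
#' @param curve data frame with columns `cycle` (strictly increasing,
#'   >= 20 values) and `fluorescence`.
#' @param min_range minimum dynamic range (max - min fluorescence) below
#'   which a curve is declared non-amplifying.
#' @return list of class `amp_fit`: `baseline`, `amplitude`, `midpoint`,
#'   `rate`, `rms_residual`, `flags` (character vector), `ok`.
#' @export
fit_amplification <- function(curve, min_range = 10) {
  cyc <- curve$cycle; fl <- curve$fluorescence
  if (length(cyc) < 20) stop("need at least 20 cycles")
  if (is.unsorted(cyc, strictly = TRUE)) stop("cycles must be strictly increasing")
  if (length(fl) != length(cyc)) stop("cycle/fluorescence length mismatch")
  empty <- list(baseline = NA_real_, amplitude = NA_real_,
                midpoint = NA_real_, rate = NA_real_,
                rms_residual = NA_real_, flags = "no_amplification",
                ok = FALSE)
  class(empty) <- "amp_fit"
  if (max(fl) - min(fl) < min_range) return(empty)

  b0 <- mean(fl[1:3]); L0 <- max(fl) - b0
  crossing <- function(frac) {
    target <- b0 + frac * L0
    i <- which(fl >= target)[1]
    if (is.na(i) || i == 1) return(cyc[1])
    cyc[i - 1] + (target - fl[i - 1]) / (fl[i] - fl[i - 1]) *
      (cyc[i] - cyc[i - 1])
  }
  m0 <- crossing(0.5)
  k0 <- 2 * log(3) / max(crossing(0.75) - crossing(0.25), 0.5)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      fl ~ b + L / (1 + exp(-k * (cyc - m))),
      start = list(b = b0, L = L0, m = m0, k = k0),
      lower = c(b = -Inf, L = 0, m = min(cyc) - 10, k = 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    empty$flags <- "fit_failed"
    return(empty)
  }
  co <- stats::coef(fit)
  out <- list(baseline = unname(co["b"]), amplitude = unname(co["L"]),
              midpoint = unname(co["m"]), rate = unname(co["k"]),
              rms_residual = sqrt(mean(stats::resid(fit)^2)),
              flags = character(0), ok = TRUE)
  class(out) <- "amp_fit"
  out
}

#' Estimate amplification efficiency and cycle threshold
#'
#' The cycle threshold is threshold-free: the fractional cycle of maximum
#' second derivative of the fitted logistic, \eqn{CT = m - \log(2+\sqrt 3)/k}.
#' Efficiency is estimated from the exponential window — the cycles where the
#' background-subtracted signal lies between 5% and 50% of the fitted
#' amplitude — as \eqn{E = e^{slope} - 1} from the regression of
#' log(background-subtracted fluorescence) on cycle. Background is the mean
#' of the earliest cycles, which is far more accurate than the symmetric-
#' logistic baseline parameter when the true chemistry saturates
#' asymmetrically. Estimates above 1.1 are clipped with a flag; windows
#' shorter than 3 cycles are flagged `unreliable_efficiency`.
#'
#' @param curve data frame with `cycle` and `fluorescence`.
#' @param fit an accepted [fit_amplification()] result.
#' @param window numeric length-2, exponential-window bounds as fractions of
#'   the fitted amplitude.
#' @param n_background number of earliest cycles averaged as background.
#' @return list of class `qpcr_measurement`: `E`, `CT`, `R0`, `rms_residual`,
#'   `flags`, `ok`. `R0` is computed in the log domain as
#'   \eqn{\exp(-CT \log(1+E))}.
#' @export
estimate_efficiency_ct <- function(curve, fit, window = c(0.05, 0.5),
                                   n_background = 5) {
  if (!fit$ok) stop("efficiency estimation requires an accepted fit")
  cyc <- curve$cycle; fl <- curve$fluorescence
  flags <- fit$flags
  bg <- mean(fl[seq_len(n_background)])
  s <- fl - bg
  frac <- s / fit$amplitude
  idx <- which(frac >= window[1] & frac <= window[2] & s > 0)
  ct <- fit$midpoint - log(2 + sqrt(3)) / fit$rate
  if (length(idx) < 3) {
    flags <- c(flags, "unreliable_efficiency")
    # fall back on the fitted logistic rate
    E <- exp(fit$rate) - 1
  } else {
    slope <- stats::coef(stats::lm(log(s[idx]) ~ cyc[idx]))[[2]]
    E <- exp(slope) - 1
  }
  if (is.na(E) || E <= 0) {
    flags <- c(flags, "nonpositive_efficiency")
    return(structure(list(E = NA_real_, CT = NA_real_, R0 = NA_real_,
                          rms_residual = fit$rms_residual, flags = flags,
                          ok = FALSE), class = "qpcr_measurement"))
  }
  if (E > 1.1) {
    warning("estimated efficiency ", format(E, digits = 3),
            " clipped to 1.1")
    flags <- c(flags, "efficiency_clipped")
    E <- 1.1
  }
  if (ct < min(cyc) || ct > max(cyc)) flags <- c(flags, "ct_out_of_range")
  ok <- !any(flags %in% c("ct_out_of_range"))
  structure(list(E = E, CT = ct, R0 = relative_quantity(E, ct),
                 rms_residual = fit$rms_residual, flags = flags, ok = ok),
            class = "qpcr_measurement")
}

#' Relative initial template concentration
#'
#' \eqn{R_0 = (1+E)^{-CT}}, evaluated in the log domain
#' (`exp(-CT * log1p(E))`) so that late thresholds (CT > 35) do not
#' underflow prematurely.
#'
#' @param E amplification efficiency, `>= 0` (1 = perfect doubling).
#' @param CT cycle threshold, `> 0` (fractional cycles).
#' @return relative initial template concentration (arbitrary units).
#' @examples
#' relative_quantity(1, 10)   # 2^-10
#' relative_quantity(0, 30)   # 1
#' @export
relative_quantity <- function(E, CT) {
  if (any(E < 0)) stop("efficiency must be non-negative")
  if (any(CT <= 0)) stop("CT must be positive")
  exp(-CT * log1p(E))
}

#' Quantify a table of amplification curves
#'
#' Runs [fit_amplification()] and [estimate_efficiency_ct()] on every
#' reaction of a long curve table and returns one measurement row per
#' reaction together with QC flags.
#'
#' @param curves long data frame: `reaction_id`, `fish_id`, `nucleus`,
#'   `gene`, `cycle`, `fluorescence`.
#' @param min_range passed to [fit_amplification()].
#' @return data frame: reaction metadata plus `E`, `CT`, `R0`,
#'   `rms_residual`, `flags` (";"-joined), `ok`.
#' @export
quantify_curves <- function(curves, min_range = 10) {
  stopifnot(all(c("reaction_id", "fish_id", "nucleus", "gene", "cycle",
                  "fluorescence") %in% names(curves)))
  ids <- unique(curves$reaction_id)
  split_idx <- split(seq_len(nrow(curves)), curves$reaction_id)
  rows <- lapply(ids, function(id) {
    cc <- curves[split_idx[[id]], ]
    cc <- cc[order(cc$cycle), ]
    meta <- cc[1, c("reaction_id", "fish_id", "nucleus", "gene")]
    fit <- fit_amplification(cc, min_range = min_range)
    if (!fit$ok) {
      return(cbind(meta, data.frame(E = NA_real_, CT = NA_real_,
                                    R0 = NA_real_, rms_residual = NA_real_,
                                    flags = paste(fit$flags, collapse = ";"),
                                    ok = FALSE)))
    }
    m <- estimate_efficiency_ct(cc, fit)
    cbind(meta, data.frame(E = m$E, CT = m$CT, R0 = m$R0,
                           rms_residual = m$rms_residual,
                           flags = paste(m$flags, collapse = ";"),
                           ok = m$ok))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Normalize target quantities to the reference gene
#'
#' For each fish x nucleus cell, divides every target gene's relative initial
#' template concentration by the same cell's reference-gene value. Flagged
#' reactions are dropped (and logged via warning); cells whose reference
#' reaction is missing or rejected are emitted as missing entirely.
#'
#' @param measurements output of [quantify_curves()] (or a pre-quantified
#'   table with `fish_id`, `nucleus`, `gene`, `E`, `CT` — `R0` and `ok` are
#'   then derived).
#' @param reference_gene name of the reference gene.
#' @param fish optional fish table (`fish_id`, `dyad_id`, `treatment`) merged
#'   into the output.
#' @return expression table: one row per fish x nucleus x target gene with
#'   `relative_expression = R0_target / R0_reference` (positive), plus
#'   metadata columns when `fish` is given.
#' @export
normalize_expression <- function(measurements, reference_gene,
                                 fish = NULL) {
  m <- measurements
  if (!"R0" %in% names(m)) m$R0 <- relative_quantity(m$E, m$CT)
  if (!"ok" %in% names(m)) m$ok <- TRUE
  m <- m[!is.na(m$R0) & m$ok, ]
  ref <- m[m$gene == reference_gene, c("fish_id", "nucleus", "R0")]
  names(ref)[3] <- "R0_reference"
  if (any(duplicated(ref[, c("fish_id", "nucleus")])))
    stop("multiple accepted reference reactions in one fish x nucleus cell")
  tg <- m[m$gene != reference_gene, c("fish_id", "nucleus", "gene", "R0")]
  out <- merge(tg, ref, by = c("fish_id", "nucleus"), all.x = TRUE)
  n_missing <- sum(is.na(out$R0_reference))
  if (n_missing > 0) {
    warning(n_missing, " target reactions dropped: missing reference ",
            "reaction in their fish x nucleus cell")
    out <- out[!is.na(out$R0_reference), ]
  }
  out$relative_expression <- out$R0 / out$R0_reference
  out <- out[, c("fish_id", "nucleus", "gene", "relative_expression")]
  if (!is.null(fish)) {
    out <- merge(out, fish[, c("fish_id", "dyad_id", "treatment")],
                 by = "fish_id")
    out <- out[, c("fish_id", "dyad_id", "treatment", "nucleus", "gene",
                   "relative_expression")]
  }
  out <- out[order(out$fish_id, out$nucleus, out$gene), ]
  rownames(out) <- NULL
  out
}
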