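#' Mixed-model planned contrasts for one gene
#'
#' Fits, for a single gene, the linear mixed model
#' `log(expression) ~ treatment * nucleus + (1 | subject) + (1 | dyad)`
#' where the subject intercept crosses nuclei within a fish and the dyad
#' intercept is shared by the winner and loser of a real-opponent contest
#' (mirror-fighters and controls each form their own singleton dyad level,
#' so the component is identified by the real dyads only). Omnibus F tests
#' (Satterthwaite denominator df) are reported for treatment, nucleus and
#' their interaction; planned pairwise treatment comparisons within each
#' nucleus are reported as `z = estimate / SE` with normal-theory two-sided
#' p-values, unadjusted for multiplicity. Each contrast carries Cohen's
#' effect size computed from the cell data: \eqn{d_z} on dyad-paired
#' differences for winner-vs-loser, \eqn{d_s} otherwise.
#'
#' Singular fits are handled by refitting without the near-zero variance
#' component(s) (down to ordinary least squares), with the decision logged in
#' the returned `notes`.
#'
#' @param table screened expression table: `fish_id`, `dyad_id`, `treatment`,
#'   `nucleus`, `gene`, `relative_expression`.
#' @param gene gene analyzed (one at a time).
#' @param log_scale analyze `log(relative_expression)` (default; matches the
#'   multiplicative error structure of qPCR ratios). Set `FALSE` for the raw
#'   scale.
#' @param omnibus compute omnibus F tests (skippable for speed in
#'   simulation studies; the plain maximum-likelihood machinery is then used
#'   for the contrasts).
#' @param effect_sizes attach Cohen's d to each contrast (skippable for
#'   speed in simulation studies).
#' @return list: `contrasts` (gene, nucleus, pair, estimate, SE, z, p, d,
#'   d_type, magnitude), `omnibus` (term, F, df1, df2, p) or `NULL`,
#'   `model`, `notes`.
#' @export
fit_lmm_contrasts <- function(table, gene, log_scale = TRUE, omnibus = TRUE,
                              effect_sizes = TRUE) {
  d <- table[table$gene == gene, , drop = FALSE]
  if (!nrow(d)) stop("no rows for gene ", gene)
  d$y <- if (log_scale) log(d$relative_expression) else d$relative_expression
  trt_levels <- intersect(c("control", "mirror", "winner", "loser"),
                          unique(d$treatment))
  d$treatment <- factor(d$treatment, levels = trt_levels)
  d$nucleus <- factor(d$nucleus, levels = unique(d$nucleus))
  # dyad grouping factor: real dyads shared, everyone else a singleton level
  d$dyad <- ifelse(d$treatment %in% c("winner", "loser"),
                   d$dyad_id, paste0("solo_", d$fish_id))
  notes <- character(0)

  # lmerTest (Satterthwaite machinery) only when omnibus F tests are wanted;
  # the cheaper lme4 fit gives identical contrast estimates and SEs
  fit_fun <- function(formula) {
    if (omnibus)
      suppressMessages(suppressWarnings(
        lmerTest::lmer(formula, data = d, REML = TRUE)))
    else
      suppressMessages(suppressWarnings(
        lme4::lmer(formula, data = d, REML = TRUE,
                   control = lme4::lmerControl(calc.derivs = FALSE,
                                               check.conv.singular = "ignore"))))
  }
  fit <- fit_fun(y ~ treatment * nucleus + (1 | fish_id) + (1 | dyad))
  if (lme4::isSingular(fit, tol = 1e-5)) {
    vc <- as.data.frame(lme4::VarCorr(fit))
    vc <- vc[vc$grp != "Residual", ]
    drop_grp <- vc$grp[vc$sdcor < 1e-4]
    keep <- setdiff(c("fish_id", "dyad"), drop_grp)
    notes <- c(notes, paste0("singular fit; dropped random effect(s): ",
                             paste(drop_grp, collapse = ", ")))
    if (length(keep) == 2) {
      # singular but neither component pinned at zero: keep the full fit
      notes <- c(notes, "no near-zero component; full fit retained")
    } else if (length(keep) == 1) {
      fit <- fit_fun(stats::as.formula(
        paste0("y ~ treatment * nucleus + (1 | ", keep, ")")))
    } else {
      fit <- stats::lm(y ~ treatment * nucleus, data = d)
    }
  }

  omni <- NULL
  if (omnibus) {
    if (inherits(fit, "lmerMod")) {
      an <- stats::anova(fit, type = 3)
      omni <- data.frame(term = rownames(an), F = an[["F value"]],
                         df1 = an[["NumDF"]], df2 = an[["DenDF"]],
                         p = an[["Pr(>F)"]], row.names = NULL)
    } else {
      an <- stats::anova(fit)
      an <- an[rownames(an) != "Residuals", ]
      omni <- data.frame(term = rownames(an), F = an[["F value"]],
                         df1 = an[["Df"]],
                         df2 = stats::df.residual(fit),
                         p = an[["Pr(>F)"]], row.names = NULL)
    }
  }

  emm <- emmeans::emmeans(fit, ~ treatment | nucleus, lmer.df = "asymptotic")
  ctr <- summary(emmeans::contrast(emm, method = "pairwise", adjust = "none"),
                 infer = FALSE)
  est <- ctr$estimate
  se <- ctr$SE
  z <- est / se
  res <- data.frame(gene = gene, nucleus = as.character(ctr$nucleus),
                    pair = gsub(" - ", " vs ", ctr$contrast),
                    estimate = est, SE = se, z = z,
                    p = 2 * stats::pnorm(-abs(z)))

  # effect sizes from the cell data
  res$d <- NA_real_; res$d_type <- NA_character_
  res$magnitude <- NA_character_
  if (effect_sizes) for (i in seq_len(nrow(res))) {
    parts <- strsplit(res$pair[i], " vs ", fixed = TRUE)[[1]]
    a <- d[d$treatment == parts[1] & d$nucleus == res$nucleus[i], ]
    b <- d[d$treatment == parts[2] & d$nucleus == res$nucleus[i], ]
    if (nrow(a) < 2 || nrow(b) < 2) next
    paired <- setequal(parts, c("winner", "loser"))
    es <- tryCatch(
      if (paired)
        cohens_d(a$y, b$y, paired = TRUE,
                 pair_key_x = a$dyad_id, pair_key_y = b$dyad_id)
      else cohens_d(a$y, b$y),
      error = function(e) NULL)
    if (!is.null(es)) {
      res$d[i] <- es$d
      res$d_type[i] <- es$d_type
      res$magnitude[i] <- es$magnitude
    }
  }
  list(contrasts = res, omnibus = omni, model = fit, notes = notes)
}
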