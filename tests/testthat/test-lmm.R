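make_expression_table <- function(seed, design = study_design(),
                                  effects = default_effects(design,
                                                            null = TRUE)) {
  simulate_study(design, effects, seed = seed,
                 curves = FALSE)$expression_true
}

test_that("with null random effects, contrasts equal raw cell-mean differences", {
  des <- study_design(n_control = 10, n_mirror = 10, n_winner = 10,
                      n_loser = 10)
  eff <- effect_spec(des, mu = default_effects(des)$mu,
                     delta = default_effects(des)$delta,
                     sigma_subject = 0, sigma_dyad = 0, sigma_resid = 0.5)
  tab <- simulate_study(des, eff, seed = 13, curves = FALSE)$expression_true
  res <- suppressWarnings(fit_lmm_contrasts(tab, "bdnf", omnibus = FALSE))
  d <- tab[tab$gene == "bdnf", ]
  d$y <- log(d$relative_expression)
  for (i in sample(nrow(res$contrasts), 8)) {
    row <- res$contrasts[i, ]
    parts <- strsplit(row$pair, " vs ")[[1]]
    cm <- mean(d$y[d$treatment == parts[1] & d$nucleus == row$nucleus]) -
      mean(d$y[d$treatment == parts[2] & d$nucleus == row$nucleus])
    expect_equal(row$estimate, cm, tolerance = 1e-6)
  }
})

test_that("winner-loser contrasts use dyad-paired d_z, others d_s", {
  tab <- make_expression_table(17)
  res <- fit_lmm_contrasts(tab, "npas4", omnibus = FALSE)
  cc <- res$contrasts
  wl <- cc[cc$pair == "winner vs loser", ]
  expect_true(all(wl$d_type == "d_z"))
  expect_true(all(cc$d_type[cc$pair != "winner vs loser"] == "d_s",
                  na.rm = TRUE))
  expect_true(all(cc$magnitude %in% c("negligible", "small", "medium",
                                      "large")))
  # z is estimate/SE with two-sided normal p
  expect_equal(cc$z, cc$estimate / cc$SE)
  expect_equal(cc$p, 2 * stats::pnorm(-abs(cc$z)))
})

test_that("contrast z-statistics are invariant to positive rescaling of expression", {
  tab <- make_expression_table(19)
  res1 <- fit_lmm_contrasts(tab, "wnt3", omnibus = FALSE)
  tab2 <- tab
  tab2$relative_expression <- tab2$relative_expression * 37.5
  res2 <- fit_lmm_contrasts(tab2, "wnt3", omnibus = FALSE)
  expect_equal(res1$contrasts$z, res2$contrasts$z, tolerance = 1e-6)
  expect_equal(res1$contrasts$estimate, res2$contrasts$estimate,
               tolerance = 1e-6)
})

test_that("omnibus table reports treatment, nucleus and interaction tests", {
  tab <- make_expression_table(23, effects = default_effects())
  res <- fit_lmm_contrasts(tab, "bdnf")
  expect_setequal(res$omnibus$term,
                  c("treatment", "nucleus", "treatment:nucleus"))
  expect_true(all(res$omnibus$p >= 0 & res$omnibus$p <= 1))
  # strong nucleus profile injected for bdnf: the nucleus effect is large
  expect_lt(res$omnibus$p[res$omnibus$term == "nucleus"], 1e-6)
})

test_that("singular fits drop the near-zero variance component and log it", {
  des <- study_design()
  eff <- effect_spec(des, mu = default_effects(des)$mu,
                     delta = default_effects(des)$delta * 0,
                     sigma_subject = 0, sigma_dyad = 0, sigma_resid = 0.4)
  tab <- simulate_study(des, eff, seed = 29, curves = FALSE)$expression_true
  res <- suppressWarnings(fit_lmm_contrasts(tab, "nlgn1", omnibus = FALSE))
  expect_true(length(res$notes) >= 1)
  expect_match(res$notes[1], "singular")
  expect_equal(nrow(res$contrasts), 6 * 5)  # 6 pairs x 5 nuclei
})

test_that("an injected shift is estimated without bias", {
  des <- study_design()
  eff <- default_effects(des, null = TRUE)
  eff$delta["winner", "Dm", "bdnf"] <- 0.5
  ests <- vapply(1:30, function(i) {
    tab <- simulate_study(des, eff, seed = 400 + i,
                          curves = FALSE)$expression_true
    res <- fit_lmm_contrasts(tab, "bdnf", omnibus = FALSE,
                             effect_sizes = FALSE)
    cc <- res$contrasts
    -cc$estimate[cc$pair == "control vs winner" & cc$nucleus == "Dm"]
  }, numeric(1))
  # mean error below 0.05 residual SD (sigma_resid = 0.5)
  expect_lt(abs(mean(ests) - 0.5), 0.05 * 0.5 + 3 * stats::sd(ests) / sqrt(30))
  expect_gt(mean(ests > 0), 0.9)
})
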