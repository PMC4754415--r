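test_that("default design yields 45 fish in 11 complete winner-loser dyads", {
  s <- quick_study(seed = 11)
  expect_equal(nrow(s$fish), 45)
  expect_equal(as.vector(table(s$fish$treatment)[c("control", "mirror",
                                                   "winner", "loser")]),
               c(10, 12, 12, 11))
  w <- s$fish[s$fish$treatment == "winner", ]
  l <- s$fish[s$fish$treatment == "loser", ]
  complete <- intersect(w$dyad_id, l$dyad_id)
  expect_length(complete, 11)
  # the surplus winner is explicitly flagged as a dropout pairing
  expect_equal(sum(w$partner_dropout), 1)
  expect_false(any(l$dyad_id %in% w$dyad_id[w$partner_dropout]))
  expect_false(anyDuplicated(s$fish$fish_id) > 0)
})

test_that("simulation is deterministic in the master seed and stable under subsetting", {
  a <- quick_study(seed = 5)
  b <- quick_study(seed = 5)
  expect_identical(a$truth, b$truth)
  expect_identical(a$behavior, b$behavior)
  expect_identical(a$cortisol, b$cortisol)
  c <- quick_study(seed = 6)
  expect_false(identical(a$truth$log_expression, c$truth$log_expression))
  # per-fish substreams: shrinking the control group leaves other fish
  # identical once ids match
  small <- quick_study(seed = 5, design = study_design(n_control = 2))
  shared <- intersect(small$fish$fish_id, a$fish$fish_id)
  shared_trt <- a$fish$treatment[match(shared, a$fish$fish_id)] ==
    small$fish$treatment[match(shared, small$fish$fish_id)]
  same_ids <- shared[shared_trt]
  ta <- a$truth[a$truth$fish_id %in% same_ids, ]
  ts <- small$truth[small$truth$fish_id %in% same_ids, ]
  expect_equal(ts$resid[match(paste(ta$fish_id, ta$nucleus, ta$gene),
                              paste(ts$fish_id, ts$nucleus, ts$gene))],
               ta$resid)
})

test_that("winner-loser pairs share their dyad intercept; controls have none", {
  s <- quick_study(seed = 7,
                   effects = effect_spec(study_design(),
                                         mu = default_effects()$mu,
                                         delta = default_effects()$delta * 0,
                                         sigma_dyad = 0.4))
  tr <- s$truth
  for (d in unique(tr$dyad_id[tr$treatment == "loser"])) {
    vals <- unique(tr$b_dyad[tr$dyad_id == d &
                               tr$treatment %in% c("winner", "loser")])
    expect_length(vals, 1)
  }
  expect_true(all(tr$b_dyad[tr$treatment %in% c("control", "mirror")] == 0))
  expect_gt(stats::sd(tr$b_dyad[tr$treatment == "winner"]), 0)
})

test_that("non-PSD coexpression is rejected naming the offending condition", {
  des <- study_design()
  bad <- matrix(0.99, 6, 6); diag(bad) <- 1
  bad[1, 2] <- bad[2, 1] <- -0.99  # violates PSD
  coex <- default_effects(des)$coexpression
  coex[["winner"]][["Vs"]] <- bad
  expect_error(
    effect_spec(des, mu = default_effects()$mu,
                delta = default_effects()$delta, coexpression = coex),
    "positive semi-definite.*winner.*Vs|winner, Vs")
})

test_that("latent residual correlations converge to the specified coexpression", {
  des <- study_design(n_control = 2000, n_mirror = 2, n_winner = 2,
                      n_loser = 2, nuclei = "Dm")
  C <- coexpr_archetype(3, des$genes)
  coex <- stats::setNames(lapply(des$treatments, function(t)
    stats::setNames(list(C), "Dm")), des$treatments)
  eff <- effect_spec(des, mu = matrix(0, 1, 6), delta = array(0, c(4, 1, 6)),
                     sigma_subject = 0, sigma_dyad = 0, sigma_resid = 1,
                     coexpression = coex)
  s <- simulate_study(des, eff, seed = 21, curves = FALSE)
  tr <- s$truth[s$truth$treatment == "control", ]
  wide <- matrix(tr$resid, ncol = 6, byrow = TRUE)
  emp <- stats::cor(wide)
  expect_lt(max(abs(emp - C)), 0.1)
})

test_that("variance decomposition of latent expression matches the components", {
  des <- study_design(n_control = 2000, n_mirror = 2, n_winner = 2,
                      n_loser = 2, nuclei = "Dm")
  eff <- effect_spec(des, mu = matrix(0, 1, 6), delta = array(0, c(4, 1, 6)),
                     sigma_subject = 0.3, sigma_dyad = 0.2, sigma_resid = 0.5)
  s <- simulate_study(des, eff, seed = 22, curves = FALSE)
  tr <- s$truth[s$truth$treatment == "control" & s$truth$gene == "bdnf", ]
  # controls carry no dyad effect: variance = sigma_subject^2 + sigma_resid^2
  expect_equal(stats::var(tr$log_expression), 0.3^2 + 0.5^2, tolerance = 0.08)
})

test_that("behavioral streams obey the contest phenomenology", {
  s <- quick_study(seed = 8)
  ev <- s$behavior
  session <- s$design$interaction_minutes * 60
  expect_true(all(ev$time_s >= 0 & ev$time_s <= session))
  aggr <- c("bite", "chase", "strike"); subm <- c("freeze", "flee")
  res <- stats::setNames(s$resolution$resolution_time_s, s$resolution$dyad_id)
  for (i in which(s$fish$treatment == "loser")) {
    f <- s$fish[i, ]
    post <- ev[ev$fish_id == f$fish_id & ev$time_s > res[[f$dyad_id]], ]
    expect_true(all(post$behavior %in% subm))
  }
  for (i in which(s$fish$treatment == "winner")) {
    f <- s$fish[i, ]
    fe <- ev[ev$fish_id == f$fish_id, ]
    expect_true(all(fe$behavior %in% aggr))
  }
  mirror_ev <- ev[ev$fish_id %in% s$fish$fish_id[s$fish$treatment == "mirror"], ]
  expect_false(any(mirror_ev$behavior %in% subm))
  expect_true(all(is.na(
    s$resolution$resolution_time_s[!s$resolution$dyad_id %in%
                                     s$fish$dyad_id])))
  control_ev <- ev[ev$fish_id %in%
                     s$fish$fish_id[s$fish$treatment == "control"], ]
  expect_equal(nrow(control_ev), 0)
})

test_that("resolution times follow the configured distribution", {
  des <- study_design(n_winner = 50, n_loser = 50)
  s <- quick_study(seed = 31, design = des)
  rt <- s$resolution$resolution_time_s
  se <- stats::sd(rt) / sqrt(length(rt))
  expect_lt(abs(mean(rt) - 420), 3 * se + 1e-9)
})

test_that("amplification-curve edge cases behave", {
  k <- default_kinetics()
  k$E_true <- 1; k$noise_sd <- 0
  flat <- simulate_amplification_curves(0, k, seed = 1)
  expect_true(all(abs(flat$fluorescence - k$baseline) < 1e-9))
  up <- simulate_amplification_curves(1, k, seed = 1)
  expect_true(all(diff(up$fluorescence) >= -1e-9))
  expect_error(simulate_amplification_curves(-1, k, seed = 1),
               "non-negative")
  k$plateau <- -5
  expect_error(simulate_amplification_curves(1, k, seed = 1), "plateau")
})
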