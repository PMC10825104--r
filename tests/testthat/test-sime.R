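idif_truth_problem <- function(delta = 0.3) {
  fp <- feng_params(850, 22, 21, 4, 0.12, 0.01, delta)
  g <- human_frame_grid()
  cp <- feng_input(fp, g)
  regs <- lapply(1:6, function(i) {
    ct <- twotcm_forward(table_params(i), cp, R = 1)
    ct$label <- paste0("VOI", i)
    ct
  })
  wb <- twotcm_forward(table_params(7), cp, R = 1)
  wb$label <- "WB"
  anchors <- data.frame(time_min = c(28.5, 53.5),
                        conc = feng_input(fp, c(28.5, 53.5)))
  list(fp = fp, cp = cp, regs = regs, wb = wb, anchors = anchors)
}

test_that("SIME problems validate their inputs", {
  d <- idif_truth_problem()
  expect_error(sime_problem(d$wb, d$regs[1], d$anchors), "at least 2")
  expect_error(sime_problem(d$wb, d$regs,
                            data.frame(time_min = 70, conc = 10)),
               "scan window")
  expect_error(sime_problem(d$wb, d$regs,
                            data.frame(time_min = 30, conc = -1)),
               "positive")
  p <- sime_problem(d$wb, d$regs, d$anchors, R = 1, mode = "mdif")
  expect_equal(p$anchors$weight, c(1, 1))
  p2 <- sime_problem(d$wb, d$regs, d$anchors, R = 1, mode = "idif")
  expect_equal(p2$anchors$weight, c(10, 10))
})

test_that("free-parameter counts are 4n+4 (MDIF) and 4n+7 (IDIF)", {
  d <- idif_truth_problem()
  prob_m <- sime_problem(d$wb, d$regs, d$anchors, R = 1, mode = "mdif")
  prob_i <- sime_problem(d$wb, d$regs, d$anchors, R = 1, mode = "idif")
  # tiny iteration cap: only the structural layout matters here
  suppressWarnings({
    res_m <- fit_sime_mdif(prob_m, n_starts = 0, seed = 1, maxiter = 2)
    res_i <- fit_sime_idif(prob_i, n_starts = 0, seed = 1, maxiter = 2)
  })
  expect_equal(res_m$n_parameters, 28L)
  expect_equal(res_i$n_parameters, 31L)
  expect_length(res_m$region_params, 6L)
})

test_that("arrival delay is read off the whole-brain TAC rise", {
  g <- uniform_grid(5, 1 / 60)
  # step onset at 0.5 min
  v <- ifelse(g$mid_time < 0.5, 0, 10)
  expect_lt(abs(estimate_delay(tac(g, v)) - 0.5), 0.02)
  # reference simulation has no delay
  sim <- reference_simulation()
  expect_lt(estimate_delay(sim$wb_tac), 0.1)
  # shifting the curve by 20 s shifts the estimate by ~20 s
  d <- idif_truth_problem(delta = 0.3)
  d2 <- idif_truth_problem(delta = 0.3 + 20 / 60)
  shift <- estimate_delay(d2$wb) - estimate_delay(d$wb)
  expect_lt(abs(shift - 20 / 60), 0.05)
  # flat curves are rejected
  expect_error(estimate_delay(tac(g, rep(0, length(g)))), "flat")
})

test_that("the cost at the generating parameters is the anchor floor", {
  s <- reference_sime_fit()
  sim <- s$sim
  prob <- sime_problem(sim$wb_tac, sim$region_tacs, sim$anchors,
                       R = sim$R, mode = "mdif")
  tr <- sim$truth
  reg_true <- lapply(1:6, table_params)
  wb_true <- table_params(7)
  c0 <- sime_cost(prob, wb_true, reg_true)
  # anchors are read from the analytic input at frame mid-times, so the
  # floor is numerically zero on noiseless data
  expect_lt(c0, 1e-12)
  # and the truth is locally optimal: any perturbed parameter set costs more
  set.seed(11)
  for (i in 1:10) {
    fac <- 1 + stats::rnorm(4, sd = 0.03)
    wb_p <- micro_params(tr$K1[7] * fac[1], tr$k2[7] * fac[2],
                         tr$k3[7] * fac[3], tr$Vb[7] * fac[4])
    expect_gt(sime_cost(prob, wb_p, reg_true), c0)
  }
})

test_that("MDIF-SIME recovers all parameters from noiseless data", {
  s <- reference_sime_fit()
  tr <- s$sim$truth
  expect_true(s$fit$converged)
  expect_equal(s$fit$n_parameters, 28L)
  expect_lt(s$fit$cost, 1e-9)
  # whole-brain parameters to < 1 %
  wb <- s$fit$wb_params
  expect_lt(max(abs(c(wb$K1 / tr$K1[7], wb$k2 / tr$k2[7],
                      wb$k3 / tr$k3[7], wb$Vb / tr$Vb[7]) - 1)), 0.01)
  # jointly fitted regional parameters to < 1 %
  for (j in 1:6) {
    p <- s$fit$region_params[[j]]
    expect_lt(max(abs(c(p$K1 / tr$K1[j], p$k2 / tr$k2[j], p$k3 / tr$k3[j],
                        p$Vb / tr$Vb[j], p$Ki / tr$Ki[j]) - 1)), 0.01)
  }
  # constraint satisfaction: box bounds and K1 < k2 + k3 on every set
  for (p in c(list(wb), s$fit$region_params)) {
    expect_true(p$K1 < p$k2 + p$k3)
    expect_true(all(c(p$K1, p$k2, p$k3, p$Vb) >= 0.01 - 1e-9))
    expect_true(p$k2 <= 0.4 && p$k3 <= 0.2 && p$Vb <= 0.10 && p$K1 <= 0.2)
  }
  # the recovered input matches the true one
  cmp <- compare_curves(s$fit$input_function, s$sim$aif)
  expect_lt(abs(cmp$overall_ratio - 1), 0.001)
})

test_that("scaling the anchors scales the recovered input upward", {
  s <- reference_sime_fit()
  sim <- s$sim
  a2 <- sim$anchors
  a2$conc <- 1.10 * a2$conc
  prob2 <- sime_problem(sim$wb_tac, sim$region_tacs, a2, R = sim$R,
                        mode = "mdif")
  res2 <- fit_sime_mdif(prob2, n_starts = 2, seed = 1)
  auc <- function(x) compare_curves(x, sim$aif)$overall_ratio
  expect_gt(auc(res2$input_function), auc(s$fit$input_function))
})

test_that("IDIF-SIME recovers kinetics from exponential-model data", {
  d <- idif_truth_problem(delta = 0.3)
  prob <- sime_problem(d$wb, d$regs, d$anchors, R = 1, mode = "idif")
  res <- fit_sime_idif(prob, n_starts = 4, seed = 1)
  expect_equal(res$n_parameters, 31L)
  # delay is pinned by the WB-rise estimate
  expect_lt(abs(res$feng$delta - 0.3), 10 / 60)
  # regional Ki within a few percent; input AUC close to truth
  for (j in 1:6)
    expect_lt(abs(res$region_params[[j]]$Ki / ki_of(table_params(j)) - 1),
              0.05)
  expect_lt(abs(compare_curves(res$input_function, d$cp)$overall_ratio - 1),
            0.05)
  # a zero-amplitude input candidate is always worse than the fit
  zero_in <- feng_params(0, 0, 0, 4, 0.12, 0.01, res$feng$delta)
  expect_gt(sime_cost(prob, zero_in, res$region_params), res$cost)
})

test_that("anchors pin the scale: without them only the shape is identified", {
  # The noiseless anchor-free objective has an exact scaling ridge
  # (Cp -> c Cp with K1 -> K1 (1-Vb)/(c-Vb), Vb -> Vb/c reproduces every
  # tissue curve), so zero anchor weight must still fit the regions
  # perfectly while the input is recovered only up to a scale factor.
  d <- idif_truth_problem(delta = 0.3)
  prob0 <- sime_problem(d$wb, d$regs,
                        cbind(d$anchors, weight = 0), R = 1, mode = "idif")
  res0 <- fit_sime_idif(prob0, n_starts = 4, seed = 1)
  expect_lt(res0$cost, 1e-9)
  sel <- d$cp$grid$mid_time > 1
  ratio <- res0$input_function$values[sel] / d$cp$values[sel]
  expect_lt(stats::sd(ratio) / mean(ratio), 0.02)
})
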