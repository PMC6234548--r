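small_cohort_td <- function(n = 150, seed = 13, transition = c(1, 2)) {
  sim <- simulate_cohort(hivlike_scenario(n), seed = seed)
  extract_transition_dataset(sim$dataset, transition)
}

test_that("a single root-only forest tree averages to its own Nelson-Aalen", {
  td <- small_cohort_td()
  ens <- fit_msrsf(td, B = 1, n0 = 1e6, seed = 42)
  expect_length(ens$trees, 1L)
  expect_length(ens$trees[[1]]$nodes, 1L)
  root <- ens$trees[[1]]$nodes[[1]]
  ch <- ensemble_hazard(ens, td$data[1, ])
  expect_identical(ch$times, root$times)
  expect_identical(ch$dA, root$dA)
  # ensemble cumulative hazard is nondecreasing for any covariate vector
  ens2 <- fit_msrsf(td, B = 8, n0 = 6, seed = 43)
  tt <- seq(0, td$tau, length.out = 40)
  for (i in c(1, 7, 20)) {
    A <- predict_ensemble_cumhaz(ens2, td$data[i, ], tt)
    expect_true(all(diff(A[1, ]) >= -1e-12))
    S <- predict_ensemble_survival(ens2, td$data[i, ], tt)
    expect_true(all(diff(S[1, ]) <= 1e-12))
    expect_true(all(S >= 0 & S <= 1))
  }
})

test_that("conditional survival of a root-only tree is the KM conditional law", {
  td <- small_cohort_td(n = 120, seed = 5)
  ens <- fit_msrist(td, M = 1, n_cycles = 1, nmin = 1e6, seed = 9)
  cfix <- sort(td$data$time[td$data$status == 1])[5] + 1e-6
  law <- conditional_survival(ens, td$data[1, ], c = cfix)
  sf <- survival::survfit(survival::Surv(time, status) ~ 1, data = td$data)
  km_at <- function(t) {
    i <- findInterval(t, sf$time)
    if (i == 0) 1 else sf$surv[i]
  }
  s_c <- km_at(cfix)
  for (k in seq_along(law$times)) {
    tk <- law$times[k]
    prev <- if (k == 1) cfix else law$times[k - 1]
    expect_equal(law$prob[k], (km_at(prev) - km_at(tk)) / s_c,
                 tolerance = 1e-10)
  }
  expect_equal(law$p_tau, km_at(max(law$times)) / s_c, tolerance = 1e-10)
  expect_equal(sum(law$prob) + law$p_tau, 1, tolerance = 1e-10)
  expect_true(all(law$times > cfix))
})

test_that("conditional survival handles forced and empty outcomes", {
  # no events after c -> all mass on tau-censoring
  td <- make_td(time = c(1, 2, 3, 9, 9.5), status = c(1, 1, 1, 0, 0),
                covariates = data.frame(x = rnorm(5)))
  ens <- fit_msrist(td, M = 1, n_cycles = 1, nmin = 1e6, seed = 1)
  law <- conditional_survival(ens, td$data[1, ], c = 5)
  expect_length(law$times, 0L)
  expect_equal(law$p_tau, 1)
  expect_error(conditional_survival(ens, td$data[1, ], c = 100), "precede")
})

test_that("one-step imputation preserves observed rows and draws the right law", {
  td <- small_cohort_td(n = 200, seed = 23)
  ens <- fit_msrist(td, M = 5, n_cycles = 2, seed = 3)
  imp <- impute_one_step(td, ens, seed = 11)
  # provenance partitions the rows
  expect_equal(sum(table(imp$data$provenance)), nrow(td$data))
  expect_equal(sum(imp$data$provenance == "original" & td$data$status == 1),
               sum(td$data$status == 1))
  obs <- td$data$status == 1
  expect_identical(imp$data$time[obs], td$data$time[obs])
  expect_identical(imp$data$status[obs], td$data$status[obs])
  # imputed events strictly exceed their original censoring times
  iev <- imp$data$provenance == "imputed_event"
  expect_true(all(imp$data$time[iev] > td$data$time[iev]))
  expect_true(all(imp$data$status[iev] == 1))
  itau <- imp$data$provenance == "imputed_tau"
  expect_true(all(imp$data$time[itau] == td$tau))
  expect_true(all(imp$data$status[itau] == 0))
  # nothing to impute -> identity
  td_full <- td
  keep <- td$data$status == 1
  td_full$data <- td$data[keep, , drop = FALSE]
  td_full$tau <- max(td_full$data$time)
  imp2 <- impute_one_step(td_full, ens, seed = 2)
  expect_identical(imp2$data$time, td_full$data$time)
  expect_identical(imp2$data$status, td_full$data$status)
  expect_true(all(imp2$data$provenance == "original"))
})

test_that("imputation draws match the conditional law empirically", {
  td <- small_cohort_td(n = 80, seed = 29)
  ens <- fit_msrist(td, M = 3, n_cycles = 1, nmin = 20, seed = 7)
  laws <- msforest:::censored_conditional_laws(ens, td)
  k <- 1L
  i <- laws$rows[k]
  law <- conditional_survival(ens, td$data[i, ], c = td$data$time[i])
  # aggregate the law into three buckets around its median event time
  med <- law$times[max(1L, findInterval(0.5, cumsum(law$prob)))]
  p_early <- sum(law$prob[law$times <= med])
  p_late <- sum(law$prob[law$times > med])
  draws <- sapply(1:4000, function(s) {
    one <- msforest:::draw_imputation(td, laws, seed = s)
    if (one$data$provenance[i] == "imputed_tau") "tau"
    else if (one$data$time[i] <= med) "early" else "late"
  })
  expect_equal(mean(draws == "early"), p_early, tolerance = 0.025)
  expect_equal(mean(draws == "late"), p_late, tolerance = 0.025)
  expect_equal(mean(draws == "tau"), law$p_tau, tolerance = 0.025)
})

test_that("MSRIST degenerates to the raw Nelson-Aalen and is seed-deterministic", {
  td <- small_cohort_td(n = 100, seed = 37)
  ens <- fit_msrist(td, M = 1, n_cycles = 1, nmin = 1e6, seed = 4)
  na <- nelson_aalen(td)
  ch <- ensemble_hazard(ens, td$data[1, ])
  expect_identical(ch$times, na$times)
  expect_identical(ch$dA, na$dA)
  expect_error(fit_msrist(td, M = 0), "at least 1")
  expect_error(fit_msrist(td, M = 1, n_cycles = 0), "at least 1")
  expect_error(fit_msrsf(td, B = 0), "at least 1")
})

test_that("fully observed data make every MSRIST cycle a refit of the same rows", {
  td <- small_cohort_td(n = 150, seed = 41)
  keep <- td$data$status == 1
  td$data <- td$data[keep, , drop = FALSE]
  td$tau <- max(td$data$time)
  e3 <- fit_msrist(td, M = 3, n_cycles = 3, seed = 50)
  # imputation is a no-op, so every cycle's trees are grown on the raw
  # rows: each tree's root bookkeeping matches the dataset exactly
  for (tr in e3$trees) {
    expect_equal(tr$nodes[[1]]$n, nrow(td$data))
    expect_equal(tr$nodes[[1]]$n_events, nrow(td$data))
  }
  # and a root-only refit reproduces the raw Nelson-Aalen bitwise
  e1 <- fit_msrist(td, M = 2, n_cycles = 4, nmin = 1e6, seed = 51)
  na <- nelson_aalen(td)
  ch <- ensemble_hazard(e1, td$data[1, ])
  expect_identical(ch$times, na$times)
  expect_equal(ch$dA, na$dA, tolerance = 1e-12)
})

test_that("fitted ensembles serialize deterministically under a repeated seed", {
  sim <- simulate_cohort(hivlike_scenario(120), seed = 53)
  m1 <- fit_multistate_model(sim$dataset, method = "msrist", M = 3,
                             n_cycles = 2, seed = 77)
  m2 <- fit_multistate_model(sim$dataset, method = "msrist", M = 3,
                             n_cycles = 2, seed = 77)
  expect_identical(serialize_model(m1), serialize_model(m2))
  f1 <- fit_multistate_model(sim$dataset, method = "msrsf", B = 5, seed = 78)
  f2 <- fit_multistate_model(sim$dataset, method = "msrsf", B = 5, seed = 78)
  expect_identical(serialize_model(f1), serialize_model(f2))
  # and survives a save/load round trip
  tmp <- withr::local_tempfile(fileext = ".json")
  save_model(m1, tmp)
  expect_identical(serialize_model(load_model(tmp)), serialize_model(m1))
})

test_that("multistate predictions are probability vectors and match AJ for stumps", {
  sim <- simulate_cohort(constant_rate_scenario(250,
    censoring = list(type = "uniform", max = 12)), seed = 59)
  ds <- sim$dataset
  bl <- fit_multistate_model(ds, method = "baseline")
  aj <- aalen_johansen(fit_all_nelson_aalen(ds), ds$structure)
  for (t in c(1, 3, 6)) {
    pv <- predict_transition_probabilities(bl, data.frame(), s = 0, t = t)
    expect_equal(unname(pv), transition_probability(aj, 0, t)[1, ],
                 tolerance = 1e-12)
    expect_equal(sum(pv), 1, tolerance = 1e-10)
  }
  # degenerate horizon: unit vector at the current state
  pv0 <- predict_transition_probabilities(bl, data.frame(), s = 2, t = 2)
  expect_equal(unname(pv0), c(1, 0, 0))
  pva <- predict_transition_probabilities(bl, data.frame(), s = 2, t = 5,
                                          current_state = 3)
  expect_equal(unname(pva), c(0, 0, 1))
  expect_error(predict_transition_probabilities(bl, data.frame(), s = 3, t = 2),
               "precede")
})

test_that("a strong covariate effect orders predicted transition probabilities", {
  # binary covariate doubling the illness intensity: P12(0,t | z=1) should
  # exceed P12(0,t | z=0) in nearly every seeded fit
  scen <- simulation_scenario(
    illness_death_structure(),
    baselines = list("1->2" = list(type = "exp", rate = 0.15),
                     "1->3" = list(type = "exp", rate = 0.08),
                     "2->3" = list(type = "exp", rate = 0.25)),
    betas = list("1->2" = list(x = log(2))),
    covariates = list(x = list(kind = "binary", p = 0.5),
                      noise = list(kind = "normal", mean = 0, sd = 1)),
    censoring = list(type = "uniform", max = 12), n_subjects = 300)
  wins <- 0L
  for (r in 1:20) {
    sim <- simulate_cohort(scen, seed = 100 + r)
    m <- fit_multistate_model(sim$dataset, method = "msrsf", B = 20,
                              seed = 200 + r)
    p1 <- predict_transition_probabilities(m, data.frame(x = 1, noise = 0),
                                           s = 0, t = 4)
    p0 <- predict_transition_probabilities(m, data.frame(x = 0, noise = 0),
                                           s = 0, t = 4)
    if (p1[["state2"]] > p0[["state2"]]) wins <- wins + 1L
  }
  expect_gte(wins, 18L)
})
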