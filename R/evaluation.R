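#' IPCW Brier curve for state occupation
#'
#' At every grid time s, the Brier prediction error for state h is the
#' weighted mean of (I\{x_i(s) = h\} - pi_h(s | z_i))^2 across test
#' subjects, with inverse-probability-of-censoring weights: a subject past
#' an observed terminal transition before s contributes with weight
#' 1/G(t_i-), a subject still under observation at s with weight 1/G(s),
#' and a subject censored before s contributes nothing. On a test set
#' without censoring G is identically 1 and the weights all reduce to 1
#' (the complete-data estimator).
#'
#' @param pihat numeric matrix of predicted occupation probabilities,
#'   one row per test subject (ordered as \code{sort(unique(id))}), one
#'   column per grid time.
#' @param test a \code{multistate_dataset}.
#' @param state state label h whose occupation is scored.
#' @param grid evaluation times (study clock), nondecreasing.
#' @param G a \code{censoring_survival} for the test set; computed from
#'   \code{test} (marginal reverse Kaplan-Meier of last-contact times)
#'   when omitted.
#' @param weight_cap weights are truncated at this value; grid points
#'   where G = 0 have their terms dropped, with the count recorded.
#' @return object of class \code{brier_curve}: list with \code{state},
#'   \code{grid}, \code{values}, \code{integrated} (trapezoid over the
#'   grid, normalized by its span) and \code{n_dropped}.
#' @export
brier_curve <- function(pihat, test, state, grid, G = NULL,
                        weight_cap = 20) {
  stopifnot(inherits(test, "multistate_dataset"))
  ids <- sort(unique(test$records$id))
  pihat <- as.matrix(pihat)
  if (nrow(pihat) != length(ids) || ncol(pihat) != length(grid))
    stop("pihat must be n_subjects x n_grid")
  last <- do.call(rbind, lapply(ids, function(sid) {
    rr <- test$records[test$records$id == sid, , drop = FALSE]
    data.frame(t_last = rr$exit[nrow(rr)], absorbed = rr$status[nrow(rr)] == 1)
  }))
  if (is.null(G))
    G <- censoring_survival(list(time = last$t_last,
                                 status = as.integer(last$absorbed)))
  occ <- vapply(ids, function(sid) state_at(test, sid, grid),
                numeric(length(grid)))
  occ <- matrix(occ, nrow = length(grid))  # grid x subjects
  values <- numeric(length(grid))
  n_dropped <- 0L
  n <- length(ids)
  g_tminus <- censoring_at(G, last$t_last, left = TRUE)
  for (k in seq_along(grid)) {
    s <- grid[k]
    w <- numeric(n)
    past <- last$t_last <= s
    w[past & last$absorbed] <- 1 / g_tminus[past & last$absorbed]
    gs <- censoring_at(G, s)
    w[!past] <- if (gs > 0) 1 / gs else Inf
    bad <- !is.finite(w)
    n_dropped <- n_dropped + sum(bad)
    w[bad] <- 0
    w <- pmin(w, weight_cap)
    ind <- as.numeric(!is.na(occ[k, ]) & occ[k, ] == state)
    ind[is.na(occ[k, ]) ] <- 0  # weight is 0 there anyway
    values[k] <- sum(w * (ind - pihat[, k])^2) / n
  }
  structure(list(state = state, grid = grid, values = values,
                 integrated = trapezoid_mean(grid, values),
                 n_dropped = n_dropped),
            class = "brier_curve")
}

trapezoid_mean <- function(grid, values) {
  if (length(grid) < 2L) return(values[1L])
  span <- max(grid) - min(grid)
  if (span <= 0) return(values[1L])
  sum(diff(grid) * (utils::head(values, -1L) + utils::tail(values, -1L)) / 2) / span
}

#' @export
print.brier_curve <- function(x, ...) {
  cat("Brier curve for state ", x$state, ": ", length(x$grid),
      " grid points, IBS = ", format(x$integrated), "\n", sep = "")
  invisible(x)
}

# IPCW Brier for a single transition dataset: outcome is occupation of the
# destination state on the transition's clock (event = transitioned).
# surv: matrix of predicted event-free probabilities, rows = td rows,
# cols = grid. Subjects not yet at risk at s (delayed entry) are excluded
# from that grid point's mean.
transition_brier <- function(surv, td, grid, G = NULL, weight_cap = 20) {
  dat <- td$data
  if (is.null(G)) G <- censoring_survival(td)
  pihat <- 1 - as.matrix(surv)
  n_dropped <- 0L
  g_tminus <- censoring_at(G, dat$time, left = TRUE)
  values <- vapply(seq_along(grid), function(k) {
    s <- grid[k]
    at_risk <- dat$entry <= s
    w <- numeric(nrow(dat))
    past_event <- dat$time <= s & dat$status == 1L
    w[past_event] <- 1 / g_tminus[past_event]
    gs <- censoring_at(G, s)
    still <- dat$time > s
    w[still] <- if (gs > 0) 1 / gs else Inf
    bad <- !is.finite(w)
    n_dropped <<- n_dropped + sum(bad)
    w[bad] <- 0
    w <- pmin(w, weight_cap) * at_risk
    ind <- as.numeric(past_event)
    n_eff <- sum(at_risk)
    if (n_eff == 0) return(NA_real_)
    sum(w * (ind - pihat[, k])^2) / n_eff
  }, numeric(1))
  structure(list(state = td$transition[2L], grid = grid, values = values,
                 integrated = trapezoid_mean(grid, values),
                 n_dropped = n_dropped),
            class = "brier_curve")
}

#' Harrell concordance index
#'
#' Fraction of usable pairs whose predicted risk ordering agrees with the
#' observed event ordering. A pair is usable when its ordering is
#' determinable under censoring: the member with the earlier time has an
#' observed event and the times differ. Score ties count 1/2.
#'
#' @param scores predicted risk scores (higher = riskier, expected to
#'   fail earlier).
#' @param time observed times.
#' @param status 1 = event, 0 = censored.
#' @return concordance in [0, 1], with attribute \code{n_pairs};
#'   \code{NA} when no pair is usable.
#' @export
concordance_index <- function(scores, time, status) {
  n <- length(time)
  stopifnot(length(scores) == n, length(status) == n)
  ti <- matrix(time, n, n); tj <- t(ti)
  di <- matrix(status == 1L, n, n)
  usable <- di & ti < tj
  si <- matrix(scores, n, n); sj <- t(si)
  conc <- sum(usable & si > sj)
  ties <- sum(usable & si == sj)
  n_pairs <- sum(usable)
  out <- if (n_pairs == 0L) NA_real_ else (conc + 0.5 * ties) / n_pairs
  attr(out, "n_pairs") <- n_pairs
  out
}

# evaluation grid for a transition dataset: event times up to the
# tau_quantile of observed times (guards the IPCW tail), bracketed by 0
eval_grid <- function(td, tau_quantile = 0.9) {
  tau_star <- as.numeric(stats::quantile(td$data$time, tau_quantile))
  ev <- sort(unique(td$data$time[td$data$status == 1L]))
  unique(c(0, ev[ev <= tau_star], tau_star))
}

#' Evaluate a fitted ensemble on a test transition dataset
#'
#' Computes the IPCW integrated Brier score over [0, tau*] (tau* = the
#' \code{tau_quantile} of observed test times) and the Harrell
#' concordance index, using the ensemble cumulative hazard at
#' \code{horizon} (default: median observed event time of the test set)
#' as the risk score.
#'
#' @param ensemble a \code{transition_ensemble}.
#' @param td_test test \code{transition_dataset} for the same transition.
#' @param horizon risk-score horizon.
#' @param tau_quantile upper quantile bounding the Brier grid.
#' @return list with \code{ibs}, \code{cindex}, \code{brier}
#'   (\code{brier_curve}) and \code{n_events}.
#' @export
evaluate_ensemble <- function(ensemble, td_test, horizon = NULL,
                              tau_quantile = 0.9) {
  stopifnot(inherits(td_test, "transition_dataset"))
  dat <- td_test$data
  if (sum(dat$status) == 0L)
    return(list(ibs = NA_real_, cindex = NA_real_, brier = NULL,
                n_events = 0L))
  grid <- eval_grid(td_test, tau_quantile)
  Z <- dat[names(ensemble$covariates)]
  S <- predict_ensemble_survival(ensemble, Z, grid)
  bc <- transition_brier(S, td_test, grid)
  if (is.null(horizon))
    horizon <- stats::median(dat$time[dat$status == 1L])
  risk <- predict_ensemble_cumhaz(ensemble, Z, horizon)[, 1L]
  ci <- concordance_index(risk, dat$time, dat$status)
  list(ibs = bc$integrated, cindex = as.numeric(ci), brier = bc,
       n_events = sum(dat$status))
}

#' Random-daughter variable importance
#'
#' The VIMP of covariate x is the increase in prediction error (IPCW
#' integrated Brier score by default) when test cases are dropped down the
#' trees with every split on x replaced by a uniformly random daughter
#' assignment, averaged over \code{n_repeats} randomization draws. A
#' covariate never used in any split has VIMP exactly 0.
#'
#' @param model a \code{multistate_model}, or a single
#'   \code{transition_ensemble}.
#' @param test the matching test data: a \code{multistate_dataset} for a
#'   model (per-transition datasets are extracted with the model's
#'   \code{markov_mode}), or a \code{transition_dataset} for an ensemble.
#' @param covariates covariate names to score (default: all in the
#'   schema, including \code{d} when sojourn-augmented).
#' @param n_repeats randomization draws (default 10).
#' @param seed integer seed for the random routing.
#' @param tau_quantile upper quantile bounding the Brier grid.
#' @return data.frame with columns \code{transition}, \code{covariate},
#'   \code{vimp}, \code{se} (Monte Carlo spread over repeats),
#'   \code{error_intact}, \code{error_randomized}.
#' @export
vimp <- function(model, test, covariates = NULL, n_repeats = 10L,
                 seed = NULL, tau_quantile = 0.9) {
  if (inherits(model, "transition_ensemble")) {
    stopifnot(inherits(test, "transition_dataset"))
    return(vimp_ensemble(model, test, covariates, n_repeats, seed,
                         tau_quantile))
  }
  stopifnot(inherits(model, "multistate_model"),
            inherits(test, "multistate_dataset"))
  if (is.null(seed)) seed <- sample.int(2^31 - 2L, 1L)
  out <- list()
  for (k in names(model$ensembles)) {
    hj <- parse_trans_key(k)
    td <- extract_transition_dataset(test, hj,
                                     augment_sojourn =
                                       model$markov_mode == "sojourn_augmented")
    res <- vimp_ensemble(model$ensembles[[k]], td, covariates, n_repeats,
                         derive_seed(seed, match(k, names(model$ensembles))),
                         tau_quantile)
    out[[k]] <- res
  }
  do.call(rbind, out)
}

vimp_ensemble <- function(ensemble, td_test, covariates, n_repeats, seed,
                          tau_quantile) {
  if (is.null(covariates)) covariates <- names(ensemble$covariates)
  if (is.null(seed)) seed <- sample.int(2^31 - 2L, 1L)
  dat <- td_test$data
  key <- trans_key(ensemble$transition[1L], ensemble$transition[2L])
  if (sum(dat$status) == 0L)
    return(data.frame(transition = key, covariate = covariates,
                      vimp = NA_real_, se = NA_real_,
                      error_intact = NA_real_, error_randomized = NA_real_))
  grid <- eval_grid(td_test, tau_quantile)
  G <- censoring_survival(td_test)
  Z <- dat[names(ensemble$covariates)]
  err_of <- function(randomize_on = NULL) {
    S <- predict_ensemble_survival(ensemble, Z, grid, randomize_on)
    transition_brier(S, td_test, grid, G)$integrated
  }
  err0 <- err_of()
  used <- unique(unlist(lapply(ensemble$trees, tree_split_vars)))
  res <- lapply(covariates, function(x) {
    if (!x %in% used)
      return(data.frame(transition = key, covariate = x, vimp = 0,
                        se = 0, error_intact = err0,
                        error_randomized = err0))
    errs <- vapply(seq_len(n_repeats), function(r) {
      set.seed(derive_seed(seed, 131 * match(x, covariates) + r))
      err_of(randomize_on = x)
    }, numeric(1))
    data.frame(transition = key, covariate = x,
               vimp = mean(errs) - err0,
               se = stats::sd(errs) / sqrt(n_repeats),
               error_intact = err0, error_randomized = mean(errs))
  })
  do.call(rbind, res)
}

# subject-level subset of a multistate dataset (records stay chained)
subset_subjects <- function(dataset, ids) {
  out <- dataset
  out$records <- dataset$records[dataset$records$id %in% ids, , drop = FALSE]
  rownames(out$records) <- NULL
  out$tau <- max(out$records$exit)
  out
}

#' Repeated train/test evaluation harness
#'
#' Repeatedly splits the cohort into training and testing sets at the
#' subject level (all records of a subject stay together), fits each
#' configured model on the training set, evaluates the IPCW integrated
#' Brier score and concordance index per transition on the test set, and
#' summarizes mean and standard deviation per method, transition and
#' metric. A repeat whose test split has no events for some transition is
#' recorded as missing for that cell.
#'
#' @param dataset a \code{multistate_dataset}.
#' @param configs named list of model configurations; each is a list with
#'   \code{method} (\code{"msrist"}, \code{"msrsf"}, \code{"baseline"}),
#'   optionally \code{markov_mode}, and hyperparameters for
#'   [fit_multistate_model()].
#' @param n_repeats number of random splits.
#' @param split_fraction training fraction (default 0.67); the training
#'   set has \code{floor(split_fraction * n_subjects)} subjects.
#' @param seed master seed.
#' @param tau_quantile upper quantile bounding the Brier grid.
#' @return list with \code{summary} (data.frame: method, transition,
#'   metric, mean, sd, n_effective) and \code{details} (per-repeat long
#'   data.frame).
#' @export
repeated_holdout <- function(dataset, configs, n_repeats = 1L,
                             split_fraction = 0.67, seed = NULL,
                             tau_quantile = 0.9) {
  stopifnot(inherits(dataset, "multistate_dataset"),
            n_repeats >= 1L, split_fraction > 0, split_fraction < 1)
  if (is.null(seed)) seed <- sample.int(2^31 - 2L, 1L)
  if (is.null(names(configs)))
    names(configs) <- vapply(configs, `[[`, character(1), "method")
  ids <- sort(unique(dataset$records$id))
  n_train <- floor(split_fraction * length(ids))
  keys <- structure_keys(dataset$structure)
  details <- list()
  for (r in seq_len(n_repeats)) {
    set.seed(derive_seed(seed, r))
    train_ids <- sample(ids, n_train)
    train <- subset_subjects(dataset, train_ids)
    test <- subset_subjects(dataset, setdiff(ids, train_ids))
    for (ci in seq_along(configs)) {
      cfg <- configs[[ci]]
      mm <- cfg$markov_mode %||% "markov"
      pars <- cfg[setdiff(names(cfg), c("method", "markov_mode"))]
      model <- do.call(fit_multistate_model,
                       c(list(dataset = train, method = cfg$method,
                              markov_mode = mm,
                              seed = derive_seed(seed, 1000L * r + ci)),
                         pars))
      for (k in keys) {
        hj <- parse_trans_key(k)
        td_test <- extract_transition_dataset(test, hj,
                                              augment_sojourn = mm == "sojourn_augmented")
        td_train <- extract_transition_dataset(train, hj,
                                               augment_sojourn = mm == "sojourn_augmented")
        horizon <- if (td_n_events(td_train) > 0L)
          stats::median(td_train$data$time[td_train$data$status == 1L]) else NULL
        ev <- evaluate_ensemble(model$ensembles[[k]], td_test,
                                horizon = horizon,
                                tau_quantile = tau_quantile)
        details[[length(details) + 1L]] <-
          data.frame(repeat_ = r, method = names(configs)[ci],
                     transition = k, ibs = ev$ibs, cindex = ev$cindex,
                     n_test_events = ev$n_events)
      }
    }
  }
  details <- do.call(rbind, details)
  long <- rbind(
    data.frame(method = details$method, transition = details$transition,
               metric = "ibs", value = details$ibs),
    data.frame(method = details$method, transition = details$transition,
               metric = "cindex", value = details$cindex))
  agg <- stats::aggregate(value ~ method + transition + metric, long,
                          function(v) c(mean = mean(v, na.rm = TRUE),
                                        sd = stats::sd(v, na.rm = TRUE),
                                        n = sum(!is.na(v))),
                          na.action = stats::na.pass)
  summary <- data.frame(method = agg$method, transition = agg$transition,
                        metric = agg$metric,
                        mean = agg$value[, "mean"], sd = agg$value[, "sd"],
                        n_effective = agg$value[, "n"])
  list(summary = summary, details = details)
}
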