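#' Define a simulation scenario with known transition intensities
#'
#' A scenario fixes everything the cohort simulator needs: the transition
#' structure, a baseline intensity per transition (constant rate or
#' Weibull, on that transition's clock), log-linear covariate effects on
#' each intensity, an optional log-linear effect of the state-entry time
#' \code{d} (which makes the process semi-Markov), the covariate
#' generators, and the censoring mechanism.
#'
#' @param structure a [transition_structure()].
#' @param baselines named list by \code{"h->j"}: either
#'   \code{list(type = "exp", rate)} or
#'   \code{list(type = "weibull", shape, scale)}.
#' @param betas named list by \code{"h->j"} of log-hazard-ratio vectors,
#'   named by covariate. For a factor covariate the element may itself be
#'   a named vector of per-level offsets (unnamed levels get 0).
#' @param d_coefs named numeric vector by \code{"h->j"}: log-linear effect
#'   of the entry time into the origin state on the intensity (0 =
#'   Markov).
#' @param covariates named list of generator specs:
#'   \code{list(kind = "binary", p)}, \code{list(kind = "categorical",
#'   levels, probs)}, or \code{list(kind = "normal", mean, sd)}.
#' @param censoring one of \code{list(type = "none")},
#'   \code{list(type = "admin", tau)}, \code{list(type = "uniform", max)}
#'   (staggered-entry administrative censoring),
#'   \code{list(type = "exponential", rate)}, or
#'   \code{list(type = "mixed", tau, rate)}.
#' @param n_subjects cohort size.
#' @param label scenario name.
#' @return object of class \code{simulation_scenario}.
#' @seealso [simulate_cohort()], [hivlike_scenario()],
#'   [markov_check_scenario()]
#' @export
simulation_scenario <- function(structure, baselines, betas = NULL,
                                d_coefs = NULL, covariates = list(),
                                censoring = list(type = "none"),
                                n_subjects = 500L, label = "scenario") {
  stopifnot(inherits(structure, "transition_structure"))
  keys <- structure_keys(structure)
  if (!setequal(names(baselines), keys))
    stop("baselines must be given for exactly the transitions: ",
         paste(keys, collapse = ", "))
  for (k in keys) {
    b <- baselines[[k]]
    ok <- (identical(b$type, "exp") && is.numeric(b$rate) && b$rate >= 0) ||
      (identical(b$type, "weibull") && b$shape > 0 && b$scale > 0)
    if (!ok) stop("invalid baseline for ", k)
  }
  dc <- stats::setNames(rep(0, length(keys)), keys)
  if (!is.null(d_coefs)) dc[names(d_coefs)] <- d_coefs
  bad <- names(dc)[dc != 0 & vapply(names(dc), function(k)
    parse_trans_key(k)[1L] == structure$initial, logical(1))]
  if (length(bad))
    stop("d_coefs on transitions out of the initial state (d = 0) are vacuous: ",
         paste(bad, collapse = ", "))
  structure(list(structure = structure, baselines = baselines,
                 betas = betas %||% list(), d_coefs = dc,
                 covariates = covariates, censoring = censoring,
                 n_subjects = as.integer(n_subjects), label = label),
            class = "simulation_scenario")
}

# baseline cumulative hazard and its inverse, on the transition clock
base_cumhaz <- function(b, t) {
  if (b$type == "exp") b$rate * t else (t / b$scale)^b$shape
}
base_cumhaz_inv <- function(b, a) {
  if (b$type == "exp") {
    if (b$rate == 0) rep(Inf, length(a)) else a / b$rate
  } else b$scale * a^(1 / b$shape)
}
base_rate <- function(b, t) {
  if (b$type == "exp") rep(b$rate, length(t))
  else (b$shape / b$scale) * (t / b$scale)^(b$shape - 1)
}

# linear predictor of a transition for a covariate data.frame
scenario_lp <- function(scenario, key, Z) {
  lp <- numeric(nrow(Z))
  bb <- scenario$betas[[key]]
  for (v in names(bb)) {
    x <- Z[[v]]
    if (is.factor(x) || is.character(x)) {
      co <- bb[[v]]
      lp <- lp + ifelse(as.character(x) %in% names(co),
                        co[as.character(x)], 0)
    } else {
      lp <- lp + bb[[v]] * x
    }
  }
  lp
}

draw_covariates <- function(scenario, n) {
  out <- list()
  for (v in names(scenario$covariates)) {
    sp <- scenario$covariates[[v]]
    out[[v]] <- switch(sp$kind,
      binary = stats::rbinom(n, 1L, sp$p),
      categorical = factor(sample(sp$levels, n, replace = TRUE,
                                  prob = sp$probs), levels = sp$levels),
      normal = stats::rnorm(n, sp$mean %||% 0, sp$sd %||% 1),
      stop("unknown covariate kind: ", sp$kind))
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

draw_censoring <- function(cens, n) {
  switch(cens$type,
         none = rep(Inf, n),
         admin = rep(cens$tau, n),
         uniform = stats::runif(n, 0, cens$max),
         exponential = stats::rexp(n, cens$rate),
         mixed = pmin(cens$tau, stats::rexp(n, cens$rate)),
         stop("unknown censoring type: ", cens$type))
}

# latent transition time out of state h for subjects entering h at d:
# inverse-transform draw from intensity base(t) * exp(lp + d_coef * d) on
# the transition's clock. Returns the sojourn duration.
draw_sojourn <- function(b, clock, lp, d) {
  e <- stats::rexp(length(lp))
  a <- e / exp(lp)
  if (clock == "forward") {
    base_cumhaz_inv(b, base_cumhaz(b, d) + a) - d
  } else {
    base_cumhaz_inv(b, a)
  }
}

#' Simulate a multistate cohort with known ground truth
#'
#' Generates, per subject: covariates; from each occupied state, competing
#' latent transition times with intensity
#' \code{alpha_hj(t) * exp(beta' z + d_coef * d)} on the transition's
#' clock (inverse-transform sampling, the minimum wins); then independent
#' right censoring. Emits the chained long-format records plus the latent
#' uncensored path table for oracle checks.
#'
#' @param scenario a [simulation_scenario()].
#' @param seed integer seed.
#' @return list with \code{dataset} (a \code{multistate_dataset}) and
#'   \code{truth} (data.frame of the latent uncensored records:
#'   \code{id, from, to, entry, exit}).
#' @export
simulate_cohort <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  if (!is.null(seed)) set.seed(seed)
  st <- scenario$structure
  n <- scenario$n_subjects
  Z <- draw_covariates(scenario, n)
  cens <- draw_censoring(scenario$censoring, n)
  cens <- pmax(cens, 1e-9)

  # latent paths, stage by stage (structures are acyclic)
  state <- rep(st$initial, n)
  entry <- rep(0, n)
  alive <- rep(TRUE, n)   # not yet absorbed (latently)
  latent <- list()
  keys <- structure_keys(st)
  repeat {
    active_states <- unique(state[alive])
    active_states <- setdiff(active_states, st$absorbing)
    if (length(active_states) == 0L) break
    h <- active_states[1L]
    idx <- which(alive & state == h)
    outs <- keys[vapply(keys, function(k) parse_trans_key(k)[1L] == h,
                        logical(1))]
    soj <- matrix(Inf, length(idx), length(outs))
    for (oi in seq_along(outs)) {
      k <- outs[oi]
      lp <- scenario_lp(scenario, k, Z[idx, , drop = FALSE]) +
        scenario$d_coefs[[k]] * entry[idx]
      soj[, oi] <- draw_sojourn(scenario$baselines[[k]],
                                unname(st$clock[k]), lp, entry[idx])
    }
    wmin <- apply(soj, 1L, which.min)
    w <- soj[cbind(seq_along(idx), wmin)]
    if (any(!is.finite(w)))
      stop("state ", h, " has no exit intensity; subjects would remain forever")
    dest <- vapply(outs[wmin], function(k) parse_trans_key(k)[2L], integer(1))
    latent[[length(latent) + 1L]] <-
      data.frame(id = idx, from = h, to = dest, entry = entry[idx],
                 exit = entry[idx] + w)
    state[idx] <- dest
    entry[idx] <- entry[idx] + w
  }
  truth <- do.call(rbind, latent)
  truth <- truth[order(truth$id, truth$entry), , drop = FALSE]
  rownames(truth) <- NULL

  # apply censoring: keep sojourns entered before C, truncate the one
  # containing C into a censored record
  ci <- cens[truth$id]
  keep <- truth$entry < ci
  rec <- truth[keep, , drop = FALSE]
  ck <- cens[rec$id]
  cut <- rec$exit > ck
  rec$to[cut] <- 0L
  rec$exit[cut] <- ck[cut]
  rec$status <- as.integer(!cut)
  rec <- cbind(rec, Z[rec$id, , drop = FALSE])
  ds <- multistate_dataset(rec, st)
  list(dataset = ds, truth = truth)
}

#' Ground-truth transition probabilities of a scenario
#'
#' For Markov scenarios on an illness-death (or 2-3 state progressive)
#' structure, evaluates the closed-form solution of the forward Kolmogorov
#' equations at the covariate vector \code{z}
#' ([illness_death_closed_form()] with intensities
#' \code{alpha_hj(t) exp(beta' z)}). Otherwise (or on request) falls back
#' to forward Monte Carlo simulation of latent paths at fixed \code{z}.
#'
#' @param scenario a [simulation_scenario()].
#' @param z single covariate row (may be NULL when the scenario has no
#'   covariate effects).
#' @param s,t interval on the study clock.
#' @param method \code{"auto"}, \code{"closed_form"} or
#'   \code{"montecarlo"}.
#' @param current_state state occupied at \code{s} (default initial).
#' @param n_sim Monte Carlo path count.
#' @param seed Monte Carlo seed.
#' @return named probability vector over the states.
#' @export
true_transition_probability <- function(scenario, z = NULL, s, t,
                                        method = c("auto", "closed_form",
                                                   "montecarlo"),
                                        current_state = NULL,
                                        n_sim = 1e5, seed = NULL) {
  method <- match.arg(method)
  st <- scenario$structure
  h <- current_state %||% st$initial
  N <- st$n_states
  state_names <- paste0("state", seq_len(N))
  if (t == s) {
    out <- stats::setNames(rep(0, N), state_names); out[h] <- 1
    return(out)
  }
  markov_ok <- all(vapply(structure_keys(st), function(k) {
    clockf <- unname(st$clock[k]) == "forward"
    constant <- scenario$baselines[[k]]$type == "exp"
    scenario$d_coefs[[k]] == 0 && (clockf || constant)
  }, logical(1)))
  closed_ok <- markov_ok && N <= 3L && h == 1L &&
    all(apply(st$transitions, 1L, function(r)
      trans_key(r[1L], r[2L]) %in% c("1->2", "1->3", "2->3")))
  if (method == "auto") method <- if (closed_ok) "closed_form" else "montecarlo"
  if (method == "closed_form") {
    if (!closed_ok)
      stop("closed form requires a Markov illness-death/progressive scenario from state 1")
    rate_fn <- function(k) {
      if (!k %in% structure_keys(st)) return(function(u) rep(0, length(u)))
      lp <- if (is.null(z)) 0 else
        scenario_lp(scenario, k, as.data.frame(z))
      b <- scenario$baselines[[k]]
      function(u) base_rate(b, u) * exp(lp)
    }
    p <- illness_death_closed_form(rate_fn("1->2"), rate_fn("1->3"),
                                   rate_fn("2->3"), s, t)
    out <- stats::setNames(rep(0, N), state_names)
    out["state1"] <- p[["P11"]]
    if (N >= 2L) out["state2"] <- p[["P12"]]
    if (N >= 3L) out["state3"] <- p[["P13"]]
    return(out)
  }
  # Monte Carlo: simulate latent paths at fixed z, no censoring
  sc <- scenario
  sc$n_subjects <- as.integer(n_sim)
  sc$censoring <- list(type = "none")
  if (!is.null(z)) {
    zdf <- as.data.frame(z)
    sc$covariates <- list()
    for (v in names(zdf)) {
      xv <- zdf[[v]][1L]
      sc$covariates[[v]] <- if (is.factor(xv) || is.character(xv))
        list(kind = "categorical", levels = as.character(xv), probs = 1)
      else list(kind = "normal", mean = as.numeric(xv), sd = 0)
    }
  }
  sim <- simulate_cohort(sc, seed = seed)
  at_s <- occupancy_from_truth(sim$truth, s, sc$n_subjects, st$initial)
  at_t <- occupancy_from_truth(sim$truth, t, sc$n_subjects, st$initial)
  sel <- at_s == h
  if (!any(sel)) stop("no simulated path occupies state ", h, " at time ", s)
  out <- stats::setNames(tabulate(at_t[sel], N) / sum(sel), state_names)
  out
}

# vectorized state occupancy at time u from the latent (uncensored) record
# table: a subject occupies `to` of their last record with exit <= u, else
# the initial state. Rows are sorted by (id, entry), so within a subject
# the last matching assignment wins.
occupancy_from_truth <- function(truth, u, n, initial = 1L) {
  occ <- rep(as.integer(initial), n)
  sel <- truth$exit <= u
  ids <- truth$id[sel]
  tos <- truth$to[sel]
  # last row per id among sel (rows already in increasing entry order)
  last <- !duplicated(ids, fromLast = TRUE)
  occ[ids[last]] <- as.integer(tos[last])
  occ
}

#' HIV-like default scenario
#'
#' A progressive three-state cohort (infection, intermediate disease
#' stage, disease-related death) mirroring the shape of a ten-year
#' registry cohort: staggered-entry administrative censoring over a
#' 10-year window, roughly half the subjects experiencing the first
#' transition and roughly a quarter of those the second. Ten covariates
#' (six binary, one three-level categorical, three continuous), of which
#' three carry signal: a continuous immune-status marker (\code{cd4},
#' standardized; strongly protective against the first transition),
#' treatment (\code{haart}; protective for both transitions) and
#' co-infection (\code{tb}; harmful for the second transition). The second
#' transition runs on a reset clock (time since entering the intermediate
#' state).
#'
#' @param n_subjects cohort size (default 2473).
#' @return a \code{simulation_scenario}.
#' @export
hivlike_scenario <- function(n_subjects = 2473L) {
  st <- transition_structure(3L, rbind(c(1L, 2L), c(2L, 3L)),
                             clock = c("2->3" = "reset"))
  simulation_scenario(
    structure = st,
    baselines = list("1->2" = list(type = "exp", rate = 0.19),
                     "2->3" = list(type = "exp", rate = 0.078)),
    betas = list("1->2" = list(cd4 = -1.0, haart = -0.4),
                 "2->3" = list(haart = -0.6, tb = 0.9)),
    covariates = list(
      sex = list(kind = "binary", p = 0.78),
      prison = list(kind = "binary", p = 0.60),
      smoker = list(kind = "binary", p = 0.53),
      drug = list(kind = "binary", p = 0.50),
      tb = list(kind = "binary", p = 0.105),
      haart = list(kind = "binary", p = 0.42),
      marital = list(kind = "categorical",
                     levels = c("single", "married", "other"),
                     probs = c(0.40, 0.39, 0.21)),
      cd4 = list(kind = "normal", mean = 0, sd = 1),
      age = list(kind = "normal", mean = 34, sd = 10.4),
      bmi = list(kind = "normal", mean = 23, sd = 3)),
    censoring = list(type = "uniform", max = 10),
    n_subjects = n_subjects,
    label = "hivlike")
}

#' Scenario pair for the sojourn-time Markov check
#'
#' Progressive three-state cohort whose second transition runs on a reset
#' clock; with \code{sojourn_effect != 0} its intensity depends
#' log-linearly on the entry time \code{d} into the intermediate state
#' (strongly semi-Markov), with \code{sojourn_effect = 0} the matched
#' Markov scenario. Fitting the second transition with sojourn
#' augmentation and reading the variable importance of \code{d}
#' operationalizes a test of the Markov assumption: large VIMP of
#' \code{d} indicates the assumption fails.
#'
#' @param n_subjects cohort size.
#' @param sojourn_effect log-linear effect of \code{d} on the second
#'   transition's intensity (default 0.35 per time unit).
#' @return a \code{simulation_scenario}.
#' @export
markov_check_scenario <- function(n_subjects = 600L, sojourn_effect = 0.35) {
  st <- transition_structure(3L, rbind(c(1L, 2L), c(2L, 3L)),
                             clock = c("2->3" = "reset"))
  simulation_scenario(
    structure = st,
    baselines = list("1->2" = list(type = "exp", rate = 0.30),
                     "2->3" = list(type = "exp", rate = 0.08)),
    betas = list("1->2" = list(x1 = 0.5),
                 "2->3" = list(x1 = 0.3)),
    d_coefs = c("2->3" = sojourn_effect),
    covariates = list(
      x1 = list(kind = "binary", p = 0.5),
      x2 = list(kind = "binary", p = 0.5),
      x3 = list(kind = "normal", mean = 0, sd = 1),
      x4 = list(kind = "normal", mean = 0, sd = 1)),
    censoring = list(type = "uniform", max = 12),
    n_subjects = n_subjects,
    label = if (sojourn_effect != 0) "semi_markov_check" else "markov_check")
}

#' @export
print.simulation_scenario <- function(x, ...) {
  cat("Simulation scenario '", x$label, "': n = ", x$n_subjects, ", ",
      length(x$covariates), " covariates, censoring = ",
      x$censoring$type, "\n", sep = "")
  invisible(x)
}
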