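# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately naive (loops, enumeration, Riemann sums) so they
# share no code with the implementation paths they check.

# textbook two-sample log-rank: loop over unique event times, O-E and
# hypergeometric variance accumulated directly
logrank_oracle <- function(time, status, group, entry = NULL) {
  if (is.null(entry)) entry <- rep(0, length(time))
  ev <- sort(unique(time[status == 1]))
  O1 <- E1 <- V <- 0
  for (u in ev) {
    at_risk <- entry < u & time >= u
    Y <- sum(at_risk); Y1 <- sum(at_risk & group)
    d <- sum(time == u & status == 1)
    d1 <- sum(time == u & status == 1 & group)
    O1 <- O1 + d1
    E1 <- E1 + d * Y1 / Y
    if (Y > 1)
      V <- V + d * (Y1 / Y) * (1 - Y1 / Y) * (Y - d) / (Y - 1)
  }
  if (V <= 0) 0 else (O1 - E1)^2 / V
}

# exhaustive pair-enumeration concordance (Harrell convention)
cindex_oracle <- function(scores, time, status) {
  conc <- ties <- usable <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (status[i] == 1 && time[i] < time[j]) {
      usable <- usable + 1
      if (scores[i] > scores[j]) conc <- conc + 1
      else if (scores[i] == scores[j]) ties <- ties + 1
    }
  }
  if (usable == 0) NA_real_ else (conc + 0.5 * ties) / usable
}

# brute-force Riemann quadrature for the illness-death P12 integral
riemann_P12 <- function(a12, a13, a23, s, t, n_steps = 1e5) {
  u <- seq(s, t, length.out = n_steps + 1)
  du <- (t - s) / n_steps
  mid <- (u[-1] + u[-length(u)]) / 2
  # cumulative intensities on the midpoint grid by running sums
  A12 <- cumsum(a12(mid)) * du
  A13 <- cumsum(a13(mid)) * du
  A23 <- cumsum(a23(mid)) * du
  A23_t <- A23[length(A23)]
  P11su <- exp(-((A12 - a12(mid) * du / 2) + (A13 - a13(mid) * du / 2)))
  P22ut <- exp(-(A23_t - (A23 - a23(mid) * du / 2)))
  sum(P11su * a12(mid) * P22ut) * du
}

# four-subject illness-death toy cohort: two reach state 2 (one dies, one
# censored there), one goes 1->3 directly, one censored in state 1
toy_illness_death <- function() {
  rec <- rbind(
    data.frame(id = 1, from = 1, to = 2, entry = 0, exit = 2, status = 1),
    data.frame(id = 1, from = 2, to = 3, entry = 2, exit = 5, status = 1),
    data.frame(id = 2, from = 1, to = 2, entry = 0, exit = 3, status = 1),
    data.frame(id = 2, from = 2, to = 0, entry = 3, exit = 7, status = 0),
    data.frame(id = 3, from = 1, to = 3, entry = 0, exit = 4, status = 1),
    data.frame(id = 4, from = 1, to = 0, entry = 0, exit = 4, status = 0))
  rec$z <- c(0.1, 0.1, 0.9, 0.9, 0.5, 0.3)
  multistate_dataset(rec, illness_death_structure())
}

# build a transition_dataset directly from vectors (unit-test shortcut)
make_td <- function(time, status, entry = NULL, covariates = NULL,
                    transition = c(1L, 2L), clock = "reset",
                    cens_type = NULL) {
  n <- length(time)
  if (is.null(entry)) entry <- rep(0, n)
  if (is.null(cens_type))
    cens_type <- ifelse(status == 1, "event", "lost")
  dat <- data.frame(id = seq_len(n), entry = entry, time = time,
                    status = as.integer(status), cens_type = cens_type,
                    entry_offset = entry, stringsAsFactors = FALSE)
  kinds <- character(0)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    dat <- cbind(dat, covariates)
    kinds <- vapply(names(covariates), function(v)
      if (is.factor(covariates[[v]]) || is.character(covariates[[v]]))
        "factor" else "numeric", character(1))
  }
  structure(list(data = dat, transition = as.integer(transition),
                 clock = clock, covariates = kinds, tau = max(time)),
            class = "transition_dataset")
}

# Markov illness-death scenario with constant rates (shared by several tests)
constant_rate_scenario <- function(n, r12 = 0.2, r13 = 0.1, r23 = 0.3,
                                   censoring = list(type = "none")) {
  simulation_scenario(
    illness_death_structure(),
    baselines = list("1->2" = list(type = "exp", rate = r12),
                     "1->3" = list(type = "exp", rate = r13),
                     "2->3" = list(type = "exp", rate = r23)),
    covariates = list(),
    censoring = censoring, n_subjects = n, label = "constant_markov")
}

fit_all_nelson_aalen <- function(dataset) {
  st <- dataset$structure
  keys <- apply(st$transitions, 1L, function(r) paste0(r[1], "->", r[2]))
  haz <- lapply(keys, function(k) {
    hj <- as.integer(strsplit(k, "->", fixed = TRUE)[[1]])
    nelson_aalen(extract_transition_dataset(dataset, hj))
  })
  names(haz) <- keys
  haz
}
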