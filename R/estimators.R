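#' Nelson-Aalen cumulative hazard for one transition
#'
#' Estimates the cumulative transition hazard A_hj(t) of a
#' [transition_dataset()] by the Nelson-Aalen estimator: a jump of
#' dN_hj(u) / Y_h(u) at every observed event time u, where dN_hj(u) counts
#' h -> j transitions at exactly u and Y_h(u) counts subjects at risk in h
#' just before u. The risk set honours delayed entry: a subject
#' contributes on (entry, time], so clock-forward transitions out of
#' non-initial states are handled correctly.
#'
#' @param td a \code{transition_dataset} (or anything with
#'   \code{$data$time}, \code{$data$status}, \code{$data$entry}).
#' @return object of class \code{cumulative_hazard}: list with
#'   \code{transition}, \code{times} (strictly increasing jump times),
#'   \code{dA} (positive increments) and \code{n_risk}, \code{n_event}
#'   bookkeeping vectors. Evaluate with [cumhaz_value()].
#' @examples
#' td <- list(data = data.frame(id = 1:4, entry = 0,
#'                              time = c(2, 3, 5, 6),
#'                              status = c(1, 0, 1, 0)),
#'            transition = c(1L, 2L))
#' ch <- nelson_aalen(td)
#' cumhaz_value(ch, 5)  # 1/4 + 1/2
#' @export
nelson_aalen <- function(td) {
  dat <- td$data
  if (is.null(dat) || nrow(dat) == 0L) stop("empty transition dataset")
  na <- na_increments(dat$time, dat$status, dat$entry)
  structure(list(transition = td$transition, times = na$times, dA = na$dA,
                 n_risk = na$Y, n_event = na$dN),
            class = "cumulative_hazard")
}

# core Nelson-Aalen computation on (entry, time] risk intervals
na_increments <- function(time, status, entry = NULL) {
  if (is.null(entry)) entry <- rep(0, length(time))
  ev <- sort(unique(time[status == 1L]))
  if (length(ev) == 0L)
    return(list(times = numeric(0), dA = numeric(0),
                Y = numeric(0), dN = numeric(0)))
  st <- sort(time); se <- sort(entry)
  # Y(u) = #{entry < u <= time} = #{entry < u} - #{time < u}
  Y <- findInterval(ev, se, left.open = TRUE) - findInterval(ev, st, left.open = TRUE)
  dN <- as.numeric(tapply(rep(1L, sum(status == 1L)),
                          factor(time[status == 1L], levels = ev), sum))
  list(times = ev, dA = dN / Y, Y = Y, dN = dN)
}

#' Evaluate a cumulative hazard step function
#'
#' Returns A(s, t] = sum of increments at jump times u with s < u <= t.
#'
#' @param ch a \code{cumulative_hazard}.
#' @param t evaluation time(s).
#' @param s left endpoint (default 0).
#' @return numeric vector of the same length as \code{t}.
#' @export
cumhaz_value <- function(ch, t, s = 0) {
  step_eval(ch$times, cumsum(ch$dA), t) - step_eval(ch$times, cumsum(ch$dA), s)
}

# right-continuous step function: value at t is cumvals[last jump <= t], 0 before
step_eval <- function(times, cumvals, t) {
  idx <- findInterval(t, times)
  c(0, cumvals)[idx + 1L]
}

# Kaplan-Meier style survival from hazard increments: S(t) = prod_{u<=t}(1-dA)
surv_eval <- function(times, dA, t) {
  c(1, cumprod(1 - dA))[findInterval(t, times) + 1L]
}

#' @export
as.data.frame.cumulative_hazard <- function(x, ...) {
  data.frame(time = x$times, value = cumsum(x$dA),
             n_risk = x$n_risk, n_event = x$n_event)
}

#' @export
print.cumulative_hazard <- function(x, ...) {
  cat("Nelson-Aalen cumulative hazard",
      if (!is.null(x$transition))
        paste0("for ", trans_key(x$transition[1L], x$transition[2L])),
      ": ", length(x$times), " jumps, A(0, max) = ",
      format(sum(x$dA)), "\n", sep = "")
  invisible(x)
}

#' Aalen-Johansen transition probability matrix
#'
#' Assembles per-transition cumulative hazards into the matrix-valued
#' product integral P(s,t) = prod_{s < u <= t} (I + dA(u)) over the pooled
#' jump times, where the factor at u has off-diagonal (h,j) entry
#' dA_hj(u) and diagonal entry 1 - sum_j dA_hj(u). Factors are applied in
#' increasing time order; a time point where some state's increments sum
#' past 1 (negative diagonal) is rejected by name.
#'
#' @param hazards named list of \code{cumulative_hazard} objects, keyed by
#'   \code{"h->j"}; every transition of \code{structure} must be present.
#' @param structure a [transition_structure()].
#' @return object of class \code{aalen_johansen}: list with
#'   \code{structure}, \code{times} (pooled jump times) and \code{dA}
#'   (N x N x T increment array). Evaluate with [transition_probability()].
#' @export
aalen_johansen <- function(hazards, structure) {
  keys <- structure_keys(structure)
  missing_k <- setdiff(keys, names(hazards))
  if (length(missing_k))
    stop("hazards missing for transition(s): ", paste(missing_k, collapse = ", "))
  N <- structure$n_states
  times <- sort(unique(unlist(lapply(hazards[keys], `[[`, "times"))))
  dA <- array(0, dim = c(N, N, length(times)))
  for (k in keys) {
    hj <- parse_trans_key(k)
    ch <- hazards[[k]]
    if (length(ch$times))
      dA[hj[1L], hj[2L], match(ch$times, times)] <- ch$dA
  }
  for (h in seq_len(N)) {
    tot <- if (length(times)) colSums(matrix(dA[h, -h, , drop = FALSE],
                                             ncol = length(times))) else numeric(0)
    bad <- which(tot > 1 + 1e-12)
    if (length(bad))
      stop("negative diagonal in product-integral factor for state ", h,
           " at time ", format(times[bad[1L]]),
           " (hazard increments sum to ", format(tot[bad[1L]]), ")")
    dA[h, h, ] <- 1 - tot
  }
  diag_idx <- seq_len(N)
  structure(list(structure = structure, times = times, dA = dA),
            class = "aalen_johansen")
}

#' Evaluate Aalen-Johansen transition probabilities
#'
#' @param aj an \code{aalen_johansen} object.
#' @param s,t evaluation interval, \code{s <= t}. \code{t} may be a vector.
#' @return if \code{t} is scalar, the N x N matrix P(s,t); otherwise an
#'   N x N x length(t) array (t must be nondecreasing).
#' @export
transition_probability <- function(aj, s, t) {
  stopifnot(inherits(aj, "aalen_johansen"), all(t >= s))
  N <- aj$structure$n_states
  if (length(t) > 1L && is.unsorted(t))
    stop("vector t must be nondecreasing")
  P <- diag(N)
  out <- array(NA_real_, dim = c(N, N, length(t)))
  idx <- which(aj$times > s & aj$times <= max(t))
  k <- 1L
  for (ti in seq_along(t)) {
    while (k <= length(idx) && aj$times[idx[k]] <= t[ti]) {
      # explicit small-matrix product: keeps the arithmetic identical to
      # the scalar product-limit form (no BLAS reassociation/FMA)
      F <- aj$dA[, , idx[k]]
      Pn <- P
      for (i in seq_len(N)) for (j in seq_len(N))
        Pn[i, j] <- sum(P[i, ] * F[, j])
      P <- Pn
      k <- k + 1L
    }
    out[, , ti] <- P
  }
  if (length(t) == 1L) out[, , 1L] else out
}

#' @export
print.aalen_johansen <- function(x, ...) {
  cat("Aalen-Johansen estimator on", x$structure$n_states, "states,",
      length(x$times), "pooled jump times\n")
  invisible(x)
}

#' Closed-form Markov illness-death transition probabilities
#'
#' For the Markov illness-death model (states 1 = healthy, 2 = ill,
#' 3 = dead) with integrable intensity functions a12, a13, a23 on the
#' study clock, the transition probabilities solve the forward Kolmogorov
#' equations in closed form:
#' P11(s,t) = exp(-(A12 + A13)(s,t)), P22(s,t) = exp(-A23(s,t)), and
#' P12(s,t) = integral over u in (s,t) of P11(s,u) a12(u) P22(u,t) du,
#' with P13 = 1 - P11 - P12 by conservation. Integrals are evaluated by
#' adaptive quadrature.
#'
#' @param a12,a13,a23 vectorized nonnegative intensity functions of time.
#' @param s,t interval, \code{s <= t}.
#' @param rel_tol quadrature relative tolerance for P12.
#' @return named vector \code{c(P11, P22, P12, P13)}.
#' @export
illness_death_closed_form <- function(a12, a13, a23, s, t, rel_tol = 1e-8) {
  stopifnot(t >= s)
  probe <- seq(s, max(t, s + 1e-9), length.out = 17L)
  for (f in list(a12, a13, a23))
    if (any(f(probe) < 0)) stop("negative intensity values")
  if (t == s) return(c(P11 = 1, P22 = 1, P12 = 0, P13 = 0))
  cumint <- function(f, lo, hi) {
    if (hi <= lo) 0
    else stats::integrate(f, lo, hi, rel.tol = 1e-10,
                          subdivisions = 500L)$value
  }
  P11 <- function(lo, hi) exp(-(cumint(a12, lo, hi) + cumint(a13, lo, hi)))
  P22 <- function(lo, hi) exp(-cumint(a23, lo, hi))
  integrand <- Vectorize(function(u) P11(s, u) * a12(u) * P22(u, t))
  P12 <- stats::integrate(integrand, s, t, rel.tol = rel_tol,
                          subdivisions = 500L)$value
  p11 <- P11(s, t); p22 <- P22(s, t)
  c(P11 = p11, P22 = p22, P12 = P12, P13 = 1 - p11 - P12)
}

#' Censoring-distribution survival (reverse Kaplan-Meier)
#'
#' Estimates the survival function G(t) of the censoring time by the
#' Kaplan-Meier estimator with the roles of event and censoring reversed:
#' censored observations are the "events". Used as the
#' inverse-probability-of-censoring weight denominator in the Brier score.
#' Estimated marginally (unconditional on covariates).
#'
#' @param td a \code{transition_dataset}, or a data.frame/list with
#'   \code{time}, \code{status} (and optionally \code{entry}) components.
#' @return object of class \code{censoring_survival}; evaluate with
#'   [censoring_at()].
#' @export
censoring_survival <- function(td) {
  dat <- if (inherits(td, "transition_dataset")) td$data else as.data.frame(td)
  if (nrow(dat) == 0L) stop("empty dataset")
  entry <- if (!is.null(dat$entry)) dat$entry else rep(0, nrow(dat))
  cens <- 1 - dat$status
  sf <- if (all(entry == 0)) {
    survival::survfit(survival::Surv(dat$time, cens) ~ 1)
  } else {
    survival::survfit(survival::Surv(entry, dat$time, cens) ~ 1)
  }
  keep <- sf$n.event > 0
  structure(list(times = sf$time[keep], surv = sf$surv[keep]),
            class = "censoring_survival")
}

#' Evaluate the censoring survival function
#'
#' @param g a \code{censoring_survival}.
#' @param t evaluation time(s).
#' @param left if \code{TRUE}, return the left limit G(t-).
#' @return numeric vector in (0, 1].
#' @export
censoring_at <- function(g, t, left = FALSE) {
  idx <- findInterval(t, g$times, left.open = left)
  c(1, g$surv)[idx + 1L]
}

#' @export
print.censoring_survival <- function(x, ...) {
  cat("Censoring survival (reverse Kaplan-Meier):", length(x$times),
      "drops, G(max) =", format(if (length(x$surv)) min(x$surv) else 1), "\n")
  invisible(x)
}
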