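new_transition_ensemble <- function(td, trees, method, oob, config) {
  structure(list(transition = td$transition, clock = td$clock,
                 trees = trees, method = method, oob = oob,
                 config = config, covariates = td$covariates,
                 tau = td$tau),
            class = "transition_ensemble")
}

#' Fit a multistate random survival forest (MSRSF) for one transition
#'
#' Grows \code{B} bootstrap multistate trees ([grow_bootstrap_tree()]) on
#' the transition dataset; the ensemble estimate for a covariate vector is
#' the pointwise average over trees of the terminal-node cumulative hazard
#' (and of the survival curve derived per tree).
#'
#' @param td a \code{transition_dataset}.
#' @param B number of bootstrap trees (default 1000).
#' @param K candidate covariates per split; default \code{floor(sqrt(p))}.
#' @param n0 minimum unique cases per terminal node (default 6).
#' @param seed master seed; per-tree seeds are derived from it by counter.
#' @param n_cuts random cut points per numeric candidate.
#' @return a \code{transition_ensemble} with \code{method = "forest"} and
#'   per-tree out-of-bag row indices in \code{$oob}.
#' @seealso [predict_ensemble_survival()], [fit_msrist()]
#' @export
fit_msrsf <- function(td, B = 1000L, K = NULL, n0 = 6L, seed = NULL,
                      n_cuts = 1L) {
  stopifnot(inherits(td, "transition_dataset"))
  if (B < 1L) stop("B must be at least 1")
  if (is.null(K)) K <- max(1L, floor(sqrt(length(td$covariates))))
  if (is.null(seed)) seed <- sample.int(2^31 - 2L, 1L)
  fits <- lapply(seq_len(B), function(b)
    grow_bootstrap_tree(td, K = K, n0 = n0, seed = derive_seed(seed, b),
                        n_cuts = n_cuts))
  new_transition_ensemble(td, lapply(fits, `[[`, "tree"), "forest",
                          lapply(fits, `[[`, "oob"),
                          list(B = B, K = K, n0 = n0, seed = seed,
                               n_cuts = n_cuts))
}

#' Fit multistate recursively imputed survival trees (MSRIST) for one
#' transition
#'
#' Cycle 1 fits \code{M} extremely randomized multistate trees
#' ([grow_ermt()]) to the raw transition dataset. Each subsequent cycle
#' computes the ensemble-conditional survival distribution of every
#' imputable censored observation from the current \code{M} trees, draws
#' \code{M} independently imputed datasets (each censored sojourn replaced
#' by an event before tau or a censoring at tau), and fits one ERMT per
#' imputed dataset. After \code{n_cycles} rounds the final \code{M} trees
#' form the ensemble; earlier cycles are discarded.
#'
#' Only censored rows still in the origin state at last contact are
#' imputed; rows censored by a competing exit are structurally
#' unobservable for this transition and are left untouched.
#'
#' @param td a \code{transition_dataset}.
#' @param M trees per cycle (default 50).
#' @param K candidate covariates per split; default \code{floor(sqrt(p))}.
#' @param nmin minimum events per terminal node (default 6).
#' @param n_cycles total fitting rounds including the initial raw fit
#'   (default 5).
#' @param seed master seed.
#' @param n_cuts random cut points per numeric candidate.
#' @return a \code{transition_ensemble} with \code{method = "rist"}; its
#'   \code{config$n_cycles} records the cycles actually run.
#' @export
fit_msrist <- function(td, M = 50L, K = NULL, nmin = 6L, n_cycles = 5L,
                       seed = NULL, n_cuts = 1L) {
  stopifnot(inherits(td, "transition_dataset"))
  if (M < 1L) stop("M must be at least 1")
  if (n_cycles < 1L) stop("n_cycles must be at least 1")
  if (is.null(K)) K <- max(1L, floor(sqrt(length(td$covariates))))
  if (is.null(seed)) seed <- sample.int(2^31 - 2L, 1L)
  counter <- 0L
  next_seed <- function() { counter <<- counter + 1L; derive_seed(seed, counter) }

  trees <- lapply(seq_len(M), function(m)
    grow_ermt(td, K = K, nmin = nmin, seed = next_seed(), n_cuts = n_cuts))
  if (n_cycles > 1L) {
    for (cyc in 2:n_cycles) {
      ens <- new_transition_ensemble(td, trees, "rist", NULL, list())
      laws <- censored_conditional_laws(ens, td)
      trees <- lapply(seq_len(M), function(m) {
        imp <- draw_imputation(td, laws, seed = next_seed())
        grow_ermt(imp, K = K, nmin = nmin, seed = next_seed(),
                  n_cuts = n_cuts)
      })
    }
  }
  new_transition_ensemble(td, trees, "rist", NULL,
                          list(M = M, K = K, nmin = nmin,
                               n_cycles = n_cycles, seed = seed,
                               n_cuts = n_cuts))
}

#' Fit a covariate-free baseline "ensemble"
#'
#' A single root-only tree whose estimate is the Nelson-Aalen cumulative
#' hazard of the whole transition dataset, regardless of covariates: the
#' Aalen-Johansen building block without covariate information. Used as the
#' reference model in evaluations.
#'
#' @param td a \code{transition_dataset}.
#' @return a \code{transition_ensemble} with \code{method = "baseline"}.
#' @export
fit_baseline <- function(td) {
  stopifnot(inherits(td, "transition_dataset"))
  na <- na_increments(td$data$time, td$data$status, td$data$entry)
  node <- list(times = na$times, dA = na$dA, n_risk = na$Y,
               n_event_t = na$dN, n = nrow(td$data),
               n_events = sum(td$data$status == 1L))
  tree <- new_mstree(td, list(node), list(mode = "baseline"))
  new_transition_ensemble(td, list(tree), "baseline", NULL, list())
}

# pooled event-time grid of an ensemble (union of terminal jump times)
ensemble_grid <- function(ensemble) {
  sort(unique(unlist(lapply(ensemble$trees, function(tr)
    unlist(lapply(tr$nodes[tree_terminal_ids(tr)], `[[`, "times"))))))
}

#' Ensemble survival / cumulative hazard predictions
#'
#' Averages the terminal-node estimators over the ensemble's trees for
#' each row of \code{newdata}: survival is the mean of the per-tree
#' product-limit curves, cumulative hazard the mean of the per-tree
#' Nelson-Aalen curves.
#'
#' @param ensemble a \code{transition_ensemble}.
#' @param newdata data.frame of covariate rows.
#' @param times evaluation times on the transition's clock.
#' @param randomize_on variables whose splits are routed randomly (VIMP
#'   mechanism); uses the current RNG state.
#' @return numeric matrix, rows = \code{newdata} rows, columns = times.
#' @export
predict_ensemble_survival <- function(ensemble, newdata, times,
                                      randomize_on = NULL) {
  ens_eval(ensemble, newdata, times, randomize_on, what = "surv")
}

#' @rdname predict_ensemble_survival
#' @export
predict_ensemble_cumhaz <- function(ensemble, newdata, times,
                                    randomize_on = NULL) {
  ens_eval(ensemble, newdata, times, randomize_on, what = "chaz")
}

ens_eval <- function(ensemble, newdata, times, randomize_on, what) {
  newdata <- as.data.frame(newdata)
  m <- nrow(newdata)
  acc <- matrix(0, m, length(times))
  for (tr in ensemble$trees) {
    term <- route_rows(tr, newdata, randomize_on)
    ut <- unique(term)
    vals <- vapply(ut, function(nid) {
      nd <- tr$nodes[[nid]]
      if (what == "surv") surv_eval(nd$times, nd$dA, times)
      else step_eval(nd$times, cumsum(nd$dA), times)
    }, numeric(length(times)))
    vals <- matrix(vals, nrow = length(times))  # times x terminals
    acc <- acc + t(vals)[match(term, ut), , drop = FALSE]
  }
  acc / length(ensemble$trees)
}

#' Ensemble-conditional distribution beyond a censoring time
#'
#' For a censored observation with covariates \code{z} and censoring time
#' \code{c}, computes the ensemble survival curve S(t|z) (mean of per-tree
#' terminal survival curves) and conditions it on survival past \code{c}:
#' a discrete law over the pooled jump grid in (c, tau], with residual
#' mass S(tau|z)/S(c|z) assigned to "censored at tau". If S(c|z) = 0 the
#' conditional is degenerate at the first grid time after \code{c}
#' (flagged).
#'
#' @param ensemble a fitted \code{transition_ensemble}.
#' @param z single covariate row.
#' @param c censoring time, \code{c < tau}.
#' @param tau horizon; defaults to the largest observed time of the
#'   training data.
#' @return list with \code{times}, \code{prob} (event-time law),
#'   \code{p_tau} (tau-censoring mass), \code{tau}, \code{s_c} (S(c|z))
#'   and \code{degenerate} flag.
#' @export
conditional_survival <- function(ensemble, z, c, tau = NULL) {
  tau <- tau %||% ensemble$tau
  if (c >= tau) stop("censoring time must precede tau")
  grid <- ensemble_grid(ensemble)
  grid <- grid[grid > c & grid <= tau]
  S <- predict_ensemble_survival(ensemble, as.data.frame(z), c(c, grid))
  s_c <- S[1L, 1L]
  if (s_c <= 0) {
    if (length(grid) == 0L)
      return(list(times = numeric(0), prob = numeric(0), p_tau = 1,
                  tau = tau, s_c = 0, degenerate = TRUE))
    return(list(times = grid[1L], prob = 1, p_tau = 0, tau = tau,
                s_c = 0, degenerate = TRUE))
  }
  if (length(grid) == 0L)
    return(list(times = numeric(0), prob = numeric(0), p_tau = 1,
                tau = tau, s_c = s_c, degenerate = FALSE))
  Sg <- S[1L, -1L]
  prob <- (c(s_c, Sg[-length(Sg)]) - Sg) / s_c
  prob[prob < 0] <- 0
  p_tau <- max(0, Sg[length(Sg)] / s_c)
  # guard tiny numerical drift
  tot <- sum(prob) + p_tau
  list(times = grid, prob = prob / tot, p_tau = p_tau / tot, tau = tau,
       s_c = s_c, degenerate = FALSE)
}

# conditional laws for all imputable ("lost") censored rows at once
censored_conditional_laws <- function(ensemble, td, tau = NULL) {
  tau <- tau %||% td$tau
  dat <- td$data
  rows <- which(dat$status == 0L & dat$cens_type == "lost" & dat$time < tau)
  if (length(rows) == 0L)
    return(list(rows = integer(0), tau = tau))
  grid <- ensemble_grid(ensemble)
  grid <- grid[grid <= tau]
  Z <- dat[rows, names(td$covariates), drop = FALSE]
  Sg <- predict_ensemble_survival(ensemble, Z, grid)
  # the ensemble survival curve only jumps on the pooled grid, so S(c) is
  # the value at the largest grid time <= c (1 before the first jump)
  idx <- findInterval(dat$time[rows], grid)
  s_c <- ifelse(idx == 0L, 1, Sg[cbind(seq_along(rows), pmax(idx, 1L))])
  list(rows = rows, grid = grid, Sg = Sg, s_c = s_c, tau = tau,
       c_times = dat$time[rows])
}

# one imputed dataset: each imputable row drawn from its conditional law
draw_imputation <- function(td, laws, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dat <- td$data
  prov <- ifelse(dat$status == 1L, "original",
                 ifelse(dat$cens_type == "competing", "competing", "original"))
  for (k in seq_along(laws$rows)) {
    i <- laws$rows[k]
    ci <- laws$c_times[k]
    sel <- laws$grid > ci
    times_i <- laws$grid[sel]
    if (length(times_i) == 0L) { prov[i] <- "imputed_tau"; dat$time[i] <- laws$tau; next }
    Si <- laws$Sg[k, sel]
    sc <- laws$s_c[k]
    if (sc <= 0) {  # degenerate conditional: event at first grid time after c
      dat$time[i] <- times_i[1L]; dat$status[i] <- 1L
      dat$cens_type[i] <- "event"; prov[i] <- "imputed_event"
      next
    }
    prob <- (c(sc, Si[-length(Si)]) - Si) / sc
    prob[prob < 0] <- 0
    p_tau <- max(0, Si[length(Si)] / sc)
    draw <- sample.int(length(times_i) + 1L, 1L,
                       prob = c(prob, p_tau))
    if (draw <= length(times_i)) {
      dat$time[i] <- times_i[draw]; dat$status[i] <- 1L
      dat$cens_type[i] <- "event"; prov[i] <- "imputed_event"
    } else {
      dat$time[i] <- laws$tau; prov[i] <- "imputed_tau"
    }
  }
  out <- td
  out$data <- dat
  out$data$provenance <- prov
  out$tau <- max(dat$time)
  out
}

#' One-step imputation of censored observations
#'
#' Replaces every imputable censored row of the transition dataset by a
#' draw from its ensemble-conditional distribution: an event at a time in
#' (c, tau] or a censoring at tau. Observed events are never altered, and
#' rows censored by a competing exit (the subject left the origin state to
#' a different destination) are not imputed, since their h -> j time is
#' structurally unobservable.
#'
#' @param td a \code{transition_dataset}.
#' @param ensemble a \code{transition_ensemble} fitted on \code{td} (or
#'   its predecessor imputation cycle).
#' @param seed optional integer seed.
#' @return a \code{transition_dataset} whose \code{$data} carries a
#'   \code{provenance} column with values \code{original},
#'   \code{competing}, \code{imputed_event}, \code{imputed_tau}.
#' @export
impute_one_step <- function(td, ensemble, seed = NULL) {
  stopifnot(inherits(td, "transition_dataset"),
            inherits(ensemble, "transition_ensemble"))
  laws <- censored_conditional_laws(ensemble, td)
  out <- draw_imputation(td, laws, seed = seed)
  # rows already at tau keep their censored status but are bookkept
  lost_at_tau <- which(out$data$status == 0L & out$data$cens_type == "lost" &
                         out$data$provenance == "original" &
                         out$data$time >= td$tau)
  out$data$provenance[lost_at_tau] <- "imputed_tau"
  out
}

#' @export
print.transition_ensemble <- function(x, ...) {
  cat("Transition ensemble [", x$method, "] for ",
      trans_key(x$transition[1L], x$transition[2L]), ": ",
      length(x$trees), " trees\n", sep = "")
  invisible(x)
}
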