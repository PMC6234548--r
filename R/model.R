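#' Fit per-transition ensembles for a whole multistate model
#'
#' Applies the separate approach: each transition of the structure gets
#' its own transition dataset ([extract_transition_dataset()]) and its own
#' ensemble fit — MSRIST ([fit_msrist()]), MSRSF ([fit_msrsf()]) or the
#' covariate-free baseline ([fit_baseline()]). Under
#' \code{markov_mode = "sojourn_augmented"}, transitions out of
#' non-initial states are fitted with the state-entry time \code{d} added
#' to the covariates (the non-Markov augmentation).
#'
#' @param dataset a \code{multistate_dataset}.
#' @param method \code{"msrist"}, \code{"msrsf"} or \code{"baseline"}.
#' @param markov_mode \code{"markov"} or \code{"sojourn_augmented"}.
#' @param seed master seed; each transition's fit derives its own seed.
#' @param ... hyperparameters passed to the per-transition fitter
#'   (\code{M}, \code{B}, \code{K}, \code{nmin}, \code{n0},
#'   \code{n_cycles}, \code{n_cuts}).
#' @return object of class \code{multistate_model}: list with
#'   \code{structure}, \code{ensembles} (named by \code{"h->j"}),
#'   \code{markov_mode}, \code{method}.
#' @export
fit_multistate_model <- function(dataset,
                                 method = c("msrist", "msrsf", "baseline"),
                                 markov_mode = c("markov", "sojourn_augmented"),
                                 seed = NULL, ...) {
  stopifnot(inherits(dataset, "multistate_dataset"))
  method <- match.arg(method)
  markov_mode <- match.arg(markov_mode)
  if (is.null(seed)) seed <- sample.int(2^31 - 2L, 1L)
  st <- dataset$structure
  keys <- structure_keys(st)
  ensembles <- vector("list", length(keys))
  names(ensembles) <- keys
  for (k in seq_along(keys)) {
    hj <- parse_trans_key(keys[k])
    td <- extract_transition_dataset(dataset, hj,
                                     augment_sojourn =
                                       markov_mode == "sojourn_augmented")
    ensembles[[k]] <- switch(method,
      msrist = fit_msrist(td, seed = derive_seed(seed, k), ...),
      msrsf = fit_msrsf(td, seed = derive_seed(seed, k), ...),
      baseline = fit_baseline(td))
  }
  structure(list(structure = st, ensembles = ensembles,
                 markov_mode = markov_mode, method = method, seed = seed),
            class = "multistate_model")
}

#' Predict state-occupation probabilities from a fitted multistate model
#'
#' Evaluates each transition's ensemble cumulative hazard at the covariate
#' vector \code{z} and assembles the hazards into transition probabilities
#' by the Aalen-Johansen product integral over the pooled jump grid in
#' (s, t]. Reset-clock transitions out of the current state are shifted to
#' the study clock by the state-entry time \code{entry_offset}; under
#' sojourn augmentation, \code{entry_offset} is injected as the \code{d}
#' covariate for those transitions. Reset-clock transitions out of states
#' other than the current one have no valid study-clock hazard (the entry
#' time is unknown; the semi-Markov process admits no Kolmogorov
#' equations) and are rejected — predict from the state itself, or refit
#' clock-forward.
#'
#' @param model a \code{multistate_model}.
#' @param z single covariate row.
#' @param s prediction time (study clock), \code{s <= t}.
#' @param t horizon(s), nondecreasing.
#' @param current_state occupied state at \code{s} (default initial).
#' @param entry_offset time of entry into \code{current_state} on the
#'   study clock (default \code{s} for non-initial states is NOT assumed;
#'   supply it when the current state is non-initial).
#' @return named probability vector over the states (rows sum to 1); a
#'   matrix with one row per element of \code{t} when \code{t} is a
#'   vector.
#' @export
predict_transition_probabilities <- function(model, z, s, t,
                                             current_state = NULL,
                                             entry_offset = 0) {
  stopifnot(inherits(model, "multistate_model"))
  if (any(t < s)) stop("horizon t must not precede s")
  st <- model$structure
  h <- current_state %||% st$initial
  state_names <- paste0("state", seq_len(st$n_states))
  if (h %in% st$absorbing) {
    out <- matrix(0, length(t), st$n_states,
                  dimnames = list(NULL, state_names))
    out[, h] <- 1
    return(if (length(t) == 1L) out[1L, ] else out)
  }
  keys <- structure_keys(st)
  hazards <- vector("list", length(keys))
  names(hazards) <- keys
  z <- as.data.frame(z)
  if (nrow(z) == 0L) z <- data.frame(row.names = 1L)  # covariate-free model
  for (k in keys) {
    hj <- parse_trans_key(k)
    ens <- model$ensembles[[k]]
    clock <- unname(st$clock[k])
    if (clock == "reset" && hj[1L] != h)
      stop("transition ", k, " uses a reset clock but its origin is not ",
           "the current state; study-clock hazard is undefined")
    zz <- z
    if (model$markov_mode == "sojourn_augmented" && hj[1L] != st$initial) {
      if (hj[1L] != h)
        stop("sojourn-augmented transition ", k, " out of a future state ",
             "needs an entry time that is not yet known")
      zz$d <- entry_offset
    }
    ch <- ensemble_hazard(ens, zz)
    if (clock == "reset") ch$times <- ch$times + entry_offset
    hazards[[k]] <- ch
  }
  aj <- aalen_johansen(hazards, st)
  P <- transition_probability(aj, s, t)
  if (length(t) == 1L) {
    out <- P[h, ]
    names(out) <- state_names
  } else {
    out <- t(P[h, , ])
    colnames(out) <- state_names
  }
  out
}

#' Ensemble cumulative hazard for one covariate vector
#'
#' Pools the jump times of the routed terminal nodes across trees and
#' averages their Nelson-Aalen increments, yielding the ensemble
#' cumulative hazard as an explicit step function.
#'
#' @param ensemble a \code{transition_ensemble}.
#' @param z single covariate row.
#' @return a \code{cumulative_hazard}.
#' @export
ensemble_hazard <- function(ensemble, z) {
  z <- as.data.frame(z)
  stopifnot(nrow(z) == 1L)
  payloads <- lapply(ensemble$trees, function(tr) {
    nid <- route_rows(tr, z)[1L]
    tr$nodes[[nid]]
  })
  times <- sort(unique(unlist(lapply(payloads, `[[`, "times"))))
  dA <- numeric(length(times))
  for (pl in payloads) {
    if (length(pl$times))
      dA[match(pl$times, times)] <- dA[match(pl$times, times)] + pl$dA
  }
  structure(list(transition = ensemble$transition, times = times,
                 dA = dA / length(ensemble$trees),
                 n_risk = rep(NA_real_, length(times)),
                 n_event = rep(NA_real_, length(times))),
            class = "cumulative_hazard")
}

#' @export
print.multistate_model <- function(x, ...) {
  cat("Multistate model [", x$method, ", ", x$markov_mode, "]\n", sep = "")
  for (k in names(x$ensembles))
    cat("  ", k, ": ", length(x$ensembles[[k]]$trees), " trees\n", sep = "")
  invisible(x)
}

# ---- serialization ---------------------------------------------------------

tree_to_list <- function(tree) {
  list(transition = tree$transition, clock = tree$clock,
       covariates = as.list(tree$covariates),
       params = tree$params,
       nodes = lapply(tree$nodes, function(nd) {
         nd[!vapply(nd, is.null, logical(1))]
       }))
}

tree_from_list <- function(x) {
  structure(list(transition = as.integer(unlist(x$transition)),
                 clock = x$clock,
                 nodes = lapply(x$nodes, function(nd) {
                   for (f in c("times", "dA", "n_risk", "n_event_t"))
                     if (!is.null(nd[[f]])) nd[[f]] <- as.numeric(unlist(nd[[f]]))
                   for (f in c("left", "right", "n", "n_events"))
                     if (!is.null(nd[[f]])) nd[[f]] <- as.integer(unlist(nd[[f]]))
                   if (!is.null(nd$left_levels))
                     nd$left_levels <- as.character(unlist(nd$left_levels))
                   if (!is.null(nd$node_levels))
                     nd$node_levels <- as.character(unlist(nd$node_levels))
                   nd
                 }),
                 covariates = unlist(x$covariates),
                 params = x$params),
            class = "multistate_tree")
}

ensemble_to_list <- function(ens) {
  list(transition = ens$transition, clock = ens$clock, method = ens$method,
       config = ens$config, tau = ens$tau,
       covariates = as.list(ens$covariates),
       trees = lapply(ens$trees, tree_to_list))
}

ensemble_from_list <- function(x) {
  structure(list(transition = as.integer(unlist(x$transition)),
                 clock = x$clock,
                 trees = lapply(x$trees, tree_from_list),
                 method = x$method, oob = NULL, config = x$config,
                 covariates = unlist(x$covariates),
                 tau = as.numeric(x$tau)),
            class = "transition_ensemble")
}

#' Serialize / restore a fitted multistate model as a JSON bundle
#'
#' The bundle records the transition structure, the fit configuration and
#' every tree (split rules, terminal jump times and increments), so a
#' model can be audited, stored and reloaded without refitting.
#' Serialization is deterministic: the same fitted model always yields the
#' same JSON text.
#'
#' @param model a \code{multistate_model}.
#' @param path file path; \code{serialize_model} returns the JSON string
#'   instead.
#' @return \code{load_model} returns the restored
#'   \code{multistate_model}; \code{save_model} invisibly returns
#'   \code{path}.
#' @export
save_model <- function(model, path) {
  writeLines(serialize_model(model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
serialize_model <- function(model) {
  stopifnot(inherits(model, "multistate_model"))
  st <- model$structure
  bundle <- list(
    format = "msforest-model-v1",
    structure = list(n_states = st$n_states,
                     transitions = st$transitions,
                     clock = as.list(st$clock)),
    method = model$method, markov_mode = model$markov_mode,
    seed = model$seed,
    ensembles = lapply(model$ensembles, ensemble_to_list))
  jsonlite::toJSON(bundle, auto_unbox = TRUE, digits = NA, null = "null")
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(x$format, "msforest-model-v1"))
    stop("not an msforest model bundle")
  tm <- matrix(as.integer(unlist(x$structure$transitions)), ncol = 2L,
               byrow = TRUE)
  st <- transition_structure(x$structure$n_states, tm,
                             clock = unlist(x$structure$clock))
  structure(list(structure = st,
                 ensembles = lapply(x$ensembles, ensemble_from_list),
                 markov_mode = x$markov_mode, method = x$method,
                 seed = x$seed),
            class = "multistate_model")
}
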