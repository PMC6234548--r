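#' Transition structure of a multistate process
#'
#' Defines the directed graph of allowed moves between the states of a
#' finite-state process, together with the time-scale ("clock") convention
#' used for each transition. States are labelled \code{1..n_states}; a
#' transition is an ordered pair \code{(h, j)} with \code{h != j}. States
#' with no outgoing transition are absorbing.
#'
#' Two clocks are supported per transition: \code{"forward"} indexes the
#' transition hazard by time since entry into the initial state (study
#' clock), which yields a Markov model; \code{"reset"} indexes it by time
#' since entry into the origin state \code{h} (sojourn clock), the
#' semi-Markov convention.
#'
#' @param n_states number of states.
#' @param transitions two-column integer matrix; each row is an allowed
#'   \code{(from, to)} move.
#' @param clock either a single string (\code{"forward"} or \code{"reset"})
#'   applied to every transition, or a named character vector keyed by
#'   \code{"h->j"} labels for per-transition control. Transitions not named
#'   default to \code{"forward"}.
#' @return an object of class \code{transition_structure} with elements
#'   \code{n_states}, \code{transitions} (matrix), \code{absorbing}
#'   (integer vector), \code{initial} (state 1) and \code{clock} (named
#'   character vector keyed by \code{"h->j"}).
#' @examples
#' illness_death_structure()
#' progressive_structure(3)
#' @export
transition_structure <- function(n_states, transitions, clock = "forward") {
  stopifnot(is.numeric(n_states), n_states >= 2)
  n_states <- as.integer(n_states)
  transitions <- matrix(as.integer(transitions), ncol = 2,
                        dimnames = list(NULL, c("from", "to")))
  if (nrow(transitions) < 1L)
    stop("at least one transition is required")
  if (any(transitions < 1L | transitions > n_states))
    stop("transition states must lie in 1..", n_states)
  if (any(transitions[, 1L] == transitions[, 2L]))
    stop("self-transitions are not allowed")
  if (anyDuplicated(paste(transitions[, 1L], transitions[, 2L])))
    stop("duplicate transitions")
  keys <- trans_key(transitions[, 1L], transitions[, 2L])
  absorbing <- setdiff(seq_len(n_states), unique(transitions[, 1L]))
  if (any(transitions[, 1L] %in% absorbing))
    stop("internal error: absorbing state with outgoing transition")

  if (length(clock) == 1L && is.null(names(clock))) {
    clk <- rep(match.arg(clock, c("forward", "reset")), length(keys))
    names(clk) <- keys
  } else {
    if (is.null(names(clock)))
      stop("per-transition 'clock' must be named by \"h->j\" labels")
    bad <- setdiff(names(clock), keys)
    if (length(bad))
      stop("clock given for unknown transition(s): ", paste(bad, collapse = ", "))
    clk <- rep("forward", length(keys))
    names(clk) <- keys
    clk[names(clock)] <- vapply(clock, match.arg,
                                character(1), c("forward", "reset"))
  }
  # a reset clock is only meaningful out of a non-initial state
  for (k in seq_along(keys)) {
    if (clk[k] == "reset" && transitions[k, 1L] == 1L)
      stop("clock=reset on transition ", keys[k],
           " out of the initial state is meaningless (clocks coincide)")
  }
  structure(list(n_states = n_states, transitions = transitions,
                 absorbing = as.integer(absorbing), initial = 1L,
                 clock = clk),
            class = "transition_structure")
}

#' @rdname transition_structure
#' @details \code{progressive_structure(n)} builds the chain
#'   \code{1 -> 2 -> ... -> n}; \code{illness_death_structure()} builds the
#'   three-state illness-death graph \code{{1->2, 1->3, 2->3}} (healthy,
#'   ill, dead).
#' @export
progressive_structure <- function(n_states, clock = "forward") {
  transition_structure(n_states,
                       cbind(seq_len(n_states - 1L), 2:n_states),
                       clock = clock)
}

#' @rdname transition_structure
#' @export
illness_death_structure <- function(clock = "forward") {
  transition_structure(3L, rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L)),
                       clock = clock)
}

trans_key <- function(from, to) paste0(from, "->", to)

parse_trans_key <- function(key) {
  parts <- strsplit(key, "->", fixed = TRUE)[[1L]]
  as.integer(parts)
}

has_transition <- function(structure, h, j) {
  any(structure$transitions[, 1L] == h & structure$transitions[, 2L] == j)
}

structure_keys <- function(structure) {
  trans_key(structure$transitions[, 1L], structure$transitions[, 2L])
}

#' @export
print.transition_structure <- function(x, ...) {
  cat("Multistate transition structure:", x$n_states, "states\n")
  keys <- structure_keys(x)
  cat("  transitions:",
      paste0(keys, " [", x$clock[keys], "]", collapse = ", "), "\n")
  cat("  absorbing:", paste(x$absorbing, collapse = ", "), "\n")
  invisible(x)
}
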