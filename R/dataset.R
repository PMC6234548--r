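#' Assemble and validate a long-format multistate dataset
#'
#' A multistate event history is stored in long ("counting process") format:
#' one row per sojourn of a subject in a state, with the study-clock entry
#' and exit times of the sojourn, the destination state (or 0 for a
#' censored sojourn), an event indicator and the subject's covariates.
#' Every subject's rows chain: the exit time and destination of one row are
#' the entry time and origin of the next, the chain starts in state 1 at
#' time 0, and it ends either with an event into an absorbing state or with
#' a censored row (last contact).
#'
#' @param records data.frame with columns \code{id}, \code{from}, \code{to},
#'   \code{entry}, \code{exit}, \code{status} (1 = observed transition,
#'   0 = censored, in which case \code{to} must be 0), plus covariate
#'   columns. Covariates must be constant within subject.
#' @param structure a [transition_structure()].
#' @param covariate_kinds optional named character vector mapping covariate
#'   names to \code{"numeric"} or \code{"factor"}; by default character and
#'   factor columns are treated as categorical, everything else as numeric.
#' @return an object of class \code{multistate_dataset}: list with
#'   \code{records} (validated data.frame, ordered by subject and entry
#'   time), \code{structure}, \code{tau} (largest observed exit time) and
#'   \code{covariates} (named character vector of covariate kinds).
#' @seealso [read_long_csv()], [extract_transition_dataset()], [state_at()]
#' @export
multistate_dataset <- function(records, structure, covariate_kinds = NULL) {
  stopifnot(inherits(structure, "transition_structure"))
  required <- c("id", "from", "to", "entry", "exit", "status")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols))
    stop("records lack required column(s): ", paste(missing_cols, collapse = ", "))
  records <- as.data.frame(records)
  covar_names <- setdiff(names(records), required)
  records <- records[c(required, covar_names)]

  problems <- character(0)
  note <- function(rows, msg) {
    problems <<- c(problems, paste0("row ", paste(rows, collapse = ","), ": ", msg))
  }

  if (any(!is.finite(records$entry)) || any(!is.finite(records$exit)))
    note(which(!is.finite(records$entry) | !is.finite(records$exit)),
         "non-finite entry/exit time")
  bad <- which(records$exit <= records$entry)
  if (length(bad)) note(bad, "exit time must exceed entry time (zero-length sojourns are invalid)")
  bad <- which(records$entry < 0)
  if (length(bad)) note(bad, "negative entry time")
  bad <- which(!records$status %in% c(0, 1))
  if (length(bad)) note(bad, "status must be 0 or 1")
  bad <- which(!records$from %in% seq_len(structure$n_states))
  if (length(bad)) note(bad, "unknown origin state")
  bad <- which(records$from %in% structure$absorbing)
  if (length(bad)) note(bad, "origin state is absorbing (no exits allowed)")
  bad <- which(records$status == 1 &
                 !mapply(has_transition, records$from, records$to,
                         MoreArgs = list(structure = structure)))
  if (length(bad)) note(bad, "transition not allowed by the structure")
  bad <- which(records$status == 0 & records$to != 0)
  if (length(bad)) note(bad, "censored rows must have to = 0")
  bad <- which(records$status == 1 & records$to == 0)
  if (length(bad)) note(bad, "event rows must name a destination state")
  if (length(problems))
    stop("invalid multistate records:\n  ", paste(problems, collapse = "\n  "))

  ord <- order(records$id, records$entry)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL

  # per-subject chain validation
  for (chain in split(seq_len(nrow(records)), records$id)) {
    rr <- records[chain, , drop = FALSE]
    sid <- rr$id[1L]
    if (rr$entry[1L] != 0 || rr$from[1L] != structure$initial)
      note(chain[1L], paste0("subject ", sid, " must start in state ",
                             structure$initial, " at time 0"))
    n <- nrow(rr)
    if (n > 1L) {
      if (any(rr$status[-n] != 1))
        note(chain[which(rr$status[-n] != 1)],
             paste0("subject ", sid, ": only the last record may be censored"))
      link_ok <- rr$exit[-n] == rr$entry[-1L] & rr$to[-n] == rr$from[-1L]
      if (any(!link_ok))
        note(chain[1L + which(!link_ok)],
             paste0("subject ", sid, ": record does not chain from the previous one"))
    }
    last <- rr[n, ]
    if (last$status == 1 && !last$to %in% structure$absorbing)
      note(chain[n], paste0("subject ", sid,
                            ": chain ends with an event into non-absorbing state ",
                            last$to, " (a final censored sojourn is required)"))
    if (anyDuplicated(rr$from))
      note(chain[1L], paste0("subject ", sid, ": revisits a state (not supported)"))
  }
  if (length(problems))
    stop("invalid multistate records:\n  ", paste(problems, collapse = "\n  "))

  kinds <- detect_covariate_kinds(records, covar_names, covariate_kinds)
  for (v in covar_names) {
    if (kinds[[v]] == "factor" && !is.factor(records[[v]]))
      records[[v]] <- factor(records[[v]])
    if (kinds[[v]] == "numeric")
      records[[v]] <- as.numeric(records[[v]])
  }

  structure(list(records = records, structure = structure,
                 tau = max(records$exit), covariates = kinds),
            class = "multistate_dataset")
}

detect_covariate_kinds <- function(records, covar_names, covariate_kinds) {
  kinds <- vapply(covar_names, function(v) {
    if (is.factor(records[[v]]) || is.character(records[[v]]) ||
        is.logical(records[[v]])) "factor" else "numeric"
  }, character(1))
  if (!is.null(covariate_kinds)) {
    bad <- setdiff(names(covariate_kinds), covar_names)
    if (length(bad))
      stop("covariate_kinds given for unknown covariate(s): ",
           paste(bad, collapse = ", "))
    kinds[names(covariate_kinds)] <-
      vapply(covariate_kinds, match.arg, character(1), c("numeric", "factor"))
  }
  kinds
}

#' Read / write long-format multistate CSV
#'
#' The on-disk format is mstate-style long format: header row, columns
#' \code{id, from, to, entry, exit, status}, then covariates. Censoring is
#' encoded as destination state 0 with status 0.
#'
#' @param path CSV file path.
#' @inheritParams multistate_dataset
#' @return \code{read_long_csv} returns a validated
#'   \code{multistate_dataset}; \code{write_long_csv} invisibly returns
#'   \code{path}.
#' @export
read_long_csv <- function(path, structure, covariate_kinds = NULL) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE)
  multistate_dataset(records, structure, covariate_kinds)
}

#' @rdname read_long_csv
#' @param dataset a \code{multistate_dataset}.
#' @export
write_long_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "multistate_dataset"))
  utils::write.csv(dataset$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' State occupied by a subject at a given time
#'
#' Piecewise-constant interpolation of the subject's transition chain. For
#' a censored subject, times past last contact are unobservable and return
#' \code{NA} (the "state 0" convention used by the IPCW weights); a subject
#' absorbed at time t remains in the absorbing state for all later times.
#'
#' @param dataset a \code{multistate_dataset}.
#' @param subject_id subject identifier.
#' @param s nonnegative time (vectorized).
#' @return integer vector of state labels, \code{NA} where unobservable.
#' @export
state_at <- function(dataset, subject_id, s) {
  stopifnot(inherits(dataset, "multistate_dataset"), all(s >= 0))
  rr <- dataset$records[dataset$records$id == subject_id, , drop = FALSE]
  if (nrow(rr) == 0L) stop("unknown subject id: ", subject_id)
  vapply(s, function(si) {
    inside <- which(rr$entry <= si & si < rr$exit)
    if (length(inside)) return(as.integer(rr$from[inside[1L]]))
    last <- rr[nrow(rr), ]
    if (si >= last$exit) {
      if (last$status == 1) as.integer(last$to) else NA_integer_
    } else as.integer(rr$from[1L])  # si < first entry (= 0): initial state
  }, integer(1))
}

#' Extract the transition-specific dataset for one transition
#'
#' Implements the "separate approach": each transition \code{h -> j} is
#' modelled on its own risk set, consisting of every subject whose chain
#' visits state \code{h}. A subject's outcome on this dataset is an event
#' if they exited \code{h} to \code{j}; exits to any other state
#' ("competing") and last-contact censorings ("lost") are cause-specific
#' censorings. Time is measured on the transition's clock: study-clock exit
#' time under \code{clock = "forward"} (with delayed entry at the state
#' entry time \code{d}), sojourn duration under \code{clock = "reset"}.
#'
#' @param dataset a \code{multistate_dataset}.
#' @param transition length-2 integer vector \code{c(h, j)}.
#' @param augment_sojourn if \code{TRUE} and \code{h} is not the initial
#'   state, the state-entry time \code{d} is appended to the covariates as
#'   column \code{"d"} (the non-Markov augmentation); a no-op for the
#'   initial state where \code{d == 0} for everyone.
#' @return an object of class \code{transition_dataset}: list with
#'   \code{data} (columns \code{id, entry, time, status, cens_type,
#'   entry_offset}, then covariates; \code{entry} is the delayed-entry time
#'   on the transition clock), \code{transition}, \code{clock},
#'   \code{covariates} (named kinds vector) and \code{tau} (largest
#'   observed time on this clock).
#' @export
extract_transition_dataset <- function(dataset, transition,
                                       augment_sojourn = FALSE) {
  stopifnot(inherits(dataset, "multistate_dataset"), length(transition) == 2L)
  h <- as.integer(transition[1L]); j <- as.integer(transition[2L])
  st <- dataset$structure
  if (!has_transition(st, h, j))
    stop("transition ", trans_key(h, j), " is not in the structure")
  clock <- unname(st$clock[trans_key(h, j)])

  rr <- dataset$records[dataset$records$from == h, , drop = FALSE]
  d <- rr$entry
  time <- if (clock == "reset") rr$exit - rr$entry else rr$exit
  entry <- if (clock == "reset") rep(0, nrow(rr)) else d
  status <- as.integer(rr$status == 1 & rr$to == j)
  cens_type <- ifelse(status == 1, "event",
                      ifelse(rr$status == 1, "competing", "lost"))
  covar_names <- names(dataset$covariates)
  out <- data.frame(id = rr$id, entry = entry, time = time, status = status,
                    cens_type = cens_type, entry_offset = d,
                    stringsAsFactors = FALSE)
  out <- cbind(out, rr[covar_names])
  kinds <- dataset$covariates
  if (isTRUE(augment_sojourn) && h != st$initial) {
    out$d <- d
    kinds <- c(kinds, d = "numeric")
  }
  rownames(out) <- NULL
  structure(list(data = out, transition = c(h, j), clock = clock,
                 covariates = kinds,
                 tau = if (nrow(out)) max(out$time) else NA_real_),
            class = "transition_dataset")
}

#' @export
print.multistate_dataset <- function(x, ...) {
  cat("Multistate dataset:", length(unique(x$records$id)), "subjects,",
      nrow(x$records), "sojourn records, tau =", format(x$tau), "\n")
  cat("  covariates:",
      paste0(names(x$covariates), " (", x$covariates, ")", collapse = ", "),
      "\n")
  print(x$structure)
  invisible(x)
}

#' @export
print.transition_dataset <- function(x, ...) {
  cat("Transition dataset ", trans_key(x$transition[1L], x$transition[2L]),
      " [clock ", x$clock, "]: ", nrow(x$data), " subjects, ",
      sum(x$data$status), " events\n", sep = "")
  invisible(x)
}

# number of this transition's events in a td (cause-specific)
td_n_events <- function(td) sum(td$data$status == 1L)
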