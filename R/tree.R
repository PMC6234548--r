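#' Two-sample log-rank statistic
#'
#' Chi-square form of the two-sample log-rank test, ((O - E)^2 / V), used
#' as the splitting criterion: the larger the statistic, the more distinct
#' the survival experience of the two daughter nodes. Risk sets honour
#' delayed entry. A partition with no events contributes no information
#' and scores 0 (as does a degenerate hypergeometric variance).
#'
#' @param time observation times on the transition clock.
#' @param status 1 = event, 0 = censored.
#' @param group logical or two-level assignment: \code{TRUE}/first level =
#'   left daughter.
#' @param entry optional delayed-entry times (default 0).
#' @return nonnegative scalar.
#' @export
logrank_statistic <- function(time, status, group, entry = NULL) {
  if (is.null(entry)) entry <- rep(0, length(time))
  group <- if (is.logical(group)) group else group == group[
    which.min(duplicated(group))]
  if (!any(group) || all(group)) stop("both sides of the partition must be nonempty")
  ev <- sort(unique(time[status == 1L]))
  if (length(ev) == 0L) return(0)
  st <- sort(time); se <- sort(entry)
  st1 <- sort(time[group]); se1 <- sort(entry[group])
  Y <- findInterval(ev, se, left.open = TRUE) - findInterval(ev, st, left.open = TRUE)
  Y1 <- findInterval(ev, se1, left.open = TRUE) - findInterval(ev, st1, left.open = TRUE)
  f <- factor(time[status == 1L], levels = ev)
  d <- as.numeric(table(f))
  d1 <- as.numeric(table(f[group[status == 1L]]))
  O1 <- sum(d1)
  E1 <- sum(d * Y1 / Y)
  ok <- Y > 1
  V <- sum((d * (Y1 / Y) * (1 - Y1 / Y) * (Y - d) / (Y - 1))[ok])
  if (V <= 0) return(0)
  (O1 - E1)^2 / V
}

#' Propose random candidate splits at a node
#'
#' Draws \code{K} candidate covariates without replacement; for each
#' numeric covariate, \code{n_cuts} cut points are drawn uniformly from
#' the open range of its values observed at the node; for each categorical
#' covariate, a uniformly random nonempty proper subset of the observed
#' levels defines the left daughter. Covariates that are constant at the
#' node yield no candidate. Uses the current RNG state; seed upstream for
#' reproducibility.
#'
#' @param rows data.frame of node rows (covariate columns present), or a
#'   \code{transition_dataset}.
#' @param kinds named character vector of covariate kinds
#'   (\code{"numeric"}/\code{"factor"}); taken from \code{rows} when it is
#'   a \code{transition_dataset}.
#' @param K number of candidate covariates; default
#'   \code{floor(sqrt(p))}.
#' @param n_cuts random cut points per numeric candidate (default 1).
#' @return list of candidate split rules, each a list with \code{var},
#'   \code{kind} and \code{cut} (numeric) or \code{left_levels}
#'   (categorical); empty list if nothing is splittable.
#' @export
propose_splits <- function(rows, kinds = NULL, K = NULL, n_cuts = 1L) {
  if (inherits(rows, "transition_dataset")) {
    kinds <- rows$covariates
    rows <- rows$data
  }
  stopifnot(!is.null(kinds))
  p <- length(kinds)
  if (is.null(K)) K <- max(1L, floor(sqrt(p)))
  if (K > p) stop("K must not exceed the number of covariates")
  vars <- sample(names(kinds), K)
  out <- list()
  for (v in vars) {
    x <- rows[[v]]
    if (kinds[[v]] == "numeric") {
      rng <- range(x)
      if (!is.finite(rng[1L]) || rng[1L] >= rng[2L]) next
      for (cut in stats::runif(n_cuts, rng[1L], rng[2L])) {
        if (cut <= rng[1L] || cut >= rng[2L]) next  # guard open interval
        out[[length(out) + 1L]] <- list(var = v, kind = "numeric", cut = cut)
      }
    } else {
      lev <- sort(unique(as.character(x)))
      if (length(lev) < 2L) next
      # uniformly random nonempty proper subset
      repeat {
        pick <- lev[stats::runif(length(lev)) < 0.5]
        if (length(pick) > 0L && length(pick) < length(lev)) break
      }
      out[[length(out) + 1L]] <- list(var = v, kind = "factor",
                                      left_levels = pick,
                                      node_levels = lev)
    }
  }
  out
}

split_goes_left <- function(rule, x) {
  if (rule$kind == "numeric") x <= rule$cut
  else as.character(x) %in% rule$left_levels
}

# Recursive tree builder shared by ERMT and bootstrap trees.
# stop_mode "events": a candidate is valid only if both daughters keep >=
# stop_min cause-specific events (nodes with < 2*stop_min events are
# terminal outright, an equivalent shortcut). stop_mode "unique": the
# bootstrap-tree rule, both daughters must keep >= stop_min unique cases.
grow_tree_core <- function(dat, kinds, K, stop_mode, stop_min, n_cuts) {
  nodes <- list()
  build <- function(idx) {
    nid <- length(nodes) + 1L
    nodes[[nid]] <<- list()  # reserve slot
    size_of <- function(ii) {
      if (stop_mode == "events") sum(dat$status[ii] == 1L)
      else length(unique(dat$id[ii]))
    }
    make_terminal <- function() {
      na <- na_increments(dat$time[idx], dat$status[idx], dat$entry[idx])
      nodes[[nid]] <<- list(times = na$times, dA = na$dA,
                            n_risk = na$Y, n_event_t = na$dN,
                            n = length(idx), n_events = sum(dat$status[idx] == 1L))
      nid
    }
    if (size_of(idx) < 2L * stop_min) return(make_terminal())
    cand <- propose_splits(dat[idx, , drop = FALSE], kinds, K, n_cuts)
    best <- NULL; best_stat <- -Inf; best_left <- NULL
    for (rule in cand) {
      gl <- split_goes_left(rule, dat[[rule$var]][idx])
      if (!any(gl) || all(gl)) next
      if (size_of(idx[gl]) < stop_min || size_of(idx[!gl]) < stop_min) next
      stat <- logrank_statistic(dat$time[idx], dat$status[idx], gl,
                                dat$entry[idx])
      if (stat > best_stat) {  # ties broken by first candidate in order
        best_stat <- stat; best <- rule; best_left <- gl
      }
    }
    if (is.null(best)) return(make_terminal())
    left_id <- build(idx[best_left])
    right_id <- build(idx[!best_left])
    nodes[[nid]] <<- list(var = best$var, kind = best$kind,
                          cut = best$cut, left_levels = best$left_levels,
                          node_levels = best$node_levels,
                          statistic = best_stat,
                          left = left_id, right = right_id,
                          n = length(idx),
                          n_events = sum(dat$status[idx] == 1L))
    nid
  }
  build(seq_len(nrow(dat)))
  nodes
}

new_mstree <- function(td, nodes, params) {
  structure(list(transition = td$transition, clock = td$clock,
                 nodes = nodes, covariates = td$covariates,
                 params = params),
            class = "multistate_tree")
}

#' Grow an extremely randomized multistate tree (ERMT)
#'
#' Recursive partitioning of a transition dataset: at each node, K
#' candidate covariates with random cut points are proposed and the
#' candidate maximizing the log-rank statistic between daughters is kept.
#' A node becomes terminal when no candidate split leaves at least
#' \code{nmin} of this transition's events in each daughter (or nothing is
#' splittable). The tree is grown on the full dataset, without resampling.
#' Each terminal node carries the Nelson-Aalen cumulative hazard and the
#' product-limit survival curve of its rows.
#'
#' @param td a \code{transition_dataset}.
#' @param K candidate covariates per node; default \code{floor(sqrt(p))}.
#' @param nmin minimum observed events per terminal node (default 6).
#' @param seed optional integer seed.
#' @param n_cuts random cut points per numeric candidate.
#' @return a \code{multistate_tree}.
#' @export
grow_ermt <- function(td, K = NULL, nmin = 6L, seed = NULL, n_cuts = 1L) {
  stopifnot(inherits(td, "transition_dataset"), nmin >= 1L)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(K)) K <- max(1L, floor(sqrt(length(td$covariates))))
  if (td_n_events(td) == 0L)
    warning("transition dataset has no events; growing a zero-hazard stump")
  nodes <- grow_tree_core(td$data, td$covariates, K, "events", nmin, n_cuts)
  new_mstree(td, nodes, list(K = K, nmin = nmin, n_cuts = n_cuts,
                             seed = seed, mode = "ermt"))
}

#' Grow a bootstrap multistate tree (for MSRSF)
#'
#' As [grow_ermt()], but grown on a with-replacement bootstrap sample of
#' the rows; on average about 37\% of rows are excluded (out-of-bag). The
#' stopping rule follows the forest convention: every terminal node keeps
#' at least \code{n0} unique cases of the bootstrap sample.
#'
#' @inheritParams grow_ermt
#' @param n0 minimum unique cases per terminal node (default 6).
#' @return list with \code{tree} (a \code{multistate_tree}), \code{oob}
#'   (row indices of \code{td} not drawn) and \code{inbag} (drawn row
#'   indices, with multiplicity).
#' @export
grow_bootstrap_tree <- function(td, K = NULL, n0 = 6L, seed = NULL,
                                n_cuts = 1L) {
  stopifnot(inherits(td, "transition_dataset"), n0 >= 1L)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(K)) K <- max(1L, floor(sqrt(length(td$covariates))))
  n <- nrow(td$data)
  inbag <- sample.int(n, n, replace = TRUE)
  oob <- setdiff(seq_len(n), inbag)
  dat <- td$data[inbag, , drop = FALSE]
  nodes <- grow_tree_core(dat, td$covariates, K, "unique", n0, n_cuts)
  tree <- new_mstree(td, nodes, list(K = K, n0 = n0, n_cuts = n_cuts,
                                     seed = seed, mode = "bootstrap"))
  list(tree = tree, oob = oob, inbag = inbag)
}

# Vectorized routing of covariate rows to terminal node ids. When a split
# variable is in randomize_on, each row goes to a uniformly random
# daughter (the random-daughter VIMP mechanism). Unseen categorical
# levels route right and are tallied in attr(,"unseen").
route_rows <- function(tree, Z, randomize_on = NULL) {
  res <- integer(nrow(Z))
  unseen <- 0L
  rec <- function(nid, idx) {
    node <- tree$nodes[[nid]]
    if (is.null(node$var)) { res[idx] <<- nid; return(invisible()) }
    if (!is.null(randomize_on) && node$var %in% randomize_on) {
      go_left <- stats::runif(length(idx)) < 0.5
    } else {
      if (!node$var %in% names(Z))
        stop("covariate '", node$var, "' missing from prediction data")
      v <- Z[[node$var]][idx]
      if (node$kind == "numeric") {
        go_left <- v <= node$cut
      } else {
        vc <- as.character(v)
        unseen <<- unseen + sum(!vc %in% node$node_levels)
        go_left <- vc %in% node$left_levels
      }
    }
    if (any(go_left)) rec(node$left, idx[go_left])
    if (!all(go_left)) rec(node$right, idx[!go_left])
    invisible()
  }
  rec(1L, seq_len(nrow(Z)))
  attr(res, "unseen") <- unseen
  res
}

#' Drop a case down a multistate tree
#'
#' Routes a covariate vector through the tree's split rules to a terminal
#' node and returns that node's estimators. With \code{randomize_on}, the
#' case is sent to a uniformly random daughter whenever a split on one of
#' the listed variables is met — the mechanism behind random-daughter
#' variable importance.
#'
#' @param tree a \code{multistate_tree}.
#' @param z single-row data.frame (or coercible list) of covariates.
#' @param randomize_on character vector of variable names whose splits are
#'   randomized.
#' @return list with \code{times}, \code{dA} (terminal Nelson-Aalen
#'   increments), \code{surv} (terminal product-limit survival at the jump
#'   times), \code{n}, \code{n_events} and \code{node} (terminal id).
#' @export
drop_down <- function(tree, z, randomize_on = NULL) {
  Z <- as.data.frame(z)
  stopifnot(nrow(Z) == 1L)
  nid <- route_rows(tree, Z, randomize_on)[1L]
  node <- tree$nodes[[nid]]
  list(times = node$times, dA = node$dA,
       surv = cumprod(1 - node$dA), n = node$n,
       n_events = node$n_events, node = nid)
}

tree_depth <- function(tree) {
  depth_of <- function(nid) {
    node <- tree$nodes[[nid]]
    if (is.null(node$var)) return(1L)
    1L + max(depth_of(node$left), depth_of(node$right))
  }
  depth_of(1L)
}

tree_terminal_ids <- function(tree) {
  which(vapply(tree$nodes, function(nd) is.null(nd$var), logical(1)))
}

tree_split_vars <- function(tree) {
  unique(unlist(lapply(tree$nodes, function(nd) nd$var)))
}

#' @export
print.multistate_tree <- function(x, ...) {
  nt <- length(tree_terminal_ids(x))
  cat("Multistate tree for ", trans_key(x$transition[1L], x$transition[2L]),
      ": ", length(x$nodes), " nodes (", nt, " terminal), depth ",
      tree_depth(x), "\n", sep = "")
  invisible(x)
}
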