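## Stochastic simulator of GRB evolution after whole-genome duplication.
##
## A cluster of N UCNEs sits upstream of its target gene; a fraction q of
## the N(N-1)/2 element pairs interact. After duplication both copies start
## intact. Mutational events -- synteny breaks at inter-element gaps
## (disconnecting all elements distal to the break from the target) and
## single-element knockouts -- are proposed uniformly and accepted only if
## every interacting pair keeps both members connected to the target in at
## least one common copy (and, under the stand-alone constraint, every
## element stays connected in at least one copy). The process runs to
## fixation: the state where no remaining event is acceptable.
##
## Proposals that would be rejected leave the state unchanged, so the chain
## of *accepted* events is equivalently simulated by choosing uniformly
## (type-weighted) among the currently acceptable events; fixation is then
## detected exactly by exhausting the candidate list.

#' Simulation configuration for GRB evolution after duplication
#'
#' @param N number of UCNEs in the cluster (>= 2).
#' @param q fraction of interacting element pairs in `[0, 1]`; the number of
#'   pairs is `round_half_up(q * N(N-1)/2)`, sampled uniformly without
#'   replacement.
#' @param n_reps number of replicates for [sim_sweep()] (default 10000).
#' @param standalone_constraint logical; when `TRUE` (default) every
#'   element, interacting or not, must stay connected to the target in at
#'   least one copy. Without it, q = 0 erodes both copies completely.
#' @param event_weights named numeric vector `c(knockout = , break = )` of
#'   per-event relative proposal weights (default both 1: uniform over all
#'   candidate events).
#' @param seed optional RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(N, q, n_reps = 10000, standalone_constraint = TRUE,
                       event_weights = c(knockout = 1, "break" = 1),
                       seed = NULL) {
  stopifnot(N >= 2, q >= 0, q <= 1, n_reps >= 1)
  stopifnot(all(c("knockout", "break") %in% names(event_weights)),
            all(event_weights >= 0), any(event_weights > 0))
  structure(list(N = as.integer(N), q = q, n_reps = as.integer(n_reps),
                 standalone_constraint = isTRUE(standalone_constraint),
                 event_weights = event_weights, seed = seed),
            class = "sim_config")
}

## round-half-up (round() uses banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

#' Initialize one simulation replicate
#'
#' Both cluster copies start fully connected; the interaction graph is
#' sampled uniformly without replacement from the N(N-1)/2 possible pairs
#' and stays fixed for the replicate.
#'
#' @param config a [sim_config()].
#' @return a `grb_state`: list with `conn` (N x 2 logical connectivity
#'   matrix), `pairs` (2-column matrix of interacting element indices) and
#'   `config`.
#' @export
init_replicate <- function(config) {
  N <- config$N
  npair_all <- N * (N - 1) / 2
  npair <- round_half_up(config$q * npair_all)
  all_pairs <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
  sel <- if (npair > 0) all_pairs[sample.int(npair_all, npair), , drop = FALSE]
         else all_pairs[0, , drop = FALSE]
  structure(list(conn = matrix(TRUE, N, 2), pairs = unname(sel),
                 config = config),
            class = "grb_state")
}

## Candidate (effective) events of a state: every knockout of a connected
## element and every break at an inter-element gap k (1..N-1) that would
## disconnect at least one element, i.e. k < max(connected index).
## Returns a data.frame(type, copy, pos, weight).
candidate_events <- function(state) {
  w <- state$config$event_weights
  out <- list()
  for (cp in 1:2) {
    idx <- which(state$conn[, cp])
    if (length(idx)) {
      out[[length(out) + 1L]] <- data.frame(type = "knockout", copy = cp,
                                            pos = idx, weight = w[["knockout"]])
      mx <- max(idx)
      if (mx > 1) {
        out[[length(out) + 1L]] <- data.frame(type = "break", copy = cp,
                                              pos = seq_len(mx - 1),
                                              weight = w[["break"]])
      }
    }
  }
  if (!length(out)) {
    return(data.frame(type = character(0), copy = integer(0),
                      pos = integer(0), weight = numeric(0)))
  }
  do.call(rbind, out)
}

## connectivity matrix after applying an event (no constraint check)
apply_event_conn <- function(conn, type, copy, pos) {
  if (type == "knockout") {
    conn[pos, copy] <- FALSE
  } else {
    kill <- seq_len(nrow(conn)) > pos
    conn[kill, copy] <- FALSE
  }
  conn
}

## does a connectivity matrix satisfy the acceptance constraints?
constraints_ok <- function(conn, pairs, standalone) {
  if (standalone && !all(conn[, 1] | conn[, 2])) return(FALSE)
  if (nrow(pairs)) {
    i <- pairs[, 1]; j <- pairs[, 2]
    ok <- (conn[i, 1] & conn[j, 1]) | (conn[i, 2] & conn[j, 2])
    if (!all(ok)) return(FALSE)
  }
  TRUE
}

#' Propose a mutational event
#'
#' Draws one event at random (weighted by the configured event weights)
#' from the candidate events of the state: knockouts of connected elements
#' and synteny breaks that would disconnect at least one element.
#'
#' @param state a `grb_state` from [init_replicate()].
#' @return list with `type` (`"knockout"` or `"break"`), `copy` (1 or 2)
#'   and `pos` (element index, or gap index for breaks); `NULL` if no
#'   candidate events remain.
#' @export
propose_event <- function(state) {
  cand <- candidate_events(state)
  if (!nrow(cand)) return(NULL)
  k <- sample.int(nrow(cand), 1, prob = cand$weight)
  list(type = cand$type[k], copy = cand$copy[k], pos = cand$pos[k])
}

#' Test whether an event is accepted
#'
#' An event is accepted iff, after applying it, every interacting pair has
#' both members connected to the target in at least one common copy, and
#' (under the stand-alone constraint) every element remains connected in at
#' least one copy. Rejected events leave the state unchanged.
#'
#' @param state a `grb_state`.
#' @param event list as returned by [propose_event()].
#' @return logical.
#' @export
accept_event <- function(state, event) {
  conn <- apply_event_conn(state$conn, event$type, event$copy, event$pos)
  constraints_ok(conn, state$pairs, state$config$standalone_constraint)
}

#' Apply an accepted event to a state
#'
#' @inheritParams accept_event
#' @return the updated `grb_state`.
#' @export
apply_event <- function(state, event) {
  state$conn <- apply_event_conn(state$conn, event$type, event$copy, event$pos)
  state
}

## endpoint (a, b, c) and label from a final connectivity matrix;
## major copy = larger surviving-connected set, ties toward copy 1.
endpoint_from_conn <- function(conn) {
  n1 <- sum(conn[, 1]); n2 <- sum(conn[, 2])
  major <- if (n2 > n1) 2L else 1L
  minor <- 3L - major
  a <- sum(conn[, major] & !conn[, minor])
  b <- sum(conn[, major] & conn[, minor])
  c <- sum(!conn[, major] & conn[, minor])
  label <- if (a + b + c > 0) classify_pattern(a, b, c) else NA_character_
  list(a = a, b = b, c = c, label = label, major_copy = major,
       major_tie = n1 == n2)
}

#' Run one replicate to fixation
#'
#' Iterates mutational events until no acceptable event remains. Because a
#' rejected proposal leaves the state unchanged, the first accepted proposal
#' is distributed uniformly (type-weighted) over the acceptable events, so
#' the accepted-event chain is simulated directly by sampling from the
#' acceptable set; fixation is detected by exhausting it. Every accepted
#' event disconnects at least one element, so fixation is reached within
#' 2N accepted events.
#'
#' @param config a [sim_config()].
#' @param seed optional RNG seed for this replicate.
#' @return a `sim_endpoint`: list with `a`, `b`, `c`, `label`,
#'   `major_copy`, `major_tie`, `n_events` (accepted events applied) and
#'   the final `conn` matrix.
#' @export
run_to_fixation <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  state <- init_replicate(config)
  standalone <- config$standalone_constraint
  n_events <- 0L
  repeat {
    cand <- candidate_events(state)
    if (!nrow(cand)) break
    ok <- vapply(seq_len(nrow(cand)), function(k) {
      conn <- apply_event_conn(state$conn, cand$type[k], cand$copy[k],
                               cand$pos[k])
      constraints_ok(conn, state$pairs, standalone)
    }, logical(1))
    if (!any(ok)) break
    acc <- which(ok)
    k <- if (length(acc) == 1) acc else
      acc[sample.int(length(acc), 1, prob = cand$weight[acc])]
    state$conn <- apply_event_conn(state$conn, cand$type[k], cand$copy[k],
                                   cand$pos[k])
    n_events <- n_events + 1L
  }
  ep <- endpoint_from_conn(state$conn)
  ep$n_events <- n_events
  ep$conn <- state$conn
  class(ep) <- "sim_endpoint"
  ep
}

#' Sweep endpoint label fractions over a (N, q) grid
#'
#' Runs `n_reps` replicates to fixation for every combination of `N` and
#' `q` and tabulates the fractions of winner-takes-all, concordant and
#' reciprocal endpoints with binomial standard errors.
#'
#' @param N integer vector of cluster sizes.
#' @param q numeric vector of connectivity fractions.
#' @param n_reps replicates per grid cell (default 10000).
#' @param seed RNG seed (one stream across the whole sweep).
#' @param standalone_constraint,event_weights passed to [sim_config()].
#' @return data.frame with columns `N`, `q`, `reps`, `frac_winner`,
#'   `frac_concordant`, `frac_reciprocal`, `se` (binomial SE of
#'   `frac_winner`).
#' @export
sim_sweep <- function(N, q, n_reps = 10000, seed = NULL,
                      standalone_constraint = TRUE,
                      event_weights = c(knockout = 1, "break" = 1)) {
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(N = N, q = q)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    cfg <- sim_config(grid$N[g], grid$q[g], n_reps = n_reps,
                      standalone_constraint = standalone_constraint,
                      event_weights = event_weights)
    labels <- vapply(seq_len(n_reps),
                     function(r) run_to_fixation(cfg)$label %||% "none",
                     character(1))
    fw <- mean(labels == "winner")
    data.frame(N = grid$N[g], q = grid$q[g], reps = n_reps,
               frac_winner = fw,
               frac_concordant = mean(labels == "concordant"),
               frac_reciprocal = mean(labels == "reciprocal"),
               se = sqrt(fw * (1 - fw) / n_reps))
  })
  do.call(rbind, rows)
}

`%||%` <- function(x, y) if (is.null(x) || is.na(x)) y else x

#' Exact endpoint distribution by exhaustive enumeration
#'
#' Independent oracle for [run_to_fixation()]: enumerates the Markov chain
#' over connectivity states exactly, conditioning on a fixed interaction
#' graph. At each state the acceptable events are enumerated and followed
#' with their (type-weighted) proposal probabilities; results are memoized
#' per state. Feasible for small N (state space grows as 4^N).
#'
#' @param pairs 2-column matrix of interacting element index pairs.
#' @param N number of elements.
#' @param standalone_constraint,event_weights as in [sim_config()].
#' @return named numeric vector of endpoint label probabilities over
#'   `c("winner", "concordant", "reciprocal", "none")`.
#' @export
enumerate_endpoints <- function(pairs, N, standalone_constraint = TRUE,
                                event_weights = c(knockout = 1, "break" = 1)) {
  memo <- new.env(parent = emptyenv())
  labels <- c("winner", "concordant", "reciprocal", "none")
  state0 <- structure(list(conn = matrix(TRUE, N, 2),
                           pairs = pairs,
                           config = list(event_weights = event_weights,
                                         standalone_constraint = standalone_constraint)),
                      class = "grb_state")
  rec <- function(conn) {
    key <- paste(as.integer(conn), collapse = "")
    if (!is.null(memo[[key]])) return(memo[[key]])
    st <- state0
    st$conn <- conn
    cand <- candidate_events(st)
    ok <- if (nrow(cand)) vapply(seq_len(nrow(cand)), function(k) {
      constraints_ok(apply_event_conn(conn, cand$type[k], cand$copy[k],
                                      cand$pos[k]),
                     pairs, standalone_constraint)
    }, logical(1)) else logical(0)
    if (!any(ok)) {
      ep <- endpoint_from_conn(conn)
      d <- setNames(numeric(4), labels)
      d[ep$label %||% "none"] <- 1
    } else {
      acc <- which(ok)
      wts <- cand$weight[acc] / sum(cand$weight[acc])
      d <- setNames(numeric(4), labels)
      for (m in seq_along(acc)) {
        k <- acc[m]
        d <- d + wts[m] * rec(apply_event_conn(conn, cand$type[k],
                                               cand$copy[k], cand$pos[k]))
      }
    }
    memo[[key]] <- d
    d
  }
  rec(matrix(TRUE, N, 2))
}
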