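## Detection and elimination of "independent" rearrangement events.
##
## An independent transposition swaps two adjacent blocks so that a window
## of four becomes signed-consecutive (+ (q-1) +q +(q+1) +(q+2) or its
## negative mirror); the inverted variant additionally restores one sign.
## Independent (inverted) block interchanges swap two separated single
## blocks so that both flanking triples become signed-consecutive.  Each
## transposition-kind event removes exactly 3 breakpoints, each
## interchange-kind event exactly 4; eliminating them before the inversion
## analysis keeps spurious inversions out of the computed scenarios.
##
## All detectors work on the capped extension (sentinels +0 and +(n+1)), so
## events touching a scaffold end are matched like interior ones.  A window
## (w1, w2, w3, w4) is signed-consecutive iff each entry is its left
## neighbour plus one, which covers both the ascending-positive and the
## descending-negative mirror patterns at once.

consecutive_run <- function(v) all(diff(v) == 1L)

new_event <- function(kind, positions, blocks, sign_detail = NA_character_) {
  structure(list(kind = kind, positions = positions, blocks = blocks,
                 sign_detail = sign_detail), class = "rearrangement_event")
}

#' @export
print.rearrangement_event <- function(x, ...) {
  cat(sprintf("%s at positions (%s); blocks (%s)%s\n", x$kind,
              paste(x$positions, collapse = ","),
              paste(x$blocks, collapse = ","),
              if (is.na(x$sign_detail)) "" else paste0(" [", x$sign_detail, "]")))
  invisible(x)
}

#' Detect independent rearrangement events in a permutation
#'
#' The four detectors scan a signed permutation (capped internally with
#' sentinels +0 and +(n+1)) for the restricted event patterns whose
#' application resolves all breakpoints at the event's junctions:
#' \describe{
#'   \item{transposition}{adjacent pair (pi_{i+1}, pi_i) whose swap makes a
#'     window of four signed-consecutive; 3 breakpoints resolved.}
#'   \item{inverted transposition}{adjacent pair with one sign flipped,
#'     (-pi_{i+1}, pi_i) or (pi_{i+1}, -pi_i); 3 breakpoints resolved.}
#'   \item{block interchange}{two separated single blocks whose swap makes
#'     both flanking triples signed-consecutive; 4 breakpoints resolved.}
#'   \item{inverted block interchange}{as above with both signs flipped.}
#' }
#' Positions in the returned events are 1-based positions in the uncapped
#' permutation; `blocks` holds the signed entries involved.
#'
#' @param perm signed permutation.
#' @return list of `rearrangement_event` objects (possibly empty), in
#'   left-to-right scan order.
#' @export
find_independent_transpositions <- function(perm) {
  e <- cap_perm(perm)
  out <- list()
  for (t in 2:(length(e) - 2L)) {
    w <- e[(t - 1L):(t + 2L)]
    if (w[2L] != w[3L] && consecutive_run(w[c(1L, 3L, 2L, 4L)]))
      out[[length(out) + 1L]] <- new_event(
        "transposition", c(t - 1L, t), w[2:3])
  }
  out
}

#' @rdname find_independent_transpositions
#' @export
find_independent_inverted_transpositions <- function(perm) {
  e <- cap_perm(perm)
  out <- list()
  for (t in 2:(length(e) - 2L)) {
    w <- e[(t - 1L):(t + 2L)]
    ## pattern 1: (pi_{i-1}, -pi_{i+1}, pi_i, pi_{i+2})
    if (consecutive_run(c(w[1L], w[3L], -w[2L], w[4L])))
      out[[length(out) + 1L]] <- new_event(
        "inverted_transposition", c(t - 1L, t), w[2:3], "first_flipped")
    ## pattern 2: (pi_{i-1}, pi_{i+1}, -pi_i, pi_{i+2})
    else if (consecutive_run(c(w[1L], -w[3L], w[2L], w[4L])))
      out[[length(out) + 1L]] <- new_event(
        "inverted_transposition", c(t - 1L, t), w[2:3], "second_flipped")
  }
  out
}

#' @rdname find_independent_transpositions
#' @export
find_independent_block_interchanges <- function(perm) {
  e <- cap_perm(perm)
  n <- length(e) - 2L
  out <- list()
  for (ti in 2:(length(e) - 1L)) {
    for (tk in ti:(length(e) - 1L)) {
      if (tk - ti < 2L) next                 # adjacent swaps are transpositions
      x <- e[ti]; y <- e[tk]
      if (consecutive_run(c(e[ti - 1L], y, e[ti + 1L])) &&
          consecutive_run(c(e[tk - 1L], x, e[tk + 1L])))
        out[[length(out) + 1L]] <- new_event(
          "block_interchange", c(ti - 1L, tk - 1L), c(x, y))
    }
  }
  out
}

#' @rdname find_independent_transpositions
#' @export
find_independent_inverted_block_interchanges <- function(perm) {
  e <- cap_perm(perm)
  out <- list()
  for (ti in 2:(length(e) - 1L)) {
    for (tk in ti:(length(e) - 1L)) {
      if (tk - ti < 2L) next
      x <- e[ti]; y <- e[tk]                 # x = -pi_k, y = -pi_i
      if (consecutive_run(c(e[ti - 1L], -y, e[ti + 1L])) &&
          consecutive_run(c(e[tk - 1L], -x, e[tk + 1L])))
        out[[length(out) + 1L]] <- new_event(
          "inverted_block_interchange", c(ti - 1L, tk - 1L), c(x, y),
          "both_flipped")
    }
  }
  out
}

## apply the resolving swap of an event to an (uncapped) permutation
apply_event <- function(perm, ev) {
  i <- ev$positions[1L]
  switch(ev$kind,
    transposition = {
      perm[c(i, i + 1L)] <- perm[c(i + 1L, i)]
    },
    inverted_transposition = {
      ## pattern 1 current = (-pi_{i+1}, pi_i), target (pi_i, pi_{i+1});
      ## pattern 2 current = (pi_{i+1}, -pi_i), target (pi_i, pi_{i+1})
      w <- perm[c(i, i + 1L)]
      perm[c(i, i + 1L)] <- if (ev$sign_detail == "first_flipped")
        c(w[2L], -w[1L]) else c(-w[2L], w[1L])
    },
    block_interchange = {
      k <- ev$positions[2L]
      perm[c(i, k)] <- perm[c(k, i)]
    },
    inverted_block_interchange = {
      k <- ev$positions[2L]
      perm[c(i, k)] <- c(-perm[k], -perm[i])
    },
    stop("unknown event kind: ", ev$kind))
  perm
}

#' Eliminate independent rearrangement events between two scaffolds
#'
#' Iteratively: collapse common adjacencies of the pair, scan the second
#' permutation (relabelled against the first) for independent events in a
#' fixed priority order -- transposition, inverted transposition, block
#' interchange, inverted block interchange, leftmost match first -- apply
#' the resolving swap, and repeat until no event remains.  Every applied
#' transposition-kind event is checked to remove exactly 3 breakpoints and
#' every interchange-kind event exactly 4; a violation aborts.
#'
#' Event `blocks` are reported as runs of original `a`-frame block labels
#' (merged regions keep the full label run), so counts per kind give the
#' non-inversion rearrangement distance between the scaffolds.
#'
#' @param a,b signed permutations over the same block set (no duplicates).
#' @return list with `a`, `b` (the reduced, renumbered pair after a final
#'   collapse; `a` is an identity), `events` (list of
#'   `rearrangement_event`), and `counts` (named integer vector per kind).
#' @examples
#' eliminate_independent_events(identity_perm(5), c(1, 2, 4, 3, 5))$counts
#' @export
eliminate_independent_events <- function(a, b) {
  a <- as_signed_perm(a); b <- as_signed_perm(b)
  if (length(a) != length(b) || !setequal(abs(a), abs(b)))
    stop("permutations must be over the same block set (deduplicate first)")
  kinds <- c("transposition", "inverted_transposition",
             "block_interchange", "inverted_block_interchange")
  finders <- list(find_independent_transpositions,
                  find_independent_inverted_transpositions,
                  find_independent_block_interchanges,
                  find_independent_inverted_block_interchanges)
  expected_delta <- c(3L, 3L, 4L, 4L)
  events <- list()

  cc <- collapse_common_adjacencies(a, b)
  cur <- cc$b
  groups <- cc$groups                     # current id -> original a labels
  repeat {
    found <- NULL
    for (k in seq_along(kinds)) {
      hits <- finders[[k]](cur)
      if (length(hits)) { found <- hits[[1L]]; delta <- expected_delta[k]; break }
    }
    if (is.null(found)) break
    before <- perm_breakpoints(cur)
    nxt <- apply_event(cur, found)
    after <- perm_breakpoints(nxt)
    if (before - after != delta)
      stop(sprintf("breakpoint-delta violation: %s removed %d breakpoints, expected %d",
                   found$kind, before - after, delta))
    ## translate involved blocks to original labels before re-collapsing
    found$blocks <- lapply(found$blocks, function(sv) {
      run <- groups[[abs(sv)]]
      if (sv > 0L) run else -rev(run)
    })
    events[[length(events) + 1L]] <- found
    ## re-collapse the reduced pair, composing the grouping record
    cc <- collapse_common_adjacencies(seq_along(nxt), nxt)
    groups <- lapply(cc$groups, function(run)
      unlist(lapply(run, function(sv) {
        g <- groups[[abs(sv)]]
        if (sv > 0L) g else -rev(g)
      })))
    cur <- cc$b
  }
  counts <- vapply(kinds, function(k)
    sum(vapply(events, function(e) e$kind == k, logical(1))), integer(1))
  list(a = seq_along(cur), b = cur, events = events, counts = counts,
       groups = groups)
}
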