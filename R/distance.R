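## Exact minimum-inversion distance between signed permutations via
## breakpoint-graph theory: d = (n+1) - c + h + f, where c counts the
## alternating cycles of the capped graph, h the hurdles among unoriented
## components of the cycle-interleaving graph and f flags a fortress.

## gray edges with 0-based positions in the doubled sequence; a gray edge is
## oriented iff its endpoint positions share parity (the reversal acting on
## its two black edges then merges/splits cycles favourably).
gray_edge_table <- function(perm) {
  L <- double_perm(perm)
  n <- length(perm)
  posv <- integer(2L * n + 2L)     # posv[value + 1] = 0-based position
  posv[L + 1L] <- seq_along(L) - 1L
  j <- 0:n
  p1 <- posv[2L * j + 1L]
  p2 <- posv[2L * j + 2L]
  data.frame(
    lo = pmin(p1, p2), hi = pmax(p1, p2),
    oriented = (p1 + p2) %% 2L == 0L
  )
}

## map each gray edge to its cycle id
gray_cycle_ids <- function(bg, n) {
  cyc_of <- integer(2L * n + 2L)
  for (k in seq_along(bg$cycles)) cyc_of[bg$cycles[[k]] + 1L] <- k
  cyc_of[bg$gray[, 1L] + 1L]      # both endpoints share the cycle
}

## hurdle count for a set of unoriented component spans (matrix lo,hi):
## minimal components (containing no other unoriented component) are
## hurdles; one extra hurdle if a non-minimal component contains all others.
count_hurdles <- function(spans) {
  k <- nrow(spans)
  if (k == 0L) return(0L)
  contains <- function(i, j)                 # span i strictly contains span j
    spans[i, 1L] <= spans[j, 1L] && spans[j, 2L] <= spans[i, 2L] && i != j
  minimal <- vapply(seq_len(k), function(i)
    !any(vapply(seq_len(k), function(j) contains(i, j), logical(1))),
    logical(1))
  h <- sum(minimal)
  greatest <- vapply(seq_len(k), function(i)
    all(vapply(seq_len(k)[-i], function(j) contains(i, j), logical(1))),
    logical(1))
  if (any(greatest & !minimal)) h <- h + 1L
  as.integer(h)
}

#' Exact inversion distance to the identity
#'
#' Computes the minimum number of inversions transforming `perm` into
#' +1+2...+n, by cycle decomposition of the breakpoint graph with the
#' hurdle and fortress corrections.  The result is contractually equal to
#' the exhaustive [bfs_oracle()] wherever the oracle is feasible.
#'
#' @param perm signed permutation.
#' @return object of class `distance_detail`: list with `distance`,
#'   `cycles`, `hurdles`, `fortress` satisfying
#'   `distance == (n+1) - cycles + hurdles + fortress`.
#' @examples
#' inversion_distance(c(1, 2, 4, 3, 5))$distance   # 3
#' inversion_distance(c(1, 2, -4, 3, 5))$distance  # 2
#' @export
inversion_distance <- function(perm) {
  perm <- as_signed_perm(perm)
  n <- length(perm)
  bg <- breakpoint_graph(perm)
  cyc <- length(bg$cycles)

  ge <- gray_edge_table(perm)
  gcyc <- gray_cycle_ids(bg, n)
  nontrivial <- which(bg$cycle_sizes > 2L)

  h <- 0L; f <- 0L
  if (length(nontrivial)) {
    idx <- which(gcyc %in% nontrivial)
    lo <- ge$lo[idx]; hi <- ge$hi[idx]; ori <- ge$oriented[idx]
    cid <- match(gcyc[idx], nontrivial)      # cycle index within nontrivial

    ## union-find over nontrivial cycles, joined when gray edges interleave
    parent <- seq_along(nontrivial)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    m <- length(idx)
    if (m > 1L) {
      for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
        inter <- xor(lo[i] < lo[j] && lo[j] < hi[i],
                     lo[i] < hi[j] && hi[j] < hi[i])
        if (inter) {
          ri <- find(cid[i]); rj <- find(cid[j])
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
    roots <- vapply(cid, find, integer(1))
    comp_or <- tapply(ori, roots, any)
    comp_lo <- tapply(lo, roots, min)
    comp_hi <- tapply(hi, roots, max)
    un <- which(!comp_or)
    spans <- cbind(comp_lo[un], comp_hi[un])
    h <- count_hurdles(spans)
    if (h %% 2L == 1L && h > 1L) {
      ## fortress: h odd and every hurdle is a superhurdle, i.e. deleting
      ## it does not lower the hurdle count (a protected non-hurdle
      ## unoriented component becomes a hurdle in its place)
      k <- nrow(spans)
      contains <- function(i, j)
        spans[i, 1L] <= spans[j, 1L] && spans[j, 2L] <= spans[i, 2L] && i != j
      minimal <- vapply(seq_len(k), function(i)
        !any(vapply(seq_len(k), function(j) contains(i, j), logical(1))),
        logical(1))
      greatest <- vapply(seq_len(k), function(i)
        all(vapply(seq_len(k)[-i], function(j) contains(i, j), logical(1))),
        logical(1))
      hurdle_idx <- which(minimal | (greatest & !minimal))
      super <- vapply(hurdle_idx, function(kk)
        count_hurdles(spans[-kk, , drop = FALSE]) >= h, logical(1))
      if (length(hurdle_idx) && all(super)) f <- 1L
    }
  }
  structure(list(
    distance = as.integer((n + 1L) - cyc + h + f),
    cycles = as.integer(cyc), hurdles = as.integer(h), fortress = as.integer(f)
  ), class = "distance_detail")
}

#' @export
print.distance_detail <- function(x, ...) {
  cat("inversion distance:", x$distance,
      sprintf("(cycles %d, hurdles %d, fortress %d)\n",
              x$cycles, x$hurdles, x$fortress))
  invisible(x)
}

## relabel (a, b) so that b becomes the identity; returns transformed a
relabel_to_target <- function(a, b) {
  a <- as_signed_perm(a); b <- as_signed_perm(b)
  if (length(a) != length(b) || !setequal(abs(a), abs(b)))
    stop("permutations must be over the same block set")
  m <- integer(length(b))
  m[abs(b)] <- seq_along(b) * sign(b)
  sign(a) * m[abs(a)]
}

#' Inversion distance between two scaffolds
#'
#' Relabels so the second permutation becomes the identity, then applies
#' [inversion_distance()].  Symmetric in its arguments.
#'
#' @param a,b signed permutations over the same block set (no duplicates;
#'   duplicated blocks must be resolved upstream, see [dedup_duplicates()]).
#' @return `distance_detail` for the pair.
#' @export
pairwise_distance <- function(a, b) {
  inversion_distance(relabel_to_target(a, b))
}

#' Parsimonious inversion scenario between two scaffolds
#'
#' Greedy construction of one optimal scenario: at each step, among all
#' inversions that reduce the exact distance by one, the one with the
#' smallest left position (then smallest right position) is applied.  The
#' returned steps, applied in order to `a`, yield `b`, and their number
#' equals `pairwise_distance(a, b)$distance`.
#'
#' @param a,b signed permutations over the same block set.
#' @return object of class `inversion_scenario`: list with `steps`
#'   (two-column matrix of (i, j) positions on the evolving source frame)
#'   and `distance`.
#' @export
optimal_scenario <- function(a, b) {
  cur <- relabel_to_target(a, b)
  n <- length(cur)
  d <- inversion_distance(cur)$distance
  steps <- matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("i", "j")))
  while (d > 0L) {
    found <- FALSE
    for (i in seq_len(n)) {
      for (j in i:n) {
        cand <- cur
        cand[i:j] <- -rev(cand[i:j])
        if (inversion_distance(cand)$distance == d - 1L) {
          steps <- rbind(steps, c(i, j))
          cur <- cand
          d <- d - 1L
          found <- TRUE
          break
        }
      }
      if (found) break
    }
    if (!found) stop("internal error: no distance-reducing inversion found")
  }
  structure(list(steps = steps, distance = nrow(steps)),
            class = "inversion_scenario")
}

#' @export
print.inversion_scenario <- function(x, ...) {
  cat("inversion scenario of length", x$distance, "\n")
  if (x$distance > 0)
    cat(paste(sprintf("  (%d,%d)", x$steps[, 1], x$steps[, 2]),
              collapse = "\n"), "\n")
  invisible(x)
}

## ---- exhaustive oracle ----------------------------------------------------

## encode signed permutations as numeric keys: symbol s in 1..2n per entry,
## key = sum s_i * (2n+1)^(i-1); exact in doubles for n <= 8.
perm_codes <- function(mat, n) {
  sym <- ifelse(mat > 0, mat, n - mat)       # -k -> n + k
  pows <- (2 * n + 1)^(0:(n - 1))
  as.vector(sym %*% pows)
}

## breadth-first search over the whole space from the identity, vectorised
## over the frontier; returns list(codes, dist) for every reachable state.
bfs_all_distances <- function(n) {
  stopifnot(n >= 1, n <= 8)
  revs <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  revs <- revs[, c("row", "col"), drop = FALSE]
  frontier <- matrix(seq_len(n), nrow = 1L)
  codes <- perm_codes(frontier, n)
  dist <- 0L
  all_codes <- codes
  all_dist <- 0L
  while (nrow(frontier) > 0L) {
    nxt <- vector("list", nrow(revs))
    for (r in seq_len(nrow(revs))) {
      i <- revs[r, 1L]; j <- revs[r, 2L]
      m <- frontier
      m[, i:j] <- -m[, j:i, drop = FALSE]
      nxt[[r]] <- m
    }
    cand <- do.call(rbind, nxt)
    cc <- perm_codes(cand, n)
    keep <- !duplicated(cc) & is.na(match(cc, all_codes))
    frontier <- cand[keep, , drop = FALSE]
    dist <- dist + 1L
    if (nrow(frontier) > 0L) {
      all_codes <- c(all_codes, cc[keep])
      all_dist <- c(all_dist, rep.int(dist, sum(keep)))
    }
  }
  list(codes = all_codes, dist = all_dist)
}

.bfs_cache <- new.env(parent = emptyenv())

#' Brute-force inversion distance by breadth-first search
#'
#' Independent verification oracle: explores the full space of signed
#' permutations from the identity by applying all n(n+1)/2 inversions.
#' Feasible only for `n <= 8`; larger inputs are refused.  The full
#' distance table for a given n is cached per session, so bulk checks
#' amortise to table lookups.
#'
#' @param perm signed permutation with at most 8 blocks.
#' @return exact minimum number of inversions to the identity.
#' @export
bfs_oracle <- function(perm) {
  perm <- as_signed_perm(perm)
  n <- length(perm)
  if (n > 8L) stop("bfs_oracle is limited to n <= 8 (resource guard)")
  key <- as.character(n)
  if (is.null(.bfs_cache[[key]]))
    .bfs_cache[[key]] <- bfs_all_distances(n)
  tab <- .bfs_cache[[key]]
  code <- perm_codes(matrix(perm, nrow = 1L), n)
  hit <- match(code, tab$codes)
  if (is.na(hit)) stop("state not reached by BFS (should be impossible)")
  as.integer(tab$dist[hit])
}
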