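#' Signed permutations of core-genome blocks
#'
#' A core-genome scaffold is modelled as a signed permutation: an ordering of
#' the blocks 1..n in which every block appears exactly once, as +i when it
#' lies on the forward strand and -i when inverted.  Internally a signed
#' permutation is a plain integer vector of non-zero entries whose absolute
#' values are exactly 1..n; all rearrangement arithmetic in the package is
#' carried out on this representation.
#'
#' @param x integer vector with non-zero entries; `abs(x)` must be a
#'   permutation of `1:length(x)`.
#' @return `as_signed_perm()` returns the validated integer vector.
#' @examples
#' as_signed_perm(c(1L, -3L, 2L))
#' identity_perm(5)
#' @export
as_signed_perm <- function(x) {
  if (length(x) < 1L) stop("a signed permutation needs at least one block")
  x <- as.integer(x)
  if (anyNA(x) || any(x == 0L)) stop("entries must be non-zero integers")
  n <- length(x)
  if (!identical(sort(abs(x)), seq_len(n)))
    stop("abs(values) must be exactly 1..n, each once")
  x
}

#' @rdname as_signed_perm
#' @param n number of blocks (positive integer).
#' @export
identity_perm <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 1) stop("n must be a positive integer")
  seq_len(as.integer(n))
}

is_signed_perm <- function(x) {
  is.numeric(x) && length(x) >= 1L && !anyNA(x) && all(x != 0) &&
    identical(sort(abs(as.integer(x))), seq_along(x))
}

#' Apply an inversion (reversal) to a signed permutation
#'
#' Reverses the order of positions `i..j` and flips all their signs, the
#' elementary operation of inversion-distance theory.  Applying the same
#' inversion twice restores the input.
#'
#' @param perm signed permutation.
#' @param i,j 1-based positions, `1 <= i <= j <= n`.
#' @return the rearranged signed permutation.
#' @export
apply_inversion <- function(perm, i, j) {
  perm <- as_signed_perm(perm)
  n <- length(perm)
  if (length(i) != 1L || length(j) != 1L || is.na(i) || is.na(j) ||
      i < 1 || j > n || i > j)
    stop("inversion endpoints must satisfy 1 <= i <= j <= n")
  perm[i:j] <- -rev(perm[i:j])
  perm
}

## Capped extension: sentinels 0 and n+1 make end-of-genome adjacencies
## explicit, so patterns at scaffold ends are treated like interior ones.
cap_perm <- function(perm) {
  perm <- as_signed_perm(perm)
  c(0L, perm, length(perm) + 1L)
}

#' Count breakpoints of a signed permutation
#'
#' A breakpoint is a capped adjacency (a, b) with `b != a + 1` in signed
#' notation; the identity has none.  Note that (-3, -2) is *not* a breakpoint
#' (reading the reverse strand gives 2, 3).
#'
#' @param perm signed permutation.
#' @return non-negative integer count over the n + 1 capped adjacencies.
#' @export
perm_breakpoints <- function(perm) {
  e <- cap_perm(perm)
  sum(e[-1L] != e[-length(e)] + 1L)
}

## Unsigned doubling: +x -> (2x-1, 2x), -x -> (2x, 2x-1), with caps 0 and
## 2n+1.  Returns the vertex sequence L of length 2n+2 (0-based positions).
double_perm <- function(perm) {
  perm <- as_signed_perm(perm)
  n <- length(perm)
  body <- vapply(perm, function(p) {
    if (p > 0L) c(2L * p - 1L, 2L * p) else c(-2L * p, -2L * p - 1L)
  }, integer(2))
  c(0L, as.integer(body), 2L * n + 1L)
}

#' Breakpoint graph of a signed permutation (against the identity)
#'
#' Builds the classical doubled-vertex graph: black edges are the capped
#' adjacencies of `perm`, gray edges those of the identity.  Every vertex has
#' black- and gray-degree one, so the edges decompose into alternating
#' cycles; a shared adjacency yields a trivial 2-edge cycle and the number of
#' cycles drives the inversion distance.
#'
#' @param perm signed permutation.
#' @return a list of class `breakpoint_graph` with elements
#'   `vertices` (values 0..2n+1 in permutation order), `black`, `gray`
#'   (two-column matrices of vertex values), `cycles` (list of integer
#'   vectors of vertex values, in traversal order) and `cycle_sizes`
#'   (edge counts per cycle).
#' @export
breakpoint_graph <- function(perm) {
  perm <- as_signed_perm(perm)
  n <- length(perm)
  L <- double_perm(perm)
  m <- n + 1L                      # number of black (= gray) edges
  black <- cbind(L[2L * seq_len(m) - 1L], L[2L * seq_len(m)])
  gray <- cbind(2L * (seq_len(m) - 1L), 2L * (seq_len(m) - 1L) + 1L)

  black_mate <- integer(2L * n + 2L)   # indexed by vertex value + 1
  black_mate[black[, 1L] + 1L] <- black[, 2L]
  black_mate[black[, 2L] + 1L] <- black[, 1L]
  gray_mate <- integer(2L * n + 2L)
  gray_mate[gray[, 1L] + 1L] <- gray[, 2L]
  gray_mate[gray[, 2L] + 1L] <- gray[, 1L]

  seen <- logical(2L * n + 2L)
  cycles <- list()
  for (v0 in c(black[, 1L])) {
    if (seen[v0 + 1L]) next
    cyc <- integer(0)
    v <- v0
    use_black <- TRUE
    repeat {
      cyc <- c(cyc, v)
      seen[v + 1L] <- TRUE
      v <- if (use_black) black_mate[v + 1L] else gray_mate[v + 1L]
      use_black <- !use_black
      if (v == v0) break
    }
    cycles[[length(cycles) + 1L]] <- cyc
  }
  structure(list(
    vertices = L, black = black, gray = gray,
    cycles = cycles, cycle_sizes = lengths(cycles)
  ), class = "breakpoint_graph")
}

#' @export
print.breakpoint_graph <- function(x, ...) {
  cat("breakpoint graph:", nrow(x$black), "black +", nrow(x$gray),
      "gray edges,", length(x$cycles), "cycles (sizes",
      paste(sort(x$cycle_sizes, decreasing = TRUE), collapse = ","), ")\n")
  invisible(x)
}

#' Merge blocks that are adjacent in both permutations
#'
#' Pre-process shared by all comparisons: two blocks consecutive in both
#' input scaffolds with consistent relative orientation carry no
#' rearrangement signal, so they are fused into one block.  Fusion is
#' maximal (run-based, scanned left to right in `a`'s frame) and the result
#' is renumbered so that `a` maps to the identity; the grouping record maps
#' each new id to the run of original `a`-frame signed block ids it covers.
#'
#' @param a,b signed permutations over the same block set.
#' @return list with `a`, `b` (collapsed, renumbered permutations; `a` is
#'   the identity) and `groups`, a list whose k-th element is the signed
#'   vector of original blocks (as oriented in `a`) fused into new block k.
#' @examples
#' collapse_common_adjacencies(identity_perm(8), c(1, 2, 6, 7, 3, 4, 5, 8))
#' @export
collapse_common_adjacencies <- function(a, b) {
  a <- as_signed_perm(a)
  b <- as_signed_perm(b)
  if (length(a) != length(b) || !setequal(abs(a), abs(b)))
    stop("permutations must be over the same block set")
  n <- length(a)

  ## relabel so a -> identity; remember original labels per position of a
  relab <- integer(n)                       # relab[old id] = signed new id
  relab[abs(a)] <- seq_len(n) * sign(a)
  b1 <- sign(b) * relab[abs(b)]
  ## orig[k] = original signed label of a at position k (as oriented in a)
  orig <- a

  ## adjacency (x, x+1) is common iff consecutive in b1 with consistent
  ## orientation: ... +x +(x+1) ... or ... -(x+1) -x ...
  pos <- integer(n)
  pos[abs(b1)] <- seq_len(n)
  common <- vapply(seq_len(n - 1L), function(x) {
    px <- pos[x]; py <- pos[x + 1L]
    (py == px + 1L && b1[px] == x && b1[py] == x + 1L) ||
      (px == py + 1L && b1[py] == -(x + 1L) && b1[px] == -x)
  }, logical(1))
  if (n == 1L) common <- logical(0)

  ## runs of blocks joined by common adjacencies
  run_id <- cumsum(c(TRUE, !common))        # per position 1..n of identity
  m <- max(run_id)
  groups <- split(orig, run_id)
  names(groups) <- NULL
  run_of <- run_id                           # run_of[x] for block value x

  ## collapsed b: scan b1, keep one entry per run, signed by orientation
  keep <- logical(n)
  out <- integer(0)
  i <- 1L
  while (i <= n) {
    v <- b1[i]
    r <- run_of[abs(v)]
    len <- sum(run_of == r)
    out <- c(out, if (v > 0L) r else -r)
    i <- i + len
  }
  list(a = seq_len(m), b = as.integer(out), groups = groups)
}

#' Read and write scaffolds in plain-text permutation format
#'
#' One genome per stanza: a `>name` header line followed by
#' whitespace-separated signed integers, optionally terminated by `$`
#' (the format used by classical rearrangement tools).  `read_perms()`
#' and `write_perms()` round-trip.
#'
#' @param path file path.
#' @param perms named list of signed integer vectors.
#' @return `read_perms()`: named list of integer vectors.
#' @export
read_perms <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  out <- list()
  cur <- NULL
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      cur <- trimws(substring(ln, 2L))
      out[[cur]] <- integer(0)
    } else {
      if (is.null(cur)) stop("permutation data before any '>' header")
      toks <- strsplit(ln, "[[:space:]]+")[[1]]
      toks <- toks[nzchar(toks) & toks != "$"]
      out[[cur]] <- c(out[[cur]], as.integer(toks))
    }
  }
  out
}

#' @rdname read_perms
#' @export
write_perms <- function(perms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(perms)) {
    writeLines(paste0(">", nm), con)
    writeLines(paste(c(perms[[nm]], "$"), collapse = " "), con)
  }
  invisible(path)
}
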