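# brute-force pattern scanners used as the soundness/completeness oracle:
# try every candidate swap and test the definitional outcome directly

brute_transpositions <- function(perm) {
  e <- c(0L, perm, length(perm) + 1L)
  hits <- integer(0)
  for (i in seq_len(length(perm) - 1L)) {
    w <- e[i:(i + 3L)]
    after <- c(w[1], w[3], w[2], w[4])
    if (w[2] != w[3] && all(diff(after) == 1L)) hits <- c(hits, i)
  }
  hits
}

test_that("independent transposition detection matches the definitions", {
  ev <- find_independent_transpositions(c(1L, 2L, 4L, 3L, 5L))
  expect_length(ev, 1L)
  expect_identical(ev[[1]]$blocks, c(4L, 3L))
  expect_length(find_independent_transpositions(identity_perm(5)), 0L)
  # negative-mirror pattern
  ev <- find_independent_transpositions(c(-5L, -4L, -2L, -3L, -1L))
  expect_length(ev, 1L)
  expect_identical(ev[[1]]$blocks, c(-2L, -3L))
})

test_that("inverted transposition patterns are detected with sign detail", {
  ev <- find_independent_inverted_transpositions(c(1L, 2L, -4L, 3L, 5L))
  expect_length(ev, 1L)
  expect_equal(ev[[1]]$sign_detail, "first_flipped")
  ev <- find_independent_inverted_transpositions(c(1L, 2L, 4L, -3L, 5L))
  expect_length(ev, 1L)
  expect_equal(ev[[1]]$sign_detail, "second_flipped")
  expect_length(find_independent_inverted_transpositions(identity_perm(5)), 0L)
})

test_that("block interchange patterns are detected with correct arity", {
  ev <- find_independent_block_interchanges(c(1L, 4L, 3L, 2L, 5L))
  expect_length(ev, 1L)
  expect_identical(ev[[1]]$positions, c(2L, 4L))
  expect_length(find_independent_block_interchanges(identity_perm(5)), 0L)
  expect_length(find_independent_block_interchanges(c(1L, 2L, 4L, 3L, 5L)), 0L)
  ev <- find_independent_inverted_block_interchanges(c(1L, -4L, 3L, -2L, 5L))
  expect_length(ev, 1L)
  expect_length(find_independent_inverted_block_interchanges(identity_perm(5)), 0L)
  expect_length(find_independent_inverted_block_interchanges(c(1L, -4L, 3L, 2L, 5L)), 0L)
})

test_that("transposition detector agrees with a brute-force scanner (n <= 5)", {
  for (n in 2:5) {
    ap <- all_signed_perms(n)
    # subsample for n = 5 rows to keep runtime modest but deterministic
    rows <- if (nrow(ap) > 800) seq(1, nrow(ap), by = 5) else seq_len(nrow(ap))
    for (r in rows) {
      p <- ap[r, ]
      got <- vapply(find_independent_transpositions(p),
                    function(e) e$positions[1L], integer(1))
      expect_identical(got, brute_transpositions(p),
                       info = paste(p, collapse = ","))
    }
  }
})

test_that("elimination resolves the worked example and obeys breakpoint deltas", {
  el <- eliminate_independent_events(identity_perm(5), c(1L, 2L, 4L, 3L, 5L))
  expect_equal(unname(el$counts["transposition"]), 1L)
  expect_equal(sum(el$counts), 1L)
  expect_identical(el$b, 1L)       # fully resolved, collapses to a point
  el <- eliminate_independent_events(c(3L, 1L, 2L), c(3L, 1L, 2L))
  expect_equal(sum(el$counts), 0L)
  expect_identical(el$b, 1L)
  expect_error(eliminate_independent_events(c(1L, 1L), c(1L, 1L)))
})

test_that("elimination reports merged-region labels", {
  # +1+2+6+7+3+4+5+8 vs identity: swapping merged regions (6,7) and (3,4,5)
  el <- eliminate_independent_events(identity_perm(8),
                                     c(1L, 2L, 6L, 7L, 3L, 4L, 5L, 8L))
  expect_equal(unname(el$counts["transposition"]), 1L)
  ev <- el$events[[1]]
  expect_identical(ev$blocks[[1]], c(6L, 7L))
  expect_identical(ev$blocks[[2]], c(3L, 4L, 5L))
})

test_that("elimination terminates, shrinks breakpoints, never raises distance", {
  set.seed(31)
  for (rep in 1:60) {
    n <- sample(3:7, 1)
    a <- random_signed_perm(n); b <- random_signed_perm(n)
    el <- eliminate_independent_events(a, b)
    d_before <- pairwise_distance(a, b)$distance
    d_after <- inversion_distance(el$b)$distance
    expect_lte(d_after, d_before)
    expect_equal(d_after, bfs_oracle(el$b)) # still exact on the reduced pair
  }
})
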