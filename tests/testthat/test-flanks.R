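# deterministic sequence fixtures built in code
rand_seq <- function(n, seed) { set.seed(seed); panrearr:::random_dna(n, 0.5) }
rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

test_that("inverted repeats are found with exact coordinates", {
  X <- rand_seq(820, 1)
  left <- paste0(rand_seq(1500, 2), X, rand_seq(700, 3))
  right <- paste0(rand_seq(900, 4), rc(X), rand_seq(1200, 5))
  rp <- find_inverted_repeat(left, right)
  expect_false(is.null(rp))
  expect_equal(rp$orientation, "inverted")
  expect_gte(rp$length, 820L)
  expect_gte(rp$identity, 0.99)
  # occurrence coordinates point at the planted copies (0-based half-open)
  expect_lte(abs(rp$occ1[["start"]] - 1500L), 5L)
  expect_lte(abs(rp$occ2[["start"]] - 900L), 5L)
  # direct copy only: no inverted pair
  right_direct <- paste0(rand_seq(900, 6), X, rand_seq(1200, 7))
  expect_null(find_inverted_repeat(left, right_direct))
  # independent random sequences: nothing at min_len 50
  expect_null(find_inverted_repeat(rand_seq(5000, 8), rand_seq(5000, 9),
                                   min_len = 50))
  expect_error(find_inverted_repeat("ACXGT", "ACGT"), "non-IUPAC")
})

test_that("direct repeats are found and orientation is respected", {
  X <- rand_seq(700, 11)
  left <- paste0(rand_seq(1000, 12), X, rand_seq(400, 13))
  right <- paste0(rand_seq(600, 14), X, rand_seq(800, 15))
  rp <- find_direct_repeat(left, right)
  expect_false(is.null(rp))
  expect_equal(rp$orientation, "direct")
  expect_gte(rp$length, 700L)
  # inverted copy only: no direct pair
  right_inv <- paste0(rand_seq(600, 16), rc(X), rand_seq(800, 17))
  expect_null(find_direct_repeat(left, right_inv))
})

test_that("reverse-complement symmetry of inverted detection", {
  X <- rand_seq(750, 21)
  left <- paste0(rand_seq(800, 22), X, rand_seq(500, 23))
  right <- paste0(rand_seq(400, 24), rc(X), rand_seq(900, 25))
  rp1 <- find_inverted_repeat(left, right)
  rp2 <- find_inverted_repeat(rc(right), rc(left))
  expect_false(is.null(rp1) || is.null(rp2))
  expect_equal(rp1$length, rp2$length)
  # mirrored coordinates: occ1 of the mirrored call maps onto occ2
  expect_equal(unname(rp2$occ1[["start"]]),
               nchar(right) - rp1$occ2[["end"]])
})

test_that("raising thresholds never adds detections", {
  X <- rand_seq(300, 31)
  # 6% mismatches planted
  v <- strsplit(X, "")[[1]]
  set.seed(32)
  pos <- sample(300, 18)
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  Xmut <- paste(v, collapse = "")
  left <- paste0(rand_seq(500, 33), X, rand_seq(200, 34))
  right <- paste0(rand_seq(300, 35), rc(Xmut), rand_seq(400, 36))
  lo <- find_inverted_repeat(left, right, min_id = 0.85)
  hi <- find_inverted_repeat(left, right, min_id = 0.995)
  expect_false(is.null(lo))
  expect_true(is.null(hi) || hi$length <= lo$length)
  long <- find_inverted_repeat(left, right, min_id = 0.85, min_len = 400)
  expect_true(is.null(long) || long$length >= 400)
})

test_that("repeat occurrences are located across strains and strands", {
  X <- rand_seq(900, 41)
  gA <- paste0(rand_seq(3000, 42), X, rand_seq(2000, 43))
  gB <- paste0(rand_seq(1000, 44), rc(X), rand_seq(500, 45), X,
               rand_seq(1500, 46))
  gC <- rand_seq(6000, 47)
  occ <- locate_repeat_occurrences(X, list(A = gA, B = gB, C = gC))
  expect_setequal(unique(occ$strain), c("A", "B"))
  expect_equal(nrow(occ[occ$strain == "B", ]), 2L)
  expect_setequal(occ$strand[occ$strain == "B"], c("+", "-"))
  expect_equal(occ$start[occ$strain == "A"], 3000L)
  expect_equal(occ$end[occ$strain == "A"], 3900L)
  expect_equal(nrow(locate_repeat_occurrences(X, list())), 0L)
})

test_that("breakpoint windows cover planted repeats and clip at ends", {
  ds <- default_dataset(seed = 0)
  mg <- merge_core_blocks(ds$map)
  scs <- build_scaffolds(mg$map)
  # strain2 carries the inversion mediated by repeat A
  s2 <- scs$strain2
  neg <- which(s2$blocks < 0)
  w <- inversion_breakpoint_windows(
    c(s2$blocks[neg[1]], s2$blocks[neg[length(neg)]]), s2,
    ds$genomes[["strain2"]])
  rp <- find_inverted_repeat(w$left$seq, w$right$seq)
  expect_false(is.null(rp))
  expect_gte(rp$identity, 0.99)
  # clipping: margin larger than the genome start
  w0 <- inversion_breakpoint_windows(
    c(s2$blocks[1], s2$blocks[1]), s2, ds$genomes[["strain2"]],
    margin = 1e7, cap = 1e7)
  expect_equal(w0$left$start, 0L)
  # zero margin on an event-free junction yields (nearly) empty windows
  wz <- inversion_breakpoint_windows(
    c(s2$blocks[1], s2$blocks[1]), s2, ds$genomes[["strain2"]], margin = 0)
  expect_lte(nchar(wz$left$seq), 1L)
})

test_that("transposition junctions share a direct repeat; prevalence sums", {
  ds <- default_dataset(seed = 0)
  g5 <- ds$genomes[["strain5"]]
  occ <- locate_repeat_occurrences(ds$library[["R"]], list(s5 = g5))
  expect_equal(nrow(occ), 3L)
  win <- lapply(seq_len(3), function(i)
    substr(g5, max(1, occ$start[i] - 500), occ$end[i] + 500))
  chk <- check_event_ends("transposition", win)
  expect_true(chk$all_conserved)
  expect_true(all(chk$pairs$orientation == "direct"))
  expect_error(check_event_ends("transposition", win[1:2]), "3 junctions")

  reports <- data.frame(length_bp = c(15000, 12000, 3000, 8000),
                        ir_found = c(TRUE, TRUE, FALSE, TRUE))
  s <- summarize_prevalence(reports)
  expect_equal(s$n_inversions, 4L)
  expect_equal(s$n_flanked, 3L)
  expect_equal(s$n_long, 2L)
  expect_equal(s$n_long_flanked, 2L)
  expect_equal(summarize_prevalence(NULL)$n_inversions, 0L)
})

test_that("BED6 output carries identity as score and 0-based intervals", {
  occ <- data.frame(strain = "A", start = 10L, end = 110L, strand = "-",
                    identity = 0.955)
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed6(occ, "IRA", path)
  bed <- utils::read.delim(path, header = FALSE)
  expect_equal(unlist(bed[1, ], use.names = FALSE),
               c("A", "10", "110", "IRA", "955", "-"))
})
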