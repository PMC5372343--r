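test_that("block maps read/write and classify", {
  map <- toy_block_map(list(A = 1:3, B = 1:3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_block_map(map, path)
  expect_identical(read_block_map(path), map)
  map2 <- rbind(map, data.frame(strain = "A", block = "9", contig = "chr",
                                start = 90000L, end = 90500L, strand = "+"))
  cls <- block_classes(map2)
  expect_setequal(cls$class[cls$block %in% c("1", "2", "3")], "core")
  expect_equal(cls$class[cls$block == "9"], "strain_specific")
})

test_that("MAF alignment blocks become classified occurrences", {
  maf <- c("##maf version=1", "",
           "a score=100 label=1",
           "s sA.chr 0 900 + 10000 ACGT",
           "s sB.chr 100 900 + 12000 ACGT",
           "s sC.chr 50 880 - 9000 ACGT",
           "",
           "a score=50 label=2",
           "s sA.chr 2000 400 + 10000 ACGT",
           "s sB.chr 2500 400 + 12000 ACGT")
  map <- blocks_from_maf(maf)
  expect_equal(nrow(map), 5L)
  expect_equal(sort(unique(map$class)), c("core", "dispensable"))
  # minus-strand start converted to forward coordinates
  sc <- map[map$strain == "sC", ]
  expect_equal(sc$start, 9000L - 50L - 880L)
  expect_equal(sc$end - sc$start, 880L)
  expect_error(blocks_from_maf(c("s sA.chr 0 9 + 100 ACGT")), "parse error")
})

test_that("short core blocks are filtered on the reference strain", {
  map <- toy_block_map(list(A = 1:4, B = 1:4),
                       block_len = c(`1` = 1000L, `2` = 499L, `3` = 500L,
                                     `4` = 2000L))
  out <- filter_short_blocks(map, min_len = 500)
  expect_setequal(unique(out$block), c("1", "3", "4"))
  expect_identical(filter_short_blocks(map, min_len = 0), map)
})

test_that("core-block merging stops exactly at rearrangement boundaries", {
  # strain C carries an inversion of blocks 3..4 (consistent orientation)
  map <- toy_block_map(list(A = 1:6, B = 1:6, C = c(1L, 2L, -4L, -3L, 5L, 6L)))
  mg <- merge_core_blocks(map)
  expect_identical(unname(mg$members),
                   list(c("1", "2"), c("3", "4"), c("5", "6")))
  # idempotent
  mg2 <- merge_core_blocks(mg$map)
  expect_equal(length(mg2$members), 3L)
  expect_identical(unname(lapply(mg2$members, length)), list(1L, 1L, 1L))
  # all strains identical: everything fuses into one block
  m1 <- merge_core_blocks(toy_block_map(list(A = 1:5, B = 1:5)))
  expect_equal(length(m1$members), 1L)
})

test_that("scaffolds follow genomic order and build groups by identity", {
  map <- toy_block_map(list(A = 1:4, B = 1:4, C = c(1L, -3L, -2L, 4L),
                            D = c(1L, -3L, -2L, 4L), E = c(2L, 1L, 3L, 4L),
                            FF = 1:4))
  sc <- build_scaffolds(map)
  expect_identical(sc$C$blocks, c(1L, -3L, -2L, 4L))
  expect_identical(sc$A$blocks, 1:4)
  gr <- build_groups(sc)
  expect_equal(length(gr), 3L)
  expect_equal(vapply(gr, function(g) length(g$strains), integer(1)),
               c(3L, 2L, 1L))
  expect_setequal(gr[[1]]$strains, c("A", "B", "FF"))
  expect_equal(gr[[2]]$strains, c("C", "D"))
})

test_that("duplicate copies resolve to the adjacency-preserving copy", {
  ref <- c(1L, 2L, 3L, 4L, 5L)
  expect_identical(dedup_duplicates(ref, ref), ref)
  # extra copy of 3 far from its reference neighbours is dropped
  withdup <- c(1L, 2L, 3L, 4L, 3L, 5L)
  expect_identical(dedup_duplicates(withdup, ref), c(1L, 2L, 3L, 4L, 5L))
  # inverted context: the copy whose (orientation-aware) neighbours match
  # the reference wins even when it is not first
  withdup2 <- c(1L, 3L, -4L, -3L, -2L, 5L)       # -3 next to -4,-2 wins
  expect_identical(dedup_duplicates(withdup2, ref), c(1L, -4L, -3L, -2L, 5L))
  # seven copies leave exactly one survivor
  many <- c(1L, rep(2L, 7L), 3L, 4L, 5L)
  out <- dedup_duplicates(many, ref)
  expect_equal(sum(abs(out) == 2L), 1L)
  expect_error(dedup_duplicates(c(1L, 2L, 6L), c(1L, 2L, 6L, 3L)), "missing")
  expect_error(dedup_duplicates(c(1L, 2L), c(1L, 2L, 2L)), "duplicate-free")
})

test_that("closest pairs pick the smallest total distance deterministically", {
  scs <- list(s1 = 1:5, s2 = 1:5, s3 = c(1L, 2L, -4L, -3L, 5L),
              s4 = c(1L, 3L, 2L, 4L, 5L))
  gr <- build_groups(scs)
  cp <- closest_pairs(gr)
  # totals tie at 1 (inversion vs transposition); lower group id wins
  expect_equal(cp[[1]]$closest_group, 2L)
  expect_equal(cp[[1]]$inv_d, 1L)
  expect_equal(cp[[1]]$r_d, 0L)
  expect_equal(cp[[3]]$closest_group, 1L)
  expect_equal(cp[[3]]$inv_d, 0L)
  expect_equal(cp[[3]]$r_d, 1L)
  expect_equal(cp[[2]]$closest_group, 1L)
  expect_equal(cp[[2]]$inv_d, 1L)
  expect_equal(nrow(cp[[2]]$inversions), 1L)
  expect_equal(cp[[2]]$inversions$start_block, -4L)
  expect_equal(cp[[2]]$inversions$end_block, -3L)
  # identical groups cannot arise from build_groups; identical scaffolds fuse
  expect_equal(length(gr), 3L)
})

test_that("pipeline recovers planted group structure end to end", {
  map <- toy_block_map(list(
    A = 1:8, B = 1:8,
    C = c(1L, 2L, -6L, -5L, -4L, -3L, 7L, 8L),
    D = c(1L, 2L, 5L, 6L, 3L, 4L, 7L, 8L)))
  rep <- run_pipeline(map = map, min_block_len = 0)
  expect_equal(length(rep$groups), 3L)
  p <- rep$pairs
  src <- vapply(p, function(x) x$source_group, integer(1))
  # group of C: one inversion from group 1; group of D: one transposition
  gC <- rep$groups[[which(vapply(rep$groups, function(g) "C" %in% g$strains,
                                 logical(1)))]]$id
  gD <- rep$groups[[which(vapply(rep$groups, function(g) "D" %in% g$strains,
                                 logical(1)))]]$id
  expect_equal(p[[which(src == gC)]]$inv_d, 1L)
  expect_equal(p[[which(src == gD)]]$inv_d, 0L)
  expect_equal(p[[which(src == gD)]]$r_d, 1L)
  expect_match(rep$warnings, "repeat-flank", all = FALSE)
})
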