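test_that("ancestor generation is seeded and validates config", {
  cfg <- sim_config(seed = 4, n_blocks = 20)
  a1 <- generate_ancestor(cfg)
  a2 <- generate_ancestor(cfg)
  expect_identical(track_seq(a1$track), track_seq(a2$track))
  expect_identical(a1$map, a2$map)
  expect_equal(nrow(a1$map), 20L)
  expect_identical(a1$blocks, 1:20)
  # genome size approximately the sum of drawn block lengths plus spacers
  glen <- nchar(track_seq(a1$track))
  expect_equal(glen, sum(nchar(a1$track$segments$seq)))
  expect_gt(glen, 20 * 500)
  expect_error(sim_config(n_blocks = 0), ">= 1")
  expect_error(sim_config(gc = 1.2), "gc")
})

test_that("repeat planting shifts coordinates and rejects collisions", {
  cfg <- sim_config(seed = 5, n_blocks = 6)
  anc <- generate_ancestor(cfg)
  pl <- plant_repeats(anc$track, data.frame(
    label = c("X", "X"), after_block = c(1L, 4L), orient = c(1L, -1L)), cfg)
  co <- track_coords(pl$track)
  expect_equal(sum(co$type == "repeat"), 2L)
  # block count and per-block lengths unchanged
  m2 <- track_block_map(pl$track, "s")
  expect_equal(m2$end - m2$start, anc$map$end - anc$map$start)
  # planted copy sequence matches the library
  g <- track_seq(pl$track)
  r1 <- co[co$type == "repeat", ][1, ]
  expect_identical(substr(g, r1$start + 1, r1$end), unname(pl$library["X"]))
  expect_error(
    plant_repeats(anc$track, data.frame(label = c("X", "Y"),
                                        after_block = c(2L, 2L),
                                        orient = c(1L, 1L)), cfg),
    "overlapping")
  expect_identical(
    plant_repeats(anc$track, data.frame(label = character(0),
                                        after_block = integer(0),
                                        orient = integer(0)), cfg)$track,
    anc$track)
})

test_that("IR inversion reverse-complements the interior only", {
  cfg <- sim_config(seed = 6, n_blocks = 8)
  anc <- generate_ancestor(cfg)
  pl <- plant_repeats(anc$track, data.frame(
    label = "X", after_block = c(2L, 5L), orient = c(1L, -1L)), cfg)
  pre <- track_seq(pl$track)
  tr2 <- apply_ir_inversion(pl$track, "X")
  post <- track_seq(tr2)
  ext <- panrearr:::repeat_outer_extent(pl$track, "X", 1:2)
  expect_identical(substr(pre, 1, ext["start"]), substr(post, 1, ext["start"]))
  expect_identical(substr(pre, ext["end"] + 1, nchar(pre)),
                   substr(post, ext["end"] + 1, nchar(post)))
  co <- track_coords(pl$track)
  reps <- co[co$type == "repeat", ]
  inner_pre <- substr(pre, reps$end[1] + 1, reps$start[2])
  inner_post <- substr(post, reps$end[1] + 1, reps$start[2])
  expect_identical(inner_post,
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(inner_pre))))
  # involution
  expect_identical(track_seq(apply_ir_inversion(tr2, "X")), pre)
  # direct-orientation pair refuses
  pl2 <- plant_repeats(anc$track, data.frame(
    label = "X", after_block = c(2L, 5L), orient = c(1L, 1L)), cfg)
  expect_error(apply_ir_inversion(pl2$track, "X"), "opposite orientation")
  # block-level effect: interior blocks reversed and negated
  expect_identical(track_scaffold_blocks(tr2),
                   c(1L, 2L, -5L, -4L, -3L, 6L, 7L, 8L))
})

test_that("DR transposition swaps the two inter-repeat segments", {
  cfg <- sim_config(seed = 7, n_blocks = 9)
  anc <- generate_ancestor(cfg)
  pl <- plant_repeats(anc$track, data.frame(
    label = "R", after_block = c(2L, 5L, 8L), orient = c(1L, 1L, 1L)), cfg)
  pre <- track_seq(pl$track)
  tr2 <- apply_dr_transposition(pl$track, "R")
  post <- track_seq(tr2)
  expect_equal(nchar(pre), nchar(post))
  ext <- panrearr:::repeat_outer_extent(pl$track, "R", 1:3)
  expect_identical(substr(pre, 1, ext["start"]), substr(post, 1, ext["start"]))
  expect_identical(substr(pre, ext["end"] + 1, nchar(pre)),
                   substr(post, ext["end"] + 1, nchar(post)))
  expect_identical(track_scaffold_blocks(tr2),
                   c(1L, 2L, 6L, 7L, 8L, 3L, 4L, 5L, 9L))
  # involution
  expect_identical(track_seq(apply_dr_transposition(tr2, "R")), pre)
  # mixed orientations refuse
  plx <- plant_repeats(anc$track, data.frame(
    label = "R", after_block = c(2L, 5L, 8L), orient = c(1L, -1L, 1L)), cfg)
  expect_error(apply_dr_transposition(plx$track, "R"), "same-orientation")
  expect_error(apply_dr_transposition(pl$track, "R", copies = 1:4), "copies")
})

test_that("event scripts derive strains with a consistent truth log", {
  ds <- default_dataset(seed = 0)
  expect_equal(length(ds$genomes), 5L)
  # empty script strain identical to ancestor-with-repeats
  expect_identical(ds$genomes[["strain1"]],
                   track_seq(ds$tracks[["strain1"]]))
  expect_identical(ds$scaffolds[["strain1"]], 1:40)
  # truth log replay: block-level effects chain correctly per strain
  for (s in unique(vapply(ds$truth, function(e) e$strain, character(1)))) {
    evs <- Filter(function(e) e$strain == s, ds$truth)
    cur <- ds$scaffolds[["strain1"]]
    for (e in evs) {
      expect_identical(e$blocks_before, cur)
      cur <- e$blocks_after
    }
    expect_identical(cur, ds$scaffolds[[s]])
  }
  # all five inversions exceed the long threshold at block level
  inv <- Filter(function(e) e$kind == "ir_inversion", ds$truth)
  expect_length(inv, 5L)
  expect_error(
    apply_event_script(ds$tracks[["strain1"]],
                       list(strain2 = list(list(kind = "ir_inversion",
                                                label = "ZZ", copies = 1:2))),
                       paste0("strain", 1:2), ds$config),
    "absent repeat")
})

test_that("datasets are deterministic and round-trip through emit/load", {
  d1 <- default_dataset(seed = 3)
  d2 <- default_dataset(seed = 3)
  expect_identical(d1$genomes, d2$genomes)
  expect_identical(d1$map, d2$map)
  dir <- withr::local_tempdir()
  emit_dataset(d1, dir)
  back <- load_dataset(dir)
  expect_identical(back$genomes, d1$genomes)
  expect_identical(back$map, d1$map)
  expect_identical(back$scaffolds, d1$scaffolds)
  expect_equal(length(back$truth), length(d1$truth))
  # FASTA is plain text at fixed width
  fl <- readLines(file.path(dir, "genomes.fasta"), n = 3)
  expect_match(fl[1], "^>")
  expect_equal(nchar(fl[2]), 70L)
})

test_that("mutation noise stays off the ancestor and repeats stay findable", {
  ds <- default_dataset(seed = 1, mutation_rate = 0.001)
  anc <- default_dataset(seed = 1)
  expect_identical(ds$genomes[["strain1"]], anc$genomes[["strain1"]])
  expect_false(identical(ds$genomes[["strain2"]], anc$genomes[["strain2"]]))
  occ <- locate_repeat_occurrences(ds$library[["A"]],
                                   ds$genomes["strain2"], min_id = 0.95)
  expect_equal(nrow(occ), 2L)
  expect_setequal(occ$strand, c("+", "-"))
})
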