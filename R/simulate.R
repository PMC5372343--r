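## Seeded simulator of multi-strain bacterial-like genomes with planted
## IS-like repeats and repeat-mediated rearrangements.
##
## A genome is held as a segment track: an ordered table of typed segments
## (core block / spacer / repeat copy) each with an orientation and a
## forward-strand sequence.  Rearrangements are list surgery on the track,
## which makes the central invariant of repeat-mediated events -- sequence
## outside the outermost mediating repeat copies is bitwise unchanged --
## hold by construction and easy to assert on the emitted sequences.

## k-th stage seed derived from the master seed.  Adjacent Mersenne-Twister
## seeds in R yield heavily correlated uniform streams (seed and seed+1 can
## emit ~97%-identical nucleotide sequences), so stage seeds are drawn from
## a seeded stream instead of computed as seed + k.
derived_seed <- function(seed, k) {
  set.seed(seed)
  sample.int(2147483646L, k)[k]
}

random_dna <- function(n, gc = 0.55) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

new_track <- function(type, id, orient, seq) {
  structure(list(segments = data.frame(
    type = type, id = id, orient = as.integer(orient), seq = seq,
    stringsAsFactors = FALSE)), class = "genome_track")
}

#' Assemble the genome sequence of a segment track
#'
#' Concatenates segment sequences, reverse-complementing segments with
#' orientation -1.
#'
#' @param track a `genome_track`.
#' @return genome sequence (character).
#' @export
track_seq <- function(track) {
  seg <- track$segments
  pieces <- ifelse(seg$orient == 1L, seg$seq,
                   vapply(seg$seq, revcomp, character(1)))
  paste(pieces, collapse = "")
}

## per-segment genomic coordinates (0-based half-open)
track_coords <- function(track) {
  seg <- track$segments
  len <- nchar(seg$seq)
  end <- cumsum(len)
  data.frame(type = seg$type, id = seg$id, orient = seg$orient,
             start = end - len, end = end, stringsAsFactors = FALSE)
}

## signed block sequence of a track
track_scaffold_blocks <- function(track) {
  seg <- track$segments
  i <- seg$type == "block"
  as.integer(seg$id[i]) * seg$orient[i]
}

#' Simulation configuration
#'
#' The defaults are the desk-scale stated world used throughout the tests:
#' 5 strains over a ~200 kb ancestor of 40 core blocks (lognormal lengths,
#' median 4 kb, clipped to 0.5--80 kb, mirroring the observed core-block
#' length range), IS-like repeats of 700--1500 bp, GC content 0.55, and no
#' substitution noise (set `mutation_rate` to e.g. 0.001 to exercise
#' approximate repeat matching).
#'
#' @param seed integer RNG seed; identical configs give bitwise-identical
#'   datasets.
#' @param n_strains number of strains (>= 1; strain 1 is the ancestor).
#' @param n_blocks number of core blocks (>= 1).
#' @param block_len_meanlog,block_len_sdlog lognormal block length params.
#' @param block_len_range clip range for block lengths (bp).
#' @param spacer_len_range uniform range for inter-block spacers (bp).
#' @param repeat_len_range uniform range for repeat lengths (bp).
#' @param gc GC content in (0, 1).
#' @param mutation_rate per-base substitution probability applied to each
#'   derived strain after its events (default 0 = noise-free).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 0L, n_strains = 5L, n_blocks = 40L,
                       block_len_meanlog = log(4000), block_len_sdlog = 0.45,
                       block_len_range = c(500, 80000),
                       spacer_len_range = c(50, 400),
                       repeat_len_range = c(700, 1500),
                       gc = 0.55, mutation_rate = 0) {
  if (n_strains < 1L || n_blocks < 1L) stop("need >= 1 strain and >= 1 block")
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  if (mutation_rate < 0 || mutation_rate > 0.2) stop("unreasonable mutation_rate")
  structure(as.list(environment()), class = "sim_config")
}

#' Generate the ancestral genome
#'
#' Draws core-block and spacer lengths and sequences under the config's
#' seed and concatenates them into the ancestor track whose scaffold is the
#' identity permutation.
#'
#' @param config a [sim_config()].
#' @return list with `track`, `map` (single-strain block map), and
#'   `blocks` (signed scaffold vector, the identity).
#' @export
generate_ancestor <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derived_seed(config$seed, 1L))
  n <- config$n_blocks
  blen <- pmin(pmax(round(stats::rlnorm(n, config$block_len_meanlog,
                                        config$block_len_sdlog)),
                    config$block_len_range[1L]), config$block_len_range[2L])
  slen <- sample(config$spacer_len_range[1L]:config$spacer_len_range[2L],
                 n - 1L, replace = TRUE)
  types <- character(0); ids <- character(0); seqs <- character(0)
  for (i in seq_len(n)) {
    types <- c(types, "block"); ids <- c(ids, as.character(i))
    seqs <- c(seqs, random_dna(blen[i], config$gc))
    if (i < n) {
      types <- c(types, "spacer"); ids <- c(ids, paste0("s", i))
      seqs <- c(seqs, random_dna(slen[i], config$gc))
    }
  }
  track <- new_track(types, ids, rep(1L, length(types)), seqs)
  list(track = track, map = track_block_map(track, "ancestor"),
       blocks = seq_len(n))
}

#' Block map of one strain's track
#'
#' @param track a `genome_track`.
#' @param strain strain name for the `strain` column.
#' @return single-strain block map data.frame.
#' @export
track_block_map <- function(track, strain) {
  co <- track_coords(track)
  co <- co[co$type == "block", ]
  data.frame(strain = strain, block = co$id, contig = "chr",
             start = co$start, end = co$end,
             strand = ifelse(co$orient == 1L, "+", "-"),
             stringsAsFactors = FALSE)
}

#' Plant repeat copies at block junctions
#'
#' Inserts each repeat copy as its own segment immediately after the named
#' block (`after_block = 0` inserts before block 1).  Two placements at the
#' same junction collide and raise an error.  Repeat sequences are drawn
#' once per label from `repeat_len_range` under the config seed (offset so
#' block sequences are unchanged), so all copies of a label are identical
#' at planting time.
#'
#' @param track ancestor `genome_track`.
#' @param placements data.frame with columns `label`, `after_block`
#'   (integer), `orient` (+1/-1).
#' @param config the [sim_config()] (for lengths, GC and seed).
#' @return list with `track` (repeats inserted) and `library` (named
#'   character vector label -> repeat sequence).
#' @export
plant_repeats <- function(track, placements, config) {
  if (nrow(placements) == 0L)
    return(list(track = track, library = character(0)))
  if (anyDuplicated(placements$after_block))
    stop("overlapping placements: one repeat copy per junction")
  set.seed(derived_seed(config$seed, 2L))
  labs <- unique(placements$label)
  lib <- vapply(labs, function(l)
    random_dna(sample(config$repeat_len_range[1L]:config$repeat_len_range[2L], 1L),
               config$gc), character(1))
  seg <- track$segments
  ## insert from the rightmost junction so earlier indices stay valid
  for (r in order(-placements$after_block)) {
    ab <- placements$after_block[r]
    at <- if (ab == 0L) 0L else which(seg$type == "block" & seg$id == as.character(ab))
    if (length(at) != 1L) stop("junction after block ", ab, " not found")
    newrow <- data.frame(type = "repeat", id = placements$label[r],
                         orient = as.integer(placements$orient[r]),
                         seq = lib[[placements$label[r]]],
                         stringsAsFactors = FALSE)
    seg <- rbind(seg[seq_len(at), , drop = FALSE], newrow,
                 seg[seq_len(nrow(seg)) > at, , drop = FALSE])
  }
  rownames(seg) <- NULL
  list(track = structure(list(segments = seg), class = "genome_track"),
       library = lib)
}

## indices of repeat segments with a label
repeat_copy_idx <- function(track, label) {
  which(track$segments$type == "repeat" & track$segments$id == label)
}

#' Repeat-mediated inversion between an inverted repeat pair
#'
#' Recombination between two oppositely oriented copies of a repeat
#' reverse-complements the sequence strictly between them; the copies
#' themselves and everything outside are bitwise unchanged.
#'
#' @param track a `genome_track`.
#' @param label repeat label.
#' @param copies indices (1-based, in genomic order) of the two mediating
#'   copies among the label's occurrences (default the first two).
#' @return the rearranged `genome_track`.
#' @export
apply_ir_inversion <- function(track, label, copies = c(1L, 2L)) {
  idx <- repeat_copy_idx(track, label)
  if (length(idx) < max(copies)) stop("repeat ", label, " has too few copies")
  i1 <- idx[copies[1L]]; i2 <- idx[copies[2L]]
  seg <- track$segments
  if (seg$orient[i1] == seg$orient[i2])
    stop("IR inversion needs copies in opposite orientation")
  if (i2 - i1 >= 2L) {
    mid <- (i1 + 1L):(i2 - 1L)
    seg[mid, ] <- seg[rev(mid), ]
    seg$orient[mid] <- -seg$orient[mid]
  }
  structure(list(segments = seg), class = "genome_track")
}

#' Repeat-mediated transposition at a direct-repeat triple
#'
#' With three same-orientation copies R1 < R2 < R3 of one repeat, the two
#' segments strictly between consecutive copies swap places; the three
#' copies and all external sequence are bitwise unchanged.
#'
#' @param track a `genome_track`.
#' @param label repeat label with at least three same-orientation copies.
#' @param copies indices of the three mediating copies (default 1:3).
#' @return the rearranged `genome_track`.
#' @export
apply_dr_transposition <- function(track, label, copies = 1:3) {
  idx <- repeat_copy_idx(track, label)
  if (length(idx) < max(copies)) stop("repeat ", label, " needs 3 copies")
  i1 <- idx[copies[1L]]; i2 <- idx[copies[2L]]; i3 <- idx[copies[3L]]
  seg <- track$segments
  if (length(unique(seg$orient[c(i1, i2, i3)])) != 1L)
    stop("DR transposition needs three same-orientation copies")
  a <- if (i2 - i1 >= 2L) (i1 + 1L):(i2 - 1L) else integer(0)
  b <- if (i3 - i2 >= 2L) (i2 + 1L):(i3 - 1L) else integer(0)
  seg2 <- rbind(seg[seq_len(i1), , drop = FALSE],
                seg[b, , drop = FALSE],
                seg[i2, , drop = FALSE],
                seg[a, , drop = FALSE],
                seg[i3:nrow(seg), , drop = FALSE])
  rownames(seg2) <- NULL
  structure(list(segments = seg2), class = "genome_track")
}

## outermost genomic extent of a label's copies (0-based half-open)
repeat_outer_extent <- function(track, label, copy_idx) {
  co <- track_coords(track)
  rows <- which(co$type == "repeat" & co$id == label)[copy_idx]
  c(start = min(co$start[rows]), end = max(co$end[rows]))
}

point_mutate <- function(seq, rate) {
  if (rate <= 0 || !nzchar(seq)) return(seq)
  n <- nchar(seq)
  k <- stats::rbinom(1L, n, rate)
  if (k == 0L) return(seq)
  pos <- sample.int(n, k)
  v <- strsplit(seq, "")[[1]]
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
  paste(v, collapse = "")
}

#' Derive strain genomes by applying an event script
#'
#' The script is a named list (one entry per derived strain) of event
#' lists; each event is `list(kind, label, copies)` with kind
#' `"ir_inversion"` or `"dr_transposition"`.  Every event is applied to the
#' strain's current track and checked literally for end conservation: the
#' emitted sequence outside the outermost mediating repeat copies must be
#' bitwise identical before and after.  The truth log records, per event,
#' the mediating repeat, the outer extent, and the block-level effect
#' (signed scaffold before and after), so planted events can be compared
#' with what the analysis pipeline reports.
#'
#' @param ancestor list from [generate_ancestor()] after [plant_repeats()]
#'   (i.e., `list(track = ...)`; only `track` is used).
#' @param script named list of per-strain event lists; strains absent from
#'   the script are identical to the ancestor.
#' @param strains character vector of all strain names (first is the
#'   unrearranged ancestor strain).
#' @param config the [sim_config()] (mutation rate, seed).
#' @return list with `tracks`, `genomes` (character), `scaffolds` (signed
#'   block vectors), `map` (multi-strain block map) and `truth` (event log).
#' @export
apply_event_script <- function(ancestor, script, strains, config) {
  track0 <- if (inherits(ancestor, "genome_track")) ancestor else ancestor$track
  bad <- setdiff(names(script), strains)
  if (length(bad)) stop("script names unknown strains: ", paste(bad, collapse = ", "))
  tracks <- list(); truth <- list()
  for (s in strains) {
    tr <- track0
    evs <- script[[s]]
    for (ev in evs) {
      if (!ev$label %in% tr$segments$id)
        stop("script references absent repeat ", ev$label)
      pre_seq <- track_seq(tr)
      pre_blocks <- track_scaffold_blocks(tr)
      ext <- repeat_outer_extent(tr, ev$label, ev$copies)
      tr2 <- switch(ev$kind,
        ir_inversion = apply_ir_inversion(tr, ev$label, ev$copies),
        dr_transposition = apply_dr_transposition(tr, ev$label, ev$copies),
        stop("unknown event kind ", ev$kind))
      post_seq <- track_seq(tr2)
      stopifnot(nchar(pre_seq) == nchar(post_seq))
      if (substr(pre_seq, 1L, ext["start"]) != substr(post_seq, 1L, ext["start"]) ||
          substr(pre_seq, ext["end"] + 1L, nchar(pre_seq)) !=
          substr(post_seq, ext["end"] + 1L, nchar(post_seq)))
        stop("end-conservation violated by ", ev$kind, " at repeat ", ev$label)
      truth[[length(truth) + 1L]] <- list(
        strain = s, kind = ev$kind, label = ev$label,
        outer_start = unname(ext["start"]), outer_end = unname(ext["end"]),
        blocks_before = pre_blocks,
        blocks_after = track_scaffold_blocks(tr2))
      tr <- tr2
    }
    tracks[[s]] <- tr
  }
  ## optional per-strain substitution noise (never touches the ancestor copy)
  if (config$mutation_rate > 0) {
    set.seed(derived_seed(config$seed, 3L))
    for (s in strains[-1L]) {
      seg <- tracks[[s]]$segments
      seg$seq <- vapply(seg$seq, point_mutate, character(1),
                        rate = config$mutation_rate)
      tracks[[s]] <- structure(list(segments = seg), class = "genome_track")
    }
  }
  genomes <- vapply(tracks, track_seq, character(1))
  scaffolds <- lapply(tracks, track_scaffold_blocks)
  map <- do.call(rbind, lapply(strains, function(s)
    track_block_map(tracks[[s]], s)))
  rownames(map) <- NULL
  list(tracks = tracks, genomes = genomes, scaffolds = scaffolds,
       map = map, truth = truth)
}

## pick a run of >= min_blocks consecutive blocks starting at `from` whose
## total length first exceeds min_bp (used to make inversions "long")
run_exceeding <- function(block_lens, from, min_bp, min_blocks = 2L) {
  j <- from + min_blocks - 1L
  while (j <= length(block_lens) && sum(block_lens[from:j]) <= min_bp)
    j <- j + 1L
  if (j > length(block_lens)) stop("not enough sequence for a long event")
  c(from, j)
}

#' The default synthetic dataset
#'
#' Seed 0, 5 strains, 40 core blocks (~200 kb): strain 2 carries one
#' IR-mediated inversion, strains 3 and 4 two each (all five longer than
#' 10 kb, each bounded by its own inverted repeat pair A..E), and strain 5
#' one direct-repeat-mediated transposition (repeat R, three copies).
#' Strain 1 is the unrearranged ancestor.
#'
#' @param seed RNG seed (default 0, the reference dataset).
#' @param mutation_rate optional substitution noise (default 0).
#' @return list as returned by [apply_event_script()], plus `config`,
#'   `ancestor`, `library` and `placements`.
#' @export
default_dataset <- function(seed = 0L, mutation_rate = 0) {
  config <- sim_config(seed = seed, mutation_rate = mutation_rate)
  anc <- generate_ancestor(config)
  blen <- with(track_coords(anc$track), end[type == "block"] - start[type == "block"])
  ## five long inversion targets on distinct strains/regions + one DR triple
  r1 <- run_exceeding(blen, 4L, 10000)      # strain 2
  r2 <- run_exceeding(blen, 9L, 10000)      # strain 3
  r3 <- run_exceeding(blen, r2[2L] + 2L, 10000)
  r4 <- run_exceeding(blen, 22L, 10000)     # strain 4
  r5 <- run_exceeding(blen, r4[2L] + 2L, 10000)
  stopifnot(r5[2L] <= 33L)
  placements <- rbind(
    data.frame(label = "A", after_block = r1[1L] - 1L, orient = 1L),
    data.frame(label = "A", after_block = r1[2L], orient = -1L),
    data.frame(label = "B", after_block = r2[1L] - 1L, orient = 1L),
    data.frame(label = "B", after_block = r2[2L], orient = -1L),
    data.frame(label = "C", after_block = r3[1L] - 1L, orient = 1L),
    data.frame(label = "C", after_block = r3[2L], orient = -1L),
    data.frame(label = "D", after_block = r4[1L] - 1L, orient = 1L),
    data.frame(label = "D", after_block = r4[2L], orient = -1L),
    data.frame(label = "E", after_block = r5[1L] - 1L, orient = 1L),
    data.frame(label = "E", after_block = r5[2L], orient = -1L),
    data.frame(label = "R", after_block = 34L, orient = 1L),
    data.frame(label = "R", after_block = 36L, orient = 1L),
    data.frame(label = "R", after_block = 38L, orient = 1L))
  pl <- plant_repeats(anc$track, placements, config)
  strains <- paste0("strain", seq_len(config$n_strains))
  script <- list(
    strain2 = list(list(kind = "ir_inversion", label = "A", copies = c(1L, 2L))),
    strain3 = list(list(kind = "ir_inversion", label = "B", copies = c(1L, 2L)),
                   list(kind = "ir_inversion", label = "C", copies = c(1L, 2L))),
    strain4 = list(list(kind = "ir_inversion", label = "D", copies = c(1L, 2L)),
                   list(kind = "ir_inversion", label = "E", copies = c(1L, 2L))),
    strain5 = list(list(kind = "dr_transposition", label = "R", copies = 1:3)))
  ds <- apply_event_script(list(track = pl$track), script, strains, config)
  c(ds, list(config = config, ancestor = anc, library = pl$library,
             placements = placements, script = script))
}

#' Write and re-read a simulated dataset
#'
#' `emit_dataset()` writes per-strain FASTA (70-column, upper case), the
#' multi-strain block map TSV, scaffold permutation files and a truth JSON;
#' `load_dataset()` reads them back so the files round-trip through the
#' package readers.
#'
#' @param dataset list from [apply_event_script()] / [default_dataset()].
#' @param outdir output directory (created if missing).
#' @return `emit_dataset()` returns `outdir` invisibly; `load_dataset()`
#'   returns `list(genomes, map, scaffolds, truth)`.
#' @export
emit_dataset <- function(dataset, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dna <- Biostrings::DNAStringSet(dataset$genomes)
  Biostrings::writeXStringSet(dna, file.path(outdir, "genomes.fasta"), width = 70L)
  write_block_map(dataset$map, file.path(outdir, "blockmap.tsv"))
  write_perms(dataset$scaffolds, file.path(outdir, "scaffolds.perm"))
  jsonlite::write_json(dataset$truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' @rdname emit_dataset
#' @param dir directory written by `emit_dataset()`.
#' @export
load_dataset <- function(dir) {
  dna <- Biostrings::readDNAStringSet(file.path(dir, "genomes.fasta"))
  genomes <- stats::setNames(as.character(dna), names(dna))
  list(genomes = genomes,
       map = read_block_map(file.path(dir, "blockmap.tsv")),
       scaffolds = read_perms(file.path(dir, "scaffolds.perm")),
       truth = jsonlite::read_json(file.path(dir, "truth.json"),
                                   simplifyVector = FALSE))
}
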