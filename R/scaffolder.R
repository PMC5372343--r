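## Core-genome scaffold construction from block maps.
##
## A block map is a plain data.frame of block occurrences with columns
## strain, block, contig, start, end, strand (0-based half-open
## coordinates).  Blocks present in every strain are "core", in a strict
## subset "dispensable", in exactly one strain "strain_specific"; only core
## blocks enter scaffolds.  Bacterial single-chromosome input is assumed:
## a strain spanning several contigs is rejected.

BLOCKMAP_COLS <- c("strain", "block", "contig", "start", "end", "strand")

validate_block_map <- function(map) {
  if (!is.data.frame(map) || !all(BLOCKMAP_COLS %in% names(map)))
    stop("block map needs columns: ", paste(BLOCKMAP_COLS, collapse = ", "))
  if (any(map$start < 0) || any(map$end <= map$start))
    stop("occurrences must satisfy 0 <= start < end")
  if (!all(map$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  map
}

#' Read and write block maps
#'
#' Tab-separated occurrence tables with header columns
#' `strain, block, contig, start, end, strand`; coordinates are 0-based
#' half-open base pairs.
#'
#' @param path file path.
#' @param map block occurrence data.frame.
#' @return `read_block_map()` returns the validated data.frame.
#' @export
read_block_map <- function(path) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(block = "character"))
  validate_block_map(map[, BLOCKMAP_COLS])
}

#' @rdname read_block_map
#' @export
write_block_map <- function(map, path) {
  validate_block_map(map)
  utils::write.table(map[, BLOCKMAP_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify blocks as core, dispensable or strain-specific
#'
#' @param map block map.
#' @param strains optional character vector of all strains (defaults to the
#'   strains present in the map); a block is core iff it occurs in all of
#'   them.
#' @return data.frame with columns `block` and
#'   `class` (`core`/`dispensable`/`strain_specific`).
#' @export
block_classes <- function(map, strains = NULL) {
  validate_block_map(map)
  if (is.null(strains)) strains <- unique(map$strain)
  cov <- tapply(map$strain, map$block, function(s) length(unique(s)))
  data.frame(
    block = names(cov),
    class = ifelse(cov == length(strains), "core",
                   ifelse(cov == 1L, "strain_specific", "dispensable")),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Derive a block map from a multiple whole-genome alignment (MAF)
#'
#' Parses the `a`/`s` line dialect of MAF as emitted by whole-genome
#' aligners such as Mugsy.  Each alignment block becomes one block
#' occurrence per participating strain; `s` lines carry
#' `src start size strand srcSize text`, with `src` of the form
#' `strain.contig`, and minus-strand starts are converted to
#' forward-strand 0-based half-open coordinates.
#'
#' @param lines character vector of MAF lines (or a length-1 path read with
#'   `readLines()` by the caller).
#' @param strains optional complete strain list for classification.
#' @return block map data.frame (one row per occurrence) with a
#'   `class` column joined from [block_classes()].
#' @export
blocks_from_maf <- function(lines, strains = NULL) {
  rows <- list()
  block_id <- 0L
  in_block <- FALSE
  for (ii in seq_along(lines)) {
    ln <- trimws(lines[ii])
    if (!nzchar(ln) || startsWith(ln, "#")) { in_block <- FALSE; next }
    if (startsWith(ln, "a")) { block_id <- block_id + 1L; in_block <- TRUE; next }
    if (startsWith(ln, "s")) {
      if (!in_block) stop("MAF parse error at line ", ii, ": 's' before 'a'")
      f <- strsplit(ln, "[[:space:]]+")[[1]]
      if (length(f) < 6L) stop("MAF parse error at line ", ii, ": short 's' record")
      src <- f[2L]
      dot <- regexpr(".", src, fixed = TRUE)
      if (dot < 1L) stop("MAF parse error at line ", ii, ": src must be strain.contig")
      strain <- substr(src, 1L, dot - 1L)
      contig <- substring(src, dot + 1L)
      start <- suppressWarnings(as.integer(f[3L]))
      size <- suppressWarnings(as.integer(f[4L]))
      strand <- f[5L]
      src_size <- suppressWarnings(as.integer(f[6L]))
      if (anyNA(c(start, size, src_size)) || !strand %in% c("+", "-"))
        stop("MAF parse error at line ", ii, ": bad numeric/strand field")
      fwd_start <- if (strand == "+") start else src_size - start - size
      rows[[length(rows) + 1L]] <- data.frame(
        strain = strain, block = as.character(block_id), contig = contig,
        start = fwd_start, end = fwd_start + size, strand = strand,
        stringsAsFactors = FALSE)
    }
  }
  map <- do.call(rbind, rows)
  if (is.null(map)) stop("no alignment blocks found")
  cls <- block_classes(map, strains)
  merge(validate_block_map(map), cls, by = "block", sort = FALSE)
}

core_block_ids <- function(map, strains = NULL) {
  cls <- block_classes(map, strains)
  cls$block[cls$class == "core"]
}

#' Drop short core blocks
#'
#' Removes core blocks whose length in the reference strain is below
#' `min_len` (strictly; a block of exactly `min_len` is kept).  Block
#' lengths differ slightly between strains, so the threshold is measured
#' on one designated reference strain.
#'
#' @param map block map.
#' @param min_len minimum length in bp (default 500).
#' @param reference reference strain (default: first strain alphabetically).
#' @return filtered block map.
#' @export
filter_short_blocks <- function(map, min_len = 500, reference = NULL) {
  validate_block_map(map)
  if (is.null(reference)) reference <- sort(unique(map$strain))[1L]
  core <- core_block_ids(map)
  ref <- map[map$strain == reference & map$block %in% core, ]
  len <- tapply(ref$end - ref$start, ref$block, max)
  drop <- names(len)[len < min_len]
  map[!(map$block %in% drop), , drop = FALSE]
}

## per-strain core-block order (ranks by genomic start among core blocks)
core_ranks <- function(map, strains) {
  core <- core_block_ids(map, strains)
  lapply(stats::setNames(nm = strains), function(s) {
    occ <- map[map$strain == s & map$block %in% core, ]
    occ[order(occ$start), , drop = FALSE]
  })
}

#' Merge core blocks consecutive in every strain
#'
#' Two core blocks a, b fuse iff in every strain they are genomically
#' adjacent among core blocks (dispensable and strain-specific blocks in
#' between are ignored) with consistent relative orientation: a then b both
#' on `+`, or b then a both on `-`.  Fusion is repeated to a fixpoint and
#' drastically reduces the number of distinct scaffold blocks.  Merged
#' blocks are renumbered 1..m by genomic order in the reference strain;
#' merged occurrences span from the first member's start to the last
#' member's end.  Blocks with multiple copies in any strain never merge.
#'
#' @param map block map (core blocks are detected internally).
#' @param reference reference strain for renumbering (default first
#'   alphabetically).
#' @return list with `map` (merged block map of core blocks, block ids
#'   `"1".."m"`), and `members` (named list: new id -> original block ids
#'   in merged order).
#' @export
merge_core_blocks <- function(map, reference = NULL) {
  validate_block_map(map)
  strains <- sort(unique(map$strain))
  if (is.null(reference)) reference <- strains[1L]
  core <- core_block_ids(map, strains)
  work <- map[map$block %in% core, BLOCKMAP_COLS]
  members <- stats::setNames(as.list(unique(work$block)), unique(work$block))

  repeat {
    ranks <- core_ranks(work, strains)
    for (s in strains) {
      if (length(unique(ranks[[s]]$contig)) > 1L)
        stop("strain ", s, " spans multiple contigs; single-chromosome input required")
    }
    blocks <- unique(work$block)
    dup <- unique(unlist(lapply(ranks, function(r)
      r$block[duplicated(r$block)])))
    ## successor candidate: in EVERY strain, b follows a with consistent strands
    succ <- stats::setNames(rep(NA_character_, length(blocks)), blocks)
    ref_r <- ranks[[reference]]
    for (i in seq_len(nrow(ref_r) - 1L)) {
      ## test the genomic neighbour pair (x, y) in the reference strain
      x <- ref_r$block[i]; y <- ref_r$block[i + 1L]
      if (x %in% dup || y %in% dup) next
      sx <- ref_r$strand[i]; sy <- ref_r$strand[i + 1L]
      ## orientation-consistent fusion target: (a,b) such that merged block
      ## reads a then b forward; genomic (x,y) with (+,+) -> (x,y);
      ## with (-,-) -> (y,x); mixed strands never fuse
      if (sx == "+" && sy == "+") { a <- x; b <- y }
      else if (sx == "-" && sy == "-") { a <- y; b <- x }
      else next
      ## verify in all strains
      ok <- all(vapply(strains, function(s) {
        r <- ranks[[s]]
        pa <- which(r$block == a); pb <- which(r$block == b)
        if (length(pa) != 1L || length(pb) != 1L) return(FALSE)
        (pb == pa + 1L && r$strand[pa] == "+" && r$strand[pb] == "+") ||
          (pa == pb + 1L && r$strand[pa] == "-" && r$strand[pb] == "-")
      }, logical(1)))
      if (ok) succ[a] <- b
    }
    if (all(is.na(succ))) break
    ## assemble chains a -> succ[a] -> ... and fuse them
    has_pred <- unique(stats::na.omit(succ))
    heads <- setdiff(names(succ)[!is.na(succ)], has_pred)
    for (hd in heads) {
      chain <- hd
      while (!is.na(succ[[chain[length(chain)]]]) &&
             !(succ[[chain[length(chain)]]] %in% chain))
        chain <- c(chain, succ[[chain[length(chain)]]])
      new_id <- chain[1L]
      members[[new_id]] <- unlist(members[chain], use.names = FALSE)
      for (other in chain[-1L]) members[[other]] <- NULL
      ## fuse occurrences strain by strain
      keep_rows <- work$block == chain[1L]
      for (s in strains) {
        rows <- work$strain == s & work$block %in% chain
        occ <- work[rows, ]
        work$start[rows & keep_rows] <- min(occ$start)
        work$end[rows & keep_rows] <- max(occ$end)
      }
      work <- work[!(work$block %in% chain[-1L]), , drop = FALSE]
    }
  }
  ## renumber by genomic order in the reference strain
  ref_occ <- work[work$strain == reference, ]
  ref_occ <- ref_occ[order(ref_occ$start), ]
  renum <- stats::setNames(as.character(seq_len(nrow(ref_occ))), ref_occ$block)
  members <- stats::setNames(members[names(renum)], renum[names(renum)])
  work$block <- renum[work$block]
  rownames(work) <- NULL
  list(map = validate_block_map(work), members = members)
}

#' Build per-strain core-genome scaffolds
#'
#' Orders each strain's core blocks by genomic start; a block on the minus
#' strand enters the scaffold with negative sign.  Duplicated blocks are
#' permitted here (they are resolved by [dedup_duplicates()] before
#' distance computations).
#'
#' @param map block map of (merged) core blocks with integer-like block ids.
#' @return named list of `scaffold` objects: `list(strain, blocks, occ)`.
#' @export
build_scaffolds <- function(map) {
  validate_block_map(map)
  strains <- sort(unique(map$strain))
  lapply(stats::setNames(nm = strains), function(s) {
    occ <- map[map$strain == s, ]
    if (length(unique(occ$contig)) > 1L)
      stop("strain ", s, " spans multiple contigs; single-chromosome input required")
    occ <- occ[order(occ$start), ]
    blocks <- as.integer(occ$block) * ifelse(occ$strand == "+", 1L, -1L)
    structure(list(strain = s, blocks = blocks, occ = occ),
              class = "scaffold")
  })
}

#' @export
print.scaffold <- function(x, ...) {
  cat("scaffold", x$strain, ":", paste(sprintf("%+d", x$blocks), collapse = " "), "\n")
  invisible(x)
}

#' Group identical scaffolds
#'
#' Partitions scaffolds by exact signed block sequence.  Groups are
#' numbered 1..k by decreasing size; ties broken by the order of first
#' appearance in the input.
#'
#' @param scaffolds list of scaffolds (or of signed block vectors).
#' @return list of groups: `list(id, strains, blocks, canonical)`.
#' @export
build_groups <- function(scaffolds) {
  blocks <- lapply(scaffolds, function(s)
    if (inherits(s, "scaffold")) s$blocks else as.integer(s))
  nm <- names(scaffolds)
  if (is.null(nm)) nm <- paste0("strain", seq_along(scaffolds))
  key <- vapply(blocks, paste, character(1), collapse = " ")
  first <- !duplicated(key)
  uk <- key[first]
  sizes <- as.integer(table(key)[uk])
  ord <- order(-sizes, match(uk, key))
  uk <- uk[ord]
  lapply(seq_along(uk), function(g) {
    idx <- which(key == uk[g])
    structure(list(id = g, strains = nm[idx], blocks = blocks[[idx[1L]]],
                   canonical = scaffolds[[idx[1L]]]),
              class = "scaffold_group")
  })
}

#' @export
print.scaffold_group <- function(x, ...) {
  cat(sprintf("group %d (%d strains): %s\n", x$id, length(x$strains),
              paste(sprintf("%+d", x$blocks), collapse = " ")))
  invisible(x)
}

#' Resolve duplicated blocks against a duplicate-free reference
#'
#' When a block occurs several times in a scaffold (repeat-borne extra
#' copies), the copy sharing the most adjacencies with the reference
#' scaffold is kept (orientation-aware; ties go to the first occurrence)
#' and the others are dropped, yielding a strict signed permutation.
#'
#' @param blocks signed block vector, possibly with duplicates.
#' @param reference duplicate-free signed block vector covering the same
#'   block set.
#' @return signed permutation over the reference's block set.
#' @export
dedup_duplicates <- function(blocks, reference) {
  blocks <- as.integer(blocks); reference <- as.integer(reference)
  if (anyDuplicated(abs(reference)))
    stop("reference scaffold must be duplicate-free")
  if (!all(abs(blocks) %in% abs(reference)))
    stop("scaffold contains blocks absent from the reference")
  if (!all(abs(reference) %in% abs(blocks)))
    stop("scaffold is missing blocks of the reference")
  ncap <- max(abs(reference)) + 1L
  refcap <- c(0L, reference, ncap)
  ref_prev <- ref_next <- integer(max(abs(reference)))
  for (k in 2:(length(refcap) - 1L)) {
    v <- refcap[k]
    ref_prev[abs(v)] <- if (v > 0L) refcap[k - 1L] else -refcap[k + 1L]
    ref_next[abs(v)] <- if (v > 0L) refcap[k + 1L] else -refcap[k - 1L]
  }
  cap <- c(0L, blocks, ncap)
  keep <- rep(TRUE, length(blocks))
  for (bid in unique(abs(blocks)[duplicated(abs(blocks))])) {
    pos <- which(abs(blocks) == bid)
    score <- vapply(pos, function(p) {
      v <- blocks[p]
      prv <- cap[p]; nxt <- cap[p + 2L]
      if (v < 0L) { tmp <- prv; prv <- -nxt; nxt <- -tmp }
      sum(prv == ref_prev[bid], nxt == ref_next[bid])
    }, numeric(1))
    best <- pos[which.max(score)]          # which.max takes the first tie
    keep[setdiff(pos, best)] <- FALSE
  }
  as_signed_perm(blocks[keep])
}

#' Closest scaffold group for every group
#'
#' For each source group, eliminates independent rearrangement events
#' against every other group and computes the exact inversion distance of
#' the reduced pair; the target with the minimum total rearrangement
#' distance (inversion distance plus independent-event count) is selected
#' (ties: lower group id, i.e. the larger group).  Ranking
#' by total distance rather than inversion distance alone is essential:
#' two scaffolds differing by overlapping inversions can legitimately
#' reduce to a single independent inverted transposition (inversion
#' distance 0), which would otherwise displace the biologically closer
#' group.
#' For the winning pair an optimal inversion scenario is derived and its
#' steps are reported as (start block, end block) labels in the source
#' scaffold, with core-genome segment lengths when a block map is given.
#'
#' Groups whose canonical scaffold carries duplicated blocks are first
#' resolved with [dedup_duplicates()] against the lowest-numbered
#' duplicate-free group.
#'
#' @param groups list of scaffold groups from [build_groups()].
#' @param map optional merged core block map for inversion lengths.
#' @return data.frame-like list of `pair_comparison` records, one per
#'   source group: `list(source_group, closest_group, inv_d, r_d, counts,
#'   events, inversions)` where `inversions` is a data.frame with columns
#'   `start_block`, `end_block`, `length_bp`, `length_mbp`.
#' @export
closest_pairs <- function(groups, map = NULL) {
  if (length(groups) < 2L) stop("need at least two scaffold groups")
  dupfree <- vapply(groups, function(g) !anyDuplicated(abs(g$blocks)), logical(1))
  if (!any(dupfree)) stop("no duplicate-free group to anchor deduplication")
  ref <- groups[[which(dupfree)[1L]]]$blocks
  perms <- lapply(groups, function(g)
    if (anyDuplicated(abs(g$blocks))) dedup_duplicates(g$blocks, ref)
    else as_signed_perm(g$blocks))

  lapply(seq_along(groups), function(gi) {
    src <- perms[[gi]]
    best <- NULL
    for (hi in seq_along(groups)) {
      if (hi == gi) next
      el <- eliminate_independent_events(perms[[hi]], src)
      d <- inversion_distance(el$b)$distance
      r <- sum(el$counts)
      if (is.null(best) || d + r < best$d + best$r ||
          (d + r == best$d + best$r && hi < best$hi)) {
        best <- list(hi = hi, d = d, r = r, el = el)
      }
    }
    ## scenario with endpoints in source-frame original labels
    el <- best$el
    cur <- el$b
    sc <- optimal_scenario(cur, seq_along(cur))
    seg_labels <- function(perm, i, j) {
      unlist(lapply(perm[i:j], function(v) {
        run <- el$groups[[abs(v)]]
        if (v > 0L) run else -rev(run)
      }))
    }
    inv_rows <- list()
    if (sc$distance > 0) {
      for (st in seq_len(nrow(sc$steps))) {
        i <- sc$steps[st, 1L]; j <- sc$steps[st, 2L]
        seg <- seg_labels(cur, i, j)
        len_bp <- NA_real_
        if (!is.null(map)) {
          s0 <- groups[[gi]]$strains[1L]
          occ <- map[map$strain == s0 & map$block %in% as.character(abs(seg)), ]
          if (nrow(occ)) len_bp <- sum(occ$end - occ$start)
        }
        inv_rows[[st]] <- data.frame(
          start_block = seg[1L], end_block = seg[length(seg)],
          length_bp = len_bp, length_mbp = signif(len_bp / 1e6, 4))
        cur <- apply_inversion(cur, i, j)
      }
    }
    inversions <- if (length(inv_rows)) do.call(rbind, inv_rows) else
      data.frame(start_block = integer(0), end_block = integer(0),
                 length_bp = numeric(0), length_mbp = numeric(0))
    structure(list(
      source_group = groups[[gi]]$id, closest_group = groups[[best$hi]]$id,
      inv_d = best$d, r_d = best$r, counts = el$counts,
      events = el$events, inversions = inversions
    ), class = "pair_comparison")
  })
}

#' @export
print.pair_comparison <- function(x, ...) {
  cat(sprintf("group %d -> closest %d: inv_d %d, r_d %d\n",
              x$source_group, x$closest_group, x$inv_d, x$r_d))
  if (nrow(x$inversions))
    print(x$inversions, row.names = FALSE)
  invisible(x)
}
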