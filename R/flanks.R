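## Inverted/direct repeat detection at rearrangement breakpoints.
##
## Long inversions in bacterial chromosomes are typically bounded by a pair
## of inverted repeats (IS elements and other mobile DNA); transpositions by
## direct-repeat triples.  The detector extracts sequence windows around the
## breakpoints of each event and runs a seed-and-extend comparison (exact
## k-mer seeds, gapless X-drop extension with mismatches) between windows,
## in reverse-complement orientation for inverted repeats and as-is for
## direct repeats.

IUPAC_OK <- "^[ACGTRYSWKMBDHVNacgtryswkmbdhvn]*$"

check_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L)
    stop(what, " must be a single character string")
  if (!grepl(IUPAC_OK, x))
    stop(what, " contains non-IUPAC characters")
  toupper(x)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## seed-and-extend on one diagonal: returns best gapless local extent
## around the anchor, as list(qs, qe, ts, te, len, identity) or NULL
extend_diagonal <- function(qv, tv, qa, ta, min_len, min_id,
                            mismatch_pen = 2L, xdrop = 25L) {
  nq <- length(qv); nt <- length(tv)
  ## right extension from anchor (inclusive)
  best <- 0L; score <- 0L; right <- -1L
  i <- qa; j <- ta
  while (i <= nq && j <= nt) {
    score <- score + (if (qv[i] == tv[j]) 1L else -mismatch_pen)
    if (score > best) { best <- score; right <- i - qa }
    if (best - score > xdrop) break
    i <- i + 1L; j <- j + 1L
  }
  if (right < 0L) return(NULL)
  ## left extension from anchor - 1
  bestl <- 0L; score <- 0L; left <- 0L
  i <- qa - 1L; j <- ta - 1L
  while (i >= 1L && j >= 1L) {
    score <- score + (if (qv[i] == tv[j]) 1L else -mismatch_pen)
    if (score > bestl) { bestl <- score; left <- qa - i }
    if (bestl - score > xdrop) break
    i <- i - 1L; j <- j - 1L
  }
  qs <- qa - left; qe <- qa + right
  ts <- ta - left; te <- ta + right
  len <- qe - qs + 1L
  ident <- mean(qv[qs:qe] == tv[ts:te])
  if (len < min_len || ident < min_id) return(NULL)
  list(qs = qs, qe = qe, ts = ts, te = te, len = len, identity = ident)
}

## all gapless repeat matches between query and target strings
## (already orientation-adjusted); returns list of extents
seed_and_extend <- function(query, target, min_len, min_id, seed_k) {
  nq <- nchar(query); nt <- nchar(target)
  if (nq < seed_k || nt < seed_k) return(list())
  qv <- utf8ToInt(query); tv <- utf8ToInt(target)
  qk <- substring(query, 1:(nq - seed_k + 1L), seed_k:nq)
  tk <- substring(target, 1:(nt - seed_k + 1L), seed_k:nt)
  hit <- match(tk, qk)                       # first query position per target kmer
  tpos <- which(!is.na(hit))
  if (!length(tpos)) return(list())
  qpos <- hit[tpos]
  diag <- tpos - qpos
  ## one anchor per diagonal (first seed)
  first <- !duplicated(diag)
  anchors <- data.frame(q = qpos[first], t = tpos[first])
  hits <- list()
  covered <- function(ext) any(vapply(hits, function(h)
    h$qs <= ext$qs && ext$qe <= h$qe && h$ts <= ext$ts && ext$te <= h$te,
    logical(1)))
  for (r in seq_len(nrow(anchors))) {
    ext <- extend_diagonal(qv, tv, anchors$q[r], anchors$t[r], min_len, min_id)
    if (!is.null(ext) && !covered(ext))
      hits[[length(hits) + 1L]] <- ext
  }
  hits
}

new_repeat_pair <- function(occ1, occ2, orientation, length, identity,
                            seq, label = NA_character_) {
  structure(list(label = label, occ1 = occ1, occ2 = occ2,
                 orientation = orientation, length = length,
                 identity = identity, seq = seq),
            class = "repeat_pair")
}

#' @export
print.repeat_pair <- function(x, ...) {
  cat(sprintf("%s repeat%s: %d bp, identity %.3f; occ1 [%d,%d)%s occ2 [%d,%d)%s\n",
              x$orientation,
              if (is.na(x$label)) "" else paste0(" ", x$label),
              x$length, x$identity,
              x$occ1["start"], x$occ1["end"], x$occ1["strand"],
              x$occ2["start"], x$occ2["end"], x$occ2["strand"]))
  invisible(x)
}

#' Find an inverted or direct repeat pair between two windows
#'
#' `find_inverted_repeat()` seeds exact k-mers between `left` and the
#' reverse complement of `right` and extends them gaplessly, reporting the
#' highest-scoring pair with aligned length at least `min_len` and identity
#' at least `min_id`; `find_direct_repeat()` does the same without
#' reverse-complementing.  Occurrence coordinates are 0-based half-open
#' within each window; `strand` is `+` in `left` and `-`/`+` in `right`
#' for inverted/direct pairs respectively.
#'
#' @param left,right window sequences (character).
#' @param min_len minimum repeat length in bp (default 50).
#' @param min_id minimum identity fraction (default 0.90).
#' @param seed_k exact seed length (default 15).
#' @return a `repeat_pair` or `NULL` when no pair qualifies.
#' @export
find_inverted_repeat <- function(left, right, min_len = 50, min_id = 0.90,
                                 seed_k = 15) {
  left <- check_dna(left, "left window"); right <- check_dna(right, "right window")
  if (!nzchar(left) || !nzchar(right)) return(NULL)
  nr <- nchar(right)
  hits <- seed_and_extend(left, revcomp(right), min_len, min_id, seed_k)
  if (!length(hits)) return(NULL)
  best <- hits[[which.max(vapply(hits, function(h) h$len * h$identity, numeric(1)))]]
  ## map target (revcomp) coords back onto right, 0-based half-open
  rs <- nr - best$te; re <- nr - best$ts + 1L
  new_repeat_pair(
    occ1 = c(start = best$qs - 1L, end = best$qe, strand = 1L),
    occ2 = c(start = rs, end = re, strand = -1L),
    orientation = "inverted", length = best$len, identity = best$identity,
    seq = substr(left, best$qs, best$qe))
}

#' @rdname find_inverted_repeat
#' @export
find_direct_repeat <- function(left, right, min_len = 50, min_id = 0.90,
                               seed_k = 15) {
  left <- check_dna(left, "left window"); right <- check_dna(right, "right window")
  if (!nzchar(left) || !nzchar(right)) return(NULL)
  hits <- seed_and_extend(left, right, min_len, min_id, seed_k)
  if (!length(hits)) return(NULL)
  best <- hits[[which.max(vapply(hits, function(h) h$len * h$identity, numeric(1)))]]
  new_repeat_pair(
    occ1 = c(start = best$qs - 1L, end = best$qe, strand = 1L),
    occ2 = c(start = best$ts - 1L, end = best$te, strand = 1L),
    orientation = "direct", length = best$len, identity = best$identity,
    seq = substr(left, best$qs, best$qe))
}

#' Extract breakpoint windows around an inversion
#'
#' The left window spans from the end of the core block preceding the
#' inverted segment minus `margin` to the start of the first inverted block
#' plus `margin` (the right window symmetrically), clipped to the genome
#' and truncated to `cap` bp.  Coordinates are 0-based half-open.
#'
#' @param inversion length-2 signed vector: (start block, end block) labels
#'   of the inverted segment in the scaffold.
#' @param scaffold a `scaffold` object (with occurrence table).
#' @param genome genome sequence of the scaffold's strain (character).
#' @param margin bp extended into the flanking blocks (default 2000).
#' @param cap maximum window length in bp (default 20000).
#' @return list with `left` and `right`, each
#'   `list(start, end, seq)`.
#' @export
inversion_breakpoint_windows <- function(inversion, scaffold, genome,
                                         margin = 2000, cap = 20000) {
  genome <- check_dna(genome, "genome")
  occ <- scaffold$occ
  blocks <- scaffold$blocks
  ia <- which(abs(blocks) == abs(inversion[1L]))
  ib <- which(abs(blocks) == abs(inversion[2L]))
  if (length(ia) != 1L || length(ib) != 1L)
    stop("inversion endpoints must match unique scaffold blocks")
  lo <- min(ia, ib); hi <- max(ia, ib)
  glen <- nchar(genome)
  seg_start <- occ$start[lo]
  seg_end <- occ$end[hi]
  prev_end <- if (lo > 1L) occ$end[lo - 1L] else 0L
  next_start <- if (hi < length(blocks)) occ$start[hi + 1L] else glen
  clipwin <- function(a, b) {
    a <- max(0L, as.integer(a)); b <- min(glen, as.integer(b))
    if (b - a > cap) {                      # trim symmetrically to the cap
      mid <- (a + b) %/% 2L
      a <- mid - cap %/% 2L; b <- a + as.integer(cap)
    }
    if (b <= a) return(list(start = a, end = a, seq = ""))
    list(start = a, end = b, seq = substr(genome, a + 1L, b))
  }
  list(left = clipwin(prev_end - margin, seg_start + margin),
       right = clipwin(seg_end - margin, next_start + margin))
}

#' Locate all occurrences of a repeat in a set of genomes
#'
#' Seed-and-extend search of `repseq` against both strands of every genome;
#' overlapping hits on a strand are reported once.
#'
#' @param repseq repeat sequence (character).
#' @param genomes named character vector or list of genome sequences.
#' @param min_id minimum identity (default 0.90).
#' @param min_frac minimum aligned fraction of the repeat (default 0.8).
#' @param seed_k exact seed length (default 15).
#' @return data.frame with columns `strain`, `start`, `end` (0-based
#'   half-open), `strand`, `identity`.
#' @export
locate_repeat_occurrences <- function(repseq, genomes, min_id = 0.90,
                                      min_frac = 0.8, seed_k = 15) {
  repseq <- check_dna(repseq, "repeat")
  min_len <- max(seed_k, floor(min_frac * nchar(repseq)))
  rows <- list()
  for (s in names(genomes)) {
    g <- check_dna(as.character(genomes[[s]]), paste("genome", s))
    for (strand in c(1L, -1L)) {
      tgt <- if (strand == 1L) g else revcomp(g)
      hits <- seed_and_extend(repseq, tgt, min_len, min_id, seed_k)
      for (h in hits) {
        st <- h$ts - 1L; en <- h$te
        if (strand == -1L) { tmp <- st; st <- nchar(g) - en; en <- nchar(g) - tmp }
        rows[[length(rows) + 1L]] <- data.frame(
          strain = s, start = st, end = en,
          strand = if (strand == 1L) "+" else "-", identity = h$identity,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(strain = character(0), start = integer(0), end = integer(0),
               strand = character(0), identity = numeric(0))
  ## drop duplicate/overlapping reports of the same occurrence
  if (nrow(out) > 1L) {
    out <- out[order(out$strain, out$start, -(out$end - out$start)), ]
    keep <- rep(TRUE, nrow(out))
    for (i in 2:nrow(out)) {
      j <- max(which(keep[1:(i - 1L)]))
      if (out$strain[i] == out$strain[j] && out$start[i] < out$end[j] &&
          out$strand[i] == out$strand[j])
        keep[i] <- FALSE
    }
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Check repeat conservation at the junctions of a multi-break event
#'
#' Transpositions have three junctions, (inverted) block interchanges four.
#' Every junction window is compared against every other in both
#' orientations; a junction is "covered" when it shares a repeat with at
#' least one other junction.  For transpositions the shared repeats are
#' expected to be direct; for inverted kinds a mix of orientations.
#'
#' @param kind event kind (one of the four independent kinds).
#' @param windows list of 3 or 4 junction window sequences (character).
#' @param min_len,min_id,seed_k detection thresholds as in
#'   [find_inverted_repeat()].
#' @return list with `junctions` (per-junction logical `covered`),
#'   `pairs` (data.frame of junction pairs and orientation found) and
#'   `all_conserved` (all junctions covered).
#' @export
check_event_ends <- function(kind, windows, min_len = 50, min_id = 0.90,
                             seed_k = 15) {
  need <- if (kind %in% c("transposition", "inverted_transposition")) 3L else 4L
  if (length(windows) != need)
    stop(kind, " has ", need, " junctions; got ", length(windows), " windows")
  m <- length(windows)
  covered <- rep(FALSE, m)
  prs <- list()
  for (i in 1:(m - 1L)) for (j in (i + 1L):m) {
    rp_d <- find_direct_repeat(windows[[i]], windows[[j]], min_len, min_id, seed_k)
    rp_i <- find_inverted_repeat(windows[[i]], windows[[j]], min_len, min_id, seed_k)
    rp <- if (!is.null(rp_d) &&
              (is.null(rp_i) || rp_d$length >= rp_i$length)) rp_d else rp_i
    if (!is.null(rp)) {
      covered[c(i, j)] <- TRUE
      prs[[length(prs) + 1L]] <- data.frame(
        junction1 = i, junction2 = j, orientation = rp$orientation,
        length = rp$length, identity = rp$identity, stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(prs)) do.call(rbind, prs) else
    data.frame(junction1 = integer(0), junction2 = integer(0),
               orientation = character(0), length = integer(0),
               identity = numeric(0))
  list(junctions = covered, pairs = pairs, all_conserved = all(covered))
}

## repeat label registry: clusters detected repeats at >= cluster_id
## identity and hands out letters in discovery order (A, B, C, ...)
new_repeat_registry <- function(cluster_id = 0.90) {
  env <- new.env(parent = emptyenv())
  env$seqs <- character(0)
  env$labels <- character(0)
  env$cluster_id <- cluster_id
  env
}

assign_repeat_label <- function(registry, seq) {
  for (k in seq_along(registry$seqs)) {
    ref <- registry$seqs[k]
    hits <- c(seed_and_extend(seq, ref,
                              min_len = 0.8 * min(nchar(seq), nchar(ref)),
                              min_id = registry$cluster_id, seed_k = 15),
              seed_and_extend(seq, revcomp(ref),
                              min_len = 0.8 * min(nchar(seq), nchar(ref)),
                              min_id = registry$cluster_id, seed_k = 15))
    if (length(hits)) return(registry$labels[k])
  }
  lab <- LETTERS[length(registry$labels) + 1L]
  registry$seqs <- c(registry$seqs, seq)
  registry$labels <- c(registry$labels, lab)
  lab
}

#' Flank report for the inversions of one pair comparison
#'
#' For every inversion of a [closest_pairs()] row, extracts breakpoint
#' windows in a source-group strain, searches them for an inverted repeat
#' pair, assigns cluster labels (A, B, ...), and computes the presence
#' code: 0 = repeat located in source-group strains only, 1 = closest-group
#' strains only, 2 = both.
#'
#' @param pair a `pair_comparison`.
#' @param groups scaffold group list (for strain membership).
#' @param scaffolds named scaffold list.
#' @param genomes named character vector of genome sequences.
#' @param registry label registry from `new_repeat_registry()` (shared
#'   across pairs so labels are consistent).
#' @param min_len,min_id,seed_k,margin,cap detection parameters.
#' @param long_threshold length (bp) above which an inversion counts as
#'   long (default 10000).
#' @return data.frame with one row per inversion: `start_block`,
#'   `end_block`, `length_bp`, `long`, `ir_found`, `label`,
#'   `repeat_len`, `identity`, `presence`.
#' @export
flank_inversions <- function(pair, groups, scaffolds, genomes,
                             registry = new_repeat_registry(),
                             min_len = 50, min_id = 0.90, seed_k = 15,
                             margin = 2000, cap = 20000,
                             long_threshold = 10000) {
  src_grp <- groups[[pair$source_group]]
  clo_grp <- groups[[pair$closest_group]]
  s0 <- src_grp$strains[1L]
  sc <- scaffolds[[s0]]
  rows <- list()
  inv <- pair$inversions
  for (k in seq_len(nrow(inv))) {
    w <- inversion_breakpoint_windows(
      c(inv$start_block[k], inv$end_block[k]), sc, genomes[[s0]],
      margin = margin, cap = cap)
    rp <- find_inverted_repeat(w$left$seq, w$right$seq, min_len, min_id, seed_k)
    found <- !is.null(rp)
    lab <- NA_character_; presence <- NA_integer_
    rlen <- NA_integer_; rid <- NA_real_
    if (found) {
      lab <- assign_repeat_label(registry, rp$seq)
      rlen <- rp$length; rid <- rp$identity
      in_src <- nrow(locate_repeat_occurrences(
        rp$seq, genomes[src_grp$strains[1L]], min_id = min_id)) > 0L
      in_clo <- nrow(locate_repeat_occurrences(
        rp$seq, genomes[clo_grp$strains[1L]], min_id = min_id)) > 0L
      presence <- if (in_src && in_clo) 2L else if (in_clo) 1L else 0L
    }
    rows[[k]] <- data.frame(
      start_block = inv$start_block[k], end_block = inv$end_block[k],
      length_bp = inv$length_bp[k],
      long = isTRUE(inv$length_bp[k] > long_threshold),
      ir_found = found, label = lab, repeat_len = rlen, identity = rid,
      presence = presence, stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(start_block = integer(0), end_block = integer(0),
               length_bp = numeric(0), long = logical(0),
               ir_found = logical(0), label = character(0),
               repeat_len = integer(0), identity = numeric(0),
               presence = integer(0))
}

#' Summarise IR-flanking prevalence across inversions
#'
#' @param reports data.frame of flank reports (rows as produced by
#'   [flank_inversions()], possibly concatenated).
#' @param long_threshold length in bp separating long from short
#'   inversions (default 10000).
#' @return list of counts: total inversions, IR-flanked, long, long and
#'   IR-flanked, plus the flanked fraction among long inversions.
#' @export
summarize_prevalence <- function(reports, long_threshold = 10000) {
  if (is.null(reports) || nrow(reports) == 0L)
    return(list(n_inversions = 0L, n_flanked = 0L, n_long = 0L,
                n_long_flanked = 0L, frac_long_flanked = NaN))
  long <- !is.na(reports$length_bp) & reports$length_bp > long_threshold
  fl <- reports$ir_found
  list(n_inversions = nrow(reports),
       n_flanked = sum(fl),
       n_long = sum(long),
       n_long_flanked = sum(fl & long),
       frac_long_flanked = if (sum(long)) sum(fl & long) / sum(long) else NaN)
}

#' Write repeat occurrences as BED6
#'
#' Chrom is the strain name, score is identity scaled to 0-1000, strand as
#' detected; coordinates remain 0-based half-open per BED convention.
#'
#' @param occs occurrence data.frame from [locate_repeat_occurrences()].
#' @param label feature name for column 4.
#' @param path output file.
#' @export
write_bed6 <- function(occs, label, path) {
  bed <- data.frame(occs$strain, occs$start, occs$end, label,
                    as.integer(round(1000 * occs$identity)), occs$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     col.names = FALSE, row.names = FALSE)
  invisible(path)
}
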