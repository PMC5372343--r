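## End-to-end orchestration: block map (or MAF, or ready-made scaffolds)
## -> filter -> merge -> scaffolds -> groups -> dedup -> independent-event
## elimination -> inversion distances/scenarios -> repeat flanks ->
## prevalence summary.

#' Run the core-genome scaffold comparison pipeline
#'
#' Stages are executed in order; repeat-flank analysis runs only when
#' genome sequences are supplied (otherwise the report carries a warning
#' and `NA` IR columns).  Exactly one of `map`, `maf_lines` or `scaffolds`
#' must be given.
#'
#' @param map block map data.frame (or path to a block map TSV).
#' @param maf_lines character vector of MAF alignment lines.
#' @param scaffolds named list of signed block vectors (pre-built
#'   scaffolds, e.g. from a supplementary table); no coordinates, so
#'   inversion lengths and flanks are unavailable.
#' @param genomes optional named character vector of genome sequences.
#' @param min_block_len short-core-block filter threshold in bp
#'   (default 500).
#' @param flank_params list overriding repeat-detection defaults
#'   (`min_len`, `min_id`, `seed_k`, `margin`, `cap`, `long_threshold`).
#' @return list of class `pipeline_report`: `groups`, `pairs`
#'   (one [closest_pairs()] row per group), `flanks` (per-inversion
#'   data.frame or NULL), `prevalence`, `warnings`.
#' @export
run_pipeline <- function(map = NULL, maf_lines = NULL, scaffolds = NULL,
                         genomes = NULL, min_block_len = 500,
                         flank_params = list()) {
  given <- c(!is.null(map), !is.null(maf_lines), !is.null(scaffolds))
  if (sum(given) != 1L)
    stop("supply exactly one of map, maf_lines, scaffolds")
  warnings <- character(0)
  fp <- utils::modifyList(list(min_len = 50, min_id = 0.90, seed_k = 15,
                               margin = 2000, cap = 20000,
                               long_threshold = 10000), flank_params)
  merged_map <- NULL
  if (!is.null(scaffolds)) {
    scs <- scaffolds
  } else {
    if (!is.null(maf_lines)) map <- blocks_from_maf(maf_lines)
    if (is.character(map) && length(map) == 1L) map <- read_block_map(map)
    map <- filter_short_blocks(map, min_len = min_block_len)
    merged <- merge_core_blocks(map)
    merged_map <- merged$map
    scs <- build_scaffolds(merged_map)
  }
  groups <- build_groups(scs)
  pairs <- closest_pairs(groups, merged_map)

  flanks <- NULL
  prevalence <- NULL
  if (!is.null(genomes) && !is.null(merged_map)) {
    registry <- new_repeat_registry()
    fl <- lapply(pairs, function(p)
      flank_inversions(p, groups, scs, genomes, registry,
                       min_len = fp$min_len, min_id = fp$min_id,
                       seed_k = fp$seed_k, margin = fp$margin, cap = fp$cap,
                       long_threshold = fp$long_threshold))
    keep <- vapply(fl, nrow, integer(1)) > 0L
    src <- rep(vapply(pairs, function(p) p$source_group, integer(1)),
               vapply(fl, nrow, integer(1)))
    flanks <- if (any(keep)) cbind(source_group = src, do.call(rbind, fl)) else
      NULL
    prevalence <- summarize_prevalence(flanks, fp$long_threshold)
  } else if (is.null(genomes)) {
    warnings <- c(warnings, "no genome sequences given: repeat-flank stage skipped")
  } else {
    warnings <- c(warnings, "scaffold-only input has no coordinates: repeat-flank stage skipped")
  }
  structure(list(groups = groups, pairs = pairs, flanks = flanks,
                 prevalence = prevalence, map = merged_map,
                 warnings = warnings),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(length(x$groups), "scaffold groups (sizes",
      paste(vapply(x$groups, function(g) length(g$strains), integer(1)),
            collapse = ","), ")\n")
  for (p in x$pairs) print(p)
  if (!is.null(x$prevalence))
    cat(sprintf("IR-flanked: %d/%d inversions (%d/%d long)\n",
                x$prevalence$n_flanked, x$prevalence$n_inversions,
                x$prevalence$n_long_flanked, x$prevalence$n_long))
  for (w in x$warnings) cat("warning:", w, "\n")
  invisible(x)
}

#' Tabulate a pipeline report
#'
#' One row per inversion (plus one row for inversion-free pairs) with the
#' source group, closest group, inversion distance, endpoints, core-genome
#' length in mbp, IR label/presence when available, and the
#' independent-event distance.
#'
#' @param report a `pipeline_report`.
#' @return data.frame.
#' @export
report_table <- function(report) {
  rows <- list()
  for (p in report$pairs) {
    fl <- if (!is.null(report$flanks))
      report$flanks[report$flanks$source_group == p$source_group, , drop = FALSE]
    else NULL
    if (nrow(p$inversions) == 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        sG = p$source_group, cG = p$closest_group, inv_d = p$inv_d,
        start_block = NA_integer_, end_block = NA_integer_,
        l_mbp = NA_real_, IR = NA_character_, presence = NA_integer_,
        R_d = p$r_d, stringsAsFactors = FALSE)
    } else {
      for (k in seq_len(nrow(p$inversions))) {
        lab <- NA_character_; pres <- NA_integer_
        if (!is.null(fl) && k <= nrow(fl) && isTRUE(fl$ir_found[k])) {
          lab <- fl$label[k]; pres <- fl$presence[k]
        }
        rows[[length(rows) + 1L]] <- data.frame(
          sG = p$source_group, cG = p$closest_group, inv_d = p$inv_d,
          start_block = p$inversions$start_block[k],
          end_block = p$inversions$end_block[k],
          l_mbp = p$inversions$length_mbp[k], IR = lab, presence = pres,
          R_d = p$r_d, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Parse a supplementary-style scaffold table
#'
#' Expects a tab-separated table with a header and columns `strain` and
#' `scaffold`, the latter a whitespace-separated list of signed block ids
#' describing the strain's core-genome scaffold.
#'
#' @param path file path (or a character vector of lines).
#' @return named list of signed integer vectors, one per strain.
#' @export
parse_supplementary_scaffolds <- function(path) {
  df <- utils::read.delim(if (length(path) == 1L && file.exists(path)) path
                          else textConnection(path),
                          stringsAsFactors = FALSE)
  if (!all(c("strain", "scaffold") %in% names(df)))
    stop("scaffold table needs columns: strain, scaffold")
  out <- lapply(seq_len(nrow(df)), function(i) {
    toks <- strsplit(trimws(df$scaffold[i]), "[[:space:]]+")[[1]]
    v <- suppressWarnings(as.integer(toks))
    if (anyNA(v)) stop("malformed scaffold for strain ", df$strain[i])
    v
  })
  stats::setNames(out, df$strain)
}
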