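# shared fixtures: generated in code, no data files

random_signed_perm <- function(n) {
  sample(n) * sample(c(-1L, 1L), n, replace = TRUE)
}

# all 2^n * n! signed permutations of 1..n (small n only)
all_signed_perms <- function(n) {
  perm_rows <- function(v) {
    if (length(v) == 1L) return(matrix(v, 1L, 1L))
    do.call(rbind, lapply(seq_along(v), function(i)
      cbind(v[i], perm_rows(v[-i]))))
  }
  perms <- perm_rows(seq_len(n))
  signs <- as.matrix(expand.grid(rep(list(c(1L, -1L)), n)))
  out <- matrix(0L, nrow(perms) * nrow(signs), n)
  r <- 0L
  for (i in seq_len(nrow(perms))) for (j in seq_len(nrow(signs))) {
    r <- r + 1L
    out[r, ] <- perms[i, ] * signs[j, ]
  }
  out
}

# block map for a set of strains given each strain's signed block order;
# blocks laid head to tail with 100 bp gaps, lengths per block id
toy_block_map <- function(orders, block_len = NULL) {
  ids <- sort(unique(abs(unlist(orders))))
  if (is.null(block_len)) block_len <- stats::setNames(rep(1000L, length(ids)), ids)
  out <- do.call(rbind, lapply(names(orders), function(s) {
    ord <- orders[[s]]
    len <- block_len[as.character(abs(ord))]
    end <- cumsum(len + 100L)
    data.frame(strain = s, block = as.character(abs(ord)), contig = "chr",
               start = end - len, end = end,
               strand = ifelse(ord > 0L, "+", "-"), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

scaffold_list <- function(tab) {
  out <- lapply(strsplit(tab$scaffold, " "), as.integer)
  stats::setNames(out, tab$strain)
}
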