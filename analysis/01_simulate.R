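#!/usr/bin/env Rscript
# Generate the reference synthetic dataset: 5 strains derived from a ~200 kb
# ancestor of 40 core blocks, with five IR-mediated long inversions (repeats
# A..E) and one direct-repeat transposition (repeat R, three copies).
# Writes FASTA, block map, scaffolds and the truth log under
# results/synthetic/.

suppressPackageStartupMessages(library(panrearr))

ds <- default_dataset(seed = 0)
emit_dataset(ds, "results/synthetic")

cat("strains:", paste(names(ds$genomes), collapse = ", "), "\n")
cat("genome lengths:", paste(nchar(ds$genomes), collapse = ", "), "bp\n")
cat("planted events:\n")
for (e in ds$truth)
  cat(sprintf("  %-8s %-17s repeat %s, outer extent [%d, %d)\n",
              e$strain, e$kind, e$label, e$outer_start, e$outer_end))
cat("wrote results/synthetic/{genomes.fasta,blockmap.tsv,scaffolds.perm,truth.json}\n")
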