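## Synthetic reconstructions of the two species' scaffold tables.
##
## The original per-strain scaffold tables for the 25 Pseudomonas
## aeruginosa and 31 Escherichia coli complete genomes live in an external
## supplementary spreadsheet that is not redistributed here.  These
## builders create SYNTHETIC stand-ins: scaffolds generated by applying an
## explicit event script (inversions, independent transpositions, inverted
## transpositions, block interchanges, duplicated repeat-borne blocks) to a
## reference scaffold of 69 (P. aeruginosa) or 49 (E. coli) merged core
## blocks, so that the group structure (8 and 9 scaffold groups; sizes
## 13+6 and 21+3 for the two largest) and the per-pair rearrangement
## content match the published strain comparisons.  They are fixtures for
## exercising the pipeline at realistic scale -- not the real tables.

pa_strain_groups <- function() {
  list(
    c("NCGM1984", "B136-33", "YL84", "M18", "LESB58", "SCV20265", "LES431",
      "UCBPP-PA14", "DK2", "MTB-1", "DSM_50071", "Carb01_63", "F22031"),
    c("RP73", "213BR", "PA1", "PA1R", "19BR", "PAO1"),
    "PACS2", "FRD1", "NCGM2.S1", "VRFPA04", "NCGM1900", "PA7")
}

ec_strain_groups <- function() {
  list(
    c("EC4115", "CE10", "C227-11", "K-12_MG1655", "ST2747", "042",
      "O104H4_2011C-3493", "SE11", "SS52", "APEC_O78", "DH1Ec095", "1303",
      "O157H7_Sakai", "55989", "B_REL606", "O83H1_NRG857C", "UMN026",
      "PCN033", "789", "O127H6_E2348-69", "ED1a"),
    c("SE15", "CFT073", "536"),
    "O145H28_RM13514", "SMS-3-5", "P12b", "IAI39", "O103H2_12009",
    "NA114", "O111H-_11128")
}

## adjacent-swap surgeries producing independent event patterns
swap_adjacent <- function(p, i) { p[c(i, i + 1L)] <- p[c(i + 1L, i)]; p }
inv_transposed <- function(p, i) { p[c(i, i + 1L)] <- c(-p[i + 1L], p[i]); p }
inv_transposed2 <- function(p, i) { p[c(i, i + 1L)] <- c(p[i + 1L], -p[i]); p }

pa_scaffolds <- function() {
  g1 <- identity_perm(69)
  g2 <- apply_inversion(g1, 10, 52)
  g3 <- apply_inversion(g1, 10, 62)
  g4 <- apply_inversion(g1, 10, 65)
  ## three nested/overlapping inversions (shared junction at block 6/64)
  g5 <- apply_inversion(g1, 7, 64)
  g5 <- apply_inversion(g5, 7, 7)
  g5 <- apply_inversion(g5, 6, 6)
  ## seven isolated single-block inversions plus two independent
  ## transpositions and one independent inverted transposition, on top of g5
  g6 <- g5
  for (p in c(10L, 13L, 16L, 19L, 22L, 25L, 50L)) g6 <- apply_inversion(g6, p, p)
  g6 <- swap_adjacent(g6, 2L)
  g6 <- swap_adjacent(g6, 30L)
  g6 <- inv_transposed(g6, 66L)
  ## transposition of two merged regions (with conserved junctions)
  g7 <- c(1:17, 47:60, 18:46, 61:69)
  ## two transpositions + two inverted transpositions + repeat-borne
  ## duplicate copies of blocks 2 and 4
  g8 <- swap_adjacent(g1, 25L)
  g8 <- swap_adjacent(g8, 35L)
  g8 <- inv_transposed(g8, 55L)
  g8 <- inv_transposed2(g8, 63L)
  g8 <- append(g8, 2L, after = which(g8 == 30L))
  g8 <- append(g8, -4L, after = which(g8 == 50L))
  list(g1, g2, g3, g4, g5, g6, g7, as.integer(g8))
}

ec_scaffolds <- function() {
  g1 <- identity_perm(49)
  g2 <- apply_inversion(g1, 24, 24)
  g3 <- apply_inversion(apply_inversion(g2, 4, 7), 17, 19)
  g4 <- apply_inversion(g1, 11, 27)
  g5 <- apply_inversion(g1, 13, 25)
  ## inverted block interchange of regions 11..13 and 20..27, then four
  ## inversions (two overlapping long ones)
  g6 <- c(1:10, -(27:20), 14:19, -(13:11), 28:49)
  g6 <- apply_inversion(g6, 3, 4)
  g6 <- apply_inversion(g6, 5, 5)
  g6 <- apply_inversion(g6, 29, 38)
  g6 <- apply_inversion(g6, 37, 45)
  ## three stacked inversions sharing a junction
  g7 <- apply_inversion(g1, 35, 43)
  g7 <- apply_inversion(g7, 35, 42)
  g7 <- apply_inversion(g7, 35, 41)
  ## six independent transpositions + four inversions + six extra copies
  ## of block 45 (the retained copy sits next to -46)
  g8 <- g1
  for (i in c(3L, 7L, 15L, 21L, 31L)) g8 <- swap_adjacent(g8, i)
  g8 <- swap_adjacent(g8, 48L)
  g8 <- apply_inversion(g8, 10, 12)
  g8 <- apply_inversion(g8, 24, 26)
  g8 <- apply_inversion(g8, 28, 28)
  g8 <- apply_inversion(g8, 44, 46)
  for (v in c(5L, 13L, 19L, 29L, 33L, 38L))
    g8 <- append(g8, -45L, after = which(g8 == v))
  ## inverted transposition of block 15 with region 16..18, plus an
  ## inversion of block 48
  g9 <- c(1:14, 16:18, -15L, 19:49)
  g9 <- apply_inversion(g9, 48, 48)
  list(g1, g2, g3, g4, g5, g6, g7, as.integer(g8), g9)
}

#' Synthetic per-strain scaffold tables for the two studied species
#'
#' Returns a strain-by-strain scaffold table emulating the core-genome
#' scaffold structure of 25 *Pseudomonas aeruginosa* strains (8 scaffold
#' groups over 69 merged blocks) or 31 *Escherichia coli* strains (9
#' groups over 49 merged blocks).  The scaffolds are synthetic: they are
#' generated by an explicit rearrangement script against the reference
#' scaffold (see the package source for the construction), designed so
#' that group sizes, closest-pair inversion distances and independent
#' event counts reproduce the published comparison of these strains.  Use
#' [parse_supplementary_scaffolds()] to read the same table back from a
#' TSV file.
#'
#' @param species `"paeruginosa"` or `"ecoli"`.
#' @return data.frame with columns `strain` and `scaffold`
#'   (space-separated signed block ids).
#' @export
synthetic_scaffold_table <- function(species = c("paeruginosa", "ecoli")) {
  species <- match.arg(species)
  memb <- if (species == "paeruginosa") pa_strain_groups() else ec_strain_groups()
  scafs <- if (species == "paeruginosa") pa_scaffolds() else ec_scaffolds()
  rows <- list()
  for (g in seq_along(memb)) {
    for (s in memb[[g]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        strain = s, scaffold = paste(scafs[[g]], collapse = " "),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
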