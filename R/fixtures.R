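#' Bundled synthetic assay designs
#'
#' Synthetic stand-ins for the two ABC drop-off assays used throughout the
#' examples and tests: a CRLF2-like amplicon in the X/Y pseudoautosomal
#' region with three CpG sites covered by FAM, TAMRA and Cy5 drop-off
#' probes plus a HEX (SUN) reference probe, and a BCL2-like amplicon with
#' two CpG sites covered by FAM and Cy5 drop-off probes. Sequences and
#' coordinates are synthetic constructions with the same CpG layout an
#' ABC assay targets; they are not genome sequence.
#'
#' @return `crlf2_panel()` / `bcl2_panel()`: a [probe_panel].
#'   `crlf2_amplicon()` / `bcl2_amplicon()`: an [amplicon_ref].
#' @examples
#' panel <- crlf2_panel()
#' amp <- crlf2_amplicon()
#' amp$cpg  # local 0-based CpG positions
#' @name fixtures
NULL

# synthetic 180 bp amplicon; CG dinucleotides only at local 58, 74, 118
CRLF2_SYNTH_SEQ <- paste0(
  "ATTTATGCTTGAAATTGCTTTTGATGTTTTAGACTATAGGTATTAGATTTCTTAGATACGAAGGAGGT",
  "AGTAATCGATATTGATGTAGGTCCTTCTCATTGCTTGATAAGAACTTTGACGTTACTTAATGATAGTT",
  "GAACCAACCATGCTAGCATACTGATTGTTCAGTTGACAGAAAGT")

# synthetic 160 bp amplicon; CG dinucleotides only at local 50, 95
BCL2_SYNTH_SEQ <- paste0(
  "CTGTTCCAGCTCTAAAGACCATTCTTAGGATGTGTATAATTAAGGATCTACGTGTTTGTCTCACAAAT",
  "TGGTAGTTACATGAATTATGTAGGTTACGTGTCTAAGGTAATGATTCCTACACTGATAATTGCTCTGA",
  "ATTTATTAAATTGCAAGGTATCTC")

CRLF2_SYNTH_START <- 1187500L  # synthetic PAR1 anchor
BCL2_SYNTH_START <- 63318000L  # synthetic chr18 anchor

#' @rdname fixtures
#' @export
crlf2_panel <- function() {
  s <- CRLF2_SYNTH_START
  probe_panel(data.frame(
    name = c("CRLF2_FAM", "CRLF2_TAMRA", "CRLF2_Cy5", "CRLF2_REF"),
    dye = c("FAM", "TAMRA", "Cy5", "HEX"),
    role = c("dropoff", "dropoff", "dropoff", "reference"),
    chrom = "chrX",
    start = s + c(50L, 68L, 110L, 140L),
    end = s + c(68L, 88L, 130L, 165L),
    cpg = I(list(s + 58L, s + 74L, s + 118L, integer(0)))
  ), name = "CRLF2_ABC_synthetic")
}

#' @rdname fixtures
#' @export
bcl2_panel <- function() {
  s <- BCL2_SYNTH_START
  probe_panel(data.frame(
    name = c("BCL2_FAM", "BCL2_Cy5", "BCL2_REF"),
    dye = c("FAM", "Cy5", "HEX"),
    role = c("dropoff", "dropoff", "reference"),
    chrom = "chr18",
    start = s + c(42L, 87L, 125L),
    end = s + c(62L, 107L, 150L),
    cpg = I(list(s + 50L, s + 95L, integer(0)))
  ), name = "BCL2_ABC_synthetic")
}

#' @rdname fixtures
#' @export
crlf2_amplicon <- function() {
  amplicon_ref("CRLF2_ABC_synthetic", "chrX", CRLF2_SYNTH_START,
               CRLF2_SYNTH_SEQ)
}

#' @rdname fixtures
#' @export
bcl2_amplicon <- function() {
  amplicon_ref("BCL2_ABC_synthetic", "chr18", BCL2_SYNTH_START,
               BCL2_SYNTH_SEQ)
}
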