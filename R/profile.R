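#' Scan a sequence for AID-relevant motifs
#'
#' Finds CpG dinucleotides and the degenerate AID deamination context
#' motifs RCG, WRC and WGCW (IUPAC R = A/G, W = A/T). With
#' `both_strands = TRUE` (default), matches of the reverse complement are
#' also reported, projected onto forward-strand coordinates and
#' de-duplicated. `N` bases never match.
#'
#' @param sequence A/C/G/T/N string.
#' @param motif One of `"CpG"`, `"RCG"`, `"WRC"`, `"WGCW"`.
#' @param both_strands Scan both strands (default `TRUE`; CpG is its own
#'   reverse complement, so the flag does not change the CpG set).
#' @return Sorted integer vector of 0-based match start positions.
#' @examples
#' scan_motifs("CACAATGGGCGTATCA", "CpG")  # 9
#' @export
scan_motifs <- function(sequence, motif = c("CpG", "RCG", "WRC", "WGCW"),
                        both_strands = TRUE) {
  motif <- match.arg(motif)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) return(integer(0))
  if (!grepl("^[ACGTN]*$", sequence))
    stop("sequence must be over the alphabet A/C/G/T/N")
  pat <- c(CpG = "CG", RCG = "RCG", WRC = "WRC", WGCW = "WGCW")[[motif]]
  subj <- Biostrings::DNAString(sequence)
  hit <- function(p)
    # pattern ambiguities expand per IUPAC; subject letters are literal,
    # so N in the subject never matches
    Biostrings::start(Biostrings::matchPattern(
      Biostrings::DNAString(p), subj,
      fixed = c(pattern = FALSE, subject = TRUE))) - 1L
  pos <- hit(pat)
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(pat)))
    pos <- union(pos, hit(rc))
  }
  sort(unique(as.integer(pos)))
}

#' Per-position indel profile from amplicon alignments
#'
#' Parses SAM alignments against a single amplicon reference and counts,
#' at every reference position, the number of reads whose deletion covers
#' the position, the number of insertion events assigned to the position
#' (an insertion between reference positions p-1 and p is assigned to p),
#' and the read depth (the read's reference footprint, which spans
#' deletions). Substitutions are ignored. Unmapped, secondary and
#' supplementary records are skipped; records whose CIGAR footprint
#' extends beyond the reference are rejected; both are counted in the
#' returned log.
#'
#' @param sam Path to a SAM file aligned to `ref`.
#' @param ref An [amplicon_ref] (its `name` must match the SAM reference).
#' @return An `indel_profile`: `profile` data.frame (`pos` local 0-based,
#'   `depth`, `del_count`, `ins_count`, `del_freq`, `ins_freq`),
#'   `n_reads` (records used), and `skipped` (named counts).
#' @examples
#' amp <- crlf2_amplicon()
#' em <- edit_model(p_edit = 0.3, hotspot_centers = amp$cpg)
#' sim <- simulate_reads(amp, 500, em, seed = 1, out_dir = tempdir())
#' prof <- parse_alignments(sim$sam, amp)
#' head(subset(prof$profile, del_count > 0))
#' @export
parse_alignments <- function(sam, ref) {
  stopifnot(file.exists(sam), inherits(ref, "amplicon_ref"))
  L <- nchar(ref$seq)

  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  total <- Rsamtools::countBam(bam)$records
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  # out-of-bound footprints are detected and reported below
  ga <- suppressWarnings(GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(flag = flag)))
  n_filtered <- total - length(ga)

  if (length(ga) > 0 &&
      !all(as.character(GenomicAlignments::seqnames(ga)) == ref$name))
    stop("SAM reference name(s) do not match amplicon '", ref$name, "'")

  # reject records whose reference footprint escapes the amplicon
  bad <- GenomicAlignments::start(ga) < 1L | GenomicAlignments::end(ga) > L
  n_bad <- sum(bad)
  if (n_bad > 0L) {
    warning(n_bad, " record(s) with CIGAR footprint outside the ",
            "reference were rejected")
    ga <- ga[!bad]
  }

  cig <- GenomicAlignments::cigar(ga)
  pos <- GenomicAlignments::start(ga)

  cover_counts <- function(ir) {
    # per-position event coverage over local 1-based 1..L
    cv <- IRanges::coverage(ir, width = L)
    as.integer(cv)
  }
  depth <- cover_counts(IRanges::IRanges(pos, GenomicAlignments::end(ga)))

  del_ir <- unlist(GenomicAlignments::cigarRangesAlongReferenceSpace(
    cig, pos = pos, ops = "D"), use.names = FALSE)
  del <- cover_counts(del_ir)

  ins_ir <- unlist(GenomicAlignments::cigarRangesAlongReferenceSpace(
    cig, pos = pos, ops = "I"), use.names = FALSE)
  # zero-width range starting at 1-based q marks an insertion between
  # reference positions q-2 and q-1 (0-based); assign to 0-based q-1
  ins_pos0 <- IRanges::start(ins_ir) - 1L
  ins_pos0 <- ins_pos0[ins_pos0 >= 0L & ins_pos0 < L]
  ins <- tabulate(ins_pos0 + 1L, L)

  prof <- data.frame(pos = 0:(L - 1L), depth = depth,
                     del_count = del, ins_count = ins)
  prof$del_freq <- ifelse(prof$depth > 0, prof$del_count / prof$depth, 0)
  prof$ins_freq <- ifelse(prof$depth > 0, prof$ins_count / prof$depth, 0)

  structure(list(profile = prof, n_reads = length(ga),
                 skipped = c(filtered = n_filtered, rejected = n_bad)),
            class = "indel_profile")
}

#' @export
print.indel_profile <- function(x, ...) {
  cat(sprintf("<indel_profile> %d reads over %d positions (%d del, %d ins events at peak)\n",
              x$n_reads, nrow(x$profile), max(x$profile$del_count),
              max(x$profile$ins_count)))
  invisible(x)
}

#' Indel-to-CpG proximity enrichment
#'
#' Tests whether indel events concentrate near CpG sites. The observed
#' statistic is the fraction of indel events (per-position deletion
#' coverage plus insertion events) lying within `window` bp of any CpG
#' dinucleotide; the null re-places the same number of events over
#' covered positions with probability proportional to depth, giving a
#' fold enrichment (observed / mean null) and a permutation p-value
#' `(1 + #(null >= obs)) / (n_perm + 1)`.
#'
#' @param profile An [parse_alignments] result.
#' @param cpg_positions Local 0-based CpG start positions.
#' @param window Proximity window in bp (default 8). A position is near a
#'   CpG when its distance to either base of the dinucleotide is at most
#'   `window`; distance 0 means directly at the CpG.
#' @param n_perm Number of null replicates (default 10000).
#' @param seed Seed for the null.
#' @return An `enrichment_result` with `observed_fraction`, `fold`,
#'   `p_value`, `n_events`, `n_perm`, `seed`, `window` and `evaluable`.
#'   With zero events or zero CpGs the result is flagged
#'   `evaluable = FALSE` rather than an error.
#' @export
proximity_enrichment <- function(profile, cpg_positions, window = 8L,
                                 n_perm = 10000L, seed = 1L) {
  stopifnot(inherits(profile, "indel_profile"), window >= 0, n_perm >= 1)
  prof <- profile$profile
  events <- prof$del_count + prof$ins_count
  n_events <- sum(events)
  if (n_events == 0L || length(cpg_positions) == 0L) {
    return(structure(list(observed_fraction = NA_real_, fold = NA_real_,
                          p_value = NA_real_, n_events = n_events,
                          n_perm = n_perm, seed = seed, window = window,
                          evaluable = FALSE),
                     class = "enrichment_result"))
  }
  # near = within `window` of either base of a CpG dinucleotide
  near <- rep(FALSE, nrow(prof))
  for (c0 in cpg_positions) {
    lo <- max(c0 - window, 0L)
    hi <- min(c0 + 1L + window, nrow(prof) - 1L)
    near[(lo:hi) + 1L] <- TRUE
  }
  obs <- sum(events[near]) / n_events

  w <- prof$depth
  if (sum(w) == 0) stop("profile has zero depth everywhere")
  null_stats <- withr::with_seed(seed, {
    draws <- stats::rmultinom(n_perm, n_events, w / sum(w))
    colSums(draws[near, , drop = FALSE]) / n_events
  })
  structure(list(observed_fraction = obs,
                 fold = obs / mean(null_stats),
                 p_value = (1 + sum(null_stats >= obs)) / (n_perm + 1),
                 n_events = n_events, n_perm = n_perm, seed = seed,
                 window = window, evaluable = TRUE),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  if (!x$evaluable) {
    cat("<enrichment_result> not evaluable (no events or no CpGs)\n")
  } else {
    cat(sprintf(
      "<enrichment_result> %.1f%% of %d events within %d bp of a CpG; fold %.2f, p = %.3g\n",
      100 * x$observed_fraction, x$n_events, x$window, x$fold, x$p_value))
  }
  invisible(x)
}

#' Predicted probe drop-off from reads
#'
#' The sequence-level analog of the dPCR drop-off readout: for each probe
#' interval, the fraction of reads carrying at least one indel whose
#' reference footprint overlaps the interval (an insertion at position p
#' overlaps [p-1, p+1) for this purpose), among reads that fully span the
#' interval.
#'
#' @param sam Path to a SAM file aligned to `ref`.
#' @param probes data.frame with `name`, `start`, `end` (genomic 0-based
#'   half-open, within the amplicon span), or a [probe_panel].
#' @param ref An [amplicon_ref].
#' @return data.frame with per-probe `n_spanning`, `n_dropoff`,
#'   `fraction`.
#' @export
probe_window_dropoff <- function(sam, probes, ref) {
  stopifnot(inherits(ref, "amplicon_ref"))
  if (inherits(probes, "probe_panel")) probes <- probes$probes
  stopifnot(all(c("name", "start", "end") %in% names(probes)))
  if (any(probes$start < ref$start | probes$end > ref$end))
    stop("probe interval(s) outside the amplicon span [",
         ref$start, ", ", ref$end, ")")
  L <- nchar(ref$seq)

  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  # out-of-bound footprints are detected and reported below
  ga <- suppressWarnings(GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(flag = flag)))
  ga <- ga[GenomicAlignments::start(ga) >= 1L &
             GenomicAlignments::end(ga) <= L]
  cig <- GenomicAlignments::cigar(ga)
  pos <- GenomicAlignments::start(ga)

  del_l <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cig, pos = pos, ops = "D")
  ins_l <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cig, pos = pos, ops = "I")
  del_un <- unlist(del_l, use.names = FALSE)
  del_read <- rep(seq_along(ga), lengths(del_l))
  ins_un <- unlist(ins_l, use.names = FALSE)
  ins_read <- rep(seq_along(ga), lengths(ins_l))
  # insertion assigned to 0-based p (zero-width range at 1-based p+1)
  # overlaps [p-1, p+1) == 1-based [p, p+1]
  ins_w <- IRanges::IRanges(pmax(IRanges::start(ins_un) - 1L, 1L),
                            IRanges::start(ins_un))

  do.call(rbind, lapply(seq_len(nrow(probes)), function(i) {
    # probe interval in local 1-based coordinates
    s1 <- probes$start[i] - ref$start + 1L
    e1 <- probes$end[i] - ref$start
    span <- GenomicAlignments::start(ga) <= s1 &
      GenomicAlignments::end(ga) >= e1
    probe_ir <- IRanges::IRanges(s1, e1)
    hit_reads <- union(del_read[IRanges::overlapsAny(del_un, probe_ir)],
                       ins_read[IRanges::overlapsAny(ins_w, probe_ir)])
    n_hit <- sum(span[hit_reads])
    data.frame(probe = probes$name[i], n_spanning = sum(span),
               n_dropoff = n_hit,
               fraction = if (sum(span) > 0) n_hit / sum(span) else NA_real_)
  }))
}
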