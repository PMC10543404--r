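#' Amplicon reference
#'
#' An amplicon sequence anchored to a genomic interval (0-based
#' half-open), with its CpG dinucleotide positions pre-scanned.
#'
#' @param name Amplicon/sequence name (used as the SAM reference name).
#' @param chrom Chromosome label.
#' @param start 0-based genomic start of the amplicon.
#' @param seq Amplicon sequence (A/C/G/T/N string).
#' @param abc_intervals Optional data.frame of annotated break-cluster
#'   sub-intervals (`start`, `end`, genomic, 0-based half-open).
#' @return An `amplicon_ref` with fields `name`, `chrom`, `start`, `end`,
#'   `seq`, `cpg` (local 0-based CpG positions) and `abc_intervals`.
#' @examples
#' amp <- crlf2_amplicon()
#' substr(amp$seq, amp$cpg[1] + 1, amp$cpg[1] + 2)  # "CG"
#' @export
amplicon_ref <- function(name, chrom, start, seq, abc_intervals = NULL) {
  seq <- toupper(seq)
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) >= 1L,
            grepl("^[ACGTN]+$", seq))
  structure(list(name = name, chrom = chrom, start = as.integer(start),
                 end = as.integer(start) + nchar(seq), seq = seq,
                 cpg = scan_motifs(seq, "CpG"),
                 abc_intervals = abc_intervals),
            class = "amplicon_ref")
}

#' Indel model for the read simulator
#'
#' Each read is independently edited with probability `p_edit`. The edit
#' position is a hotspot center (a CpG site, sampled by weight) plus a
#' discretized Gaussian offset, reproducing the focal (small `kernel_sd`)
#' versus spread (large `kernel_sd`) indel regimes seen around break
#' clusters. The edit is a deletion with probability `deletion_prob`
#' (deletions dominate insertions after end-joining repair), otherwise an
#' insertion; lengths are `1 + Geometric`.
#'
#' @param p_edit Per-read edit probability in [0, 1].
#' @param hotspot_centers Local 0-based reference positions of the
#'   hotspots (typically CpG sites).
#' @param hotspot_weights Sampling weights (normalized internally).
#' @param kernel_sd Gaussian positional spread around the hotspot, bp.
#' @param deletion_prob Probability an edit is a deletion (default 0.8).
#' @param del_length_geom_p,ins_length_geom_p Geometric success
#'   probabilities; mean length is `1 + (1 - p) / p`.
#' @return An `edit_model`.
#' @export
edit_model <- function(p_edit = 0.1, hotspot_centers,
                       hotspot_weights = NULL, kernel_sd = 3,
                       deletion_prob = 0.8, del_length_geom_p = 0.5,
                       ins_length_geom_p = 0.5) {
  stopifnot(p_edit >= 0, p_edit <= 1, length(hotspot_centers) >= 1L,
            kernel_sd >= 0, deletion_prob >= 0, deletion_prob <= 1,
            del_length_geom_p > 0, del_length_geom_p <= 1,
            ins_length_geom_p > 0, ins_length_geom_p <= 1)
  if (is.null(hotspot_weights))
    hotspot_weights <- rep(1, length(hotspot_centers))
  stopifnot(length(hotspot_weights) == length(hotspot_centers),
            all(hotspot_weights >= 0), sum(hotspot_weights) > 0)
  structure(list(p_edit = p_edit,
                 hotspot_centers = as.integer(hotspot_centers),
                 hotspot_weights = hotspot_weights / sum(hotspot_weights),
                 kernel_sd = kernel_sd, deletion_prob = deletion_prob,
                 del_length_geom_p = del_length_geom_p,
                 ins_length_geom_p = ins_length_geom_p),
            class = "edit_model")
}

#' Simulate amplicon reads with CpG-focused indels
#'
#' Emits full-length amplicon reads, a fraction of which carry a single
#' indel placed by the [edit_model], as FASTQ (constant Q30) plus SAM
#' v1.6 alignments whose CIGAR strings encode the introduced edits
#' exactly, together with a per-read ground-truth table.
#'
#' Edits are re-drawn (up to 20 attempts) when the kernel places them
#' outside the editable span (positions 1 .. L-2, so every indel is
#' flanked by aligned bases); a read whose edit cannot be placed is
#' emitted unedited and counted in `n_skipped` with a warning.
#'
#' @param ref An [amplicon_ref].
#' @param n_reads Number of reads (>= 0).
#' @param model An [edit_model].
#' @param seed Integer seed.
#' @param out_dir Directory for the output files (created if needed).
#' @param basename File stem for `<stem>.fastq`, `<stem>.sam`,
#'   `<stem>.truth.json`.
#' @return List with `fastq`, `sam`, `truth_json` (paths), `truth`
#'   (data.frame: `qname`, `pos` local 0-based, `type` "del"/"ins",
#'   `length`, `inserted`; one row per edit), and `n_skipped`.
#' @examples
#' amp <- crlf2_amplicon()
#' em <- edit_model(p_edit = 0.2, hotspot_centers = amp$cpg)
#' sim <- simulate_reads(amp, 100, em, seed = 1, out_dir = tempdir())
#' head(sim$truth)
#' @export
simulate_reads <- function(ref, n_reads, model, seed,
                           out_dir = tempdir(), basename = "reads") {
  stopifnot(inherits(ref, "amplicon_ref"), inherits(model, "edit_model"),
            n_reads >= 0)
  if (missing(seed)) stop("an explicit seed is required")
  L <- nchar(ref$seq)
  if (any(model$hotspot_centers < 0L | model$hotspot_centers >= L))
    stop("hotspot centers must lie within the amplicon [0, ", L, ")")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  recs <- withr::with_seed(seed, {
    edited <- stats::runif(n_reads) < model$p_edit
    lapply(seq_len(n_reads), function(i) {
      qname <- sprintf("%s_read%06d", ref$name, i)
      if (!edited[i])
        return(list(qname = qname, seq = ref$seq,
                    cigar = paste0(L, "M"), edit = NULL))
      for (try in seq_len(20L)) {
        ctr <- sample.int(length(model$hotspot_centers), 1L,
                          prob = model$hotspot_weights)
        pos <- model$hotspot_centers[ctr] +
          as.integer(round(stats::rnorm(1, 0, model$kernel_sd)))
        is_del <- stats::runif(1) < model$deletion_prob
        len <- 1L + stats::rgeom(1, if (is_del) model$del_length_geom_p
                                 else model$ins_length_geom_p)
        # keep the edit flanked by matches: pos in [1, L-2]; deletions
        # must also end before the final base
        if (pos < 1L || pos > L - 2L) next
        if (is_del && pos + len > L - 1L) next
        if (is_del) {
          seq <- paste0(substr(ref$seq, 1L, pos),
                        substr(ref$seq, pos + len + 1L, L))
          cig <- paste0(pos, "M", len, "D", L - pos - len, "M")
          return(list(qname = qname, seq = seq, cigar = cig,
                      edit = data.frame(qname = qname, pos = pos,
                                        type = "del", length = len,
                                        inserted = "")))
        } else {
          ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                       collapse = "")
          seq <- paste0(substr(ref$seq, 1L, pos), ins,
                        substr(ref$seq, pos + 1L, L))
          cig <- paste0(pos, "M", len, "I", L - pos, "M")
          return(list(qname = qname, seq = seq, cigar = cig,
                      edit = data.frame(qname = qname, pos = pos,
                                        type = "ins", length = len,
                                        inserted = ins)))
        }
      }
      list(qname = qname, seq = ref$seq, cigar = paste0(L, "M"),
           edit = NULL, skipped = TRUE)
    })
  })

  n_skipped <- sum(vapply(recs, function(r) isTRUE(r$skipped), logical(1)))
  if (n_skipped > 0L)
    warning(n_skipped, " edit(s) could not be placed within the amplicon ",
            "after 20 attempts; those reads were emitted unedited")

  truth <- do.call(rbind, lapply(recs, `[[`, "edit"))
  if (is.null(truth))
    truth <- data.frame(qname = character(), pos = integer(),
                        type = character(), length = integer(),
                        inserted = character())

  fq_path <- file.path(out_dir, paste0(basename, ".fastq"))
  sam_path <- file.path(out_dir, paste0(basename, ".sam"))
  truth_path <- file.path(out_dir, paste0(basename, ".truth.json"))

  fq <- unlist(lapply(recs, function(r)
    c(paste0("@", r$qname), r$seq, "+",
      strrep("?", nchar(r$seq)))))  # '?' = Phred+33 Q30
  writeLines(if (is.null(fq)) character() else fq, fq_path)

  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", ref$name, L))
  body <- vapply(recs, function(r)
    paste(r$qname, 0L, ref$name, 1L, 60L, r$cigar, "*", 0L, 0L,
          r$seq, strrep("?", nchar(r$seq)), sep = "\t"),
    character(1))
  writeLines(c(header, body), sam_path)

  jsonlite::write_json(list(n_reads = n_reads, n_skipped = n_skipped,
                            edits = truth),
                       truth_path, auto_unbox = TRUE, digits = NA)

  list(fastq = fq_path, sam = sam_path, truth_json = truth_path,
       truth = truth, n_reads = n_reads, n_skipped = n_skipped)
}
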