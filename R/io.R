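#' Read and write partition-level fluorescence tables
#'
#' The on-disk contract is a CSV with columns `chip_id`,
#' `partition_index` and one intensity column per dye (`FAM`, `TAMRA`,
#' `Cy5`, `HEX`; a `SUN` column is accepted and renamed to `HEX`).
#' Unknown columns are preserved but ignored downstream.
#'
#' @param path CSV file path.
#' @param required_dyes Dye columns that must be present (default: at
#'   least one panel dye).
#' @return A `partition_table` data.frame.
#' @export
read_partition_csv <- function(path, required_dyes = NULL) {
  stopifnot(file.exists(path))
  tab <- utils::read.csv(path, check.names = FALSE)
  if ("SUN" %in% names(tab) && !("HEX" %in% names(tab)))
    names(tab)[names(tab) == "SUN"] <- "HEX"
  dyes <- intersect(PANEL_DYES, names(tab))
  if (is.null(required_dyes)) {
    if (length(dyes) == 0L)
      stop("'", path, "': no dye columns found (expected any of ",
           paste(PANEL_DYES, collapse = "/"), ")")
  } else {
    required_dyes <- normalize_dye(required_dyes)
    missing <- setdiff(required_dyes, names(tab))
    if (length(missing) > 0L)
      stop("'", path, "': missing dye column(s): ",
           paste(missing, collapse = ", "))
    dyes <- required_dyes
  }
  for (d in dyes) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(tab[[d]]))))
    if (length(bad) > 0L)
      stop("'", path, "': non-numeric ", d, " intensity at data row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "))
    tab[[d]] <- as.numeric(tab[[d]])
  }
  if (!"partition_index" %in% names(tab))
    tab$partition_index <- seq_len(nrow(tab)) - 1L
  if (!"chip_id" %in% names(tab)) tab$chip_id <- "chip1"
  class(tab) <- c("partition_table", "data.frame")
  tab
}

#' @rdname read_partition_csv
#' @param table A `partition_table`.
#' @export
write_partition_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a probe panel from JSON
#'
#' Expected layout: `{"name": ..., "probes": [{"name", "dye", "role",
#' "chrom", "start", "end", "cpg": [...]}, ...]}` with 0-based half-open
#' intervals. Validation (single reference probe, unique dyes, known dye
#' names) happens in [probe_panel]. When an `amplicon` entry with
#' `chrom`/`start`/`end` is present, probe intervals are additionally
#' checked to lie within it.
#'
#' @param path JSON file path.
#' @return A [probe_panel].
#' @export
read_panel <- function(path) {
  stopifnot(file.exists(path))
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(js$probes)) stop("'", path, "': no 'probes' entry")
  probes <- as.data.frame(js$probes)
  if (!is.null(probes$cpg)) probes$cpg <- I(as.list(probes$cpg))
  panel <- probe_panel(probes, name = js$name %||% basename(path))
  if (!is.null(js$amplicon)) {
    amp <- js$amplicon
    bad <- panel$probes$chrom != amp$chrom |
      panel$probes$start < amp$start | panel$probes$end > amp$end
    if (any(bad))
      stop("'", path, "': probe(s) outside the amplicon span: ",
           paste(panel$probes$name[bad], collapse = ", "))
  }
  panel
}

#' @rdname read_panel
#' @param panel A [probe_panel].
#' @param amplicon Optional [amplicon_ref] recorded alongside the probes.
#' @export
write_panel <- function(panel, path, amplicon = NULL) {
  probes <- panel$probes
  out <- list(name = panel$name,
              probes = lapply(seq_len(nrow(probes)), function(i)
                list(name = probes$name[i], dye = probes$dye[i],
                     role = probes$role[i], chrom = probes$chrom[i],
                     start = probes$start[i], end = probes$end[i],
                     cpg = as.integer(probes$cpg[[i]]))))
  if (!is.null(amplicon))
    out$amplicon <- list(chrom = amplicon$chrom, start = amplicon$start,
                         end = amplicon$end)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an amplicon reference from FASTA (+ optional BED annotation)
#'
#' @param fasta FASTA file with a single amplicon record.
#' @param chrom,start Genomic anchor of the amplicon (0-based start);
#'   default anchors the amplicon at 0 on a contig named after the
#'   record.
#' @return An [amplicon_ref].
#' @export
read_amplicon_fasta <- function(fasta, chrom = NULL, start = 0L) {
  ss <- Biostrings::readDNAStringSet(fasta)
  if (length(ss) != 1L)
    stop("'", fasta, "': expected exactly one amplicon record, found ",
         length(ss))
  nm <- sub("\\s.*$", "", names(ss)[1])
  amplicon_ref(nm, chrom %||% nm, start, as.character(ss[[1]]))
}

#' Read probe intervals from BED
#'
#' Minimal BED3+ reader (0-based half-open, as BED is defined); the
#' optional 4th column supplies probe names.
#'
#' @param path BED file path.
#' @return data.frame with `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L) stop("'", path, "': no BED records")
  fields <- strsplit(lines, "\t")
  if (any(lengths(fields) < 3L))
    stop("'", path, "': BED records need at least 3 fields")
  data.frame(
    chrom = vapply(fields, `[[`, character(1), 1L),
    start = as.integer(vapply(fields, `[[`, character(1), 2L)),
    end = as.integer(vapply(fields, `[[`, character(1), 3L)),
    name = vapply(fields, function(f)
      if (length(f) >= 4L) f[[4]] else NA_character_, character(1)))
}

#' @rdname read_bed
#' @param intervals data.frame with `chrom`, `start`, `end` and
#'   optionally `name`.
#' @export
write_bed <- function(intervals, path) {
  cols <- cbind(intervals$chrom, intervals$start, intervals$end)
  if (!is.null(intervals$name)) cols <- cbind(cols, intervals$name)
  writeLines(apply(cols, 1L, paste, collapse = "\t"), path)
  invisible(path)
}

#' @rdname read_amplicon_fasta
#' @param ref An [amplicon_ref].
#' @param path Output FASTA path.
#' @export
write_amplicon_fasta <- function(ref, path) {
  ss <- Biostrings::DNAStringSet(ref$seq)
  names(ss) <- ref$name
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
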