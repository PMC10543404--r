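PANEL_DYES <- c("FAM", "TAMRA", "Cy5", "HEX")

normalize_dye <- function(dye) {
  dye <- as.character(dye)
  dye[toupper(dye) == "SUN"] <- "HEX"  # SUN and HEX are the same channel
  idx <- match(toupper(dye), toupper(PANEL_DYES))
  if (anyNA(idx))
    stop("unknown dye(s): ", paste(dye[is.na(idx)], collapse = ", "),
         " (panel dyes are ", paste(PANEL_DYES, collapse = "/"), ")")
  PANEL_DYES[idx]
}

#' Probe panel for a drop-off assay
#'
#' The assay design for one amplicon: a single reference probe that binds
#' where no breaks map (and so detects every amplicon), plus one or more
#' drop-off probes placed over mutation-prone CpG sites, each read on its
#' own dye channel.
#'
#' @param probes A data.frame with columns `name`, `dye`
#'   (FAM/TAMRA/Cy5/HEX; "SUN" is accepted as an alias for HEX), `role`
#'   (`"reference"` or `"dropoff"`), `chrom`, `start`, `end` (0-based
#'   half-open genomic interval) and optionally a list column `cpg` of
#'   targeted CpG genomic positions.
#' @param name Panel label.
#' @return An object of class `probe_panel`.
#' @examples
#' crlf2_panel()
#' @export
probe_panel <- function(probes, name = "panel") {
  stopifnot(is.data.frame(probes),
            all(c("name", "dye", "role", "chrom", "start", "end") %in%
                  names(probes)))
  probes$dye <- normalize_dye(probes$dye)
  probes$role <- match.arg(probes$role, c("reference", "dropoff"),
                           several.ok = TRUE)
  if (anyDuplicated(probes$dye))
    stop("panel dyes must be unique")
  if (sum(probes$role == "reference") != 1L)
    stop("panel must contain exactly one reference probe")
  if (sum(probes$role == "dropoff") < 1L)
    stop("panel must contain at least one drop-off probe")
  if (any(probes$end <= probes$start))
    stop("probe intervals must be non-empty (0-based half-open)")
  if (is.null(probes$cpg)) probes$cpg <- vector("list", nrow(probes))
  structure(list(name = name, probes = probes), class = "probe_panel")
}

#' @export
print.probe_panel <- function(x, ...) {
  cat(sprintf("<probe_panel> %s: %d probes (reference dye %s)\n",
              x$name, nrow(x$probes), reference_dye(x)))
  print(x$probes[, c("name", "dye", "role", "chrom", "start", "end")],
        row.names = FALSE)
  invisible(x)
}

#' @rdname probe_panel
#' @param panel A `probe_panel`.
#' @export
panel_dyes <- function(panel) panel$probes$dye

#' @rdname probe_panel
#' @export
reference_dye <- function(panel)
  panel$probes$dye[panel$probes$role == "reference"]

#' @rdname probe_panel
#' @export
dropoff_probes <- function(panel)
  panel$probes[panel$probes$role == "dropoff", , drop = FALSE]
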