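#' Set per-channel positivity thresholds
#'
#' Auto mode performs a two-center 1-D k-means partitioning of each
#' channel's intensities and places the threshold midway between the two
#' centers. A channel whose two centers are separated by less than three
#' pooled within-cluster standard deviations is treated as a single
#' cluster: it is called all-negative when its center sits at the chip's
#' baseline level (the lower-cluster centers of the bimodal channels, or
#' the dimmest channel when none is bimodal), and all-positive otherwise.
#' Manual mode passes user thresholds through unchanged.
#'
#' @param table A `partition_table` data.frame (see [simulate_chip] /
#'   [read_partition_csv]).
#' @param method `"auto"` or `"manual"`.
#' @param manual_values Named numeric vector of thresholds, one per dye
#'   column (required for manual mode).
#' @return Named numeric vector of thresholds, one per dye channel.
#' @export
call_thresholds <- function(table, method = c("auto", "manual"),
                            manual_values = NULL) {
  method <- match.arg(method)
  dyes <- intersect(PANEL_DYES, names(table))
  if (length(dyes) == 0L) stop("no dye columns found in partition table")
  x_all <- as.matrix(table[, dyes, drop = FALSE])
  if (!all(is.finite(x_all))) stop("non-finite intensities in partition table")

  if (method == "manual") {
    if (is.null(manual_values) || !all(dyes %in% names(manual_values)))
      stop("manual thresholds must name every dye column: ",
           paste(setdiff(dyes, names(manual_values)), collapse = ", "))
    return(manual_values[dyes])
  }

  if (nrow(table) < 100L)
    stop("auto thresholding needs at least 100 partitions")

  fit1 <- function(x) {
    if (length(unique(x)) < 2L)
      return(list(lo = x[1], hi = x[1], sep = 0, mid = x[1]))
    km <- stats::kmeans(x, centers = 2L, nstart = 3L)
    o <- order(km$centers)
    c_lo <- km$centers[o[1]]; c_hi <- km$centers[o[2]]
    pooled_sd <- sqrt(km$tot.withinss / max(length(x) - 2L, 1L))
    list(lo = c_lo, hi = c_hi, sep = c_hi - c_lo,
         degenerate = (c_hi - c_lo) < 3 * pooled_sd,
         mid = (c_lo + c_hi) / 2)
  }
  fits <- lapply(dyes, function(d) fit1(x_all[, d]))
  names(fits) <- dyes
  bimodal <- !vapply(fits, function(f) isTRUE(f$degenerate) || f$sep == 0,
                     logical(1))

  # chip-level baseline reference used only to resolve degenerate channels
  baseline_ref <- if (any(bimodal)) {
    stats::median(vapply(fits[bimodal], `[[`, numeric(1), "lo"))
  } else {
    min(vapply(fits, `[[`, numeric(1), "mid"))
  }

  thr <- vapply(dyes, function(d) {
    f <- fits[[d]]
    if (bimodal[[d]]) return(f$mid)
    center <- (f$lo + f$hi) / 2
    spread <- stats::sd(x_all[, d])
    if (center <= baseline_ref + 4 * max(spread, 1e-12)) {
      max(x_all[, d])          # strict '>' => all-negative
    } else {
      min(x_all[, d]) - 1      # all-positive
    }
  }, numeric(1))
  names(thr) <- dyes
  thr
}

#' Gate a partition table into boolean calls
#'
#' A partition is called positive on a channel when its intensity
#' strictly exceeds that channel's threshold (ties are negative,
#' conservative for drop-off detection).
#'
#' @param table A `partition_table`.
#' @param thresholds Named numeric vector covering every dye column.
#' @return A `gate_result`: list with `thresholds`, logical `calls`
#'   matrix (partitions x dyes), and `counts` data.frame with per-channel
#'   `n_pos`/`n_neg` (summing to the partition count).
#' @examples
#' panel <- crlf2_panel()
#' sp <- make_editing_species(panel, 336.8, 0.10, "TAMRA")
#' sim <- simulate_chip(panel, chip_spec(), sp, seed = 1)
#' gr <- gate(sim$table, call_thresholds(sim$table))
#' gr$counts
#' @export
gate <- function(table, thresholds) {
  dyes <- intersect(PANEL_DYES, names(table))
  if (!all(dyes %in% names(thresholds)))
    stop("thresholds missing for dye(s): ",
         paste(setdiff(dyes, names(thresholds)), collapse = ", "))
  calls <- vapply(dyes, function(d) table[[d]] > thresholds[[d]],
                  logical(nrow(table)))
  if (nrow(table) == 1L)
    calls <- matrix(calls, nrow = 1L, dimnames = list(NULL, dyes))
  structure(
    list(thresholds = thresholds[dyes],
         calls = calls,
         counts = data.frame(dye = dyes,
                             n_pos = colSums(calls),
                             n_neg = nrow(table) - colSums(calls),
                             row.names = NULL)),
    class = "gate_result")
}

#' @export
print.gate_result <- function(x, ...) {
  cat(sprintf("<gate_result> %d partitions\n", nrow(x$calls)))
  print(cbind(x$counts, threshold = unname(x$thresholds)), row.names = FALSE)
  invisible(x)
}

#' Joint probe-pattern counts
#'
#' Tabulates the 2^k joint positive/negative states over the panel dyes
#' (the clusters of the 2-D scatterplot view), plus per drop-off probe the
#' marginal of interest for the drop-off readout: among reference-positive
#' partitions, how many are negative for that probe.
#'
#' @param gr A [gate_result].
#' @param panel A [probe_panel] whose dyes are all present in the calls.
#' @return A `pattern_counts` object: `patterns` data.frame (one logical
#'   column per dye plus `count`, covering all 2^k states and summing to
#'   the partition count), `dropoff_marginals` data.frame, and `n_total`.
#' @export
pattern_counts <- function(gr, panel) {
  stopifnot(inherits(gr, "gate_result"), inherits(panel, "probe_panel"))
  dyes <- panel_dyes(panel)
  if (!all(dyes %in% colnames(gr$calls)))
    stop("panel dye(s) missing from gated calls: ",
         paste(setdiff(dyes, colnames(gr$calls)), collapse = ", "))
  calls <- gr$calls[, dyes, drop = FALSE]
  k <- length(dyes)
  # encode each partition's joint state as an integer 0..2^k-1
  code <- as.integer(calls %*% 2^(seq_len(k) - 1))
  counts <- tabulate(code + 1L, 2^k)
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), k))
  names(grid) <- dyes
  # expand.grid varies the first factor fastest == our bit encoding
  patterns <- cbind(grid, count = counts)

  ref <- reference_dye(panel)
  dp <- dropoff_probes(panel)
  ref_pos <- calls[, ref]
  marg <- data.frame(
    probe = dp$name, dye = dp$dye,
    n_ref_pos = sum(ref_pos),
    n_ref_pos_probe_neg = vapply(dp$dye, function(d)
      sum(ref_pos & !calls[, d]), integer(1)),
    row.names = NULL)
  structure(list(patterns = patterns, dropoff_marginals = marg,
                 n_total = nrow(calls), dyes = dyes),
            class = "pattern_counts")
}

#' Pool pattern counts across replicate chips
#'
#' Sums joint-pattern and marginal counts over chips run with the same
#' panel and chip geometry, so that few-event baselines can be quantified
#' from the pooled partition counts.
#'
#' @param pcs List of [pattern_counts] objects with identical dye sets.
#' @return A single pooled `pattern_counts`.
#' @export
pool_pattern_counts <- function(pcs) {
  stopifnot(length(pcs) >= 1L,
            all(vapply(pcs, inherits, logical(1), "pattern_counts")))
  dyes <- pcs[[1]]$dyes
  for (pc in pcs) if (!identical(pc$dyes, dyes))
    stop("pattern counts were computed over different dye sets")
  out <- pcs[[1]]
  for (pc in pcs[-1]) {
    out$patterns$count <- out$patterns$count + pc$patterns$count
    out$dropoff_marginals$n_ref_pos <-
      out$dropoff_marginals$n_ref_pos + pc$dropoff_marginals$n_ref_pos
    out$dropoff_marginals$n_ref_pos_probe_neg <-
      out$dropoff_marginals$n_ref_pos_probe_neg +
      pc$dropoff_marginals$n_ref_pos_probe_neg
    out$n_total <- out$n_total + pc$n_total
  }
  out
}
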