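#' Simulate a multiplexed digital PCR chip
#'
#' Loads each allele species onto the chip independently with Poisson
#' statistics: the template count of species *s* in each partition is
#' `Poisson(concentration_s * partition_volume)`. A dye channel is truly
#' positive in a partition iff at least one template of a species whose
#' binding site for that dye is intact is present; fluorescence
#' intensities are then drawn from the noise model conditional on the
#' true state.
#'
#' @param panel A [probe_panel].
#' @param chip A [chip_spec].
#' @param species List of [allele_species]; every binding profile must
#'   cover exactly the panel dyes.
#' @param noise A [noise_model].
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param chip_id Chip label recorded in the partition table.
#'
#' @return A list with components
#'   \describe{
#'     \item{table}{`partition_table` data.frame: `chip_id`,
#'       `partition_index` (0-based) and one intensity column per dye.}
#'     \item{truth}{ground-truth record: per-partition template `counts`
#'       (matrix, partitions x species), per-species `lambda`, the
#'       boolean `true_state` matrix (partitions x dyes), and
#'       `dropoff_fraction`, the true mutant fraction per drop-off probe
#'       (concentration lacking the probe site / concentration carrying
#'       the reference site).}
#'   }
#' @examples
#' panel <- crlf2_panel()
#' sp <- make_editing_species(panel, 336.8, 0.10, "TAMRA")
#' sim <- simulate_chip(panel, chip_spec(), sp, noise_model(), seed = 1)
#' head(sim$table)
#' sim$truth$dropoff_fraction
#' @export
simulate_chip <- function(panel, chip, species, noise = noise_model(),
                          seed, chip_id = "chip1") {
  stopifnot(inherits(panel, "probe_panel"), inherits(chip, "chip_spec"),
            inherits(noise, "noise_model"), is.list(species),
            length(species) >= 1L)
  if (missing(seed)) stop("an explicit seed is required")
  dyes <- panel_dyes(panel)
  for (sp in species) {
    if (!inherits(sp, "allele_species"))
      stop("species must be allele_species objects")
    if (!setequal(names(sp$binding), dyes))
      stop("species '", sp$name, "' binding profile dyes do not match ",
           "the panel (expected ", paste(dyes, collapse = "/"), ")")
    if (!is.finite(sp$concentration) || sp$concentration < 0)
      stop("species '", sp$name, "' has an invalid concentration")
  }

  n <- chip$n_partitions
  lambda <- vapply(species, function(sp) sp$concentration *
                     chip$partition_volume, numeric(1))
  names(lambda) <- vapply(species, `[[`, character(1), "name")
  # binding matrix: species x dyes
  bind <- t(vapply(species, function(sp) sp$binding[dyes],
                   logical(length(dyes))))
  colnames(bind) <- dyes

  withr::with_seed(seed, {
    counts <- vapply(lambda, function(l) stats::rpois(n, l), integer(n))
    if (n == 1L) counts <- matrix(counts, nrow = 1L,
                                  dimnames = list(NULL, names(lambda)))
    true_state <- (counts %*% (bind + 0)) > 0
    colnames(true_state) <- dyes

    par_len <- function(x, i) if (length(x) > 1L) x[[i]] else x
    intensity <- matrix(NA_real_, n, length(dyes),
                        dimnames = list(NULL, dyes))
    for (i in seq_along(dyes)) {
      b_mu <- par_len(noise$baseline_mean, i)
      b_sd <- par_len(noise$baseline_sd, i)
      p_mu <- par_len(noise$positive_mean, i)
      p_sd <- par_len(noise$positive_sd, i)
      pos <- true_state[, i]
      x <- stats::rnorm(n, b_mu, b_sd)
      n_pos <- sum(pos)
      if (n_pos > 0L) {
        mu <- rep(p_mu, n_pos)
        rain <- stats::runif(n_pos) < noise$rain_fraction
        mu[rain] <- (b_mu + p_mu) / 2
        x[pos] <- stats::rnorm(n_pos, mu, p_sd)
      }
      intensity[, i] <- x
    }
  })

  tab <- data.frame(chip_id = chip_id, partition_index = seq_len(n) - 1L,
                    intensity, check.names = FALSE)
  class(tab) <- c("partition_table", "data.frame")

  truth <- list(counts = counts, lambda = lambda, true_state = true_state,
                dropoff_fraction = true_dropoff_fraction(panel, species))
  list(table = tab, truth = truth)
}

# True mutant fraction per drop-off probe implied by a species mix:
# concentration of species carrying the reference site but lacking the
# probe site, over the concentration carrying the reference site.
true_dropoff_fraction <- function(panel, species) {
  ref <- reference_dye(panel)
  dp <- dropoff_probes(panel)
  conc <- vapply(species, `[[`, numeric(1), "concentration")
  ref_ok <- vapply(species, function(sp) sp$binding[[ref]], logical(1))
  denom <- sum(conc[ref_ok])
  out <- vapply(seq_len(nrow(dp)), function(i) {
    hit <- vapply(species, function(sp) !sp$binding[[dp$dye[i]]], logical(1))
    if (denom == 0) return(NA_real_)
    sum(conc[ref_ok & hit]) / denom
  }, numeric(1))
  stats::setNames(out, dp$name)
}
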