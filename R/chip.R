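#' Digital PCR chip geometry
#'
#' Describes one digital PCR run: the number of microchambers the reaction
#' is partitioned into, the reaction volume, and the fraction of that
#' volume actually analyzed. The per-partition volume is derived as
#' `reaction_volume * analyzed_fraction / n_partitions` and drives the
#' Poisson loading of template molecules.
#'
#' @param n_partitions Number of microchambers (default 20480).
#' @param reaction_volume Reaction volume in microliters (default 9).
#' @param analyzed_fraction Fraction of the reaction volume that ends up in
#'   analyzed partitions, in (0, 1]. Defaults to 1 (no dead volume).
#'
#' @return An object of class `chip_spec` with fields `n_partitions`,
#'   `reaction_volume`, `analyzed_fraction` and the derived
#'   `partition_volume` (microliters).
#' @examples
#' chip <- chip_spec()
#' chip$partition_volume * chip$n_partitions  # == reaction volume
#' @export
chip_spec <- function(n_partitions = 20480L, reaction_volume = 9,
                      analyzed_fraction = 1.0) {
  n_partitions <- as.integer(n_partitions)
  stopifnot(length(n_partitions) == 1L, n_partitions >= 1L,
            length(reaction_volume) == 1L, is.finite(reaction_volume),
            reaction_volume > 0,
            length(analyzed_fraction) == 1L, analyzed_fraction > 0,
            analyzed_fraction <= 1)
  structure(
    list(n_partitions = n_partitions,
         reaction_volume = reaction_volume,
         analyzed_fraction = analyzed_fraction,
         partition_volume = reaction_volume * analyzed_fraction / n_partitions),
    class = "chip_spec")
}

#' @export
print.chip_spec <- function(x, ...) {
  cat(sprintf("<chip_spec> %d partitions, %.3g uL reaction (analyzed fraction %.3g)\n",
              x$n_partitions, x$reaction_volume, x$analyzed_fraction))
  cat(sprintf("  partition volume: %.4g nL\n", x$partition_volume * 1e3))
  invisible(x)
}

#' Mass of one haploid human genome in picograms
#'
#' Used to convert a genomic DNA input mass into template copies.
#' @export
HAPLOID_GENOME_PG <- 3.3

#' Convert a gDNA mass to template concentration
#'
#' A diploid locus contributes two template copies per cell, i.e. one copy
#' per haploid genome equivalent; 10 ng of human gDNA in a 9 uL reaction
#' therefore corresponds to about 337 copies/uL.
#'
#' @param ng_gdna Input gDNA mass in nanograms.
#' @param reaction_volume Reaction volume in microliters.
#' @param pg_per_haploid Haploid genome mass in picograms
#'   (default [HAPLOID_GENOME_PG]).
#' @return Template concentration in copies per microliter.
#' @examples
#' gdna_copies_per_ul(10)  # ~336.7 copies/uL in 9 uL
#' @export
gdna_copies_per_ul <- function(ng_gdna, reaction_volume = 9,
                               pg_per_haploid = HAPLOID_GENOME_PG) {
  stopifnot(ng_gdna >= 0, reaction_volume > 0, pg_per_haploid > 0)
  (ng_gdna * 1e3 / pg_per_haploid) / reaction_volume
}

#' Allele species loaded on a chip
#'
#' One template species with a concentration and a dye binding profile:
#' `binding[dye]` is `TRUE` when that probe's binding site is intact on
#' this species. Indels under a drop-off probe set the corresponding entry
#' to `FALSE`; a deleted reference-probe site (copy-number loss) sets the
#' reference dye entry to `FALSE`.
#'
#' @param name Species label.
#' @param concentration Concentration in copies per microliter of reaction.
#' @param binding Named logical vector, one entry per panel dye.
#' @return An object of class `allele_species`.
#' @export
allele_species <- function(name, concentration, binding) {
  stopifnot(is.character(name), length(name) == 1L,
            length(concentration) == 1L, is.finite(concentration),
            is.logical(binding), !is.null(names(binding)),
            !anyNA(binding))
  if (concentration < 0)
    stop("species '", name, "': concentration must be >= 0")
  structure(list(name = name, concentration = concentration,
                 binding = binding),
            class = "allele_species")
}

#' Two-component fluorescence noise model
#'
#' Intensities for truly negative partitions are drawn from the baseline
#' component and truly positive partitions from the positive component; a
#' `rain_fraction` of positive partitions instead fluoresces midway
#' between the two cluster means, emulating the intermediate "rain" seen
#' on real chips.
#'
#' The default is rain-free: rain partitions sit at the gating threshold
#' and are classified essentially at random, which injects differential
#' misclassification noise between channels on the order of
#' `rain_fraction / 2` of the positive fraction — enough to swamp mutant
#' signals a thousand-fold below the template load that the drop-off
#' assay is designed to resolve. Rain is therefore a robustness knob for
#' gating, not part of the default data-generating conditions.
#'
#' @param baseline_mean,baseline_sd Baseline cluster mean/sd per dye
#'   (recycled across dyes when scalar), arbitrary fluorescence units.
#' @param positive_mean,positive_sd Positive cluster mean/sd per dye.
#' @param rain_fraction Fraction of positive partitions drawn at the
#'   midpoint, in [0, 1); default 0.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(baseline_mean = 1000, baseline_sd = 100,
                        positive_mean = 5000, positive_sd = 250,
                        rain_fraction = 0) {
  stopifnot(baseline_sd > 0, positive_sd > 0,
            rain_fraction >= 0, rain_fraction < 1)
  if (any(positive_mean <= baseline_mean +
          4 * pmax(baseline_sd, positive_sd)))
    stop("noise model clusters are not separable: require positive_mean > ",
         "baseline_mean + 4 * max(baseline_sd, positive_sd)")
  structure(list(baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 positive_mean = positive_mean, positive_sd = positive_sd,
                 rain_fraction = rain_fraction),
            class = "noise_model")
}

#' Build intact + edited species for a drop-off experiment
#'
#' Splits a total template concentration into an intact species binding
#' every probe and an edited species whose drop-off probe site(s) are
#' disrupted. The reference probe site is by construction never disrupted
#' by editing.
#'
#' @param panel A [probe_panel].
#' @param total_conc Total template concentration, copies/uL.
#' @param dropoff_fraction Fraction of templates carrying the edit, in
#'   [0, 1].
#' @param affected_dyes Dyes whose binding sites the edit disrupts; must
#'   be drop-off dyes.
#' @return List of two [allele_species]: `intact` and `edited`; their
#'   concentrations sum exactly to `total_conc`.
#' @examples
#' panel <- crlf2_panel()
#' sp <- make_editing_species(panel, gdna_copies_per_ul(10), 0.10, "TAMRA")
#' sapply(sp, function(s) s$concentration)
#' @export
make_editing_species <- function(panel, total_conc, dropoff_fraction,
                                 affected_dyes) {
  stopifnot(inherits(panel, "probe_panel"), total_conc >= 0,
            dropoff_fraction >= 0, dropoff_fraction <= 1)
  dyes <- panel_dyes(panel)
  ref <- reference_dye(panel)
  affected_dyes <- match.arg(affected_dyes, dyes, several.ok = TRUE)
  if (ref %in% affected_dyes)
    stop("the reference dye (", ref, ") cannot be an edited drop-off site")
  all_bind <- stats::setNames(rep(TRUE, length(dyes)), dyes)
  edited_bind <- all_bind
  edited_bind[affected_dyes] <- FALSE
  list(
    intact = allele_species("intact", (1 - dropoff_fraction) * total_conc,
                            all_bind),
    edited = allele_species("edited", dropoff_fraction * total_conc,
                            edited_bind)
  )
}

#' Build species for a hemizygous reference-site deletion
#'
#' Models a copy-number variant in which the reference-probe binding site
#' is deleted on one homolog: half of the templates bind all probes, the
#' other half bind every drop-off probe but not the reference probe. The
#' downstream reference:drop-off concentration ratio is 0.5.
#'
#' @inheritParams make_editing_species
#' @return List of two equal-concentration [allele_species].
#' @export
make_cnv_species <- function(panel, total_conc) {
  stopifnot(inherits(panel, "probe_panel"), total_conc >= 0)
  dyes <- panel_dyes(panel)
  ref <- reference_dye(panel)
  all_bind <- stats::setNames(rep(TRUE, length(dyes)), dyes)
  del_bind <- all_bind
  del_bind[ref] <- FALSE
  list(
    intact = allele_species("intact", total_conc / 2, all_bind),
    ref_deleted = allele_species("ref_deleted", total_conc / 2, del_bind)
  )
}
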