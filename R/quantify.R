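#' Poisson rate from the negative-partition count
#'
#' The digital PCR Poisson correction: if a fraction `n_neg / n_total` of
#' partitions is negative, the mean template load per partition is
#' `lambda = -ln(n_neg / n_total)`. The confidence interval is obtained by
#' transforming Clopper-Pearson bounds on the negative fraction through
#' `-ln(.)`. A chip with no negative partitions is saturated: the point
#' estimate is undefined and only a lower bound is reported.
#'
#' @param n_neg Number of negative partitions.
#' @param n_total Total number of partitions (>= 1).
#' @param ci_level Confidence level (default 0.95).
#' @return List with `lambda`, `ci` (length-2), `saturated` flag,
#'   `n_neg`, `n_total`.
#' @examples
#' lambda_from_negatives(7358, 20000)$lambda  # ~= 1.0
#' @export
lambda_from_negatives <- function(n_neg, n_total, ci_level = 0.95) {
  stopifnot(n_total >= 1, n_neg >= 0)
  if (n_neg > n_total) stop("n_neg cannot exceed n_total")
  alpha <- 1 - ci_level
  # Clopper-Pearson bounds on p_neg
  p_lo <- if (n_neg == 0) 0 else
    stats::qbeta(alpha / 2, n_neg, n_total - n_neg + 1)
  p_hi <- if (n_neg == n_total) 1 else
    stats::qbeta(1 - alpha / 2, n_neg + 1, n_total - n_neg)
  if (n_neg == 0) {
    return(list(lambda = NA_real_, ci = c(-log(p_hi), Inf),
                saturated = TRUE, n_neg = n_neg, n_total = n_total))
  }
  list(lambda = -log(n_neg / n_total),
       ci = c(-log(p_hi), -log(p_lo)),  # -ln is decreasing
       saturated = FALSE, n_neg = n_neg, n_total = n_total)
}

#' Convert a per-partition rate to copies per microliter
#'
#' `C = lambda / partition_volume = lambda * n_partitions /
#' (reaction_volume * analyzed_fraction)`; the confidence interval
#' transforms linearly.
#'
#' @param lam Result of [lambda_from_negatives], or a bare non-negative
#'   number.
#' @param chip A [chip_spec].
#' @return List with `conc` (copies/uL) and `ci`.
#' @examples
#' concentration(lambda_from_negatives(17660, 20480), chip_spec())
#' @export
concentration <- function(lam, chip) {
  stopifnot(inherits(chip, "chip_spec"))
  if (is.numeric(lam)) {
    stopifnot(length(lam) == 1L, lam >= 0)
    lam <- list(lambda = lam, ci = c(NA_real_, NA_real_), saturated = FALSE)
  }
  v <- chip$partition_volume
  list(conc = lam$lambda / v, ci = lam$ci / v, saturated = lam$saturated)
}

# estimator core shared by point estimation and bootstrap -----------------

# Channel negatives from a joint pattern table.
.channel_negatives <- function(patterns, dyes) {
  vapply(dyes, function(d) sum(patterns$count[!patterns[[d]]]), numeric(1))
}

# Per-probe mutant lambda from pattern counts. Returns a matrix with rows
# lambda_ref, lambda_probe, lambda_mut and one column per drop-off dye.
.dropoff_lambdas <- function(patterns, n_total, ref, dp_dyes, method) {
  n_neg <- .channel_negatives(patterns, c(ref, dp_dyes))
  if (any(n_neg == 0)) return(NULL)  # saturated channel
  lam <- -log(n_neg / n_total)
  lam_ref <- lam[[ref]]
  out <- vapply(dp_dyes, function(d) {
    lam_probe <- lam[[d]]
    if (method == "difference") {
      lam_mut <- lam_ref - lam_probe
    } else {
      # joint estimator corrects co-encapsulation exactly:
      # P(ref+, probe-) = (1 - exp(-lam_mut)) * exp(-lam_intact)
      # with exp(-lam_intact) estimated by the probe-channel negative
      # fraction.
      p_probe_neg <- n_neg[[d]] / n_total
      f_pat <- sum(patterns$count[patterns[[ref]] & !patterns[[d]]]) / n_total
      arg <- 1 - f_pat / p_probe_neg
      lam_mut <- if (arg <= 0) Inf else -log(arg)
    }
    c(lam_ref, lam_probe, lam_mut)
  }, numeric(3))
  rownames(out) <- c("lambda_ref", "lambda_probe", "lambda_mut")
  out
}

#' Drop-off (mutant) concentration and fraction per probe
#'
#' Estimates, for every drop-off probe, the concentration of templates
#' whose probe site is disrupted and the drop-off fraction
#' `f = C_mut / C_ref`.
#'
#' Two estimators are provided. The default `"difference"` method takes
#' `lambda_mut = lambda_ref - lambda_probe`, each rate Poisson-corrected
#' from its own channel's negative count; negative differences are floored
#' at zero and flagged. The `"joint"` method solves the co-encapsulation
#' equation `P(ref+, probe-) = (1 - exp(-lambda_mut)) * exp(-lambda_intact)`
#' using the joint pattern frequency, which corrects the bias of the naive
#' "(ref+, probe-) / ref+" ratio at high template loads. Confidence
#' intervals for `C_mut` and `f` come from a partition-resampling
#' bootstrap (multinomial resampling of the joint pattern counts).
#'
#' @param x A [gate_result] or (pooled) [pattern_counts].
#' @param panel A [probe_panel].
#' @param chip A [chip_spec].
#' @param method `"difference"` (default) or `"joint"`.
#' @param ci_level Confidence level for all intervals.
#' @param n_boot Bootstrap replicates for `C_mut` / `f` intervals.
#' @param seed Seed for the bootstrap.
#' @return A `quant_result`: `channels` data.frame (per-dye negatives,
#'   `lambda` with CI, concentration with CI, saturation flag), `dropoff`
#'   data.frame (per-probe `lambda_mut`, `conc_mut` and `fraction` with
#'   bootstrap CIs, `floored` flag), the `patterns` used, `method`, and
#'   `chip`.
#' @examples
#' panel <- crlf2_panel()
#' sp <- make_editing_species(panel, 336.8, 0.10, "TAMRA")
#' sim <- simulate_chip(panel, chip_spec(), sp, seed = 1)
#' gr <- gate(sim$table, call_thresholds(sim$table))
#' q <- dropoff_quantify(gr, panel, chip_spec(), seed = 1)
#' q$dropoff[, c("probe", "conc_mut", "fraction")]
#' @export
dropoff_quantify <- function(x, panel, chip, method = c("difference", "joint"),
                             ci_level = 0.95, n_boot = 500L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(panel, "probe_panel"), inherits(chip, "chip_spec"))
  pc <- if (inherits(x, "gate_result")) pattern_counts(x, panel)
        else if (inherits(x, "pattern_counts")) x
        else stop("x must be a gate_result or pattern_counts")

  dyes <- panel_dyes(panel)
  ref <- reference_dye(panel)
  dp <- dropoff_probes(panel)
  n_total <- pc$n_total
  v <- chip$partition_volume

  n_neg <- .channel_negatives(pc$patterns, dyes)
  channels <- do.call(rbind, lapply(dyes, function(d) {
    lam <- lambda_from_negatives(n_neg[[d]], n_total, ci_level)
    cc <- concentration(lam, chip)
    data.frame(dye = d, n_neg = lam$n_neg, n_total = lam$n_total,
               lambda = lam$lambda, lambda_lo = lam$ci[1],
               lambda_hi = lam$ci[2], conc = cc$conc,
               conc_lo = cc$ci[1], conc_hi = cc$ci[2],
               saturated = lam$saturated)
  }))

  if (channels$saturated[channels$dye == ref])
    stop("reference channel is saturated (no negative partitions); ",
         "lambda_ref is undefined and drop-off cannot be quantified")

  est <- .dropoff_lambdas(pc$patterns, n_total, ref, dp$dye, method)
  if (is.null(est))
    stop("a drop-off channel is saturated; drop-off cannot be quantified")
  lam_mut_raw <- est["lambda_mut", ]
  floored <- lam_mut_raw < 0
  lam_mut <- pmax(lam_mut_raw, 0)
  frac <- lam_mut / est["lambda_ref", ]

  # partition-resampling bootstrap via multinomial resampling of the
  # joint pattern counts (equivalent to resampling partition rows)
  p_hat <- pc$patterns$count / n_total
  boot <- withr::with_seed(seed, {
    draws <- stats::rmultinom(n_boot, n_total, p_hat)
    apply(draws, 2, function(cnt) {
      pat <- pc$patterns
      pat$count <- cnt
      e <- .dropoff_lambdas(pat, n_total, ref, dp$dye, method)
      if (is.null(e)) rep(NA_real_, 2L * length(dp$dye))
      else c(pmax(e["lambda_mut", ], 0),
             pmax(e["lambda_mut", ], 0) / e["lambda_ref", ])
    })
  })
  if (is.null(dim(boot))) boot <- matrix(boot, nrow = 2L * nrow(dp))
  alpha <- 1 - ci_level
  k <- nrow(dp)
  qs <- function(i) stats::quantile(boot[i, ], c(alpha / 2, 1 - alpha / 2),
                                    na.rm = TRUE, names = FALSE)
  mut_ci <- vapply(seq_len(k), qs, numeric(2))
  frac_ci <- vapply(k + seq_len(k), qs, numeric(2))

  dropoff <- data.frame(
    probe = dp$name, dye = dp$dye,
    lambda_mut = lam_mut,
    conc_mut = lam_mut / v,
    conc_mut_lo = mut_ci[1, ] / v, conc_mut_hi = mut_ci[2, ] / v,
    fraction = frac,
    fraction_lo = frac_ci[1, ], fraction_hi = frac_ci[2, ],
    floored = floored, row.names = NULL)

  structure(list(channels = channels, dropoff = dropoff, patterns = pc,
                 method = method, chip = chip, panel = panel,
                 ci_level = ci_level),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("<quant_result> method '%s', %d partitions\n",
              x$method, x$patterns$n_total))
  cat("channels:\n")
  print(x$channels[, c("dye", "n_neg", "lambda", "conc")], row.names = FALSE)
  cat("drop-off:\n")
  print(x$dropoff[, c("probe", "conc_mut", "fraction",
                      "fraction_lo", "fraction_hi")], row.names = FALSE)
  invisible(x)
}

#' Aggregate quantification results across replicate chips
#'
#' Averages per-probe drop-off concentration and fraction over chips,
#' reporting mean and standard error of the mean per probe.
#'
#' @param qs List of [dropoff_quantify] results from replicate chips.
#' @return data.frame with per-probe `mean_conc_mut`, `sem_conc_mut`,
#'   `mean_fraction`, `sem_fraction`, `n_chips`.
#' @export
aggregate_quant <- function(qs) {
  stopifnot(length(qs) >= 1L,
            all(vapply(qs, inherits, logical(1), "quant_result")))
  probes <- qs[[1]]$dropoff$probe
  sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x))
                     else NA_real_
  do.call(rbind, lapply(probes, function(p) {
    cm <- vapply(qs, function(q) q$dropoff$conc_mut[q$dropoff$probe == p],
                 numeric(1))
    fr <- vapply(qs, function(q) q$dropoff$fraction[q$dropoff$probe == p],
                 numeric(1))
    data.frame(probe = p, n_chips = length(qs),
               mean_conc_mut = mean(cm), sem_conc_mut = sem(cm),
               mean_fraction = mean(fr), sem_fraction = sem(fr))
  }))
}

#' Copy-number call from probe concentration ratios
#'
#' Computes, per drop-off probe, the ratio `r = C_ref / C_probe` of the
#' reference-channel to probe-channel concentrations with a
#' partition-resampling bootstrap interval, and classifies the chip:
#' `hemizygous-reference` when every per-probe interval excludes 1 and
#' contains 0.5 (the reference-probe binding site is lost on one
#' homolog), `euploid` when every interval contains 1, otherwise
#' `other`. Also reports each channel's total concentration and the
#' union-based total over all probes as a cross-check.
#'
#' @param q A [dropoff_quantify] result.
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Bootstrap seed.
#' @param ci_level Confidence level.
#' @return A `cnv_call`: `ratios` data.frame (per-probe `ratio` with CI),
#'   `call`, `per_dye_conc`, `total_conc_union` (from the all-negative
#'   fraction over all four channels), `n_boot`, `seed`.
#' @export
cnv_ratio <- function(q, n_boot = 2000L, seed = 1L, ci_level = 0.95) {
  stopifnot(inherits(q, "quant_result"))
  if (any(q$channels$saturated))
    stop("saturated channel(s): ",
         paste(q$channels$dye[q$channels$saturated], collapse = ", "),
         "; concentration ratios are undefined")
  ref <- reference_dye(q$panel)
  dp <- dropoff_probes(q$panel)
  pc <- q$patterns
  n_total <- pc$n_total
  v <- q$chip$partition_volume

  ratio_from <- function(patterns) {
    n_neg <- .channel_negatives(patterns, c(ref, dp$dye))
    if (any(n_neg == 0)) return(rep(NA_real_, nrow(dp)))
    lam <- -log(n_neg / n_total)
    lam[[ref]] / lam[dp$dye]
  }
  r_hat <- ratio_from(pc$patterns)

  boot <- withr::with_seed(seed, {
    draws <- stats::rmultinom(n_boot, n_total, pc$patterns$count / n_total)
    apply(draws, 2, function(cnt) {
      pat <- pc$patterns; pat$count <- cnt; ratio_from(pat)
    })
  })
  if (is.null(dim(boot))) boot <- matrix(boot, nrow = nrow(dp))
  alpha <- 1 - ci_level
  ci <- apply(boot, 1, stats::quantile, probs = c(alpha / 2, 1 - alpha / 2),
              na.rm = TRUE, names = FALSE)

  ratios <- data.frame(probe = dp$name, dye = dp$dye, ratio = unname(r_hat),
                       ratio_lo = ci[1, ], ratio_hi = ci[2, ],
                       row.names = NULL)
  hemi <- all(ratios$ratio_lo > 0 & ratios$ratio_hi < 1 &
                ratios$ratio_lo <= 0.5 & ratios$ratio_hi >= 0.5)
  euploid <- all(ratios$ratio_lo <= 1 & ratios$ratio_hi >= 1)
  call <- if (hemi) "hemizygous-reference" else if (euploid) "euploid"
          else "other"

  n_all_neg <- sum(pc$patterns$count[rowSums(
    as.matrix(pc$patterns[, pc$dyes, drop = FALSE])) == 0])
  total_union <- if (n_all_neg > 0) -log(n_all_neg / n_total) / v else NA_real_

  structure(list(ratios = ratios, call = call,
                 per_dye_conc = q$channels[, c("dye", "conc")],
                 total_conc_union = total_union,
                 n_boot = n_boot, seed = seed, ci_level = ci_level),
            class = "cnv_call")
}

#' @export
print.cnv_call <- function(x, ...) {
  cat(sprintf("<cnv_call> %s (union total %.3g copies/uL)\n",
              x$call, x$total_conc_union))
  print(x$ratios, row.names = FALSE)
  invisible(x)
}
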