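#' Dose series container
#'
#' Replicate drop-off measurements (fractions or copies/uL) across
#' ordered inducer doses.
#'
#' @param dose Dose labels; ordering follows the sorted unique numeric
#'   value when coercible, otherwise the order of first appearance.
#' @param value Measurement per replicate.
#' @param probe Optional probe label (a series is analyzed per probe).
#' @return A `dose_series` data.frame with `dose` an ordered factor.
#' @export
dose_series <- function(dose, value, probe = NULL) {
  stopifnot(length(dose) == length(value), all(is.finite(value)))
  num <- suppressWarnings(as.numeric(as.character(dose)))
  lev <- if (!anyNA(num)) as.character(sort(unique(num)))
         else unique(as.character(dose))
  d <- factor(as.character(dose), levels = lev, ordered = TRUE)
  if (anyNA(d)) stop("dose labels could not be ordered")
  if (nlevels(d) < 2L) stop("a dose series needs at least 2 dose groups")
  if (any(table(d) < 1L)) stop("every dose group needs >= 1 replicate")
  out <- data.frame(dose = d, value = value)
  if (!is.null(probe)) out$probe <- probe
  class(out) <- c("dose_series", "data.frame")
  out
}

# JT statistic: sum over ordered group pairs i < j of
# #(x_i < x_j) + 1/2 #(x_i == x_j)
.jt_stat <- function(value, group_int, k) {
  s <- 0
  for (i in seq_len(k - 1L)) {
    xi <- value[group_int == i]
    for (j in (i + 1L):k) {
      xj <- value[group_int == j]
      s <- s + sum(outer(xi, xj, "<")) + 0.5 * sum(outer(xi, xj, "=="))
    }
  }
  s
}

# all permutations of seq_len(n) as an n! x n matrix (n <= 8)
.all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Jonckheere-Terpstra trend test with a permutation/exact null
#'
#' Tests the ordered alternative that measurements increase across dose
#' groups. The statistic is the sum over ordered group pairs (i < j) of
#' Mann-Whitney counts `#(x_i < x_j) + 1/2 #(x_i = x_j)`; it is invariant
#' under strictly monotone transforms of the measurements. The null is
#' obtained by permuting group labels: exhaustively (exact p-value) when
#' the total sample size is at most `exact_n`, otherwise by Monte Carlo
#' with `p = (1 + #(perm >= obs)) / (n_perm + 1)`.
#'
#' @param series A [dose_series] (or data.frame with `dose`, `value`).
#' @param n_perm Monte Carlo permutations (default 10000).
#' @param seed Seed for the Monte Carlo null.
#' @param exact_n Exhaustive enumeration cutoff (default 8).
#' @return List with `statistic`, `p_value`, `max_statistic`, `method`
#'   (`"exact"` or `"permutation"`), `n_perm`.
#' @examples
#' s <- dose_series(rep(c(0, 100, 250), each = 2), c(1, 2, 3, 4, 5, 6))
#' jonckheere_terpstra(s)  # maximal statistic 12, exact p = 1/90
#' @export
jonckheere_terpstra <- function(series, n_perm = 10000L, seed = 1L,
                                exact_n = 8L) {
  stopifnot(is.data.frame(series), all(c("dose", "value") %in% names(series)))
  g <- as.integer(factor(series$dose,
                         levels = if (is.factor(series$dose))
                           levels(series$dose) else unique(series$dose)))
  k <- max(g)
  if (k < 2L) stop("trend test needs at least 2 dose groups")
  x <- series$value
  n <- length(x)
  obs <- .jt_stat(x, g, k)
  sizes <- tabulate(g, k)
  max_stat <- sum(utils::combn(k, 2, function(ij)
    sizes[ij[1]] * sizes[ij[2]]))

  if (n <= exact_n) {
    perms <- .all_perms(n)
    stats <- apply(perms, 1L, function(idx) .jt_stat(x, g[idx], k))
    list(statistic = obs, p_value = mean(stats >= obs),
         max_statistic = max_stat, method = "exact", n_perm = nrow(perms))
  } else {
    stats <- withr::with_seed(seed, {
      vapply(seq_len(n_perm),
             function(b) .jt_stat(x, sample(g), k), numeric(1))
    })
    list(statistic = obs,
         p_value = (1 + sum(stats >= obs)) / (n_perm + 1),
         max_statistic = max_stat, method = "permutation", n_perm = n_perm)
  }
}

#' Per-dose summary of a dose series
#'
#' @param series A [dose_series].
#' @param value_floor Fold changes are computed against
#'   `max(lowest-dose mean, value_floor)`; `NA` fold when the lowest-dose
#'   mean is zero and no floor is given.
#' @return List with `summary` data.frame (per-dose `n`, `mean`, `sem` —
#'   `NA` for a single replicate —, `fold_vs_lowest`) and `monotone`
#'   (sample means non-decreasing across doses).
#' @export
trend_summary <- function(series, value_floor = 0) {
  stopifnot(is.data.frame(series), all(c("dose", "value") %in% names(series)))
  sp <- split(series$value, series$dose)
  m <- vapply(sp, mean, numeric(1))
  s <- vapply(sp, function(v)
    if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_,
    numeric(1))
  base <- max(m[[1]], value_floor)
  fold <- if (base > 0) m / base else rep(NA_real_, length(m))
  list(summary = data.frame(dose = names(sp),
                            n = lengths(sp), mean = unname(m),
                            sem = unname(s),
                            fold_vs_lowest = unname(fold),
                            row.names = NULL),
       monotone = !is.unsorted(m))
}
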