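#' Affinity constant from a binding energy
#'
#' `K = exp(-dG_b / (R T))` with `R = 8.314`, `T = 298.15` applied verbatim to
#' `dG_b` in kJ/mol (divisor 2478.82), matching the published computation this
#' pipeline reproduces. Dimensionally this reads the gas constant in
#' J/(mol K) against an energy in kJ/mol; set `physical = TRUE` for the
#' thermodynamically standard `K = exp(-dG_b * 1000 / (8.314 T))`, clearly a
#' different (much steeper) scale.
#'
#' @param dG_b binding energy (or vector of them), kJ/mol.
#' @param physical use the dimensionally consistent conversion instead of the
#'   verbatim published one (default `FALSE`).
#' @param temperature temperature in K (default 298.15).
#' @return Dimensionless affinity constant(s); `K = 1` exactly at `dG_b = 0`.
#' @export
affinity_constant <- function(dG_b, physical = FALSE, temperature = 298.15) {
  if (anyNA(dG_b) || !all(is.finite(dG_b))) stop("dG_b must be finite")
  divisor <- if (physical) 8.314 * temperature / 1000 else 8.314 * temperature
  exp(-dG_b / divisor)
}

#' Per-condition affinity constants from an energy table
#'
#' Converts each cluster's `dG_b` to `K` with [affinity_constant()], then
#' reports the per-condition mean and n-1 standard deviation of the
#' per-cluster `K` values (mean of exponentials, not exponential of the mean).
#'
#' @param rows an `energy_table` with >= 2 rows per condition; a missing
#'   `dG_b` column is assembled from the components.
#' @param physical see [affinity_constant()].
#' @return A data frame of class `affinity_estimate`: `condition`, `mean_K`,
#'   `sd_K`, `n`, and a `per_cluster_K` list column.
#' @export
condition_affinity <- function(rows, physical = FALSE) {
  if (is.null(rows$dG_b))
    rows$dG_b <- rows$dG_solv + rows$dG_coul + rows$dG_nonelec
  counts <- table(rows$condition)
  if (any(counts < 2))
    stop("need >= 2 rows per condition (violated for: ",
         paste(names(counts)[counts < 2], collapse = ", "), ")")
  conds <- unique(rows$condition)
  out <- data.frame(condition = conds,
                    mean_K = NA_real_, sd_K = NA_real_,
                    n = NA_integer_, stringsAsFactors = FALSE)
  out$per_cluster_K <- vector("list", length(conds))
  for (i in seq_along(conds)) {
    K <- affinity_constant(rows$dG_b[rows$condition == conds[i]], physical)
    out$mean_K[i] <- mean(K)
    out$sd_K[i] <- stats::sd(K)
    out$n[i] <- length(K)
    out$per_cluster_K[[i]] <- K
  }
  class(out) <- c("affinity_estimate", "data.frame")
  out
}

#' Percent decrease of an affinity constant relative to a reference
#'
#' `100 (K_ref - K_cond) / K_ref`.
#'
#' @param K_ref reference-condition affinity constant (> 0).
#' @param K_cond affinity constant under the perturbed condition.
#' @return Percent decrease (negative for an increase).
#' @export
percent_decrease <- function(K_ref, K_cond) {
  if (any(K_ref <= 0)) stop("K_ref must be > 0")
  100 * (K_ref - K_cond) / K_ref
}

#' Rescale a dissociation constant for an affinity increase
#'
#' An affinity increase by fraction `f` is applied as a multiplicative
#' decrease of the dissociation constant: `Ktt -> Ktt (1 - f)`, the mapping
#' that takes 1 mM to 0.96 mM at a 4 percent increase.
#'
#' @param base_Ktt base dissociation constant, mM.
#' @param affinity_increase fractional affinity increase in `[0, 1)`.
#' @return Adjusted dissociation constant, mM.
#' @export
adjust_ktt <- function(base_Ktt, affinity_increase) {
  if (affinity_increase < 0 || affinity_increase >= 1)
    stop("affinity_increase must be in [0, 1)")
  base_Ktt * (1 - affinity_increase)
}
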