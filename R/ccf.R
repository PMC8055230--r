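#' Expected variant allele fraction of a mutation (general three-population form)
#'
#' A bulk sample is a mixture of normal cells (diploid at the locus), a
#' reference cancer population not carrying the mutation with average local
#' copy number `cn_ref`, and a variant cancer population carrying it with
#' average local copy number `cn_var`, of which `multiplicity` copies per
#' cell harbour the variant allele. The expected VAF is the fraction of
#' variant-bearing chromosomes among all chromosomes overlapping the locus:
#'
#' \deqn{\theta = \frac{d^V \rho \tilde\phi}
#'   {2(1-\rho) + D^R \rho (1-\tilde\phi) + D^V \rho \tilde\phi}}
#'
#' @param ccf Cancer cell fraction \eqn{\tilde\phi \in [0,1]} (vectorized).
#' @param purity Sample purity \eqn{\rho \in (0,1]}.
#' @param multiplicity Variant multiplicity \eqn{d^V \ge 1}.
#' @param cn_ref,cn_var Average local total copy number of the reference and
#'   variant cancer populations; both default to 2.
#' @return Expected VAF in `[0, 1]`.
#' @export
expected_vaf_general <- function(ccf, purity, multiplicity,
                                 cn_ref = 2, cn_var = 2) {
  stopifnot(all(ccf >= 0 & ccf <= 1), all(purity > 0 & purity <= 1),
            all(multiplicity >= 1), all(multiplicity <= cn_var))
  denom <- 2 * (1 - purity) + cn_ref * purity * (1 - ccf) +
    cn_var * purity * ccf
  if (any(denom <= 0)) {
    abort("Degenerate locus: zero chromosome content in the denominator.")
  }
  multiplicity * purity * ccf / denom
}

#' Expected VAF of a clonal mutation (the zeta coefficient)
#'
#' Under the simplifying assumptions of no sub-clonal copy-number events and
#' a shared copy number `cn` for the reference and variant cancer
#' populations, the VAF of a mutation present in every cancer cell
#' (\eqn{\tilde\phi = 1}) is
#' \deqn{\zeta = \frac{d^V \rho}{2(1-\rho) + D \rho},}
#' and expected VAF is linear in CCF: \eqn{\theta = \zeta \tilde\phi}.
#'
#' @inheritParams expected_vaf_general
#' @param cn Shared local total copy number \eqn{D}.
#' @return \eqn{\zeta \in (0, 1]} (vectorized over the inputs).
#' @export
clonal_vaf_coefficient <- function(purity, cn = 2, multiplicity = 1) {
  stopifnot(all(purity > 0 & purity <= 1), all(cn >= 1),
            all(multiplicity >= 1), all(multiplicity <= cn))
  multiplicity * purity / (2 * (1 - purity) + cn * purity)
}

#' Expected VAF under the shared-copy-number simplification
#'
#' @inheritParams clonal_vaf_coefficient
#' @param ccf Cancer cell fraction in `[0, 1]`.
#' @return \eqn{\theta = \zeta \cdot \tilde\phi}.
#' @seealso [clonal_vaf_coefficient()], [expected_vaf_general()]
#' @export
expected_vaf <- function(ccf, purity, cn = 2, multiplicity = 1) {
  stopifnot(all(ccf >= 0 & ccf <= 1))
  clonal_vaf_coefficient(purity, cn, multiplicity) * ccf
}

#' Estimate the integer multiplicity of a mutation from its observed VAF
#'
#' Computes \eqn{u = \theta \rho^{-1} (2(1-\rho) + D\rho)} — the product of
#' multiplicity and CCF implied by the observed VAF — and returns the
#' closest integer to `u` when `u >= 1`, otherwise 1. Half-way ties round
#' away from zero. The estimate is clamped to `[1, cn]` so it never
#' exceeds the local copy number.
#'
#' @param vaf_obs Observed VAF in `[0, 1]` (vectorized).
#' @param purity Sample purity in `(0, 1]`.
#' @param cn Local total copy number `D >= 1`.
#' @return Integer multiplicity estimate in `[1, cn]`.
#' @export
estimate_multiplicity <- function(vaf_obs, purity, cn = 2) {
  if (any(purity <= 0)) abort("`purity` must be positive.")
  stopifnot(all(vaf_obs >= 0 & vaf_obs <= 1), all(cn >= 1))
  u <- vaf_obs / purity * (2 * (1 - purity) + cn * purity)
  d <- ifelse(u < 1, 1, floor(u + 0.5))  # round half away from zero (u > 0)
  as.integer(pmin(d, cn))
}

#' Fill in unset multiplicities of a mutation table
#'
#' For mutations whose `multiplicity` column is `NA`, estimates an integer
#' multiplicity with [estimate_multiplicity()]. By default the observed VAF
#' is pooled across samples weighted by depth and the per-sample implied
#' copy products `u_ij` are combined into one depth-weighted estimate, so a
#' mutation keeps a single multiplicity over time (consistent with the
#' assumption of no sub-clonal copy-number events); the pooled estimate is
#' clamped by the smallest local copy number seen for the mutation.
#' With `per_sample = TRUE` each (mutation, sample) cell is estimated from
#' its own VAF instead. Pre-specified multiplicities are kept verbatim.
#'
#' @param tbl A `mutation_tbl`.
#' @param per_sample Estimate separately per sample instead of pooling.
#' @return The table with `multiplicity` fully populated.
#' @export
resolve_multiplicity <- function(tbl, per_sample = FALSE) {
  tbl <- if (inherits(tbl, "mutation_tbl")) tbl else as_mutation_table(tbl)
  unset <- is.na(tbl$multiplicity)
  if (!any(unset)) return(tbl)
  if (per_sample) {
    est <- estimate_multiplicity(tbl$alt_reads / tbl$total_reads,
                                 tbl$purity, tbl$total_cn)
    tbl$multiplicity[unset] <- est[unset]
    return(tbl)
  }
  pooled <- tbl |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$mutation_id) |>
    dplyr::mutate(
      vaf_pooled = sum(.data$alt_reads) / sum(.data$total_reads),
      u = .data$vaf_pooled / .data$purity *
        (2 * (1 - .data$purity) + .data$total_cn * .data$purity)
    ) |>
    dplyr::summarise(
      u_bar = sum(.data$u * .data$total_reads) / sum(.data$total_reads),
      cn_min = min(.data$total_cn),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      d = pmin(ifelse(.data$u_bar < 1, 1, floor(.data$u_bar + 0.5)),
               .data$cn_min),
      d = as.integer(pmax(.data$d, 1L))
    )
  est <- pooled$d[match(tbl$mutation_id, pooled$mutation_id)]
  tbl$multiplicity[unset] <- est[unset]
  tbl
}

#' Observed CCF implied by read counts
#'
#' Adds `vaf` (observed alt/total) and `ccf_obs` (VAF divided by the clonal
#' coefficient \eqn{\zeta}, clamped to `[0, 1]`) columns. Requires resolved
#' multiplicities.
#'
#' @param tbl A `mutation_tbl` with no `NA` multiplicities (see
#'   [resolve_multiplicity()]).
#' @return The table with `vaf`, `zeta` and `ccf_obs` columns appended.
#' @export
observed_ccf <- function(tbl) {
  tbl <- resolve_multiplicity(tbl)
  tbl$vaf <- tbl$alt_reads / tbl$total_reads
  tbl$zeta <- clonal_vaf_coefficient(tbl$purity, tbl$total_cn,
                                     tbl$multiplicity)
  tbl$ccf_obs <- pmin(pmax(tbl$vaf / tbl$zeta, 0), 1)
  tbl
}
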