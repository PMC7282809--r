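#' Precocious sister-separation percentages with Wilson intervals
#'
#' From a scored-cell table (per strain: metaphase cells scored and cells
#' with two separated GFP dots), computes the percentage of precociously
#' separated cells, `100 * n_two_dot / n_scored`, with a 95% Wilson score
#' interval. The interval is an extension — scored-cell studies often
#' report only the point proportion — and always contains the point
#' estimate within \[0, 100\].
#'
#' @param table Data frame with columns `strain`, `n_scored` (> 0) and
#'   `n_two_dot` (in `[0, n_scored]`); see [gen_cytology()].
#' @param conf_level Confidence level for the Wilson interval.
#' @return A `separation_result` tibble with columns `strain`, `n_scored`,
#'   `n_two_dot`, `percent_two_dot`, `ci_low`, `ci_high` (all percentages).
#' @examples
#' percent_precocious(tibble::tibble(strain = "ctf4", n_scored = 100,
#'                                   n_two_dot = 49))
#' @export
percent_precocious <- function(table, conf_level = 0.95) {
  table <- as_tibble(table)
  stopifnot(all(c("strain", "n_scored", "n_two_dot") %in% names(table)))
  if (any(table$n_scored <= 0)) abort("`n_scored` must be > 0.")
  if (any(table$n_two_dot < 0 | table$n_two_dot > table$n_scored)) {
    abort("`n_two_dot` must lie in [0, n_scored].")
  }
  ci <- wilson_interval(table$n_two_dot, table$n_scored, conf_level)
  out <- tibble(strain = table$strain, n_scored = table$n_scored,
                n_two_dot = table$n_two_dot,
                percent_two_dot = 100 * table$n_two_dot / table$n_scored,
                ci_low = 100 * ci$low, ci_high = 100 * ci$high)
  class(out) <- c("separation_result", class(out))
  out
}

#' Wilson score interval for a binomial proportion
#'
#' @param x Successes (vectorised).
#' @param n Trials.
#' @param conf_level Confidence level.
#' @return A list with elements `low` and `high` on the proportion scale.
#' @export
wilson_interval <- function(x, n, conf_level = 0.95) {
  stopifnot(all(n > 0), all(x >= 0), all(x <= n))
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(low = pmax(0, center - half), high = pmin(1, center + half))
}

#' Compare precocious-separation proportions between two strains
#'
#' Difference in percentage points between two scored-cell rows with a
#' two-sided Fisher exact test on the underlying 2x2 counts. The test is an
#' extension to the plain reported proportions.
#'
#' @param a,b One-row data frames (or single rows) with `strain`,
#'   `n_scored`, `n_two_dot`.
#' @return A tibble with `strain_a`, `strain_b`, `delta_percent`
#'   (`a` minus `b`), `p_value`.
#' @examples
#' a <- tibble::tibble(strain = "ctf8", n_scored = 100, n_two_dot = 47)
#' b <- tibble::tibble(strain = "ctf8 + CHL1", n_scored = 100, n_two_dot = 18)
#' compare_strains(a, b)
#' @export
compare_strains <- function(a, b) {
  a <- as_tibble(a); b <- as_tibble(b)
  stopifnot(nrow(a) == 1L, nrow(b) == 1L)
  pa <- percent_precocious(a)
  pb <- percent_precocious(b)
  m <- matrix(c(a$n_two_dot, a$n_scored - a$n_two_dot,
                b$n_two_dot, b$n_scored - b$n_two_dot),
              nrow = 2, byrow = TRUE)
  ft <- fisher.test(m)
  tibble(strain_a = a$strain, strain_b = b$strain,
         delta_percent = pa$percent_two_dot - pb$percent_two_dot,
         p_value = ft$p.value)
}
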