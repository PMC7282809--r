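#' Simulate a flow-cytometry competition series
#'
#' Generates the per-passage event counts of a two-strain competition assay
#' in which a non-fluorescent test strain is grown against a fluorescent
#' reference, the mixed culture is diluted 1:1000 into fresh medium every
#' 24 h, and the strain ratio is measured by flow cytometry at every passage.
#'
#' The expected genotype log-ratio follows exponential selection dynamics:
#' `log r(G) = log(init_ratio) + s_true * G`, where `G` is the cumulative
#' number of generations since the day-0 sample and
#' `r = nonfluorescent / fluorescent`. Total event counts are deterministic
#' (`events_per_sample` at every sampling; `events_t0` is `events_t24`
#' divided by `2^gens_per_passage`, so that `log2(events_t24 / events_t0)`
#' recovers the generations grown in that interval), while the
#' fluorescent/non-fluorescent split at each sampling is a binomial draw —
#' the minimal counting-noise model for cytometry events.
#'
#' The returned series carries row `passage = 0` for the day-0 sample
#' (`events_t0 = events_t24`, hence zero generations) followed by
#' `n_passages` growth intervals.
#'
#' @param s_true Per-generation selection coefficient of the non-fluorescent
#'   strain relative to the fluorescent reference.
#' @param init_ratio Positive starting ratio `nonfluorescent / fluorescent`.
#' @param gens_per_passage Generations per 24 h passage; the default
#'   `log2(1000)` (about 9.97) corresponds to regrowth after a 1:1000
#'   dilution.
#' @param n_passages Number of growth intervals (>= 2).
#' @param events_per_sample Total cytometry events recorded at each sampling
#'   (> 0); 30000 events is a typical acquisition.
#' @param seed Integer seed.
#' @param replicate_id Label stored in the `replicate` column.
#'
#' @return A tibble with columns `replicate`, `passage`, `events_t0`,
#'   `events_t24`, `fluorescent`, `nonfluorescent`, carrying the simulated
#'   truth in attribute `truth_s`.
#' @examples
#' gen_competition(s_true = -0.05, init_ratio = 1, n_passages = 4,
#'                 events_per_sample = 30000, seed = 1)
#' @export
gen_competition <- function(s_true, init_ratio = 1,
                            gens_per_passage = log2(1000),
                            n_passages = 4L, events_per_sample = 30000L,
                            seed = 1L, replicate_id = "rep1") {
  if (init_ratio <= 0) abort("`init_ratio` must be > 0.")
  if (events_per_sample <= 0L) abort("`events_per_sample` must be > 0.")
  if (n_passages < 2L) abort("`n_passages` must be >= 2.")
  if (gens_per_passage <= 0) abort("`gens_per_passage` must be > 0.")
  withr::local_seed(as.integer(seed))

  events_t24 <- as.integer(events_per_sample)
  events_t0  <- max(1L, as.integer(round(events_per_sample / 2^gens_per_passage)))
  # generations as they will be measured from the rounded totals, so the
  # simulated log-ratio is exactly linear in the regression abscissa
  g_interval <- c(0, rep(log2(events_t24 / events_t0), n_passages))
  g_cum <- cumsum(g_interval)

  r_expected <- init_ratio * exp(s_true * g_cum)
  p_nonfluor <- r_expected / (1 + r_expected)
  nonfluor <- rbinom(n_passages + 1L, events_t24, p_nonfluor)
  fluor <- events_t24 - nonfluor

  out <- tibble(
    replicate = replicate_id,
    passage = 0:n_passages,
    events_t0 = c(events_t24, rep(events_t0, n_passages)),
    events_t24 = events_t24,
    fluorescent = fluor,
    nonfluorescent = nonfluor)
  attr(out, "truth_s") <- s_true
  out
}

#' Simulate a scored-cell cytology table
#'
#' Draws the number of metaphase (securin-positive) cells showing two
#' separated GFP dots at a marked locus out of `n_cells` scored, as a
#' binomial sample with per-cell precocious-separation probability
#' `p_two_dot`.
#'
#' @param n_cells Number of cells scored (> 0).
#' @param p_two_dot Probability in \[0, 1\] that a scored cell shows two dots.
#' @param seed Integer seed.
#' @param strain Strain label for the output row.
#' @return A one-row tibble with columns `strain`, `n_scored`, `n_two_dot`.
#' @examples
#' gen_cytology(n_cells = 100, p_two_dot = 0.18, seed = 1)
#' @export
gen_cytology <- function(n_cells, p_two_dot, seed = 1L, strain = "synthetic") {
  if (n_cells <= 0L) abort("`n_cells` must be > 0.")
  if (p_two_dot < 0 || p_two_dot > 1) abort("`p_two_dot` must be in [0, 1].")
  withr::local_seed(as.integer(seed))
  tibble(strain = strain, n_scored = as.integer(n_cells),
         n_two_dot = rbinom(1L, as.integer(n_cells), p_two_dot))
}
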