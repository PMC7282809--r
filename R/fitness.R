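#' Genotype ratio from cytometry event counts
#'
#' The genotype ratio at one sampling is
#' `r = nonfluorescent / fluorescent` events. Zero counts in either class
#' are an error — the remedy is acquiring more events, not pseudo-counting.
#'
#' @param nonfluorescent,fluorescent Event counts (> 0).
#' @return The ratio `r`.
#' @examples
#' genotype_ratio(300, 600)
#' @export
genotype_ratio <- function(nonfluorescent, fluorescent) {
  if (any(nonfluorescent <= 0) || any(fluorescent <= 0)) {
    abort(paste("Genotype ratio needs positive counts in both classes;",
                "acquire more events rather than pseudo-counting."))
  }
  nonfluorescent / fluorescent
}

#' Generations grown between two samplings
#'
#' Computed from the total events of the mixed culture at the start and end
#' of a growth interval: `g = log10(events_t24 / events_t0) / log10(2)`,
#' i.e. the number of population doublings.
#'
#' @param events_t0,events_t24 Total event counts at 0 h and 24 h (> 0,
#'   with `events_t24 >= events_t0`).
#' @return Generations `g`.
#' @examples
#' generations(1000, 8000)
#' @export
generations <- function(events_t0, events_t24) {
  if (any(events_t0 <= 0) || any(events_t24 <= 0)) {
    abort("Event counts must be positive.")
  }
  if (any(events_t24 < events_t0)) {
    abort("`events_t24` < `events_t0`: the culture cannot have shrunk.")
  }
  log10(events_t24 / events_t0) / log10(2)
}

#' Per-sampling regression points of a competition series
#'
#' Derives, for one replicate, the `(g_cum, log_ratio)` points that enter
#' the fitness regression: per-interval generations from [generations()]
#' accumulated over passages (the day-0 row, with `events_t0 == events_t24`,
#' contributes zero and anchors `g_cum = 0`), and the natural log of the
#' genotype ratio from [genotype_ratio()].
#'
#' @param series Data frame with columns `passage`, `events_t0`,
#'   `events_t24`, `fluorescent`, `nonfluorescent` for a single replicate.
#' @return A tibble with columns `passage`, `g`, `g_cum`, `log_ratio`.
#' @export
competition_points <- function(series) {
  series <- as_tibble(series)
  need <- c("passage", "events_t0", "events_t24", "fluorescent",
            "nonfluorescent")
  stopifnot(all(need %in% names(series)))
  series <- arrange(series, .data$passage)
  g <- generations(series$events_t0, series$events_t24)
  tibble(passage = series$passage, g = g, g_cum = cumsum(g),
         log_ratio = log(genotype_ratio(series$nonfluorescent,
                                        series$fluorescent)))
}

#' Relative fitness from a competition series
#'
#' Fits the ordinary least-squares regression of `log_e r` on cumulative
#' generations for one replicate; the slope is the relative fitness (the
#' per-generation selection coefficient of the non-fluorescent strain
#' against the fluorescent reference) and `stderr` is the usual OLS slope
#' standard error.
#'
#' @param series Data frame for one replicate (see [competition_points()]);
#'   if a `replicate` column is present it must contain a single value (use
#'   [fit_fitness_replicates()] for several).
#' @return A `fitness_fit`: list with `slope`, `stderr`, `n_points`,
#'   `points` (the regression tibble), `model` (the underlying `lm`),
#'   `replicate` and `corrected` (`NA` until [correct_fitness()]).
#' @examples
#' fit_fitness(gen_competition(s_true = -0.05, seed = 1))
#' @export
fit_fitness <- function(series) {
  series <- as_tibble(series)
  rep_id <- NA_character_
  if ("replicate" %in% names(series)) {
    ids <- unique(series$replicate)
    if (length(ids) > 1L) {
      abort("Several replicates supplied; use `fit_fitness_replicates()`.")
    }
    rep_id <- as.character(ids)
  }
  pts <- competition_points(series)
  if (nrow(pts) < 2L) abort("At least 2 samplings are required.")
  if (any(diff(pts$g_cum) <= 0)) {
    abort("Cumulative generations must be strictly increasing.")
  }
  fit <- lm(log_ratio ~ g_cum, data = pts)
  sm <- summary(fit)$coefficients
  slope <- unname(coef(fit)["g_cum"])
  stderr <- unname(sm["g_cum", "Std. Error"])
  if (!is.finite(stderr)) stderr <- 0
  structure(list(slope = slope, stderr = stderr, n_points = nrow(pts),
                 points = pts, model = fit, replicate = rep_id,
                 corrected = NA_real_),
            class = "fitness_fit")
}

#' Fit relative fitness for every replicate of a series table
#'
#' @param series Data frame with a `replicate` column and the per-sampling
#'   count columns of [competition_points()].
#' @return A tibble with one row per replicate: `replicate`, `slope`,
#'   `stderr`, `n_points`.
#' @export
fit_fitness_replicates <- function(series) {
  series <- as_tibble(series)
  stopifnot("replicate" %in% names(series))
  series |>
    dplyr::group_split(.data$replicate) |>
    purrr::map(fit_fitness) |>
    purrr::map_dfr(function(f) tibble(replicate = f$replicate,
                                      slope = f$slope, stderr = f$stderr,
                                      n_points = f$n_points))
}

#' @export
print.fitness_fit <- function(x, ...) {
  cat("<fitness_fit>", if (!is.na(x$replicate)) paste0("[", x$replicate, "]"),
      "\n")
  cat(sprintf("  relative fitness (slope): %.5f  (SE %.5f, %d points)\n",
              x$slope, x$stderr, x$n_points))
  if (!is.na(x$corrected)) {
    cat(sprintf("  fluorophore-corrected:    %.5f\n", x$corrected))
  }
  invisible(x)
}

#' @rdname fit_fitness
#' @param x A `fitness_fit`.
#' @param ... Unused.
#' @method tidy fitness_fit
#' @export
tidy.fitness_fit <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble(term = rownames(sm), estimate = unname(sm[, "Estimate"]),
         std_error = unname(sm[, "Std. Error"]),
         statistic = unname(sm[, "t value"]),
         p_value = unname(sm[, "Pr(>|t|)"]))
}

#' @rdname fit_fitness
#' @method glance fitness_fit
#' @export
glance.fitness_fit <- function(x, ...) {
  tibble(slope = x$slope, stderr = x$stderr, corrected = x$corrected,
         r_squared = summary(x$model)$r.squared, n_points = x$n_points)
}

#' Subtract the fluorophore-control fitness
#'
#' Fitness differences caused by the fluorescent markers themselves are
#' removed by subtracting the relative fitness measured between isogenic
#' strains carrying the two fluorophores from comparisons involving them:
#' `corrected = raw$slope - fluorophore_control$slope`.
#'
#' @param raw,fluorophore_control `fitness_fit` objects.
#' @return `raw` with its `corrected` field set.
#' @export
correct_fitness <- function(raw, fluorophore_control) {
  stopifnot(inherits(raw, "fitness_fit"),
            inherits(fluorophore_control, "fitness_fit"))
  raw$corrected <- raw$slope - fluorophore_control$slope
  raw$control_slope <- fluorophore_control$slope
  raw
}

#' Mean and standard deviation over biological replicates
#'
#' @param estimates Numeric vector of per-replicate fitness values
#'   (length >= 2; a warning is given below the recommended three).
#' @return A tibble with `mean`, `sd` (sample standard deviation, n - 1
#'   denominator) and `n`.
#' @export
summarize_replicates <- function(estimates) {
  estimates <- as.numeric(estimates)
  if (length(estimates) < 2L) {
    abort("At least 2 replicate estimates are required.")
  }
  if (length(estimates) < 3L) {
    warn("Fewer than 3 biological replicates; interpret the SD with care.")
  }
  tibble(mean = mean(estimates), sd = stats::sd(estimates),
         n = length(estimates))
}

#' Welch's unequal-variance t test
#'
#' Two-sided t test assuming unequal variances (Welch), as used to compare
#' replicate fitness values between strains:
#' `t = (mean_a - mean_b) / sqrt(va/na + vb/nb)` with Welch–Satterthwaite
#' degrees of freedom. Thin wrapper around [stats::t.test()] with
#' `var.equal = FALSE`.
#'
#' @param a,b Numeric vectors (each length >= 2; at least one with positive
#'   variance).
#' @return A tibble with `t`, `df`, `p`.
#' @examples
#' welch_test(c(1, 2, 3), c(2, 3, 4))
#' @export
welch_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    abort("Each sample needs at least 2 values.")
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    abort("Both samples have zero variance; the Welch test is undefined.")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  tibble(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value)
}
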