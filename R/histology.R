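# Histology cell-count statistics: pooled percentages, per-stack summaries
# with t-based confidence intervals, densities, cluster count/area
# summaries, one-way ANOVA, exponential age-trajectory fits, mixed-effects
# LRTs for age/region, and migratory-orientation summaries.

#' Pooled percentage from summed counts
#'
#' @param numerator,denominator non-negative integers,
#'   \code{numerator <= denominator}, \code{denominator > 0}.
#' @param digits decimals for the reported value (default 1, the reporting
#'   convention for marker percentages).
#' @return Percentage rounded to \code{digits}.
#' @export
pooled_percentage <- function(numerator, denominator, digits = 1) {
  if (denominator <= 0) stop("denominator must be positive")
  if (numerator > denominator) stop("numerator exceeds denominator")
  round(100 * numerator / denominator, digits)
}

#' Mean, sd and t-based 95 percent confidence interval of per-stack values
#'
#' @param values numeric vector (percentages or densities, one per
#'   z-stack); \code{n >= 2}.
#' @param conf confidence level (default 0.95).
#' @return List: \code{mean}, \code{sd} (n-1 denominator), \code{ci}
#'   (length-2), \code{n}.
#' @export
stack_summary <- function(values, conf = 0.95) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values for a confidence interval")
  m <- mean(values); s <- stats::sd(values)
  list(mean = m, sd = s, ci = t_ci(m, s, n, conf), n = n)
}

#' t-based confidence interval from summary statistics
#'
#' \code{mean +/- t(1-(1-conf)/2, n-1) * sd / sqrt(n)}.
#'
#' @param mean,sd,n sample mean, sd and size.
#' @param conf confidence level (default 0.95).
#' @return Numeric length-2 vector (lower, upper).
#' @export
t_ci <- function(mean, sd, n, conf = 0.95) {
  if (n < 2) stop("need n >= 2")
  half <- stats::qt(1 - (1 - conf) / 2, df = n - 1) * sd / sqrt(n)
  c(mean - half, mean + half)
}

#' Cell density
#'
#' @param count non-negative cell count.
#' @param area sampled area in mm^2, positive.
#' @return Cells per mm^2.
#' @export
cell_density <- function(count, area) {
  if (any(area <= 0)) stop("area must be positive")
  count / area
}

#' Summaries of cell-cluster counts and areas by age group
#'
#' Per age group: mean cluster count per section with sd and t-based CI,
#' and median/quartiles (linear interpolation) of the pooled cluster areas.
#'
#' @param t data.frame with columns \code{age_group},
#'   \code{cluster_count} (per section) and optionally
#'   \code{cluster_areas} (list column of per-cluster areas, um^2).
#' @return data.frame, one row per non-empty age group.
#' @export
cluster_summary <- function(t) {
  stopifnot(all(c("age_group", "cluster_count") %in% names(t)))
  groups <- unique(t$age_group)
  rows <- lapply(groups, function(gr) {
    sub <- t[t$age_group == gr, , drop = FALSE]
    if (nrow(sub) == 0) {
      warning("empty age group ", gr, " omitted")
      return(NULL)
    }
    n <- nrow(sub)
    m <- mean(sub$cluster_count)
    s <- if (n >= 2) stats::sd(sub$cluster_count) else NA_real_
    ci <- if (n >= 2) t_ci(m, s, n) else c(NA_real_, NA_real_)
    areas <- if ("cluster_areas" %in% names(sub))
      unlist(sub$cluster_areas) else numeric(0)
    qa <- if (length(areas) > 0)
      stats::quantile(areas, c(0.25, 0.5, 0.75), type = 7)
    else rep(NA_real_, 3)
    data.frame(age_group = gr, n_sections = n, mean_count = m, sd_count = s,
               ci_lo = ci[1], ci_hi = ci[2], area_q25 = qa[1],
               area_median = qa[2], area_q75 = qa[3],
               n_clusters = length(areas), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classical one-way ANOVA
#'
#' Between/within decomposition with an F test (equal-variance).
#'
#' @param groups list of numeric vectors, one per group.
#' @return List: \code{F}, \code{df1}, \code{df2}, \code{p}.
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  ns <- lengths(groups)
  if (any(ns < 1) || sum(ns) <= length(groups))
    stop("need total n greater than the number of groups")
  dat <- data.frame(y = unlist(groups),
                    g = factor(rep(seq_along(groups), ns)))
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  if (ssw == 0) stop("zero within-group variance everywhere")
  fit <- stats::aov(y ~ g, data = dat)
  a <- stats::anova(fit)
  list(F = a$`F value`[1], df1 = a$Df[1], df2 = a$Df[2],
       p = a$`Pr(>F)`[1])
}

#' Fit a three-parameter exponential age trajectory
#'
#' Least squares fit of \code{y = a * exp(-b * age) + c} with the decay
#' rate constrained non-negative, via Levenberg-Marquardt from multiple
#' starting values.
#'
#' @param ages ages in years (>= 4 points, >= 3 distinct).
#' @param y response values (e.g. densities or percentages).
#' @return List of class \code{trajectory_fit}: \code{a}, \code{b},
#'   \code{c}, \code{rss}, \code{n}, \code{fitted_fn}.
#' @export
fit_exponential_trajectory <- function(ages, y) {
  stopifnot(length(ages) == length(y))
  if (length(ages) < 4 || length(unique(ages)) < 3)
    stop("need >= 4 points with >= 3 distinct ages")
  rng <- diff(range(ages))
  b_starts <- c(0, 0.5, 1, 2, 5, 20) / max(rng, 1)
  best <- NULL
  for (b0 in b_starts) {
    a0 <- max(y) - min(y); c0 <- min(y)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(-b * age) + c,
                        data = data.frame(age = ages, y = y),
                        start = list(a = a0, b = b0, c = c0),
                        lower = c(a = -Inf, b = 0, c = -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss)
        best <- list(fit = fit, rss = rss)
    }
  }
  # the flat curve (a = 0, b = 0, c = mean) is always a valid boundary
  # candidate; it also covers exactly-constant data, where the decay
  # amplitude is unidentifiable and the iterative fit cannot start
  flat_rss <- sum((y - mean(y))^2)
  if (is.null(best) || flat_rss <= best$rss) {
    co <- c(a = 0, b = 0, c = mean(y))
    rss <- flat_rss
  } else {
    co <- stats::coef(best$fit)
    rss <- best$rss
  }
  structure(list(a = unname(co["a"]), b = unname(co["b"]),
                 c = unname(co["c"]), rss = rss, n = length(y),
                 fitted_fn = function(age)
                   co["a"] * exp(-co["b"] * age) + co["c"]),
            class = "trajectory_fit")
}

#' Mixed-effects likelihood-ratio test for an age or region effect
#'
#' Fits (by maximum likelihood) the full model
#' \code{log(response) ~ age + region + (age | individual) + (age | section)}
#' and the nested model without the effect of interest, and compares them
#' with a likelihood-ratio test. Responses are log-transformed with an
#' offset of half the smallest positive value when zeros occur. Singular
#' random-slope fits are refit with intercept-only random effects
#' (flagged).
#'
#' @param t cell-count data.frame with columns \code{individual},
#'   \code{age}, \code{region}, \code{section} and the response.
#' @param response column name, or numeric vector of length
#'   \code{nrow(t)}; defaults to the density
#'   \code{marker_count / area_mm2}.
#' @param effect_of_interest \code{"age"} or \code{"region"}.
#' @param random_slopes include by-individual and by-section random slopes
#'   for age (default TRUE; reduced automatically when singular).
#' @return List: \code{chi2}, \code{df}, \code{p}, \code{full},
#'   \code{reduced}, \code{singular_refit}.
#' @export
lmm_age_region_lrt <- function(t, response = NULL,
                               effect_of_interest = c("age", "region"),
                               random_slopes = TRUE) {
  effect_of_interest <- match.arg(effect_of_interest)
  stopifnot(all(c("individual", "age", "region", "section") %in% names(t)))
  if (length(unique(t$individual)) < 4)
    stop("need at least 4 individuals")
  y <- if (is.null(response)) t$marker_count / t$area_mm2
  else if (is.character(response)) t[[response]] else response
  if (any(y < 0)) stop("response must be non-negative")
  delta <- if (any(y == 0)) min(y[y > 0]) / 2 else 0
  d <- data.frame(logy = log(y + delta), age = t$age,
                  region = factor(t$region),
                  individual = factor(t$individual),
                  section = factor(t$section))
  if (effect_of_interest == "region" && nlevels(d$region) < 2)
    stop("region has a single level; nothing to drop")

  fixed_full <- "age + region"
  fixed_red <- if (effect_of_interest == "age") "region" else "age"
  fit_pair <- function(re) {
    ctl <- lme4::lmerControl(calc.derivs = FALSE,
                             check.conv.singular =
                               lme4::.makeCC(action = "ignore", tol = 1e-4))
    full <- suppressWarnings(lme4::lmer(
      stats::as.formula(paste("logy ~", fixed_full, "+", re)),
      data = d, REML = FALSE, control = ctl))
    red <- suppressWarnings(lme4::lmer(
      stats::as.formula(paste("logy ~", fixed_red, "+", re)),
      data = d, REML = FALSE, control = ctl))
    list(full = full, red = red)
  }
  singular_refit <- FALSE
  re <- if (random_slopes) "(age | individual) + (age | section)"
  else "(1 | individual) + (1 | section)"
  fits <- fit_pair(re)
  if (random_slopes && (lme4::isSingular(fits$full, tol = 1e-4) ||
                        lme4::isSingular(fits$red, tol = 1e-4))) {
    singular_refit <- TRUE
    fits <- fit_pair("(1 | individual) + (1 | section)")
  }
  df <- length(lme4::fixef(fits$full)) - length(lme4::fixef(fits$red))
  if (df <= 0) stop("reduced model is not a proper submodel")
  chi2 <- max(0, 2 * (as.numeric(stats::logLik(fits$full)) -
                        as.numeric(stats::logLik(fits$red))))
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE),
       full = fits$full, reduced = fits$red,
       singular_refit = singular_refit)
}

#' Orientation summary of putative migratory neurons
#'
#' A cell counts as oriented "toward" the reference point (e.g. the PL
#' centroid) when the angle between its leading-process vector and the
#' vector from the cell to the reference is below \code{toward_thresh}
#' degrees. Tests toward-fraction = 0.5 with a two-sided exact binomial
#' test and reports the circular mean and mean resultant length of the
#' process angles.
#'
#' @param t data.frame with columns \code{x}, \code{y} (um),
#'   \code{process_angle} (degrees, 0-360), and optionally
#'   \code{process_length}.
#' @param reference length-2 numeric (x, y) of the reference point.
#' @param toward_thresh angular threshold in degrees (default 90).
#' @return List: \code{n}, \code{frac_toward}, \code{frac_away},
#'   \code{binom_p}, \code{circular_mean} (degrees),
#'   \code{resultant_length}, \code{n_excluded}.
#' @export
orientation_summary <- function(t, reference, toward_thresh = 90) {
  stopifnot(all(c("x", "y", "process_angle") %in% names(t)),
            length(reference) == 2)
  if (any(t$process_angle < 0 | t$process_angle >= 360))
    stop("angles must lie in [0, 360)")
  dx <- reference[1] - t$x
  dy <- reference[2] - t$y
  at_ref <- dx == 0 & dy == 0
  if (any(at_ref))
    warning(sum(at_ref), " cells at the reference point excluded")
  dx <- dx[!at_ref]; dy <- dy[!at_ref]
  ang <- t$process_angle[!at_ref] * pi / 180
  if (length(ang) == 0) stop("no cells with usable angles")
  # angle between unit process vector and cell-to-reference vector
  ref_ang <- atan2(dy, dx)
  delta <- abs(((ang - ref_ang + pi) %% (2 * pi)) - pi)
  toward <- delta < toward_thresh * pi / 180
  bt <- stats::binom.test(sum(toward), length(toward), p = 0.5)
  all_ang <- t$process_angle * pi / 180
  C <- mean(cos(all_ang)); S <- mean(sin(all_ang))
  list(n = length(toward), frac_toward = mean(toward),
       frac_away = 1 - mean(toward), binom_p = bt$p.value,
       circular_mean = (atan2(S, C) * 180 / pi) %% 360,
       resultant_length = sqrt(C^2 + S^2), n_excluded = sum(at_ref))
}
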