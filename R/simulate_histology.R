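# Synthetic histology cell-count tables: per-z-stack marker+ / DAPI+ counts
# whose marker fraction follows an exponential age trajectory
# p(age) = c + a * exp(-b * age), perturbed on the logit scale by donor and
# section random effects. Emulates confocal counting of immature-neuron and
# proliferation markers across post-mortem donors of different ages.

#' Configuration for the histology count simulator
#'
#' @param n_individuals number of donors.
#' @param ages donor ages in years; default evenly spans 0-77 years, the
#'   postnatal range over which marker+ cell decline is quantified.
#' @param stacks_per_individual confocal z-stacks counted per donor.
#' @param stacks_per_section z-stacks per tissue section; sections are the
#'   second grouping level of the mixed-effects analysis.
#' @param trajectory_a,trajectory_b,trajectory_c parameters of the mean
#'   marker+ probability \code{p(age) = c + a * exp(-b * age)}.
#' @param dapi_per_stack_mean Poisson mean of DAPI+ nuclei per stack.
#' @param stack_area_mm2 sampled area per z-stack (mm^2).
#' @param donor_logit_sd,section_logit_sd sd of donor- and section-level
#'   Gaussian perturbations of \code{qlogis(p(age))}.
#' @param seed RNG seed.
#' @return A list of class \code{histo_sim_config}.
#' @export
histo_sim_config <- function(n_individuals = 40, ages = NULL,
                             stacks_per_individual = 10,
                             stacks_per_section = 5,
                             trajectory_a = 0.8, trajectory_b = 0.2,
                             trajectory_c = 0.05,
                             dapi_per_stack_mean = 400, stack_area_mm2 = 0.04,
                             donor_logit_sd = 0.3, section_logit_sd = 0,
                             seed = 1L) {
  if (is.null(ages)) ages <- seq(0, 77, length.out = n_individuals)
  cfg <- list(n_individuals = n_individuals, ages = ages,
              stacks_per_individual = stacks_per_individual,
              stacks_per_section = stacks_per_section,
              trajectory_a = trajectory_a, trajectory_b = trajectory_b,
              trajectory_c = trajectory_c,
              dapi_per_stack_mean = dapi_per_stack_mean,
              stack_area_mm2 = stack_area_mm2,
              donor_logit_sd = donor_logit_sd,
              section_logit_sd = section_logit_sd, seed = as.integer(seed))
  validate_histo_sim_config(cfg)
  structure(cfg, class = "histo_sim_config")
}

validate_histo_sim_config <- function(cfg) {
  stopifnot(cfg$n_individuals >= 1, cfg$stacks_per_individual >= 1,
            cfg$stacks_per_section >= 1, cfg$dapi_per_stack_mean > 0,
            cfg$stack_area_mm2 > 0, cfg$donor_logit_sd >= 0,
            cfg$section_logit_sd >= 0,
            length(cfg$ages) == cfg$n_individuals)
  a <- cfg$trajectory_a; b <- cfg$trajectory_b; cc <- cfg$trajectory_c
  if (a == 0 && b == 0 && cc == 0) stop("degenerate trajectory: a = b = c = 0")
  p <- cc + a * exp(-b * range(cfg$ages))
  if (any(p <= 0 | p >= 1))
    stop("trajectory must keep p(age) inside (0, 1) over the age range")
  invisible(cfg)
}

#' Simulate per-z-stack histology counts with an exponential age trajectory
#'
#' Per stack, the DAPI+ count is Poisson and the marker+ count is binomial
#' with probability \code{plogis(qlogis(p(age)) + donor + section)} where
#' \code{p(age) = c + a * exp(-b * age)}. Stacks alternate between the MPL
#' and LPL subregions and are grouped into sections.
#'
#' @param config a \code{\link{histo_sim_config}}.
#' @return A list with \code{table} (data.frame: stack_id, individual, age,
#'   region, section, marker_count, dapi_count, area_mm2) and \code{truth}
#'   (trajectory parameters and the drawn donor/section effects).
#' @export
simulate_histology_counts <- function(config) {
  validate_histo_sim_config(config)
  with_seed(config$seed, simulate_histology_impl(config))
}

simulate_histology_impl <- function(cfg) {
  n_stacks <- cfg$n_individuals * cfg$stacks_per_individual
  ind <- rep(seq_len(cfg$n_individuals), each = cfg$stacks_per_individual)
  age <- cfg$ages[ind]
  stack_in_ind <- rep(seq_len(cfg$stacks_per_individual), cfg$n_individuals)
  section_in_ind <- (stack_in_ind - 1) %/% cfg$stacks_per_section + 1
  section <- paste0("D", ind, "_sec", section_in_ind)
  region <- rep_len(c("MPL", "LPL"), n_stacks)

  u_ind <- stats::rnorm(cfg$n_individuals, 0, cfg$donor_logit_sd)
  sec_levels <- unique(section)
  v_sec <- stats::rnorm(length(sec_levels), 0, cfg$section_logit_sd)
  names(v_sec) <- sec_levels

  p_mean <- cfg$trajectory_c + cfg$trajectory_a * exp(-cfg$trajectory_b * age)
  p <- stats::plogis(stats::qlogis(p_mean) + u_ind[ind] + v_sec[section])
  dapi <- stats::rpois(n_stacks, cfg$dapi_per_stack_mean)
  marker <- stats::rbinom(n_stacks, dapi, p)

  tab <- data.frame(
    stack_id = sprintf("Z%04d", seq_len(n_stacks)),
    individual = paste0("D", ind), age = age, region = region,
    section = section, marker_count = marker, dapi_count = dapi,
    area_mm2 = cfg$stack_area_mm2, stringsAsFactors = FALSE)
  truth <- list(a = cfg$trajectory_a, b = cfg$trajectory_b,
                c = cfg$trajectory_c, donor_effects = u_ind,
                section_effects = v_sec)
  list(table = tab, truth = truth)
}
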