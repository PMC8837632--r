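#' Design for the mixed-model power simulation
#'
#' Describes a nested ST study design: two patient groups, patients within
#' groups, replicate sections within patients, and spatially annotated spots
#' (niches) within sections. The simulated outcome follows
#' `y = beta * group + u_patient + v_section + eps` with independent normal
#' random effects; `beta = effect_size * sqrt(var_resid)` so effect sizes
#' are expressed in residual-SD units.
#'
#' @param n_patients_per_group patients per group.
#' @param n_sections_per_patient replicate sections per patient.
#' @param n_spots_per_condition annotated spots per section.
#' @param effect_size group effect in residual-SD units.
#' @param var_patient,var_section,var_resid variance components (>= 0;
#'   var_resid > 0).
#' @param alpha test level.
#' @param n_sim Monte-Carlo replicates (< 100 triggers a warning: the SE is
#'   then too large to resolve an 80% power target).
#' @param seed RNG seed.
#' @return list of class `power_design`.
#' @export
power_design <- function(n_patients_per_group = 3, n_sections_per_patient = 4,
                         n_spots_per_condition = 80, effect_size = 1,
                         var_patient = 0.5, var_section = 0.25,
                         var_resid = 1, alpha = 0.05, n_sim = 1000,
                         seed = 1) {
  stopifnot(n_patients_per_group >= 2, n_sections_per_patient >= 1,
            n_spots_per_condition >= 1, var_patient >= 0, var_section >= 0,
            var_resid > 0, alpha > 0, alpha < 1, n_sim >= 1)
  if (n_sim < 100)
    warning("n_sim < 100: Monte-Carlo SE too large for 80%-power decisions")
  structure(as.list(environment()), class = "power_design")
}

#' Monte-Carlo power of the group test under a nested mixed model
#'
#' For each replicate, simulates the nested design of [power_design()] and
#' tests the group effect with a Welch two-sample t test on patient means
#' (valid and conservative for nested designs; an optional `"lmm_wald"` mode
#' fits the random-intercept model with \pkg{lme4} and uses the Wald z test
#' on the group coefficient). Power is the rejection fraction at `alpha`.
#'
#' @param d a [power_design].
#' @param target power target for `reached_target` (default 0.8).
#' @param test `"patient_t"` (default) or `"lmm_wald"`.
#' @return list of class `power_result`: `power`, `monte_carlo_se`,
#'   `reached_target`, `n_sim`.
#' @export
simulate_power <- function(d, target = 0.8, test = c("patient_t", "lmm_wald")) {
  stopifnot(inherits(d, "power_design"))
  test <- match.arg(test)
  if (test == "lmm_wald" && !requireNamespace("lme4", quietly = TRUE))
    stop_spatlo("the lmm_wald mode requires the lme4 package",
                "spatlo_parameter_error")
  beta <- d$effect_size * sqrt(d$var_resid)
  np <- d$n_patients_per_group; ns <- d$n_sections_per_patient
  nr <- d$n_spots_per_condition
  reject <- logical(d$n_sim)
  with_sim_seed(d$seed, {
    for (i in seq_len(d$n_sim)) {
      # patients 1..np group 0; np+1..2np group 1
      u <- rnorm(2 * np, 0, sqrt(d$var_patient))
      pmeans <- numeric(2 * np)
      if (test == "lmm_wald") {
        dat <- NULL
        rows <- vector("list", 2 * np)
      }
      for (p in seq_len(2 * np)) {
        grp <- as.numeric(p > np)
        v <- rnorm(ns, 0, sqrt(d$var_section))
        eps <- matrix(rnorm(ns * nr, 0, sqrt(d$var_resid)), nrow = ns)
        y <- beta * grp + u[p] + v + eps  # ns x nr
        pmeans[p] <- mean(y)
        if (test == "lmm_wald")
          rows[[p]] <- data.frame(y = as.vector(t(y)), group = grp,
                                  patient = p,
                                  section = rep(seq_len(ns), each = nr))
      }
      if (test == "patient_t") {
        tt <- t.test(pmeans[seq_len(np)], pmeans[np + seq_len(np)])
        reject[i] <- tt$p.value < d$alpha
      } else {
        dat <- do.call(rbind, rows)
        dat$sec_id <- interaction(dat$patient, dat$section)
        fit <- suppressMessages(suppressWarnings(
          lme4::lmer(y ~ group + (1 | patient) + (1 | sec_id), data = dat,
                     REML = FALSE)))
        z <- stats::coef(summary(fit))["group", "t value"]
        reject[i] <- 2 * stats::pnorm(-abs(z)) < d$alpha
      }
    }
  })
  pw <- mean(reject)
  se <- sqrt(pw * (1 - pw) / d$n_sim)
  structure(list(power = pw, monte_carlo_se = se,
                 reached_target = pw >= target, n_sim = d$n_sim),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("power = %.3f (MC SE %.3f, n_sim = %d)%s\n", x$power,
              x$monte_carlo_se, x$n_sim,
              if (x$reached_target) " [target reached]" else ""))
  invisible(x)
}

#' Search a design grid for the smallest designs reaching a power target
#'
#' Evaluates [simulate_power()] for every design in the grid, sharing one
#' seed across designs (common random numbers, which keeps estimated power
#' monotone along each grid axis in practice), and returns the frontier:
#' designs meeting the target that are not dominated by a cheaper design
#' (fewer or equal patients, sections and spots) that also meets it.
#'
#' @param grid data.frame with columns n_patients_per_group,
#'   n_sections_per_patient, n_spots_per_condition; remaining design
#'   parameters are taken from `...`.
#' @param target power target (default 0.8).
#' @param ... passed to [power_design()] (effect_size, variances, n_sim,
#'   seed, ...).
#' @return list with `results` (grid + power, se, reached_target) and
#'   `frontier` (the undominated passing designs; empty with a message when
#'   none passes).
#' @export
design_search <- function(grid, target = 0.8, ...) {
  need <- c("n_patients_per_group", "n_sections_per_patient",
            "n_spots_per_condition")
  stopifnot(all(need %in% names(grid)))
  res <- grid
  res$power <- res$se <- NA_real_
  for (i in seq_len(nrow(grid))) {
    d <- power_design(n_patients_per_group = grid$n_patients_per_group[i],
                      n_sections_per_patient = grid$n_sections_per_patient[i],
                      n_spots_per_condition = grid$n_spots_per_condition[i],
                      ...)
    r <- simulate_power(d, target = target)
    res$power[i] <- r$power
    res$se[i] <- r$monte_carlo_se
  }
  res$reached_target <- res$power >= target
  pass <- res[res$reached_target, , drop = FALSE]
  if (!nrow(pass)) {
    message("no design in the grid reaches the power target")
    return(list(results = res, frontier = pass))
  }
  dominated <- vapply(seq_len(nrow(pass)), function(i) {
    any(vapply(seq_len(nrow(pass)), function(j) {
      j != i &&
        all(pass[j, need] <= pass[i, need]) &&
        any(pass[j, need] < pass[i, need])
    }, logical(1)))
  }, logical(1))
  list(results = res, frontier = pass[!dominated, , drop = FALSE])
}
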