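# Behavioural circadian models: acclimation-stage per-mouse profiles and the
# Bayesian natural-spline multilevel study model.

#' Model specification for one behaviour
#'
#' Intake and activity are modelled as Gaussian on the square-root scale;
#' the wake fraction with a beta distribution on the logit scale. Wake values
#' of exactly 0 or 1 are nudged into the open interval by half a second of a
#' 300 s block (epsilon = 1/600) before fitting.
#'
#' @param behaviour One of `"food"`, `"water"`, `"activity"`, `"wake"`.
#' @param sampler [sampler_settings()]; default the full preset.
#' @return list with `behaviour`, `family` (`"gaussian_sqrt"` or
#'   `"beta_logit"`) and `sampler`.
#' @export
model_spec <- function(behaviour, sampler = sampler_settings("full")) {
  behaviour <- match.arg(behaviour, BEHAVIOURS)
  list(behaviour = behaviour,
       family = if (behaviour == "wake") "beta_logit" else "gaussian_sqrt",
       sampler = sampler)
}

WAKE_EPS <- 1 / 600

transform_response <- function(value, family) {
  if (family == "gaussian_sqrt") {
    stop_if_not(all(value >= 0, na.rm = TRUE),
                "sqrt family requires non-negative responses")
    sqrt(value)
  } else {
    pmin(pmax(value, WAKE_EPS), 1 - WAKE_EPS)
  }
}

#' Back-transform a square-root-scale mean to the response scale
#'
#' If `sqrt(X) ~ Normal(mean_sqrt, var_sqrt)` then
#' `E[X] = mean_sqrt^2 + var_sqrt`; this is the exact back-transformation used
#' for all square-root-modelled behaviours.
#'
#' @param mean_sqrt Mean on the square-root scale.
#' @param var_sqrt Variance on the square-root scale (must be `>= 0`).
#' @return Expected value on the response scale.
#' @export
back_transform_sqrt <- function(mean_sqrt, var_sqrt) {
  stop_if_not(all(var_sqrt >= 0), "negative variance")
  mean_sqrt^2 + var_sqrt
}

#' Per-mouse acclimation behaviour profiles
#'
#' Models the acclimation period with the circadian natural-spline basis
#' interacted with pregnancy group plus a random intercept per mouse
#' (glmmTMB; Gaussian on the sqrt scale, beta with logit link for wake), and
#' returns each mouse's predicted profile on the link/transform scale at each
#' ZT hour (fixed curve plus that mouse's intercept). Mice absent from the
#' acclimation data receive the group-level curve with a warning.
#'
#' @param hourly Hourly series from [aggregate_records()] (any phases; the
#'   acclimation subset is used).
#' @param behaviour Behaviour to profile.
#' @param mice Optional data.frame (`mouse_id`, `group`) of mice that need
#'   profiles; defaults to the mice present in `hourly`.
#' @return data.table `mouse_id, zt_hour, accl` (link/transform scale).
#' @export
fit_acclimation <- function(hourly, behaviour, mice = NULL) {
  spec <- model_spec(behaviour)
  bh <- behaviour
  hall <- data.table::as.data.table(hourly)[behaviour == bh & !is.na(value)]
  h <- hall[phase == "acclimation"]
  stop_if_not(nrow(h) > 0, "no acclimation data for behaviour")
  if (is.null(mice)) {
    mice <- unique(data.frame(mouse_id = hall$mouse_id, group = hall$group))
  }
  d <- data.frame(y = transform_response(h$value, spec$family),
                  t = hour_centre(h$zt_hour),
                  group = factor(h$group, levels = intersect(GROUPS, unique(h$group))),
                  mouse = factor(h$mouse_id))
  multi_group <- nlevels(d$group) > 1
  form <- if (multi_group) y ~ circadian_basis(t) * group + (1 | mouse)
          else y ~ circadian_basis(t) + (1 | mouse)
  fam <- if (spec$family == "beta_logit") glmmTMB::beta_family() else stats::gaussian()
  fit <- glmmTMB::glmmTMB(form, data = d, family = fam)
  newd <- merge(mice, data.frame(zt_hour = 0:23))
  newd$t <- hour_centre(newd$zt_hour)
  newd$group <- factor(newd$group, levels = levels(d$group))
  newd$mouse <- newd$mouse_id  # unseen ids become new levels -> group curve
  unknown <- !(newd$mouse_id %in% levels(d$mouse))
  if (any(unknown)) {
    warning(sprintf("%d mouse(s) absent from acclimation data; using group curve",
                    length(unique(newd$mouse_id[unknown]))))
  }
  pr <- stats::predict(fit, newdata = newd, type = "link",
                       allow.new.levels = TRUE, re.form = NULL)
  data.table::data.table(mouse_id = newd$mouse_id, zt_hour = newd$zt_hour,
                         accl = as.numeric(pr))
}

# Design matrix for the study model: spline x group x block full interaction
# plus the centred acclimation covariate.
study_design <- function(d) {
  stats::model.matrix(~ circadian_basis(t) * group * block + accl, data = d)
}

# Near-likelihood-invariant ridge directions of the study design: fixed
# effects that are constant within mouse (intercept, group indicator, the
# acclimation deviation) trade against the mouse intercepts, and block-level
# indicators against the block-within-mouse intercepts. The samplers add
# Metropolis moves along these directions, which are identified only through
# the priors and otherwise dominate the autocorrelation time.
ridge_sweeps <- function(X, d, z1, z2) {
  q1 <- max(z1); q2 <- max(z2)
  per_unit <- function(z, v, q) {
    out <- numeric(q)
    out[z] <- v
    out
  }
  mouse_preg <- per_unit(z1, as.numeric(d$group == "pregnant"), q1)
  mouse_accl <- drop(rowsum(d$accl, z1) / tabulate(z1, q1))
  unit_block <- per_unit(z2, as.integer(d$block), q2)
  unit_preg <- per_unit(z2, as.numeric(d$group == "pregnant"), q2)
  cn <- colnames(X)
  sweeps <- list(list(col = 1L, re = 1L, load = rep(1, q1)))
  add <- function(sweeps, col_name, re, load) {
    j <- match(col_name, cn)
    if (!is.na(j)) sweeps[[length(sweeps) + 1L]] <- list(col = j, re = re, load = load)
    sweeps
  }
  sweeps <- add(sweeps, "accl", 1L, mouse_accl)
  sweeps <- add(sweeps, "grouppregnant", 1L, mouse_preg)
  for (b in c("2", "3")) {
    sweeps <- add(sweeps, paste0("block", b), 2L,
                  as.numeric(unit_block == as.integer(b)))
    sweeps <- add(sweeps, paste0("grouppregnant:block", b), 2L,
                  as.numeric(unit_block == as.integer(b)) * unit_preg)
  }
  sweeps
}

#' Fit the Bayesian natural-spline multilevel model for one behaviour
#'
#' Fixed effects: the circadian natural-spline basis in full interaction with
#' pregnancy group and study block, plus each mouse's acclimation profile as
#' a linear covariate correcting for individual variation; the profile is
#' centred within group x ZT hour so it carries each mouse's deviation from
#' its group's acclimation curve (the group curve itself belongs to the
#' spline terms). Random effects: nested intercepts, one per
#' mouse and one per study block within mouse. Sampling is by conjugate Gibbs
#' (Gaussian/sqrt family) or Metropolis-within-Gibbs seeded and
#' preconditioned by a ridge-penalised Fisher-scoring beta regression (beta
#' family). Convergence is
#' summarised by split-Rhat over all fixed-effect coefficients and the
#' dispersion parameter; fits with any Rhat above 1.05 are flagged.
#'
#' @param hourly Hourly series from [aggregate_records()] (study phase rows
#'   of `behaviour` are used).
#' @param accl Acclimation profiles from [fit_acclimation()] for the same
#'   behaviour.
#' @param spec A [model_spec()].
#' @param seed Integer seed for the sampler.
#' @return An object of class `circa_fit`: posterior draws of the fixed
#'   effects (`beta`, one row per retained draw) and dispersion (`sigma2` or
#'   `phi`), the design metadata needed for prediction, `rhat`, and
#'   `converged`.
#' @export
fit_behaviour_model <- function(hourly, accl, spec, seed = 1L) {
  h <- data.table::as.data.table(hourly)[behaviour == spec$behaviour &
                                           phase == "study" & !is.na(value) &
                                           !is.na(block)]
  stop_if_not(nrow(h) > 0, "no study data for behaviour")
  h <- merge(h, data.table::as.data.table(accl), by = c("mouse_id", "zt_hour"))
  cells <- h[, .(n_mice = length(unique(mouse_id))), by = .(group, block)]
  stop_if_not(all(cells$n_mice >= 2), ">= 2 mice per group x block required")
  # centre the acclimation profile within group x hour: the covariate should
  # carry each mouse's deviation from its group's acclimation curve, not the
  # group curve itself (which belongs to the spline x group fixed effects)
  h[, accl_dev := accl - mean(accl), by = .(group, zt_hour)]
  d <- data.frame(y = transform_response(h$value, spec$family),
                  t = hour_centre(h$zt_hour),
                  group = factor(h$group, levels = GROUPS),
                  block = factor(h$block, levels = 1:3),
                  accl = h$accl_dev,
                  mouse = factor(h$mouse_id))
  d$mouse_block <- interaction(d$mouse, d$block, drop = TRUE)
  X <- study_design(d)
  z1 <- as.integer(d$mouse)
  z2 <- as.integer(d$mouse_block)
  sweeps <- ridge_sweeps(X, d, z1, z2)
  if (spec$family == "gaussian_sqrt") {
    res <- gibbs_lmm(d$y, X, z1, z2, spec$sampler, seed, sweeps = sweeps)
    disp <- list(sigma2 = res$sigma2)
  } else {
    init <- beta_fisher_init(d$y, X)
    res <- mh_beta_mlm(d$y, X, z1, z2, spec$sampler, seed,
                       Vprop = init$V, beta_init = init$beta,
                       phi_init = init$phi, sweeps = sweeps)
    disp <- list(phi = res$phi)
  }
  rhat <- res$rhat
  structure(c(list(behaviour = spec$behaviour, family = spec$family,
                   spec = spec, beta = res$beta,
                   coef_names = colnames(X),
                   xlevels = list(group = levels(d$group), block = levels(d$block)),
                   rhat = rhat, converged = all(rhat <= 1.05),
                   accept = res$accept %||% NA_real_,
                   n_obs = nrow(d)),
              disp),
            class = "circa_fit")
}

#' Posterior fitted behaviour curves per group and study block
#'
#' Evaluates every retained posterior draw of the group x block mean curve on
#' a fine ZT grid (ZT6-ZT30, default step 0.05 h) at the average acclimation
#' covariate, and back-transforms to the response scale: for sqrt-family fits
#' each draw's curve is `eta^2 + sigma2_draw` (the exact sqrt-normal mean,
#' using that draw's residual variance); for the wake model the inverse-logit
#' of the linear predictor.
#'
#' @param fit A `circa_fit` from [fit_behaviour_model()].
#' @param step Grid step in hours.
#' @param force Evaluate curves even if the fit is flagged non-converged.
#' @return Object of class `posterior_curves`: list with `grid`, `behaviour`,
#'   and `cells`, a named list (`group.block`) of draw x grid matrices on the
#'   response scale.
#' @export
posterior_curves <- function(fit, step = ZT_GRID_STEP, force = FALSE) {
  stop_if_not(inherits(fit, "circa_fit"), "fit must be a circa_fit")
  if (!fit$converged && !force) {
    stop("fit flagged as non-converged (max split-Rhat ",
         sprintf("%.3f", max(fit$rhat)), "); pass force = TRUE to override",
         call. = FALSE)
  }
  grid <- zt_grid(step)
  cells <- list()
  for (g in fit$xlevels$group) {
    for (b in fit$xlevels$block) {
      nd <- data.frame(t = grid,
                       group = factor(g, levels = fit$xlevels$group),
                       block = factor(b, levels = fit$xlevels$block),
                       accl = 0)
      Xg <- study_design(nd)
      stopifnot(identical(colnames(Xg), fit$coef_names))
      eta <- fit$beta %*% t(Xg)
      resp <- if (fit$family == "gaussian_sqrt") eta^2 + fit$sigma2
              else stats::plogis(eta)
      cells[[paste(g, b, sep = ".")]] <- resp
    }
  }
  structure(list(grid = grid, behaviour = fit$behaviour, family = fit$family,
                 cells = cells),
            class = "posterior_curves")
}

#' Plot-ready summary of posterior curves
#'
#' Pointwise posterior mean and 2.5%/97.5% quantiles of the fitted curves on
#' the response scale, per group and study block.
#'
#' @param pc A [posterior_curves()] object.
#' @return data.table: `behaviour, group, block, zt, mean, lo, hi`.
#' @export
curves_to_report <- function(pc) {
  stop_if_not(inherits(pc, "posterior_curves"), "need a posterior_curves object")
  out <- list()
  for (nm in names(pc$cells)) {
    M <- pc$cells[[nm]]
    stop_if_not(nrow(M) > 0, "empty draw set")
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    qs <- apply(M, 2, stats::quantile, probs = c(0.025, 0.975))
    out[[nm]] <- data.table::data.table(
      behaviour = pc$behaviour, group = parts[1], block = as.integer(parts[2]),
      zt = pc$grid, mean = colMeans(M), lo = qs[1, ], hi = qs[2, ])
  }
  data.table::rbindlist(out)
}
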