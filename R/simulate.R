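#' Titrant dosing schedule for the simulator
#'
#' Two dosing modes are supported. \code{"setpoint"} emulates a dynamic
#' endpoint auto-titrator: the instrument doses whatever volume drives the
#' vessel to each target pH in turn (volumes follow in closed form from the
#' charge balance). \code{"fixed"} dispenses constant volume increments.
#' Setpoint dosing is the default because it samples forward and reverse
#' runs at identical pH values, which is what makes their overlay a clean
#' hysteresis check.
#'
#' Both modes start the forward (base-direction) run after an acid pre-dose
#' that sets the acidic starting pH; the reverse (acid-direction) run starts
#' from the forward run's final base charge and titrates back down with acid.
#'
#' @param mode \code{"setpoint"} (default) or \code{"fixed"}.
#' @param targets Target pH values for setpoint mode (default pH 3.0 to 10.6
#'   every 0.1 unit, a superset of the 0.2-unit fit grid). Targets the
#'   dosing cannot reach (e.g. below the starting pH) are skipped.
#' @param acid_predose Acid volume (L) added before the forward run
#'   (default 3e-5 L of the 0.1 M titrant, i.e. ~pH 3.2 in a blank vessel).
#' @param n_steps,base_step,acid_step Fixed-mode parameters: number of
#'   increments and per-step volumes (L) for the base and acid titrant.
#' @return An object of class \code{titration_schedule}.
#' @export
titration_schedule <- function(mode = c("setpoint", "fixed"),
                               targets = seq(3.0, 10.6, by = 0.1),
                               acid_predose = 3e-5,
                               n_steps = 100, base_step = 1.5e-4,
                               acid_step = 1.5e-5) {
  mode <- match.arg(mode)
  stop_unless(acid_predose >= 0, "acid_predose must be non-negative")
  if (mode == "setpoint") {
    stop_unless(length(targets) >= 3 && all(diff(sort(targets)) > 0),
                "targets must be at least 3 distinct pH values")
    stop_unless(all(targets > 0 & targets < 14), "targets must lie in (0, 14)")
  } else {
    stop_unless(n_steps >= 3, "n_steps must be at least 3")
    stop_unless(base_step > 0 && acid_step > 0, "step volumes must be positive")
  }
  structure(list(mode = mode, targets = sort(targets),
                 acid_predose = acid_predose, n_steps = as.integer(n_steps),
                 base_step = base_step, acid_step = acid_step),
            class = "titration_schedule")
}

#' Specification of a synthetic titration experiment
#'
#' Bundles the ground-truth ligand spectrum, vessel configuration, dosing
#' schedule, measurement-noise model and seed that define a reproducible
#' simulated titration experiment (forward and reverse runs, replicated).
#'
#' @param truth A \code{\link{ligand_spectrum}} (mol/g) — the ground truth.
#' @param config A \code{\link{vessel_config}}.
#' @param schedule A \code{\link{titration_schedule}}.
#' @param noise List with \code{pH_sd} (additive Gaussian sd on recorded pH,
#'   default 0.02, typical glass-electrode repeatability) and
#'   \code{volume_sd} (multiplicative Gaussian sd on each dispensed volume,
#'   default 0.005).
#' @param n_replicates Number of replicate titrations (default 3).
#' @param seed Integer seed; a fixed seed makes the output reproducible to
#'   the byte.
#' @param sample_id Label carried through to the generated curves.
#' @return An object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(truth, config = vessel_config(eps_mass = 0.05),
                           schedule = titration_schedule(),
                           noise = list(pH_sd = 0.02, volume_sd = 0.005),
                           n_replicates = 3, seed = 1,
                           sample_id = "synthetic") {
  stop_unless(is_ligand_spectrum(truth), "truth must be a ligand_spectrum")
  stop_unless(is_vessel_config(config), "config must be a vessel_config")
  stop_unless(inherits(schedule, "titration_schedule"),
              "schedule must be a titration_schedule")
  stop_unless(is.numeric(noise$pH_sd) && noise$pH_sd >= 0 &&
                is.numeric(noise$volume_sd) && noise$volume_sd >= 0,
              "noise sds must be non-negative")
  stop_unless(n_replicates >= 1, "n_replicates must be at least 1")
  structure(list(truth = truth, config = config, schedule = schedule,
                 noise = noise, n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), sample_id = as.character(sample_id)),
            class = "synthetic_spec")
}

is_synthetic_spec <- function(x) inherits(x, "synthetic_spec")

#' Equilibrium pH of the vessel at given titrant concentrations
#'
#' Solves the charge balance
#' (Cb - Ca + [H+] - Kw/[H+]) = sum_i Ka_i l_i / (Ka_i + [H+]) + s
#' for pH, where l_i = L_Ti * m / V and s = S * m / V are the
#' solution-phase concentrations of the EPS binding sites. The residual is
#' strictly decreasing in pH, so the root in (0, 14) is unique; it is
#' bracketed and then polished by Newton steps to |residual| <= 1e-13 M.
#'
#' @param truth A \code{\link{ligand_spectrum}} (mol/g).
#' @param Ca,Cb Acid and base concentrations in the vessel (mol/L), >= 0.
#' @param config A \code{\link{vessel_config}}.
#' @param total_volume Total vessel volume (L) used to convert per-gram site
#'   concentrations into solution concentrations; defaults to
#'   \code{config$initial_volume}.
#' @return The equilibrium pH (scalar).
#' @examples
#' cfg <- vessel_config(eps_mass = 0.05)
#' blank <- ligand_spectrum(numeric(0), numeric(0), S = 0)
#' solve_equilibrium_pH(blank, Ca = 1e-4, Cb = 0, cfg)   # ~4.0, strong acid
#' @export
solve_equilibrium_pH <- function(truth, Ca, Cb, config,
                                 total_volume = config$initial_volume) {
  stop_unless(is_ligand_spectrum(truth), "truth must be a ligand_spectrum")
  stop_unless(Ca >= 0 && Cb >= 0, "Ca and Cb must be non-negative")
  m <- config$eps_mass
  l <- truth$sites$L_T * m / total_volume
  s <- truth$S * m / total_volume
  Ka <- 10^(-truth$sites$pKa)

  f <- function(pH) {
    h <- proton_concentration(pH, config)
    oh <- hydroxide_concentration(pH, config)
    occ <- if (length(l)) sum(Ka * l / (Ka + h)) else 0
    (Cb - Ca + h - oh) - (occ + s)
  }
  lo <- 1e-3; hi <- 14 - 1e-3
  flo <- f(lo); fhi <- f(hi)
  if (!(flo > 0 && fhi < 0)) {
    stop("charge balance has no root in (0, 14) for this configuration",
         call. = FALSE)
  }
  pH <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  # Newton polish on pH: d f / d pH = -ln(10) * h * (1 + Kw/h^2 + sum Ka l/(Ka+h)^2)
  for (i in 1:40) {
    fx <- f(pH)
    if (abs(fx) <= 1e-13) break
    h <- proton_concentration(pH, config)
    oh <- hydroxide_concentration(pH, config)
    dsite <- if (length(l)) sum(Ka * l / (Ka + h)^2) else 0
    fp <- -log(10) * h * (1 + oh / h + dsite)
    step <- fx / fp
    pH_new <- pH - step
    if (!is.finite(pH_new) || pH_new <= 0 || pH_new >= 14) break
    pH <- pH_new
  }
  pH
}

# Closed-form titrant volume that brings the vessel to a target pH.
# From the charge balance multiplied through by the total volume:
#   cb*Vb - ca*Va = m*(sum occ_i L_i + S) + (OH - H)*(V0 + Va + Vb)
# which is linear in the unknown volume because site occupancies depend on
# pH only. Returns NA when the dose would be negative or unattainable.
setpoint_volume <- function(truth, pH, config, fixed_acid = NULL,
                            fixed_base = NULL) {
  h <- proton_concentration(pH, config)
  oh <- hydroxide_concentration(pH, config)
  occ <- if (nrow(truth$sites)) {
    sum(10^(-truth$sites$pKa) * truth$sites$L_T /
          (10^(-truth$sites$pKa) + h))
  } else 0
  g <- config$eps_mass * (occ + truth$S)
  w <- oh - h
  V0 <- config$initial_volume
  if (!is.null(fixed_acid)) {                   # solve for base volume
    ca <- config$acid_titrant_conc; cb <- config$base_titrant_conc
    denom <- cb - w
    if (denom <= 1e-6) return(NA_real_)
    Vb <- (g + w * (V0 + fixed_acid) + ca * fixed_acid) / denom
    if (!is.finite(Vb) || Vb < 0) NA_real_ else Vb
  } else {                                      # solve for acid volume
    ca <- config$acid_titrant_conc; cb <- config$base_titrant_conc
    denom <- ca + w
    if (denom <= 1e-6) return(NA_real_)
    Va <- (cb * fixed_base - g - w * (V0 + fixed_base)) / denom
    if (!is.finite(Va) || Va < 0) NA_real_ else Va
  }
}

#' Simulate replicate forward/reverse titration curves
#'
#' Generates titration curves with known ground truth by walking the dosing
#' schedule, computing the equilibrium pH of the vessel after each addition
#' (charge balance solved for [H+]), and perturbing the record with the
#' configured measurement noise: multiplicative Gaussian noise on each
#' dispensed volume, then additive Gaussian noise on the recorded pH
#' (clamped to (0, 14)). The acid pre-dose is treated as exact.
#'
#' The forward run titrates base upward from the acid pre-dose; the reverse
#' run starts from the forward run's final base charge and titrates acid
#' back down. With zero noise, replicate curves are identical and
#' (in setpoint mode) sampled exactly at the target pH values.
#'
#' Randomness is fully governed by \code{spec$seed}: one substream seed is
#' drawn per replicate and direction, so output is byte-reproducible. The
#' caller's RNG state is preserved.
#'
#' @param spec A \code{\link{synthetic_spec}}.
#' @return Named list of \code{\link{titration_curve}} objects
#'   (\code{rep<k>_forward}, \code{rep<k>_reverse}).
#' @export
simulate_titration <- function(spec) {
  stop_unless(is_synthetic_spec(spec), "spec must be a synthetic_spec")
  cfg <- spec$config; sch <- spec$schedule; truth <- spec$truth

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  sub_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 spec$n_replicates * 2L),
                      nrow = spec$n_replicates)

  Va0 <- sch$acid_predose
  if (sch$mode == "setpoint") {
    fw_targets <- sch$targets
    fw_Vb <- vapply(fw_targets, function(p)
      setpoint_volume(truth, p, cfg, fixed_acid = Va0), numeric(1))
    keep <- logical(length(fw_Vb)); last <- 0
    for (i in seq_along(fw_Vb)) {
      if (!is.na(fw_Vb[i]) && fw_Vb[i] > last + 1e-12) {
        keep[i] <- TRUE; last <- fw_Vb[i]
      }
    }
    stop_unless(sum(keep) >= 3, "fewer than 3 attainable setpoints in forward run")
    fw_targets <- fw_targets[keep]; fw_Vb <- fw_Vb[keep]
    Vb_end <- fw_Vb[length(fw_Vb)]

    rv_targets <- rev(sch$targets)
    rv_Va <- vapply(rv_targets, function(p)
      setpoint_volume(truth, p, cfg, fixed_base = Vb_end), numeric(1))
    keep <- logical(length(rv_Va)); last <- Va0
    for (i in seq_along(rv_Va)) {
      if (!is.na(rv_Va[i]) && rv_Va[i] > last + 1e-12) {
        keep[i] <- TRUE; last <- rv_Va[i]
      }
    }
    stop_unless(sum(keep) >= 3, "fewer than 3 attainable setpoints in reverse run")
    rv_targets <- rv_targets[keep]; rv_Va <- rv_Va[keep]
  } else {
    fw_Vb <- sch$base_step * seq_len(sch$n_steps)
    fw_targets <- NULL
    Vb_end <- fw_Vb[length(fw_Vb)]
    rv_Va <- Va0 + sch$acid_step * seq_len(sch$n_steps)
    rv_targets <- NULL
  }

  make_run <- function(rseed, direction) {
    set.seed(rseed, kind = "Mersenne-Twister", normal.kind = "Inversion")
    if (direction == "forward") {
      base_vol <- fw_Vb; ref <- 0; targets <- fw_targets
    } else {
      base_vol <- rv_Va; ref <- Va0; targets <- rv_targets
    }
    inc <- diff(c(ref, base_vol))
    if (spec$noise$volume_sd > 0) {
      inc <- pmax(inc * (1 + stats::rnorm(length(inc), 0, spec$noise$volume_sd)),
                  1e-12)
    }
    vol <- ref + cumsum(inc)
    if (direction == "forward") {
      va <- rep(Va0, length(vol)); vb <- vol
    } else {
      va <- vol; vb <- rep(Vb_end, length(vol))
    }
    exact_volumes <- spec$noise$volume_sd == 0
    if (sch$mode == "setpoint" && exact_volumes) {
      pH_true <- targets
    } else {
      tc <- titrant_concentrations(va, vb, cfg)
      pH_true <- vapply(seq_along(vol), function(i)
        solve_equilibrium_pH(truth, tc$Ca[i], tc$Cb[i], cfg,
                             total_volume = tc$V_total[i]),
        numeric(1))
    }
    pH_obs <- pH_true
    if (spec$noise$pH_sd > 0) {
      pH_obs <- pH_obs + stats::rnorm(length(pH_obs), 0, spec$noise$pH_sd)
    }
    pH_obs <- pmin(pmax(pH_obs, 1e-3), 14 - 1e-3)
    titration_curve(spec$sample_id, NA, direction, cfg,
                    data.frame(acid_volume_L = va, base_volume_L = vb,
                               pH = pH_obs))
  }

  out <- list()
  for (r in seq_len(spec$n_replicates)) {
    fw <- make_run(sub_seeds[r, 1], "forward")
    rv <- make_run(sub_seeds[r, 2], "reverse")
    fw$replicate_id <- as.character(r)
    rv$replicate_id <- as.character(r)
    out[[sprintf("rep%d_forward", r)]] <- fw
    out[[sprintf("rep%d_reverse", r)]] <- rv
  }
  out
}

#' Named preset synthetic experiments
#'
#' Ships ready-made \code{\link{synthetic_spec}}s with documented ground
#' truth, parameterized to the magnitudes observed for mat EPS
#' functional-group loads (fractions of a mMol per gram, amine-dominated):
#' \describe{
#'   \item{minimal}{A single site at pKa 6.0 with L_T = 0.1 mmol/g, S = 0,
#'     zero noise, one replicate — the smallest end-to-end fixture.}
#'   \item{march-like}{Carboxyl-poor mixture: carboxyl 0.113, phosphoryl
#'     0.149, amine 0.845 mmol/g; default noise, triplicate.}
#'   \item{october-like}{Carboxyl-rich mixture: carboxyl class total
#'     0.461 mmol/g (two sites), phosphoryl 0.260, amine 0.721 mmol/g;
#'     default noise, triplicate.}
#' }
#'
#' @param seed Base seed; presets use \code{seed}, \code{seed + 1},
#'   \code{seed + 2}.
#' @return Named list of \code{\link{synthetic_spec}} objects.
#' @export
preset_specs <- function(seed = 101) {
  cfg <- vessel_config(eps_mass = 0.05)
  list(
    "minimal" = synthetic_spec(
      truth = ligand_spectrum(6.0, 1e-4, S = 0),
      config = cfg,
      noise = list(pH_sd = 0, volume_sd = 0),
      n_replicates = 1, seed = seed, sample_id = "minimal"),
    "march-like" = synthetic_spec(
      truth = ligand_spectrum(c(4.8, 7.0, 8.4),
                              c(0.113e-3, 0.149e-3, 0.845e-3), S = 5e-6),
      config = cfg,
      n_replicates = 3, seed = seed + 1, sample_id = "march-like"),
    "october-like" = synthetic_spec(
      truth = ligand_spectrum(c(4.6, 5.4, 6.8, 8.4),
                              c(0.250e-3, 0.211e-3, 0.260e-3, 0.721e-3),
                              S = 1e-5),
      config = cfg,
      n_replicates = 3, seed = seed + 2, sample_id = "october-like"))
}
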