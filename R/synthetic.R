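# Seeded synthetic stability study. Accelerated storage of PEO matrices
# degrades the polymer (chain scission by auto-oxidation), which shows up
# as faster drug release at longer storage times. The generator emulates
# that phenomenologically: each (drug, grade) arm has a base release model
# at storage 0, and an ageing rule perturbs the model parameters per
# storage week. It makes no attempt to reproduce the physics, only the
# qualitative regimes: strongly destabilised (soluble drug), borderline
# (moderately soluble drug on the low-MW grade) and stable release.

#' Ageing rule for a release model
#'
#' Two-knob parametric ageing: the rate coefficient k is accelerated
#' multiplicatively (`k' = k (1 + alpha * weeks)`) and the release exponent
#' n drifts additively (`n' = n + beta * weeks`). This is the simplest
#' family able to span both the "faster release after storage" and the
#' "unchanged release" regimes seen across drug solubility classes.
#'
#' @param alpha Fractional acceleration of k per storage week (>= 0).
#' @param beta Additive drift of n per storage week (power law only).
#' @return An object of class `ageing_rule`.
#' @export
ageing_rule <- function(alpha, beta = 0) {
  if (!is.numeric(alpha) || alpha < 0)
    dk_config_error("alpha must be >= 0, got %s", alpha)
  structure(list(alpha = alpha, beta = beta), class = "ageing_rule")
}

#' Apply an ageing rule to a release model
#'
#' @param model A [release_model()].
#' @param rule An [ageing_rule()].
#' @param weeks Storage time in weeks.
#' @return The aged [release_model()]; identical to `model` at `weeks = 0`
#'   or under the zero rule. The drifted exponent is clipped to the model's
#'   validity range (0, 1.2].
#' @examples
#' m <- release_model("power_law", k = 5, n = 0.5)
#' apply_ageing(m, ageing_rule(alpha = 0.1), weeks = 8)$k  # 9
#' @export
apply_ageing <- function(model, rule, weeks) {
  stopifnot(inherits(model, "release_model"), inherits(rule, "ageing_rule"))
  if (weeks < 0) dk_config_error("weeks must be >= 0, got %s", weeks)
  k2 <- model$k * (1 + rule$alpha * weeks)
  if (!is.finite(k2) || k2 <= 0)
    dk_config_error("ageing produced invalid rate coefficient k = %s", k2)
  model$k <- k2
  if (model$law == "power_law" && rule$beta != 0) {
    model$n <- min(1.2, max(1e-6, model$n + rule$beta * weeks))
  }
  model
}

#' Default synthetic study configuration
#'
#' The built-in configuration reproduces the structure and the qualitative
#' behaviour of a 3-drug x 2-polymer-grade x 4-storage-time accelerated
#' stability study of 1:1 drug/PEO matrix tablets:
#'
#' * drugs spanning three solubility classes -- propranolol (50 mg/ml,
#'   high), theophylline (8 mg/ml, moderate), zonisamide (0.8 mg/ml, poor);
#' * PEO grades 750 (MW 3e5) and 303 (MW 7e6);
#' * storage 0/2/4/8 weeks at 40 C, 3 replicate tablets per arm;
#' * the USP paddle sampling schedule of [default_grid()].
#'
#' Base models are power laws calibrated so the fresh noiseless curves hit
#' the study's headline release anchors (propranolol/750 reaches 50% at
#' 2 h; propranolol/303 reaches 60% at 6 h; zonisamide/750 is complete
#' within 5 h), and the default ageing rules are calibrated so the 8-week
#' f2-versus-fresh verdicts reproduce the expected stability pattern: both
#' propranolol arms destabilised (dissimilar at every storage time),
#' theophylline destabilised on the low-MW grade only (similar at 2 weeks,
#' dissimilar later) and stable on 303, zonisamide stable on both grades.
#'
#' @param noise_sd Additive Gaussian noise (in release percentage points)
#'   applied to every sampled point before monotonicity repair; default 1.5.
#' @param replicates_per_arm Replicate tablets per arm; default 3.
#' @param seed Base seed for the generator; default 42.
#' @return A `generator_config` list with elements `design`, `base_models`,
#'   `ageing`, `noise_sd`, `seed`.
#' @export
default_config <- function(noise_sd = 1.5, replicates_per_arm = 3, seed = 42) {
  drugs <- c("propranolol", "theophylline", "zonisamide")
  grades <- c("750", "303")
  weeks <- c(0, 2, 4, 8)
  arms <- list()
  for (d in drugs) for (g in grades) for (w in weeks)
    arms[[length(arms) + 1L]] <- study_arm(d, g, w)
  design <- study_design(arms, replicates_per_arm = replicates_per_arm,
                         sampling_grid = default_grid())

  # Fresh-tablet power laws, anchored to the headline release milestones.
  base_models <- list(
    "propranolol|750"  = release_model("power_law", k = 50 / 120^0.60, n = 0.60),
    "propranolol|303"  = release_model("power_law", k = 60 / 360^0.45, n = 0.45),
    "theophylline|750" = release_model("power_law", k = 40 / 120^0.55, n = 0.55),
    "theophylline|303" = release_model("power_law", k = 60 / 720^0.45, n = 0.45),
    "zonisamide|750"   = release_model("power_law", k = 100 / 240^0.89, n = 0.89),
    "zonisamide|303"   = release_model("power_law", k = 55 / 720^0.45, n = 0.45)
  )

  # Ageing acceleration per week, by arm. Large alpha = polymer strongly
  # destabilised by storage; small alpha = essentially stable release.
  ageing <- list(
    "propranolol|750"  = ageing_rule(alpha = 0.15),
    "propranolol|303"  = ageing_rule(alpha = 0.30),
    "theophylline|750" = ageing_rule(alpha = 0.05),
    "theophylline|303" = ageing_rule(alpha = 0.02),
    "zonisamide|750"   = ageing_rule(alpha = 0.02),
    "zonisamide|303"   = ageing_rule(alpha = 0.02)
  )

  generator_config(design, base_models, ageing,
                   noise_sd = noise_sd, seed = seed)
}

#' Construct a generator configuration
#'
#' @param design A [study_design()].
#' @param base_models Named list of [release_model()] objects, keyed
#'   `"drug|grade"`, giving the fresh (storage 0) model of each arm family.
#' @param ageing Named list of [ageing_rule()] objects on the same keys.
#' @param noise_sd Additive Gaussian noise sd in release percentage points.
#' @param seed Base seed.
#' @return A `generator_config` object.
#' @export
generator_config <- function(design, base_models, ageing,
                             noise_sd = 1.5, seed = 42) {
  stopifnot(inherits(design, "study_design"))
  if (noise_sd < 0) dk_config_error("noise_sd must be >= 0")
  for (arm in design$arms) {
    key <- paste(arm$drug_name, arm$polymer_grade, sep = "|")
    if (is.null(base_models[[key]]))
      dk_config_error("no base release model for arm family %s", key)
    if (is.null(ageing[[key]]))
      dk_config_error("no ageing rule for arm family %s", key)
  }
  structure(list(design = design, base_models = base_models,
                 ageing = ageing, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Stable 31-ary string hash mod (2^31 - 1). Used to derive a per-replicate
# RNG substream from the arm key, so adding arms to a design never perturbs
# the draws of existing arms. Exact in double arithmetic (h < 2^31, so
# h * 31 + byte < 2^36 << 2^53).
stable_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  h
}

#' Generate a complete synthetic stability study
#'
#' For every arm of the design and every replicate: age the arm family's
#' base model by the arm's storage time, evaluate it on the sampling grid,
#' add seeded Gaussian noise (none at t = 0), then clip and repair to a
#' monotone cumulative curve. Output is byte-reproducible for a fixed seed,
#' and each (arm, replicate) draws from its own RNG substream keyed by a
#' stable hash of its identity.
#'
#' @param config A `generator_config`, e.g. [default_config()].
#' @param noise_sd Optional override of the configured noise sd (use 0 for
#'   noiseless output).
#' @return A list of class `dissolution_study` with elements `profiles`
#'   (list of [dissolution_profile()]) and `design`.
#' @examples
#' study <- generate_study(default_config(), noise_sd = 0)
#' length(study$profiles)  # 24 arms x 3 replicates
#' @export
generate_study <- function(config, noise_sd = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(noise_sd)) noise_sd <- config$noise_sd
  grid <- config$design$sampling_grid
  profiles <- list()
  for (arm in config$design$arms) {
    key <- paste(arm$drug_name, arm$polymer_grade, sep = "|")
    aged <- apply_ageing(config$base_models[[key]], config$ageing[[key]],
                         arm$storage_weeks)
    for (rep in seq_len(config$design$replicates_per_arm)) {
      clean <- simulate_release(aged, grid, arm = arm, replicate_id = rep)
      y <- clean$release
      if (noise_sd > 0) {
        sub <- paste(arm_key(arm), rep, sep = "|")
        set.seed((config$seed + stable_hash(sub)) %% 2147483647)
        eps <- stats::rnorm(length(y), sd = noise_sd)
        eps[grid == 0] <- 0
        y <- pmin(110, pmax(0, y + eps))
      }
      p <- dissolution_profile(grid, y, arm = arm, replicate_id = rep)
      profiles[[length(profiles) + 1L]] <- validate_and_repair(p, tolerance = Inf)
    }
  }
  structure(list(profiles = profiles, design = config$design),
            class = "dissolution_study")
}

#' @export
print.dissolution_study <- function(x, ...) {
  cat(sprintf("<dissolution_study> %d profiles (%d arms x %d replicates)\n",
              length(x$profiles), length(x$design$arms),
              x$design$replicates_per_arm))
  invisible(x)
}

#' Read / write a generator configuration as YAML
#'
#' The YAML mirrors the `generator_config` structure: `design` (arms,
#' replicates, sampling grid), `base_models`, `ageing`, `noise_sd`, `seed`.
#'
#' @param path YAML file path.
#' @return `read_config` returns a `generator_config`; `write_config`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) dk_io_error("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  arms <- lapply(raw$design$arms, function(a)
    study_arm(a$drug_name, a$polymer_grade, a$storage_weeks,
              solubility = a$solubility, polymer_mw = a$polymer_mw,
              storage_temp_c = if (is.null(a$storage_temp_c)) 40 else a$storage_temp_c))
  design <- study_design(arms,
                         replicates_per_arm = raw$design$replicates_per_arm,
                         sampling_grid = unlist(raw$design$sampling_grid))
  base_models <- lapply(raw$base_models, function(m)
    release_model(m$law, k = m$k, n = m$n,
                  plateau = if (is.null(m$plateau)) 100 else m$plateau))
  ageing <- lapply(raw$ageing, function(r)
    ageing_rule(alpha = r$alpha, beta = if (is.null(r$beta)) 0 else r$beta))
  generator_config(design, base_models, ageing,
                   noise_sd = raw$noise_sd, seed = raw$seed)
}

#' @rdname read_config
#' @param config A `generator_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "generator_config"))
  out <- list(
    design = list(
      arms = lapply(config$design$arms, function(a) unclass(a)),
      replicates_per_arm = config$design$replicates_per_arm,
      sampling_grid = config$design$sampling_grid),
    base_models = lapply(config$base_models, function(m) unclass(m)),
    ageing = lapply(config$ageing, function(r) unclass(r)),
    noise_sd = config$noise_sd,
    seed = config$seed)
  yaml::write_yaml(out, path)
  invisible(path)
}
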