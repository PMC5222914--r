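#' Study arm metadata
#'
#' A study arm is one cell of the stability-study factorial: a drug, a
#' polymer grade and a storage time at elevated temperature. Dissolution
#' profiles carry a `study_arm` so that statistics can be keyed back to the
#' design.
#'
#' @param drug_name Drug label, e.g. `"propranolol"`.
#' @param polymer_grade Polymer grade label, e.g. `"750"` or `"303"`.
#' @param storage_weeks Weeks of accelerated storage (0 = fresh reference).
#' @param solubility Aqueous solubility of the drug in mg/ml. Looked up from
#'   the built-in drug table when `NULL` and the drug is known.
#' @param polymer_mw Polymer molecular weight in g/mol. Looked up from the
#'   built-in grade table when `NULL` and the grade is known.
#' @param storage_temp_c Storage temperature in degrees Celsius.
#' @return An object of class `study_arm`.
#' @examples
#' study_arm("propranolol", "750", storage_weeks = 2)
#' @export
study_arm <- function(drug_name, polymer_grade, storage_weeks,
                      solubility = NULL, polymer_mw = NULL,
                      storage_temp_c = 40) {
  drug_name <- as.character(drug_name)[1]
  polymer_grade <- as.character(polymer_grade)[1]
  if (is.null(solubility)) {
    solubility <- .drug_solubility[[drug_name]]
    if (is.null(solubility)) solubility <- NA_real_
  }
  if (is.null(polymer_mw)) {
    polymer_mw <- .grade_mw[[polymer_grade]]
    if (is.null(polymer_mw)) polymer_mw <- NA_real_
  }
  storage_weeks <- as.numeric(storage_weeks)[1]
  if (is.na(storage_weeks) || storage_weeks < 0)
    dk_metadata_error("storage_weeks must be >= 0, got %s", storage_weeks)
  if (!is.na(solubility) && solubility <= 0)
    dk_metadata_error("solubility must be > 0 mg/ml, got %s", solubility)
  if (!is.na(polymer_mw) && polymer_mw <= 0)
    dk_metadata_error("polymer_mw must be > 0 g/mol, got %s", polymer_mw)
  structure(list(drug_name = drug_name,
                 polymer_grade = polymer_grade,
                 storage_weeks = storage_weeks,
                 solubility = solubility,
                 polymer_mw = polymer_mw,
                 storage_temp_c = storage_temp_c),
            class = "study_arm")
}

# Solubilities (mg/ml in water) of the three model drugs spanning the
# high / moderate / poor solubility classes, and nominal PEO grade MWs.
.drug_solubility <- list(propranolol = 50.0, theophylline = 8, zonisamide = 0.8)
.grade_mw <- list("750" = 3e5, "303" = 7e6)

#' Solubility class of a drug
#'
#' Maps aqueous solubility to the coarse classes used to key default ageing
#' behaviour: above 10 mg/ml is `"high"`, 1--10 mg/ml `"moderate"`, below
#' 1 mg/ml `"poor"`.
#'
#' @param solubility Solubility in mg/ml.
#' @return One of `"high"`, `"moderate"`, `"poor"`.
#' @export
solubility_class <- function(solubility) {
  stopifnot(is.numeric(solubility), solubility > 0)
  ifelse(solubility > 10, "high", ifelse(solubility >= 1, "moderate", "poor"))
}

arm_key <- function(arm) {
  paste(arm$drug_name, arm$polymer_grade, arm$storage_weeks, sep = "|")
}

same_arm <- function(a, b) {
  a$drug_name == b$drug_name &&
    a$polymer_grade == b$polymer_grade &&
    a$storage_weeks == b$storage_weeks
}

#' @export
print.study_arm <- function(x, ...) {
  cat(sprintf("<study_arm> %s / PEO %s, %g week(s) at %g C\n",
              x$drug_name, x$polymer_grade, x$storage_weeks, x$storage_temp_c))
  invisible(x)
}

#' Dissolution profile
#'
#' One replicate's cumulative release curve: percent of label claim released
#' (`release`) at each sampling time (`times`, minutes). Times must be
#' strictly increasing and non-negative; release must lie in [0, 110]
#' (a small assay-overshoot allowance above 100). Monotonicity of `release`
#' is not required at construction: raw replicate curves are noisy, and
#' [validate_and_repair()] restores cumulative monotonicity before any
#' statistic is computed.
#'
#' @param times Sampling times in minutes.
#' @param release Cumulative percent released, same length as `times`.
#' @param arm A [study_arm()] (optional metadata).
#' @param replicate_id Integer replicate label; 0 marks an aggregated
#'   (mean) profile.
#' @return An object of class `dissolution_profile`.
#' @examples
#' dissolution_profile(c(0, 60, 120), c(0, 30, 55))
#' @export
dissolution_profile <- function(times, release, arm = NULL, replicate_id = 1L) {
  times <- as.numeric(times)
  release <- as.numeric(release)
  if (length(times) != length(release))
    dk_parse_error("times (%d) and release (%d) differ in length",
                   length(times), length(release))
  if (length(times) < 2)
    dk_parse_error("a profile needs at least 2 points, got %d", length(times))
  if (anyNA(times) || anyNA(release))
    dk_parse_error("times/release must not contain NA")
  if (any(times < 0))
    dk_domain_error("times must be >= 0")
  if (any(diff(times) <= 0))
    dk_duplicate_error("times must be strictly increasing")
  if (any(release < 0) || any(release > 110))
    dk_domain_error("release must lie within [0, 110] %%")
  if (!is.null(arm) && !inherits(arm, "study_arm"))
    dk_metadata_error("arm must be a study_arm or NULL")
  structure(list(times = times, release = release, meta = arm,
                 replicate_id = as.integer(replicate_id)),
            class = "dissolution_profile")
}

#' @export
print.dissolution_profile <- function(x, ...) {
  lab <- if (is.null(x$meta)) "unlabelled" else
    sprintf("%s/PEO %s, %gw", x$meta$drug_name, x$meta$polymer_grade,
            x$meta$storage_weeks)
  rep_lab <- if (x$replicate_id == 0L) "mean" else paste0("rep ", x$replicate_id)
  cat(sprintf("<dissolution_profile> %s (%s): %d points, %g-%g min, %.1f-%.1f%%\n",
              lab, rep_lab, length(x$times), min(x$times), max(x$times),
              min(x$release), max(x$release)))
  invisible(x)
}

#' @export
as.data.frame.dissolution_profile <- function(x, ...) {
  meta <- x$meta
  data.frame(
    drug = if (is.null(meta)) NA_character_ else meta$drug_name,
    polymer_grade = if (is.null(meta)) NA_character_ else meta$polymer_grade,
    storage_weeks = if (is.null(meta)) NA_real_ else meta$storage_weeks,
    replicate = x$replicate_id,
    time_min = x$times,
    release_pct = x$release,
    stringsAsFactors = FALSE
  )
}

#' Prepend the (0, 0) origin to a profile
#'
#' Tablets release nothing at t = 0, and both the DE integral and the MDT
#' increment sum run from zero, so all metric computations operate on
#' profiles anchored at the origin. A no-op when a t = 0 sample is present.
#'
#' @param profile A [dissolution_profile()].
#' @return The profile, with a (0, 0) point prepended when absent.
#' @export
prepend_origin <- function(profile) {
  stopifnot(inherits(profile, "dissolution_profile"))
  if (profile$times[1] == 0) return(profile)
  dissolution_profile(c(0, profile$times), c(0, profile$release),
                      arm = profile$meta, replicate_id = profile$replicate_id)
}

#' Validate a profile and repair small monotonicity violations
#'
#' Cumulative release curves must be non-decreasing, but raw replicate
#' curves carry assay noise. Decreases no larger than `tolerance` percent
#' are repaired by replacing the release vector with its running maximum
#' (then clipping to [0, 110]); a larger decrease is treated as a data
#' quality problem and raises an error naming the offending time point.
#' The repair is idempotent and order-preserving.
#'
#' @param profile A [dissolution_profile()].
#' @param tolerance Largest tolerated decrease, in release percentage points
#'   (default 2). Use `Inf` to repair unconditionally.
#' @return A monotone [dissolution_profile()].
#' @examples
#' p <- dissolution_profile(c(0, 30, 60, 90), c(0, 30, 29.5, 60))
#' validate_and_repair(p)$release  # 0 30 30 60
#' @export
validate_and_repair <- function(profile, tolerance = 2) {
  stopifnot(inherits(profile, "dissolution_profile"))
  y <- profile$release
  drops <- pmax(0, -diff(y))
  if (any(drops > tolerance)) {
    i <- which(drops > tolerance)[1] + 1L
    dk_data_quality_error(
      "release drops by %.3g%% at t = %g min (index %d), exceeding tolerance %g%%",
      drops[i - 1L], profile$times[i], i, tolerance)
  }
  y <- pmin(110, pmax(0, cummax(y)))
  profile$release <- y
  profile
}

#' Pointwise mean of replicate profiles
#'
#' Averages replicates of the same study arm sampled on an identical time
#' grid. Per-arm statistics in the pipeline are computed on this mean
#' profile ("mean-profile-then-statistic"), matching how single DE/MDT/f2
#' values per arm are conventionally reported.
#'
#' @param replicates A list of [dissolution_profile()] objects sharing one
#'   time grid and one study arm.
#' @return A [dissolution_profile()] with `replicate_id = 0` (aggregate).
#' @export
mean_profile <- function(replicates) {
  stopifnot(is.list(replicates), length(replicates) >= 1)
  lapply(replicates, function(p) stopifnot(inherits(p, "dissolution_profile")))
  ref <- replicates[[1]]
  for (p in replicates[-1]) {
    if (length(p$times) != length(ref$times) || any(p$times != ref$times))
      dk_grid_mismatch("replicates sampled on different time grids")
    if (!is.null(ref$meta) && !is.null(p$meta) && !same_arm(ref$meta, p$meta))
      dk_metadata_error("replicates belong to different study arms (%s vs %s)",
                        arm_key(ref$meta), arm_key(p$meta))
  }
  y <- rowMeans(vapply(replicates, function(p) p$release,
                       numeric(length(ref$times))))
  dissolution_profile(ref$times, y, arm = ref$meta, replicate_id = 0L)
}

#' Study design
#'
#' The factorial layout of a dissolution stability study: the set of arms,
#' the number of dissolution replicates per arm and the common sampling
#' grid.
#'
#' @param arms List of [study_arm()] objects, unique on
#'   (drug, polymer grade, storage weeks).
#' @param replicates_per_arm Number of replicate tablets per arm.
#' @param sampling_grid Strictly increasing sampling times in minutes.
#' @return An object of class `study_design`.
#' @export
study_design <- function(arms, replicates_per_arm = 3,
                         sampling_grid = default_grid()) {
  stopifnot(is.list(arms), length(arms) >= 1)
  keys <- vapply(arms, arm_key, character(1))
  if (anyDuplicated(keys))
    dk_metadata_error("duplicate study arm: %s", keys[duplicated(keys)][1])
  sampling_grid <- as.numeric(sampling_grid)
  if (any(diff(sampling_grid) <= 0))
    dk_domain_error("sampling_grid must be strictly increasing")
  if (replicates_per_arm < 1)
    dk_domain_error("replicates_per_arm must be >= 1")
  structure(list(arms = arms,
                 replicates_per_arm = as.integer(replicates_per_arm),
                 sampling_grid = sampling_grid),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("<study_design> %d arms x %d replicates, %d sampling times (%g-%g min)\n",
              length(x$arms), x$replicates_per_arm, length(x$sampling_grid),
              min(x$sampling_grid), max(x$sampling_grid)))
  invisible(x)
}

#' Default USP-paddle sampling grid
#'
#' Samples every 15 min up to 2 h and every 30 min thereafter up to 12 h,
#' with the t = 0 origin included: 35 time points in total.
#'
#' @return Numeric vector of sampling times in minutes.
#' @export
default_grid <- function() {
  c(seq(0, 120, by = 15), seq(150, 720, by = 30))
}
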