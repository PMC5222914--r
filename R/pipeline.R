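#' End-to-end stability analysis of a dissolution study
#'
#' Groups profiles by study arm, repairs and averages replicates, computes
#' DE (over `t_end`), MDT and an optional power-law fit per arm, and
#' compares every aged arm against the fresh (storage 0) arm of the same
#' (drug, polymer grade) with the similarity factor. The fresh arm is
#' always the f2 reference; a missing fresh arm for any (drug, grade)
#' family aborts the run, while a per-pair f2 failure (e.g. too few shared
#' points) is recorded in that row and the run continues.
#'
#' @param profiles List of [dissolution_profile()] objects (with arm
#'   metadata), or a `dissolution_study` as returned by [generate_study()].
#' @param t_end DE integration horizon in minutes (default 720).
#' @param tolerance Monotonicity-repair tolerance passed to
#'   [validate_and_repair()].
#' @param fit_kinetics Also fit the power law per arm (default TRUE).
#' @param f2_cap Release cap for f2 point selection (default 85).
#' @return A `stability_report`: data frames `metrics` (one row per arm)
#'   and `similarity` (one row per aged arm), a `provenance` list and a
#'   `log` of runtime decisions (origins prepended, repairs applied,
#'   points dropped).
#' @examples
#' study <- generate_study(default_config(), noise_sd = 0)
#' report <- run_stability_analysis(study)
#' head(report$similarity)
#' @export
run_stability_analysis <- function(profiles, t_end = 720, tolerance = 2,
                                   fit_kinetics = TRUE, f2_cap = 85) {
  if (inherits(profiles, "dissolution_study")) profiles <- profiles$profiles
  stopifnot(is.list(profiles))
  log <- character(0)
  note <- function(msg, ...) log[[length(log) + 1L]] <<- sprintf(msg, ...)

  if (length(profiles) == 0) {
    return(empty_report(t_end, tolerance))
  }
  for (p in profiles) {
    if (!inherits(p, "dissolution_profile") || is.null(p$meta))
      dk_metadata_error("all profiles must be dissolution_profile objects with study_arm metadata")
  }

  keys <- vapply(profiles, function(p) arm_key(p$meta), character(1))
  groups <- split(profiles, factor(keys, levels = unique(keys)))

  # fresh reference must exist for every (drug, grade) family
  fam <- function(arm) paste(arm$drug_name, arm$polymer_grade, sep = "|")
  fams <- unique(vapply(profiles, function(p) fam(p$meta), character(1)))
  fresh_of <- list()
  for (key in names(groups)) {
    arm <- groups[[key]][[1]]$meta
    if (arm$storage_weeks == 0) fresh_of[[fam(arm)]] <- key
  }
  for (f in fams) {
    if (is.null(fresh_of[[f]]))
      dk_reference_missing("no fresh (storage 0) reference arm for %s", f)
  }

  mean_of <- list()
  metrics_rows <- list()
  for (key in names(groups)) {
    reps <- lapply(groups[[key]], function(p) {
      q <- validate_and_repair(p, tolerance)
      if (any(q$release != p$release))
        note("repaired monotonicity of %s replicate %d", key, p$replicate_id)
      q
    })
    m <- mean_profile(reps)
    if (m$times[1] != 0) note("prepended (0,0) origin for %s", key)
    mean_of[[key]] <- m
    arm <- m$meta
    met <- compute_metrics(m, t_end = t_end)
    fit <- if (fit_kinetics) {
      tryCatch(fit_power_law(m), dissokin_error = function(e) {
        note("power-law fit skipped for %s: %s", key, conditionMessage(e))
        NULL
      })
    } else NULL
    metrics_rows[[key]] <- data.frame(
      drug = arm$drug_name, polymer_grade = arm$polymer_grade,
      storage_weeks = arm$storage_weeks,
      de_pct = met$de, mdt_h = met$mdt, n_points = met$n_points,
      k_hat = if (is.null(fit)) NA_real_ else fit$k_hat,
      n_hat = if (is.null(fit)) NA_real_ else fit$n_hat,
      mechanism = if (is.null(fit)) NA_character_ else fit$mechanism_label,
      stringsAsFactors = FALSE)
  }

  sim_rows <- list()
  for (key in names(groups)) {
    arm <- mean_of[[key]]$meta
    if (arm$storage_weeks == 0) next
    ref <- mean_of[[fresh_of[[fam(arm)]]]]
    row <- data.frame(
      drug = arm$drug_name, polymer_grade = arm$polymer_grade,
      storage_weeks = arm$storage_weeks,
      f2_vs_fresh = NA_real_, n_points_used = NA_integer_,
      points_dropped = NA_integer_, verdict = NA_character_,
      error = NA_character_, stringsAsFactors = FALSE)
    res <- tryCatch(compute_f2(ref, mean_of[[key]], cap = f2_cap),
                    dissokin_error = function(e) e)
    if (inherits(res, "similarity_result")) {
      row$f2_vs_fresh <- res$f2
      row$n_points_used <- res$n_points_used
      row$points_dropped <- res$points_dropped
      row$verdict <- as.character(res$verdict)
      if (res$points_dropped > 0)
        note("f2 for %s: dropped %d point(s) past the %g%% cap",
             key, res$points_dropped, f2_cap)
    } else {
      row$error <- conditionMessage(res)
      note("f2 failed for %s: %s", key, conditionMessage(res))
    }
    sim_rows[[key]] <- row
  }

  metrics <- do.call(rbind, c(metrics_rows, list(make.row.names = FALSE)))
  similarity <- if (length(sim_rows) > 0)
    do.call(rbind, c(sim_rows, list(make.row.names = FALSE)))
  else empty_similarity_df()
  structure(list(
    metrics = metrics,
    similarity = similarity,
    provenance = list(package = "dissokin",
                      version = as.character(utils::packageVersion("dissokin")),
                      t_end = t_end, tolerance = tolerance,
                      f2_cap = f2_cap, n_profiles = length(profiles)),
    log = log),
    class = "stability_report")
}

empty_metrics_df <- function() {
  data.frame(drug = character(0), polymer_grade = character(0),
             storage_weeks = numeric(0), de_pct = numeric(0),
             mdt_h = numeric(0), n_points = integer(0),
             k_hat = numeric(0), n_hat = numeric(0),
             mechanism = character(0), stringsAsFactors = FALSE)
}

empty_similarity_df <- function() {
  data.frame(drug = character(0), polymer_grade = character(0),
             storage_weeks = numeric(0), f2_vs_fresh = numeric(0),
             n_points_used = integer(0), points_dropped = integer(0),
             verdict = character(0), error = character(0),
             stringsAsFactors = FALSE)
}

empty_report <- function(t_end, tolerance) {
  structure(list(metrics = empty_metrics_df(),
                 similarity = empty_similarity_df(),
                 provenance = list(package = "dissokin",
                                   version = as.character(utils::packageVersion("dissokin")),
                                   t_end = t_end, tolerance = tolerance,
                                   f2_cap = 85, n_profiles = 0L),
                 log = character(0)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %d arm(s), %d f2 comparison(s)\n",
              nrow(x$metrics), nrow(x$similarity)))
  if (nrow(x$similarity) > 0) {
    tab <- table(x$similarity$verdict, useNA = "ifany")
    cat("  verdicts:", paste(names(tab), tab, sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a stability report to disk
#'
#' Writes `metrics.csv` (per-arm DE/MDT and optional power-law fit),
#' `similarity.csv` (per-aged-arm f2 versus fresh) and a Markdown
#' `summary.md` into `out_dir`. Empty reports produce header-only CSVs.
#'
#' @param report A `stability_report`.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
render_report <- function(report, out_dir) {
  stopifnot(inherits(report, "stability_report"))
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) dk_io_error("cannot create directory %s", out_dir)
  metrics_path <- file.path(out_dir, "metrics.csv")
  sim_path <- file.path(out_dir, "similarity.csv")
  md_path <- file.path(out_dir, "summary.md")
  utils::write.csv(report$metrics, metrics_path, row.names = FALSE, na = "")
  utils::write.csv(report$similarity, sim_path, row.names = FALSE, na = "")

  lines <- c("# Dissolution stability report", "",
             sprintf("- package: %s %s", report$provenance$package,
                     report$provenance$version),
             sprintf("- DE horizon: %g min", report$provenance$t_end),
             sprintf("- arms analysed: %d", nrow(report$metrics)),
             sprintf("- f2 comparisons: %d", nrow(report$similarity)), "")
  if (nrow(report$similarity) > 0) {
    lines <- c(lines, "## Similarity versus fresh reference", "",
               "| drug | grade | weeks | f2 | verdict |",
               "|------|-------|-------|-----|---------|",
               sprintf("| %s | %s | %g | %s | %s |",
                       report$similarity$drug, report$similarity$polymer_grade,
                       report$similarity$storage_weeks,
                       ifelse(is.na(report$similarity$f2_vs_fresh), "-",
                              sprintf("%.1f", report$similarity$f2_vs_fresh)),
                       ifelse(is.na(report$similarity$verdict),
                              report$similarity$error,
                              report$similarity$verdict)), "")
  }
  if (length(report$log) > 0)
    lines <- c(lines, "## Run log", "", paste0("- ", report$log), "")
  writeLines(lines, md_path)
  invisible(c(metrics_path, sim_path, md_path))
}

#' Overlay release curves per (drug, grade) family
#'
#' One panel per (drug, polymer grade), overlaying the mean release curve
#' of each storage time. Requires ggplot2.
#'
#' @param profiles List of [dissolution_profile()] objects or a
#'   `dissolution_study`.
#' @return A ggplot object.
#' @export
plot_release_curves <- function(profiles) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    dk_io_error("ggplot2 is required for plotting")
  if (inherits(profiles, "dissolution_study")) profiles <- profiles$profiles
  df <- profiles_to_df(profiles)
  df$arm <- paste(df$drug, df$polymer_grade, sep = " / PEO ")
  df$weeks <- factor(df$storage_weeks)
  agg <- stats::aggregate(release_pct ~ arm + weeks + time_min, df, mean)
  ggplot2::ggplot(
    agg,
    ggplot2::aes(x = time_min / 60, y = release_pct, colour = weeks)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~arm) +
    ggplot2::labs(x = "time (h)", y = "cumulative release (%)",
                  colour = "storage (weeks)") +
    ggplot2::theme_bw()
}
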