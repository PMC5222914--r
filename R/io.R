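# On-disk format: one long ("tidy") CSV, one row per observation, with
# columns drug, polymer_grade, storage_weeks, replicate, time_min,
# release_pct. UTF-8, '.' decimal separator, '#' comments. Long layout
# round-trips replicates and arm metadata without a sidecar file.

.profile_cols <- c("drug", "polymer_grade", "storage_weeks",
                   "replicate", "time_min", "release_pct")

#' Read dissolution profiles from a long-format CSV
#'
#' Columns are bound by name, not position, so column order is irrelevant.
#' Each (drug, polymer grade, storage weeks, replicate) combination becomes
#' one [dissolution_profile()], with rows sorted by time.
#'
#' @param path Path to a CSV with columns `drug`, `polymer_grade`,
#'   `storage_weeks`, `replicate`, `time_min`, `release_pct`.
#' @return A list of [dissolution_profile()] objects.
#' @seealso [write_profiles()]
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) dk_io_error("file not found: %s", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(.profile_cols, names(df))
  if (length(missing) > 0)
    dk_schema_error("missing required column(s): %s",
                    paste(missing, collapse = ", "))
  for (col in c("storage_weeks", "time_min", "release_pct")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & nzchar(df[[col]]))
    if (length(bad) > 0)
      dk_parse_error("non-numeric value '%s' in column %s at data row %d",
                     df[[col]][bad[1]], col, bad[1])
    if (anyNA(v))
      dk_parse_error("missing value in column %s at data row %d",
                     col, which(is.na(v))[1])
    df[[col]] <- v
  }
  df$replicate <- suppressWarnings(as.integer(df$replicate))
  if (anyNA(df$replicate))
    dk_parse_error("non-integer replicate id at data row %d",
                   which(is.na(df$replicate))[1])

  key <- paste(df$drug, df$polymer_grade, df$storage_weeks, df$replicate,
               sep = "|")
  dup <- duplicated(paste(key, df$time_min, sep = "|"))
  if (any(dup)) {
    i <- which(dup)[1]
    dk_duplicate_error(
      "duplicate time point t = %g min for %s/%s week %g replicate %d",
      df$time_min[i], df$drug[i], df$polymer_grade[i],
      df$storage_weeks[i], df$replicate[i])
  }

  profiles <- lapply(split(seq_len(nrow(df)), factor(key, levels = unique(key))),
                     function(idx) {
    rows <- df[idx[order(df$time_min[idx])], , drop = FALSE]
    arm <- study_arm(rows$drug[1], rows$polymer_grade[1], rows$storage_weeks[1])
    dissolution_profile(rows$time_min, rows$release_pct, arm = arm,
                        replicate_id = rows$replicate[1])
  })
  unname(profiles)
}

#' Write dissolution profiles to a long-format CSV
#'
#' Inverse of [read_profiles()]: the round trip reproduces the profile
#' collection exactly (release values are written at full precision).
#'
#' @param profiles List of [dissolution_profile()] objects with metadata.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  stopifnot(is.list(profiles), length(profiles) >= 1)
  rows <- do.call(rbind, lapply(profiles, as.data.frame))
  if (anyNA(rows$drug))
    dk_metadata_error("profiles must carry study_arm metadata to be written")
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(format(rows, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert a profile collection to one long data frame
#'
#' @param profiles List of [dissolution_profile()] objects.
#' @return A data frame with one row per observation.
#' @export
profiles_to_df <- function(profiles) {
  do.call(rbind, lapply(profiles, as.data.frame))
}
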