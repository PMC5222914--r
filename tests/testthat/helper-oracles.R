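# Independent oracles used to cross-check the implementation. These are
# deliberately direct transcriptions of the defining formulas, sharing no
# code with the package internals.

# f2 by direct evaluation on two aligned release vectors
f2_oracle <- function(r, s) {
  n <- length(r)
  50 * log10(100 / sqrt(1 + sum((r - s)^2) / n))
}

# trapezoidal area under (t, y) by explicit loop
trapz_oracle <- function(t, y) {
  a <- 0
  for (i in seq_len(length(t) - 1)) {
    a <- a + (y[i] + y[i + 1]) / 2 * (t[i + 1] - t[i])
  }
  a
}

# MDT in minutes by explicit loop over increments
mdt_oracle_min <- function(t, y) {
  num <- 0; den <- 0
  for (i in seq_len(length(t) - 1)) {
    dm <- y[i + 1] - y[i]
    num <- num + (t[i] + t[i + 1]) / 2 * dm
    den <- den + dm
  }
  num / den
}

# random monotone cumulative release profile anchored at (0, 0)
random_monotone_profile <- function(n_points = NULL, arm = NULL) {
  if (is.null(n_points)) n_points <- sample(4:20, 1)
  t <- c(0, sort(runif(n_points - 1, 1, 720)))
  inc <- runif(n_points - 1, 0, 10)
  y <- c(0, cumsum(inc))
  y <- y / max(y) * runif(1, 20, 100)  # total release in (20, 100]
  dissolution_profile(t, y, arm = arm)
}

make_arm <- function(drug = "propranolol", grade = "750", weeks = 0) {
  study_arm(drug, grade, weeks)
}

# small valid study CSV written to a temp file
write_profile_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}

# the qualitative stability pattern expected of the default synthetic
# study: verdict of every aged arm versus its fresh reference
expected_verdict_pattern <- function() {
  pat <- expand.grid(storage_weeks = c(2, 4, 8),
                     polymer_grade = c("750", "303"),
                     drug = c("propranolol", "theophylline", "zonisamide"),
                     stringsAsFactors = FALSE)
  pat$verdict <- "similar"
  pat$verdict[pat$drug == "propranolol"] <- "dissimilar"
  pat$verdict[pat$drug == "theophylline" & pat$polymer_grade == "750" &
                pat$storage_weeks >= 4] <- "dissimilar"
  pat[, c("drug", "polymer_grade", "storage_weeks", "verdict")]
}
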