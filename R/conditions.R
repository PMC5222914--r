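# Classed error conditions so callers (and tests) can dispatch on failure
# mode rather than on message text. All dissokin errors carry the class
# "dissokin_error" plus one specific subclass.

dk_stop <- function(class, msg, ..., call = sys.call(-1)) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "dissokin_error"),
                      call = call))
}

dk_schema_error       <- function(msg, ...) dk_stop("dk_schema_error", msg, ...)
dk_parse_error        <- function(msg, ...) dk_stop("dk_parse_error", msg, ...)
dk_duplicate_error    <- function(msg, ...) dk_stop("dk_duplicate_error", msg, ...)
dk_data_quality_error <- function(msg, ...) dk_stop("dk_data_quality_error", msg, ...)
dk_grid_mismatch      <- function(msg, ...) dk_stop("dk_grid_mismatch_error", msg, ...)
dk_metadata_error     <- function(msg, ...) dk_stop("dk_metadata_error", msg, ...)
dk_domain_error       <- function(msg, ...) dk_stop("dk_domain_error", msg, ...)
dk_extrapolation_error <- function(msg, ...) dk_stop("dk_extrapolation_error", msg, ...)
dk_undefined_statistic <- function(msg, ...) dk_stop("dk_undefined_statistic_error", msg, ...)
dk_insufficient_points <- function(msg, ...) dk_stop("dk_insufficient_points_error", msg, ...)
dk_config_error       <- function(msg, ...) dk_stop("dk_config_error", msg, ...)
dk_reference_missing  <- function(msg, ...) dk_stop("dk_reference_missing_error", msg, ...)
dk_io_error           <- function(msg, ...) dk_stop("dk_io_error", msg, ...)
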