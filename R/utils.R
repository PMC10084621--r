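# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Derive a reproducible sub-seed for a named pipeline stage
#'
#' All randomness in a pipeline run flows from one root seed; each stage draws
#' from its own named substream so stages can be rerun in isolation.  The
#' derived seed is kept inside the 32-bit integer range.
#'
#' @param seed root integer seed.
#' @param stage character stage label.
#' @return an integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 69069 + h * 1013904223) %% 2147483563L) + 1L
}

# columns required of a phenotype design table (trait columns may be absent)
.design_cols <- c("individual_id", "pond_id", "latitude", "temperature",
                  "predator", "maternal_line")
.trait_cols  <- c("mass", "head_width", "wing_pad", "dev_time")
.derived_cols <- c("grm", "grh")

.norm_category <- function(x, map, column) {
  key <- tolower(trimws(as.character(x)))
  out <- map[key]
  bad <- which(is.na(out))
  if (length(bad))
    stopf("invalid value '%s' in column '%s' (row %d); expected one of: %s",
          key[bad[1]], column, bad[1], paste(unique(map), collapse = ", "))
  unname(out)
}

.latitude_map <- c(high = "high", central = "central")
.predator_map <- c(absent = "absent", present = "present",
                   "0" = "absent", "1" = "present")
.temperature_map <- c("20" = 20, "24" = 24)

geomean <- function(x) exp(mean(log(x)))
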