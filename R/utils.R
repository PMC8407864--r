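# Internal helpers: condition constructors, deterministic sub-seeding.

em_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "ewasmeta_error", "error", "condition")))
}

em_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "ewasmeta_warning", "warning", "condition")))
}

#' Derive a deterministic child seed from a master seed and an index
#'
#' Cohorts (and other sub-streams) are seeded independently so that any one
#' cohort can be regenerated without replaying the whole consortium. The mix
#' is a simple multiplicative-congruential scramble kept below 2^31.
#'
#' @param seed master integer seed.
#' @param index non-negative integer sub-stream index.
#' @return An integer seed in [0, 2147483628].
#' @export
child_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(index), length(index) == 1L)
  m <- 2147483629
  s <- (abs(seed) %% m)
  ((s * 48271) %% m + (16807 * (abs(index) + 1)) %% m) %% m
}

# sample standard deviation with n-1 denominator, NA-tolerant
sd_nm <- function(x) stats::sd(x, na.rm = TRUE)

is_binary01 <- function(x) all(x %in% c(0, 1, NA))
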