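# Internal helpers: error formatting and reproducible seeding.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards so simulation helpers do not perturb the caller's
#' random stream. `seed = NULL` evaluates `code` against the current stream.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Deterministic substream derivation: one root seed yields a distinct,
# order-independent seed per (animal, occasion) so cohort simulation is
# reproducible regardless of iteration order. Kept strictly below 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) %% 2147483647 * 48271 +
                as.double(index) * 2654435) %% 2147483629) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

match_species <- function(species) {
  if (length(species) != 1L || !species %in% c("goat", "pig")) {
    stopf("unknown species '%s': must be \"goat\" or \"pig\"",
          paste(species, collapse = ","))
  }
  species
}

check_dose <- function(dose) {
  if (!is.numeric(dose) || length(dose) != 1L || !is.finite(dose) || dose <= 0) {
    stopf("dose must be a single positive number (mg)")
  }
  as.double(dose)
}
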