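# Internal helpers shared across modules.

# Derive a child RNG seed from a base seed and a stream index; keeps every
# logical component (genotypes, effects, noise, ...) on its own stream so
# changing one spec does not perturb the others.  Result stays < 2^31.
.subSeed <- function(seed, k) {
  as.integer((as.double(seed) %% 48611L * 7919 + k * 104729) %% 2147483629)
}

# Draw N(0, s2 * K) given a pre-computed lower Cholesky factor of K.
.mvnK <- function(cholL, s2) {
  if (s2 <= 0) return(numeric(nrow(cholL)))
  as.numeric(cholL %*% stats::rnorm(nrow(cholL))) * sqrt(s2)
}

# Lower Cholesky factor with a small jitter ladder for PSD matrices.
.cholPSD <- function(K) {
  for (j in c(0, 1e-10, 1e-8, 1e-6, 1e-4)) {
    R <- tryCatch(chol(K + diag(j * mean(diag(K)) + j, nrow(K))),
                  error = function(e) NULL)
    if (!is.null(R)) return(t(R))
  }
  stop("matrix is too far from positive semidefinite to factor")
}

.assertCount <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  invisible(as.integer(x))
}

.assertProp <- function(x, name, maxOpen = 1) {
  if (length(x) != 1L || !is.finite(x) || x < 0 || x >= maxOpen)
    stop(sprintf("'%s' must be a proportion in [0, %g)", name, maxOpen),
         call. = FALSE)
  invisible(as.numeric(x))
}

# Standardised treatment factor: levels exactly NS (non-stress), S (stress).
.treatmentFactor <- function(x) {
  f <- factor(as.character(x), levels = c("NS", "S"))
  if (anyNA(f))
    stop("treatment labels must be exactly 'NS' and 'S'", call. = FALSE)
  f
}
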