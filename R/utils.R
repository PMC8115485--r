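# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG state seeded with `seed`; never touches
# the caller's global random state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# Derive a per-replicate sub-seed that stays within 32-bit integer range.
sub_seed <- function(seed, i) {
  (as.integer(seed) * 1000L + as.integer(i)) %% .Machine$integer.max
}

check_noise <- function(noise_sd) {
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || is.na(noise_sd) ||
      noise_sd < 0) {
    abort("`noise_sd` must be a single non-negative number.")
  }
  noise_sd
}

check_column <- function(data, cols, caller) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s: required column(s) %s not found in `data`.",
      caller, paste0("`", missing, "`", collapse = ", ")
    ))
  }
  invisible(data)
}

# Standard errors of least-squares estimates from an nls.lm fit object
# (Jacobian-based covariance); NA when the Hessian is singular.
nls_lm_se <- function(fit) {
  p <- length(fit$par)
  out <- tryCatch(
    summary(fit)$coefficients[, "Std. Error"],
    error = function(e) rep(NA_real_, p)
  )
  unname(out)
}
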