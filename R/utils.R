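#' @keywords internal
"_PACKAGE"

# Run code with a temporary RNG state; the caller's .Random.seed is restored.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Round half away from zero; seconds-to-samples conversions must not depend
# on banker's rounding.
round_hafz <- function(x) sign(x) * floor(abs(x) + 0.5)

# Pearson correlation defined as 0 when either input is (numerically) constant.
safe_cor <- function(a, b) {
  sa <- stats::sd(a)
  sb <- stats::sd(b)
  if (!is.finite(sa) || !is.finite(sb) || sa < 1e-300 || sb < 1e-300) return(0)
  stats::cor(a, b)
}

stop_named <- function(name, msg) {
  cond <- structure(
    class = c(name, "ccaerp_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}
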