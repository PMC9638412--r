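# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random-number stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Round half away from zero (commercial rounding), the convention used for
# cell-count equivalents and diagnostic-time percentages.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Truncate toward zero to 2 decimals, the display convention for
# sensitivity/specificity/accuracy percentages. A tiny guard absorbs
# floating-point representation error just below an exact hundredth.
trunc2 <- function(x) {
  ifelse(is.na(x), NA_real_, sign(x) * floor(abs(x) * 100 + 1e-7) / 100)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stopf(fmt, ...)
  invisible(TRUE)
}

is_count <- function(x) length(x) == 1 && is.finite(x) && x >= 0 && x == floor(x)

# Draw `n` areas (pixel^2) from a named size distribution.
# Supported: lognormal(meanlog, sdlog), uniform(min, max), gamma(shape, rate).
draw_areas <- function(dist, n) {
  if (n == 0) return(numeric(0))
  assert_that(is.list(dist) && !is.null(dist$name),
              "size distribution must be a named list with a 'name' field")
  switch(dist$name,
    lognormal = stats::rlnorm(n, meanlog = dist$meanlog, sdlog = dist$sdlog),
    uniform   = stats::runif(n, min = dist$min, max = dist$max),
    gamma     = stats::rgamma(n, shape = dist$shape, rate = dist$rate),
    stopf("unsupported size distribution '%s'", dist$name)
  )
}

# Rec. 601 luminance for RGB -> grayscale conversion.
rgb_luminance <- function(arr) {
  0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
}
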