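#' @importFrom rlang abort warn .data
#' @importFrom stats fft rnorm runif rbinom qt pt sd var cor t.test cor.test p.adjust complete.cases predict
#' @importFrom utils head tail write.csv read.csv
NULL

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic entry points funnel
# through this so that a config/seed pair is bit-reproducible.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a base seed and a stream index, staying inside
# 32-bit integer range.
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 69069 + 12345 * stream) %% 2147483629L)
}

# Draw n angles from a von Mises distribution with mean mu and concentration
# kappa, by Best & Fisher (1979) rejection sampling. kappa = 0 is uniform;
# kappa = Inf is degenerate at mu.
rvonmises <- function(n, mu = 0, kappa = 0) {
  stopifnot(kappa >= 0)
  if (kappa == 0) return(runif(n, -pi, pi))
  if (!is.finite(kappa)) return(rep(mu, n))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    keep <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    th <- sign(u3[keep] - 0.5) * acos(pmin(pmax(f[keep], -1), 1))
    nk <- length(th)
    if (nk > 0) {
      out[(got + 1):(got + nk)] <- th
      got <- got + nk
    }
  }
  wrap_pi(out + mu)
}

# Mean resultant length of a von Mises distribution: I1(kappa)/I0(kappa).
# This is the analytic expectation of PLV/ISPC under von Mises phase lags.
vonmises_plv <- function(kappa) {
  if (kappa == 0) return(0)
  if (!is.finite(kappa)) return(1)
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

# Wrap angles into (-pi, pi].
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

# Half-open [start, end) window in ms -> sample indices on a time axis given
# in seconds. Samples are assigned by their own timestamps; the convention
# is documented on window_average().
window_samples <- function(time_s, window_ms) {
  t_ms <- time_s * 1000
  which(t_ms >= window_ms[1] - 1e-9 & t_ms < window_ms[2] - 1e-9)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
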