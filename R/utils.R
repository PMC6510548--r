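# Small numerical helpers shared across modules.

# Planck constant times speed of light [J m]
.hc <- 6.62607015e-34 * 2.99792458e8
# Avogadro's number [mol-1]
.avogadro <- 6.02214076e23

#' Gauss-Legendre quadrature on the unit interval
#'
#' Nodes and weights for \eqn{\int_0^1 f(\mu)\,d\mu \approx \sum_i w_i
#' f(\mu_i)}, computed by the Golub-Welsch eigenvalue method. The weights sum
#' to one, so one hemisphere of direction cosines is covered by one call.
#'
#' @param n number of nodes (>= 2)
#' @return list with `mu` (increasing nodes in (0,1)) and `w` (weights)
#' @export
gauss_hemisphere <- function(n) {
  stopifnot(n >= 2)
  k <- seq_len(n - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- b
  J[cbind(k + 1, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- rev(e$values)                      # nodes on (-1, 1), increasing
  w <- rev(2 * e$vectors[1, ]^2)
  list(mu = (x + 1) / 2, w = w / 2)
}

# Normalized associated Legendre functions
# Lambda_l^m(x) = sqrt((l-m)!/(l+m)!) P_l^m(x), Condon-Shortley sign dropped
# (only products Lambda(x) Lambda(x') are ever used). Returns a matrix with
# rows following x and columns l = m, m+1, ..., lmax.
legendre_norm <- function(x, lmax, m = 0L) {
  stopifnot(lmax >= m, m >= 0L)
  nl <- lmax - m + 1L
  out <- matrix(0, length(x), nl)
  # Lambda_m^m = sqrt((2m)!)/(2^m m!) (1-x^2)^{m/2}
  if (m == 0L) {
    start <- rep(1, length(x))
  } else {
    lf <- 0.5 * lgamma(2 * m + 1) - m * log(2) - lgamma(m + 1)
    start <- exp(lf + (m / 2) * log(pmax(1 - x^2, 0)))
  }
  out[, 1L] <- start
  if (nl >= 2L) {
    out[, 2L] <- sqrt(2 * m + 1) * x * start
    if (nl >= 3L) {
      for (l in (m + 1L):(lmax - 1L)) {
        a <- sqrt((l + 1 - m) * (l + 1 + m))
        bm <- sqrt((l - m) * (l + m))
        j <- l - m + 1L
        out[, j + 1L] <- ((2 * l + 1) * x * out[, j] - bm * out[, j - 1L]) / a
      }
    }
  }
  out
}

# Trapezoid quadrature weights for an arbitrary strictly increasing grid.
trapz_weights <- function(x) {
  n <- length(x)
  if (n < 2) stop("need at least two grid points")
  w <- numeric(n)
  d <- diff(x)
  w[1] <- d[1] / 2
  w[n] <- d[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (d[-1] + d[-(n - 1)]) / 2
  w
}

# Linear interpolation that refuses to extrapolate.
interp_strict <- function(x, y, xout, what = "table") {
  if (any(xout < min(x) - 1e-9) || any(xout > max(x) + 1e-9)) {
    stop(sprintf("wavelength outside the range of the %s (%.5g-%.5g nm)",
                 what, min(x), max(x)), call. = FALSE)
  }
  stats::approx(x, y, xout, rule = 1)$y
}

# exp(-x) and (1 - exp(-x))/x, stable for small x.
expm1_ratio <- function(x) {
  r <- ifelse(x < 1e-12, 1 - x / 2, -expm1(-x) / x)
  r
}

# Hash of an R object via serialization to a temp file (base tools only).
object_hash <- function(x) {
  tf <- tempfile(fileext = ".rds")
  on.exit(unlink(tf), add = TRUE)
  saveRDS(x, tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}
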