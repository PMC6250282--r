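# Internal numerics and IO helpers shared across modules.

# Gauss-Legendre abscissae/weights used by the bivariate normal CDF
# (Genz 2004 / Drezner & Wesolowsky 1990), selected by |rho|.
.gl6w <- c(0.1713244923791705, 0.3607615730481384, 0.4679139345726904)
.gl6x <- c(0.9324695142031522, 0.6612093864662647, 0.2386191860831970)
.gl12w <- c(0.04717533638651177, 0.1069393259953183, 0.1600783285433464,
            0.2031674267230659, 0.2334925365383547, 0.2491470458134029)
.gl12x <- c(0.9815606342467191, 0.9041172563704750, 0.7699026741943050,
            0.5873179542866171, 0.3678314989981802, 0.1252334085114692)
.gl20w <- c(0.01761400713915212, 0.04060142980038694, 0.06267204833410906,
            0.08327674157670475, 0.1019301198172404, 0.1181945319615184,
            0.1316886384491766, 0.1420961093183821, 0.1491729864726037,
            0.1527533871307259)
.gl20x <- c(0.9931285991850949, 0.9639719272779138, 0.9122344282513259,
            0.8391169718222188, 0.7463319064601508, 0.6360536807265150,
            0.5108670019508271, 0.3737060887154196, 0.2277858511416451,
            0.07652652113349733)

# Upper-tail bivariate normal probability P(X > h, Y > k) with correlation
# rho, vectorized over (h, k) with scalar rho.  Moderate-correlation branch
# is a straight quadrature of Drezner-Wesolowsky; |rho| >= 0.925 uses Genz's
# singular-expansion branch, computed per element (rare in practice because
# tetrachoric twin correlations live well below that).
pbvnorm_upper <- function(h, k, rho) {
  stopifnot(length(rho) == 1L, is.finite(rho), abs(rho) <= 1)
  n <- max(length(h), length(k))
  h <- rep_len(h, n)
  k <- rep_len(k, n)
  inf <- is.infinite(h) | is.infinite(k)
  if (any(inf)) {
    out <- numeric(n)
    out[inf] <- ifelse(h[inf] == Inf | k[inf] == Inf, 0,
                       ifelse(h[inf] == -Inf & k[inf] == -Inf, 1,
                              ifelse(h[inf] == -Inf, pnorm(-k[inf]),
                                     pnorm(-h[inf]))))
    if (any(!inf)) out[!inf] <- pbvnorm_upper(h[!inf], k[!inf], rho)
    return(out)
  }
  if (abs(rho) < 0.925) {
    if (abs(rho) < 0.3) {
      w <- .gl6w; x <- .gl6x
    } else if (abs(rho) < 0.75) {
      w <- .gl12w; x <- .gl12x
    } else {
      w <- .gl20w; x <- .gl20x
    }
    w2 <- c(w, w)
    sn <- sin(asin(rho) / 2 * c(1 - x, 1 + x))
    hk <- h * k
    hs <- (h * h + k * k) / 2
    # matrix n x (2m): exp((sn*hk - hs)/(1 - sn^2)) %*% w
    e <- exp((outer(hk, sn) - hs) / rep(1 - sn^2, each = n))
    p <- drop(e %*% w2) * (asin(rho) / 2) / (2 * pi) +
      pnorm(-h) * pnorm(-k)
    return(pmin(1, pmax(0, p)))
  }
  vapply(seq_len(n), function(i) .bvnu_scalar(h[i], k[i], rho), numeric(1))
}

# Scalar Genz bvnu for |rho| >= 0.925 (and exact limits).
.bvnu_scalar <- function(dh, dk, r) {
  if (is.infinite(dh) && dh > 0) return(0)
  if (is.infinite(dk) && dk > 0) return(0)
  if (is.infinite(dh)) return(if (is.infinite(dk)) 1 else pnorm(-dk))
  if (is.infinite(dk)) return(pnorm(-dh))
  if (abs(r) == 1) {
    if (r == 1) return(pnorm(-max(dh, dk)))
    return(max(0, 1 - pnorm(dh) - pnorm(dk)))
  }
  tp <- 2 * pi
  h <- dh; k <- dk; hk <- h * k; bvn <- 0
  if (r < 0) { k <- -k; hk <- -hk }
  as_ <- (1 - r) * (1 + r)
  a <- sqrt(as_)
  bs <- (h - k)^2
  cc <- (4 - hk) / 8
  d <- (12 - hk) / 16
  asr <- -(bs / as_ + hk) / 2
  if (asr > -100) {
    bvn <- a * exp(asr) *
      (1 - cc * (bs - as_) * (1 - d * bs / 5) / 3 + cc * d * as_ * as_ / 5)
  }
  if (-hk < 100) {
    b <- sqrt(bs)
    bvn <- bvn - exp(-hk / 2) * sqrt(tp) * pnorm(-b / a) * b *
      (1 - cc * bs * (1 - d * bs / 5) / 3)
  }
  a <- a / 2
  for (i in seq_along(.gl20x)) {
    for (is in c(-1, 1)) {
      xs <- (a * (is * .gl20x[i] + 1))^2
      rs <- sqrt(1 - xs)
      asr <- -(bs / xs + hk) / 2
      if (asr > -100) {
        bvn <- bvn + a * .gl20w[i] * exp(asr) *
          (exp(-hk * (1 - rs) / (2 * (1 + rs))) / rs -
             (1 + cc * xs * (1 + d * xs)))
      }
    }
  }
  bvn <- -bvn / tp
  if (r > 0) {
    bvn <- bvn + pnorm(-max(h, k))
  } else {
    bvn <- -bvn
    if (k > h) {
      bvn <- bvn + (if (h < 0) pnorm(k) - pnorm(h) else pnorm(-h) - pnorm(-k))
    }
  }
  min(1, max(0, bvn))
}

# Joint probability of a pair of binary indicators (d1, d2) whose latent
# liabilities exceed thresholds (t1, t2) under correlation rho.  Vectorized.
pair_orthant_prob <- function(d1, d2, t1, t2, rho) {
  n <- max(length(d1), length(d2), length(t1), length(t2))
  d1 <- rep_len(d1, n); d2 <- rep_len(d2, n)
  t1 <- rep_len(t1, n); t2 <- rep_len(t2, n)
  p11 <- pbvnorm_upper(t1, t2, rho)
  p1 <- pnorm(t1, lower.tail = FALSE)
  p2 <- pnorm(t2, lower.tail = FALSE)
  p <- ifelse(d1 == 1 & d2 == 1, p11,
       ifelse(d1 == 1 & d2 == 0, p1 - p11,
       ifelse(d1 == 0 & d2 == 1, p2 - p11,
              1 - p1 - p2 + p11)))
  pmax(p, 1e-300)
}

# Derive a 32-bit sub-seed for layer k from a base seed, so adding a layer
# never perturbs the draws of another.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 20000003) * 101 + 7 * k) %% 2147483647L
}

# Rank-based inverse-normal transform with Blom offset c = 3/8;
# ties get midranks, NA preserved.
inverse_normal <- function(x, offset = 3 / 8) {
  ok <- !is.na(x)
  n <- sum(ok)
  out <- rep(NA_real_, length(x))
  if (n == 0L) return(out)
  r <- rank(x[ok], ties.method = "average")
  out[ok] <- qnorm((r - offset) / (n - 2 * offset + 1))
  out
}

# Deterministic TSV writers/readers used by every stage (byte-identical
# output given identical data).
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = "NA",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

# (a2, c2, e2) from two unconstrained reals via softmax with e2 as baseline.
softmax_ace <- function(ta, tc) {
  m <- max(ta, tc, 0)
  ea <- exp(ta - m); ec <- exp(tc - m); ee <- exp(-m)
  s <- ea + ec + ee
  c(a2 = ea / s, c2 = ec / s, e2 = ee / s)
}

# Inverse of softmax_ace for interior points (used to build starting values).
softmax_ace_inv <- function(a2, c2, eps = 1e-4) {
  a2 <- min(max(a2, eps), 1 - 2 * eps)
  c2 <- min(max(c2, eps), 1 - 2 * eps)
  e2 <- max(1 - a2 - c2, eps)
  s <- a2 + c2 + e2
  c(log(a2 / s) - log(e2 / s), log(c2 / s) - log(e2 / s))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
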