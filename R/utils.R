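#' @import stats
#' @import utils
NULL

# Deterministic 32-bit string hash (FNV-1a style) for deriving per-well seeds.
# Kept in pure R so the same (seed, plate, well) triple maps to the same
# stream on any platform.
hash_string <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  h
}

#' Derive a reproducible per-well seed
#'
#' Folds a global seed with plate and well identifiers into a 31-bit seed, so
#' every well draws from its own reproducible stream regardless of the order
#' in which wells are simulated.
#'
#' @param seed Global integer seed.
#' @param plate,well Identifier strings.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
derive_well_seed <- function(seed, plate, well) {
  h <- hash_string(paste(plate, well, sep = "/"))
  as.integer((abs(seed) * 69069 + h) %% 2147483646 + 1)
}

# Pixel offsets of a filled disk of radius r (row/col integer offsets).
disk_offsets <- function(r) {
  r <- max(0, r)
  ri <- ceiling(r)
  g <- expand.grid(dr = -ri:ri, dc = -ri:ri)
  g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
}

# Otsu threshold on a numeric vector (not an image): exhaustive search over
# histogram bin boundaries maximising between-class variance. Returns the
# threshold value; used for per-cell intensity splits where EBImage::otsu
# (which expects an image in [0,1]) is not the natural interface.
otsu_threshold <- function(x, n_bins = 256) {
  x <- x[is.finite(x)]
  if (length(x) < 2 || diff(range(x)) == 0) return(NA_real_)
  h <- hist(x, breaks = seq(min(x), max(x), length.out = n_bins + 1),
            plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- -Inf
  k <- which.max(sb2)
  h$breaks[k + 1]
}

# Valley-depth bimodality check used by threshold derivation: ratio of the
# smoothed histogram density at the candidate cut to the smaller of the two
# flanking peak densities. Small ratio = deep valley = genuinely bimodal.
valley_depth_ratio <- function(x, cut) {
  d <- density(x, n = 512)
  i <- which.min(abs(d$x - cut))
  left_peak <- if (i > 1) max(d$y[1:i]) else d$y[1]
  right_peak <- if (i < length(d$y)) max(d$y[i:length(d$y)]) else d$y[i]
  d$y[i] / min(left_peak, right_peak)
}

stopifnot_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive finite number", name),
         call. = FALSE)
  invisible(x)
}
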