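#' @importFrom rlang %||% abort warn inform
#' @importFrom stats rnorm rlnorm rpois runif sd quantile median setNames
#' @importFrom utils head tail
NULL

#' Derive a reproducible substream seed from a global seed and labels
#'
#' A single global integer seed fans out to independent per-scene substreams by
#' stable string hashing, so adding one more scene to a study never reshuffles
#' the draws of the others.
#'
#' @param seed Integer global seed.
#' @param ... Labels (coerced to character) identifying the substream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' substream_seed(1, "presyn", "device", 3)
substream_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  key <- paste(c(format(seed), vapply(list(...), format, character(1))),
    collapse = "/"
  )
  h <- 5381
  for (b in utf8ToInt(key)) {
    h <- (h * 33 + b) %% 2147483629
  }
  as.integer(h)
}

# Evaluate code under a local RNG state; global stream is untouched.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# polynomial rolling hash of a character scalar, hex string; stamps outputs
stable_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  h <- 5381
  for (b in utf8ToInt(x)) {
    h <- (h * 127 + b) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf(
      "`%s` must be a single finite number in [%s, %s]",
      name, format(lower), format(upper)
    ))
  }
  invisible(x)
}

# draw a filled disc onto a matrix, returning the modified matrix
draw_disc <- function(img, r0, c0, radius, value, add = FALSE) {
  rr <- max(1L, floor(r0 - radius)):min(nrow(img), ceiling(r0 + radius))
  cc <- max(1L, floor(c0 - radius)):min(ncol(img), ceiling(c0 + radius))
  if (!length(rr) || !length(cc)) {
    return(img)
  }
  d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
  sel <- d2 <= radius^2
  block <- img[rr, cc, drop = FALSE]
  if (add) block[sel] <- block[sel] + value else block[sel] <- value
  img[rr, cc] <- block
  img
}

# draw an annulus (rim) onto a matrix
draw_annulus <- function(img, r0, c0, r_in, r_out, value) {
  rr <- max(1L, floor(r0 - r_out)):min(nrow(img), ceiling(r0 + r_out))
  cc <- max(1L, floor(c0 - r_out)):min(ncol(img), ceiling(c0 + r_out))
  if (!length(rr) || !length(cc)) {
    return(img)
  }
  d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
  sel <- d2 <= r_out^2 & d2 > r_in^2
  block <- img[rr, cc, drop = FALSE]
  block[sel] <- value
  img[rr, cc] <- block
  img
}

# Dense resampling of a polyline at ~`step` pixel spacing.
# polyline: matrix with columns (r, c). Returns matrix (r, c) plus arc length.
resample_polyline <- function(polyline, step = 0.5) {
  stopifnot(is.matrix(polyline), ncol(polyline) == 2, nrow(polyline) >= 2)
  seg <- sqrt(rowSums(diff(polyline)^2))
  total <- sum(seg)
  if (total == 0) {
    abort("degenerate polyline: zero arc length")
  }
  s <- c(0, cumsum(seg))
  out_s <- seq(0, total, by = step)
  if (tail(out_s, 1) < total) out_s <- c(out_s, total)
  r <- approx(s, polyline[, 1], xout = out_s)$y
  c_ <- approx(s, polyline[, 2], xout = out_s)$y
  list(points = cbind(r = r, c = c_), length_px = total)
}

#' @importFrom stats approx
NULL
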