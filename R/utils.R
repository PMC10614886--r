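# Internal helpers shared across modules.

# Evaluate expr with a locally seeded RNG, restoring the caller's state.
withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Bilinear interpolation of matrix m at 0-based pixel coordinates
# (x = column, y = row).  Points must satisfy 0 <= x <= ncol-1,
# 0 <= y <= nrow-1; the caller validates bounds.
bilinear <- function(m, x, y) {
  nr <- nrow(m); nc <- ncol(m)
  x0 <- pmin(floor(x), nc - 2); x0 <- pmax(x0, 0)
  y0 <- pmin(floor(y), nr - 2); y0 <- pmax(y0, 0)
  fx <- x - x0; fy <- y - y0
  i00 <- y0 + 1 + x0 * nr        # column-major linear index of (y0, x0)
  v00 <- m[i00];        v01 <- m[i00 + nr]
  v10 <- m[i00 + 1];    v11 <- m[i00 + nr + 1]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) +
    fy * ((1 - fx) * v10 + fx * v11)
}

# First (lowest-index) argmax, the pole-proximal tie-break.
argmaxFirst <- function(v) which(v == max(v))[1]

# Uniform sample spacing of a profile, in um.
profileSpacing <- function(p) {
  d <- diff(p@positions)
  mean(d)
}

stopIfNot2D <- function(pt, what) {
  if (!is.numeric(pt) || length(pt) != 2L || any(!is.finite(pt)))
    stop(what, " must be a finite length-2 numeric (x, y)", call. = FALSE)
  invisible(pt)
}
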