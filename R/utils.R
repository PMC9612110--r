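#' @useDynLib lyomorph, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats qt rnorm runif rlnorm sd var quantile approx mad median
#' @importFrom utils head tail write.csv read.csv packageVersion
"_PACKAGE"

# Coordinate convention (used everywhere): images are numeric matrices
# m[row, col] with row 1 at the top; x = column index, y = -row (so angles
# are measured counter-clockwise from the +x axis in conventional display
# orientation). Pixel centers sit at integer (row, col), 1-based. Physical
# positions in micrometres count pixel widths from the image border.

#' Run code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so generator calls are reproducible
#' without clobbering the caller's RNG stream.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a per-stage seed from one global seed
#'
#' One global seed fans out to fixed per-stage seeds so that every pipeline
#' stage is independently reproducible. The derivation is a fixed affine map
#' modulo 2^31 - 1.
#' @param seed integer global seed.
#' @param stage one of `"synth"`, `"segment"`, `"pores"`, `"front"`,
#'   `"report"`.
#' @return a positive integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stages <- c("synth", "segment", "pores", "front", "report")
  stage <- match.arg(stage, stages)
  i <- match(stage, stages)
  s <- (as.double(seed) * 1009 + i * 9973) %% 2147483647
  as.integer(s + 1)
}

# Student-t confidence-interval half-width; NA for n < 2 (undefined).
t_ci_halfwidth <- function(x, confidence = 0.95) {
  n <- length(x)
  if (n < 2) return(NA_real_)
  qt(1 - (1 - confidence) / 2, df = n - 1) * sd(x) / sqrt(n)
}

# Strip EBImage's Image class back to a plain matrix.
as_mat <- function(x) {
  x <- EBImage::imageData(x)
  d <- dim(x)
  matrix(as.numeric(x), nrow = d[1], ncol = d[2])
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
}
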