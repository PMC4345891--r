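`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Rounds to the nearest integer with ties going away from zero (unlike
#' [round()], which rounds half to even). Used for reporting physical cell
#' dimensions in micrometres.
#'
#' @param x numeric vector.
#' @return numeric vector of rounded values.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5, 241.3333))
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Evaluate `code` under a temporary RNG state seeded with `seed`; the global
# RNG stream is restored afterwards. seed = NULL means "use current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Fisher-Yates shuffle driven by the current RNG stream.
fisher_yates <- function(x) {
  n <- length(x)
  if (n < 2L) return(x)
  for (i in n:2) {
    j <- 1L + floor(stats::runif(1) * i)  # uniform on 1..i
    tmp <- x[i]; x[i] <- x[j]; x[j] <- tmp
  }
  x
}

next_id <- function(prefix) {
  .optomap$counter <- .optomap$counter + 1L
  sprintf("%s-%d", prefix, .optomap$counter)
}

is_whole <- function(x, tol = 1e-9) all(abs(x - round(x)) < tol)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
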