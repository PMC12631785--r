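# Small numeric helpers shared across modules.

vnorm <- function(v) sqrt(sum(v * v))

normalize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) return(c(0, 0, 0))
  v / n
}

#' Random rigid motion
#'
#' Draws a uniform-ish random rotation (QR of a Gaussian matrix, determinant
#' forced to +1) and a random translation.  Used throughout the test suite to
#' check E(3) invariance of features and predictions.
#'
#' @param scale translation scale in Angstrom.
#' @return list with `R` (3x3 rotation) and `t` (length-3 translation).
#' @export
random_rigid_motion <- function(scale = 50) {
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  # fix signs so Q is a proper rotation
  d <- diag(qr.R(qr_))
  Q <- Q %*% diag(sign(d))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  list(R = Q, t = stats::rnorm(3, sd = scale))
}

#' Apply a rigid motion to an n x 3 coordinate matrix
#' @param X n x 3 matrix.
#' @param motion list with `R` and `t` as from [random_rigid_motion()].
#' @export
apply_rigid_motion <- function(X, motion) {
  sweep(X %*% t(motion$R), 2, motion$t, "+")
}

# Deterministic 31-adic string hash into [0, 2^31-2]; platform independent.
string_hash <- function(s) {
  codes <- utf8ToInt(s)
  h <- 0
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

# Run fn with a local RNG seed, restoring global RNG state afterwards.
with_seed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# md5 of a character scalar (via tools::md5sum on a temp file).
text_md5 <- function(txt) {
  f <- tempfile()
  writeLines(txt, f)
  on.exit(unlink(f))
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
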