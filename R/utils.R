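`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a local, reproducible RNG state
#'
#' Sets the Mersenne-Twister generator with a fixed seed for the duration of
#' `code` and restores the caller's RNG state afterwards, so that no function
#' in the package ever leaks or depends on global generator state.
#'
#' @param seed integer seed (kept below 2^31).
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed) %% .Machine$integer.max, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

unit_vector <- function(v) {
  n <- sqrt(sum(v * v))
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

#' Angle between two 3-vectors
#'
#' @param a,b numeric 3-vectors (normalized internally; zero vectors error).
#' @return Angle in degrees, range \[0, 180\].
#' @export
vector_angle <- function(a, b) {
  a <- unit_vector(a); b <- unit_vector(b)
  d <- sum(a * b)
  acos(max(-1, min(1, d))) * 180 / pi
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix from an axis and an angle
#'
#' @param axis 3-vector (normalized internally).
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 orthonormal rotation matrix.
#' @export
rotation_matrix <- function(axis, angle_deg) {
  u <- unit_vector(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# uniform random rotation (uses the current RNG stream)
random_rotation <- function() {
  axis <- rnorm(3)
  rotation_matrix(axis, runif(1, 0, 360))
}

# squared Euclidean cross-distances between rows of A (m x 3) and B (n x 3)
cross_dist2 <- function(A, B) {
  d2 <- outer(rowSums(A * A), rowSums(B * B), "+") - 2 * (A %*% t(B))
  d2[d2 < 0] <- 0
  d2
}

# tiny FNV-1a hash for run logs (no external digest dependency)
text_hash <- function(x) {
  h <- 2166136261
  for (b in utf8ToInt(paste(x, collapse = "\n"))) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

# condition helpers for the CLI exit-code contract
tmc_config_error <- function(msg) {
  stop(structure(class = c("tmc_config_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}
tmc_data_error <- function(msg) {
  stop(structure(class = c("tmc_data_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}
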