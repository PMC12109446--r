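# Shared internal helpers: channel naming, seeded evaluation, input checks.

# Canonical smartphone channel order used throughout the package.
GAIT_CHANNELS <- c("Ax", "Ay", "Az", "Gx", "Gy", "Gz", "Yaw", "Pitch", "Roll")

# Channels the preprocessing stage drops by default: during level walking the
# mediolateral acceleration, the frontal-axis angular velocity and the pitch
# angle of a thigh-mounted phone vary little compared with the sagittal-plane
# channels, so they carry almost no event information.
DEFAULT_EXCLUDED <- c("Az", "Gx", "Pitch")

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. A NULL seed evaluates in the current stream.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
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
  force(expr)
}

#' Derive a stage seed from one root seed
#'
#' Deterministically maps a root seed and a stream name to a sub-seed in the
#' 32-bit integer range, so that one top-level seed reproducibly drives
#' every stage (simulate / split / train / ...) without stream collisions.
#'
#' @param root Integer root seed.
#' @param stream Character stream name.
#' @return An integer seed.
#' @export
derive_seed <- function(root, stream) {
  stopifnot(is.numeric(root), length(root) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(root) * 7919 + h) %% .Machine$integer.max)
}

stop_if_not_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive.", name))
  }
  invisible(x)
}

check_fraction <- function(x, name) {
  stop_if_not_scalar_number(x, name)
  if (x <= 0 || x >= 1) {
    abort(sprintf("`%s` must lie strictly between 0 and 1.", name))
  }
  invisible(x)
}

is_gait_recording <- function(x) inherits(x, "gait_recording")

assert_recording <- function(x) {
  if (!is_gait_recording(x)) {
    abort("Expected a `gait_recording` object (see `simulate_recording()`).")
  }
  invisible(x)
}

# Channels actually present in a recording, in canonical order.
recording_channels <- function(rec) {
  intersect(GAIT_CHANNELS, names(rec$signals))
}
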