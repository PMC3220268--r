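#' @keywords internal
"_PACKAGE"

## Classed conditions so callers/tests can discriminate failure modes without
## string matching.
abort <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "arpdyn_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

warn <- function(class, msg, ...) {
  warning(structure(
    class = c(class, "arpdyn_warning", "warning", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global random stream set from `seed`, then restores
#' the caller's `.Random.seed`, so generators are pure functions of their
#' seed and never perturb user code.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

## Flatten an N x 3 coordinate matrix to the (x1,y1,z1,x2,...) row layout
## used for trajectory frames, and back.
xyz_flatten <- function(m) as.vector(t(m))

xyz_unflatten <- function(v) matrix(v, ncol = 3L, byrow = TRUE)

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation by `angle_deg` degrees about the direction `axis`
#' (normalised internally).
#'
#' @param axis numeric length-3 direction vector (need not be unit).
#' @param angle_deg rotation angle in degrees.
#' @return a 3x3 proper rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
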