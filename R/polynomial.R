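#' The canonical complete-cubic monomial basis in three variables
#'
#' All 20 monomials of total degree <= 3 in (x, y, z), in the fixed canonical
#' order `1, x, y, z, x^2, xy, xz, y^2, yz, z^2, x^3, x^2y, x^2z, xy^2, xyz,
#' xz^2, y^3, y^2z, yz^2, z^3`.  20 = choose(6, 3) is the dimension of the
#' complete cubic polynomial space.
#'
#' @return A 20 x 3 integer matrix of exponents; row k gives the powers of
#'   (x, y, z) in the k-th basis monomial.
#' @export
cubic_exponents <- function() {
  .cubic_cache$exponents
}

cubic_exponents_build <- function() {
  m <- rbind(
    c(0L, 0L, 0L),
    c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L),
    c(2L, 0L, 0L), c(1L, 1L, 0L), c(1L, 0L, 1L),
    c(0L, 2L, 0L), c(0L, 1L, 1L), c(0L, 0L, 2L),
    c(3L, 0L, 0L), c(2L, 1L, 0L), c(2L, 0L, 1L),
    c(1L, 2L, 0L), c(1L, 1L, 1L), c(1L, 0L, 2L),
    c(0L, 3L, 0L), c(0L, 2L, 1L), c(0L, 1L, 2L),
    c(0L, 0L, 3L))
  rownames(m) <- c("1", "x", "y", "z", "x2", "xy", "xz", "y2", "yz", "z2",
                   "x3", "x2y", "x2z", "xy2", "xyz", "xz2",
                   "y3", "y2z", "yz2", "z3")
  colnames(m) <- c("x", "y", "z")
  m
}

#' Evaluate the 20 cubic basis monomials
#'
#' @param state Either a length-3 numeric state `(x, y, z)` or an `n x 3`
#'   matrix of states (one state per row).
#' @return For a single state, a length-20 vector; for a matrix, an `n x 20`
#'   matrix, columns in canonical order (first entry/column is always 1).
#' @export
monomial_basis <- function(state) {
  if (is.matrix(state)) {
    if (ncol(state) != 3L) stop("state matrix must have 3 columns")
    x <- state[, 1]; y <- state[, 2]; z <- state[, 3]
    out <- cbind(1, x, y, z, x * x, x * y, x * z, y * y, y * z, z * z,
                 x^3, x * x * y, x * x * z, x * y * y, x * y * z,
                 x * z * z, y^3, y * y * z, y * z * z, z^3)
    colnames(out) <- rownames(cubic_exponents())
    out
  } else {
    if (length(state) != 3L) stop("state must have 3 components")
    if (!all(is.finite(state))) stop("state must be finite")
    x <- state[1]; y <- state[2]; z <- state[3]
    c(1, x, y, z, x * x, x * y, x * z, y * y, y * z, z * z,
      x^3, x * x * y, x * x * z, x * y * y, x * y * z,
      x * z * z, y^3, y * y * z, y * z * z, z^3)
  }
}

#' Cubic-polynomial ODE model in three state variables
#'
#' Represents the autonomous system `xdot = f(x, y, z)` with each component
#' a complete cubic polynomial: `f_i = sum_k c[i, k] * m_k(x, y, z)` over the
#' canonical 20-monomial basis of [cubic_exponents()].
#'
#' @param coefficients A 3 x 20 numeric matrix; row i is the equation for
#'   the i-th state derivative, columns in canonical monomial order.
#' @param state_units Character length-3 unit labels for the state variables.
#' @param time_unit Time unit of the derivatives (fixed convention: month).
#' @return An object of class `poly_ode_model`.
#' @export
poly_ode_model <- function(coefficients,
                           state_units = c("h/month", "mm/month", "degC"),
                           time_unit = "month") {
  coefficients <- as.matrix(coefficients)
  if (!all(dim(coefficients) == c(3L, 20L)))
    stop("'coefficients' must be a 3 x 20 matrix")
  if (!all(is.finite(coefficients)))
    stop("'coefficients' must be finite")
  dimnames(coefficients) <- list(c("dx", "dy", "dz"),
                                 rownames(cubic_exponents()))
  structure(list(coefficients = coefficients,
                 state_units = state_units, time_unit = time_unit),
            class = "poly_ode_model")
}

#' @export
print.poly_ode_model <- function(x, ...) {
  act <- colSums(abs(x$coefficients) > 1e-12)
  cat(sprintf("<poly_ode_model> 3 equations x 20 cubic terms (%d active columns)\n",
              sum(act > 0)))
  invisible(x)
}

#' Right-hand side of a cubic ODE model
#'
#' @param model A [poly_ode_model()].
#' @param state Length-3 state or `n x 3` matrix of states.
#' @return Derivative triple (or `n x 3` matrix of derivatives).
#' @export
evaluate_rhs <- function(model, state) {
  b <- monomial_basis(state)
  if (is.matrix(b)) b %*% t(model$coefficients)
  else as.numeric(model$coefficients %*% b)
}

# Coefficients of r(w) = p(offset + slope * w) for a complete-cubic p.
# `coefs` length 20 in canonical order; returns length 20.
poly_substitute_affine <- function(coefs, offset, slope) {
  ex <- cubic_exponents()
  key <- ex[, 1] * 16L + ex[, 2] * 4L + ex[, 3]  # unique since exponents <= 3
  pos <- integer(64L); pos[key + 1L] <- seq_len(20L)
  out <- numeric(20L)
  for (k in seq_len(20L)) {
    ck <- coefs[k]
    if (ck == 0) next
    a <- ex[k, ]
    for (j1 in 0:a[1]) for (j2 in 0:a[2]) for (j3 in 0:a[3]) {
      w <- ck *
        choose(a[1], j1) * slope[1]^j1 * offset[1]^(a[1] - j1) *
        choose(a[2], j2) * slope[2]^j2 * offset[2]^(a[2] - j2) *
        choose(a[3], j3) * slope[3]^j3 * offset[3]^(a[3] - j3)
      tgt <- pos[j1 * 16L + j2 * 4L + j3 + 1L]
      out[tgt] <- out[tgt] + w
    }
  }
  out
}

# Affine state scaling x = center + half * u (u the scaled state).
# scale_model_down: model in x-units -> equivalent model in u-units.
# scale_model_up:   model in u-units -> equivalent model in x-units.
scale_model_down <- function(model, center, half) {
  co <- model$coefficients
  out <- co
  for (i in 1:3)
    out[i, ] <- poly_substitute_affine(co[i, ], center, half) / half[i]
  poly_ode_model(out, state_units = rep("scaled", 3),
                 time_unit = model$time_unit)
}

scale_model_up <- function(model, center, half,
                           state_units = c("h/month", "mm/month", "degC")) {
  co <- model$coefficients
  out <- co
  for (i in 1:3)
    out[i, ] <- poly_substitute_affine(co[i, ], -center / half, 1 / half) * half[i]
  poly_ode_model(out, state_units = state_units, time_unit = model$time_unit)
}

#' Analytic Jacobian of a cubic ODE model
#'
#' Partial derivatives are obtained by differentiating the monomial basis
#' exactly (no finite differences).
#'
#' @param model A [poly_ode_model()].
#' @param state Length-3 state.
#' @return The 3 x 3 Jacobian matrix of the right-hand side at `state`.
#' @export
model_jacobian <- function(model, state) {
  ex <- cubic_exponents()
  pos <- .cubic_cache$position
  b <- monomial_basis(state)
  J <- matrix(0, 3, 3)
  for (d in 1:3) {
    # d/dx_d of monomial k = a_d * monomial with exponent a_d reduced by one
    db <- numeric(20L)
    for (k in seq_len(20L)) {
      a <- ex[k, d]
      if (a > 0L) {
        red <- ex[k, ]; red[d] <- red[d] - 1L
        db[k] <- a * b[pos[red[1] * 16L + red[2] * 4L + red[3] + 1L]]
      }
    }
    J[, d] <- model$coefficients %*% db
  }
  J
}

# Partial derivatives of all 20 basis monomials with respect to variable d,
# evaluated at a matrix of states (n x 3) -> n x 20.
monomial_deriv_basis <- function(states, d) {
  ex <- cubic_exponents()
  pos <- .cubic_cache$position
  b <- monomial_basis(states)
  out <- matrix(0, nrow(states), 20L)
  for (k in seq_len(20L)) {
    a <- ex[k, d]
    if (a > 0L) {
      red <- ex[k, ]; red[d] <- red[d] - 1L
      out[, k] <- a * b[, pos[red[1] * 16L + red[2] * 4L + red[3] + 1L]]
    }
  }
  out
}

# Load-time caches: the exponent table and the monomial position lookup.
.cubic_cache <- new.env(parent = emptyenv())
local({
  .cubic_cache$exponents <- cubic_exponents_build()
  ex <- .cubic_cache$exponents
  pos <- integer(64L)
  pos[ex[, 1] * 16L + ex[, 2] * 4L + ex[, 3] + 1L] <- seq_len(20L)
  .cubic_cache$position <- pos
})

#' Serialize a cubic ODE model to JSON
#'
#' @param model A [poly_ode_model()].
#' @param path Output path; when `NULL` the JSON string is returned.
#' @return `path` (or the JSON string), invisibly.
#' @export
write_model_json <- function(model, path = NULL) {
  obj <- list(basis = rownames(cubic_exponents()),
              coefficients = unname(model$coefficients),
              state_units = model$state_units,
              time_unit = model$time_unit)
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(as.character(js), path)
  invisible(path)
}

#' Read a cubic ODE model from JSON
#' @param path JSON file written by [write_model_json()].
#' @return A [poly_ode_model()].
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  poly_ode_model(matrix(unlist(obj$coefficients), 3, 20, byrow = FALSE),
                 state_units = obj$state_units, time_unit = obj$time_unit)
}
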