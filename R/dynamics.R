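#' Find real equilibria of a cubic ODE model by multi-start Newton
#'
#' Newton iterations (analytic Jacobian) are started from a `grid_n^3`
#' lattice spanning the search box; converged roots are deduplicated within
#' `tol` in box-scaled units, restricted to the box, and sorted
#' lexicographically.  The box should cover the data range inflated about
#' twofold.  Internally the states are rescaled by the box so tolerances
#' are meaningful across units.
#'
#' @param model A [poly_ode_model()].
#' @param search_box List with `lo` and `hi` (length-3 each).
#' @param grid_n Lattice points per axis (default 15).
#' @param tol Deduplication tolerance in scaled units.
#' @param residual_tol Acceptance threshold on the scaled residual norm.
#' @return Matrix of equilibrium states (possibly 0 rows), one per row.
#' @export
find_equilibria <- function(model, search_box, grid_n = 15L, tol = 1e-6,
                            residual_tol = 1e-8) {
  lo <- search_box$lo; hi <- search_box$hi
  stopifnot(length(lo) == 3L, length(hi) == 3L, all(hi > lo))
  half <- (hi - lo) / 2
  mid <- (lo + hi) / 2
  grid1 <- lapply(1:3, function(d) seq(lo[d], hi[d], length.out = grid_n))
  S <- as.matrix(expand.grid(grid1[[1]], grid1[[2]], grid1[[3]]))
  colnames(S) <- NULL
  alive <- rep(TRUE, nrow(S))
  done <- rep(FALSE, nrow(S))
  # vectorized damped Newton over all lattice starts simultaneously
  for (it in 1:60) {
    if (!any(alive)) break
    A <- S[alive, , drop = FALSE]
    F <- monomial_basis(A) %*% t(model$coefficients)
    Fs <- sweep(F, 2, half, "/")
    rn <- sqrt(rowSums(Fs * Fs))
    conv <- is.finite(rn) & rn < residual_tol
    if (any(conv)) {
      ids <- which(alive)[conv]
      done[ids] <- TRUE
      alive[ids] <- FALSE
    }
    keep <- !conv & is.finite(rn)
    if (!any(keep)) { alive[alive] <- FALSE; next }
    ids <- which(alive)            # rows still iterating (post-conv removal)
    A <- S[ids, , drop = FALSE]
    F <- monomial_basis(A) %*% t(model$coefficients)
    Jc <- lapply(1:3, function(d)
      monomial_deriv_basis(A, d) %*% t(model$coefficients))  # n x 3 each
    # per-row 3x3 solve by cofactor expansion (columns d of J are Jc[[d]])
    a1 <- Jc[[1]][, 1]; a2 <- Jc[[2]][, 1]; a3 <- Jc[[3]][, 1]
    b1 <- Jc[[1]][, 2]; b2 <- Jc[[2]][, 2]; b3 <- Jc[[3]][, 2]
    c1 <- Jc[[1]][, 3]; c2 <- Jc[[2]][, 3]; c3 <- Jc[[3]][, 3]
    det <- a1 * (b2 * c3 - b3 * c2) - a2 * (b1 * c3 - b3 * c1) +
      a3 * (b1 * c2 - b2 * c1)
    f1 <- F[, 1]; f2 <- F[, 2]; f3 <- F[, 3]
    s1 <- (f1 * (b2 * c3 - b3 * c2) - a2 * (f2 * c3 - b3 * f3) +
             a3 * (f2 * c2 - b2 * f3)) / det
    s2 <- (a1 * (f2 * c3 - b3 * f3) - f1 * (b1 * c3 - b3 * c1) +
             a3 * (b1 * f3 - f2 * c1)) / det
    s3 <- (a1 * (b2 * f3 - f2 * c2) - a2 * (b1 * f3 - f2 * c1) +
             f1 * (b1 * c2 - b2 * c1)) / det
    step <- cbind(s1, s2, s3)
    bad <- !is.finite(det) | abs(det) < 1e-300 |
      !is.finite(rowSums(step))
    sn <- sqrt(rowSums(sweep(step, 2, half, "/")^2))
    damp <- ifelse(sn > 2, 2 / sn, 1)
    Snew <- A - step * damp
    out <- rowSums(abs(sweep(sweep(Snew, 2, mid), 2, half, "/")) > 10) > 0
    kill <- bad | out | !is.finite(rowSums(Snew))
    S[ids, ] <- ifelse(is.finite(Snew), Snew, 0)
    alive[ids[kill]] <- FALSE
  }
  cand <- S[done, , drop = FALSE]
  roots <- matrix(numeric(0), 0, 3)
  for (s in seq_len(nrow(cand))) {
    x <- cand[s, ]
    if (any(x < lo) || any(x > hi)) next
    dup <- FALSE
    if (nrow(roots) > 0) {
      d <- sweep(roots, 2, x)
      if (min(sqrt(rowSums(sweep(d, 2, half, "/")^2))) < tol) dup <- TRUE
    }
    if (!dup) roots <- rbind(roots, x)
  }
  if (nrow(roots) > 1L)
    roots <- roots[order(roots[, 1], roots[, 2], roots[, 3]), , drop = FALSE]
  rownames(roots) <- NULL
  colnames(roots) <- c("x", "y", "z")
  roots
}

#' Classify an equilibrium from its three eigenvalues
#'
#' With one complex-conjugate pair and one real eigenvalue the pair defines
#' spiralling (focus) local behaviour in its invariant plane -- unstable
#' when the real part is positive -- and the lone real eigenvalue defines
#' straight-line (node) behaviour along its eigendirection.  With three
#' real eigenvalues the point is a node (all same sign) or a saddle (mixed
#' signs).  The point is hyperbolic iff no eigenvalue has (numerically)
#' zero real part.
#'
#' @param eigenvalues Exactly three eigenvalues (complex or real).
#' @param zero_tol Threshold below which a real part counts as zero.
#' @return List of class `equilibrium_class` with `planar`
#'   (`stable_focus`, `unstable_focus`, `stable_node`, `unstable_node` or
#'   `saddle`), `axial` (`stable_node`/`unstable_node`, `NA` for the
#'   three-real case), `hyperbolic`, `any_unstable` and `label` (a
#'   human-readable characteristic string).
#' @export
classify_equilibrium <- function(eigenvalues, zero_tol = 1e-6) {
  ev <- as.complex(eigenvalues)
  if (length(ev) != 3L) stop("exactly 3 eigenvalues are required")
  re <- Re(ev); im <- Im(ev)
  hyperbolic <- min(abs(re)) > zero_tol
  any_unstable <- any(re > zero_tol)
  is_cplx <- abs(im) > 1e-12
  if (sum(is_cplx) == 2L) {
    pair_re <- re[is_cplx][1]
    axis_re <- re[!is_cplx]
    planar <- if (pair_re > 0) "unstable_focus" else "stable_focus"
    axial <- if (axis_re > 0) "unstable_node" else "stable_node"
    label <- sprintf("%s focus in (X,Y), %s node along Z",
                     if (pair_re > 0) "unstable" else "stable",
                     if (axis_re > 0) "unstable" else "stable")
  } else if (sum(is_cplx) == 0L) {
    planar <- if (all(re > 0)) "unstable_node"
              else if (all(re < 0)) "stable_node"
              else "saddle"
    axial <- NA_character_
    label <- switch(planar, unstable_node = "unstable node",
                    stable_node = "stable node", saddle = "saddle")
  } else {
    stop("eigenvalues must be three reals or one real plus a conjugate pair")
  }
  structure(list(planar = planar, axial = axial, hyperbolic = hyperbolic,
                 any_unstable = any_unstable, label = label),
            class = "equilibrium_class")
}

#' @export
print.equilibrium_class <- function(x, ...) {
  cat(sprintf("<equilibrium_class> %s%s\n", x$label,
              if (x$hyperbolic) " (hyperbolic)" else " (non-hyperbolic)"))
  invisible(x)
}

#' Equilibria of a model with eigenvalues and stability classification
#'
#' Convenience wrapper: [find_equilibria()], then the analytic Jacobian and
#' its eigenvalues at each root, then [classify_equilibrium()].
#'
#' @inheritParams find_equilibria
#' @return List of equilibrium records (`state`, `eigenvalues`,
#'   `classification`, `residual_norm`), sorted as [find_equilibria()].
#' @export
equilibrium_analysis <- function(model, search_box, grid_n = 15L,
                                 tol = 1e-6) {
  half <- (search_box$hi - search_box$lo) / 2
  pts <- find_equilibria(model, search_box, grid_n = grid_n, tol = tol)
  lapply(seq_len(nrow(pts)), function(i) {
    st <- pts[i, ]
    ev <- eigen(model_jacobian(model, st), only.values = TRUE)$values
    list(state = st, eigenvalues = ev,
         classification = classify_equilibrium(ev),
         residual_norm = sqrt(sum((evaluate_rhs(model, st) / half)^2)))
  })
}

#' Export an equilibrium table as CSV
#'
#' One row per equilibrium: state values, eigenvalues (as `a+bi` strings)
#' and the characteristic label.
#'
#' @param eq List from [equilibrium_analysis()].
#' @param path Output CSV path.
#' @return The data frame, invisibly.
#' @export
write_equilibria_csv <- function(eq, path) {
  fmt_ev <- function(v) sprintf("%.6g%+.6gi", Re(v), Im(v))
  df <- do.call(rbind, lapply(seq_along(eq), function(i) {
    e <- eq[[i]]
    data.frame(point = paste0("P", i),
               sunshine = e$state[1], precipitation = e$state[2],
               temperature = e$state[3],
               eigenvalue_1 = fmt_ev(e$eigenvalues[1]),
               eigenvalue_2 = fmt_ev(e$eigenvalues[2]),
               eigenvalue_3 = fmt_ev(e$eigenvalues[3]),
               characteristic = e$classification$label,
               hyperbolic = e$classification$hyperbolic,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Long-term integration of a model
#'
#' Fixed-step RK4 run with a blow-up guard; on divergence the run is
#' returned up to the divergence point with `completed = FALSE`.  The
#' simulated span in years is `floor(steps * dt / 12)`.
#'
#' @param model A [poly_ode_model()].
#' @param initial_state Length-3 state.
#' @param steps Number of iterations (default 7000; at `dt = 1` month this
#'   spans 583 years).
#' @param dt Step in months.
#' @param transient_frac Fraction of the run discarded as transient before
#'   period estimation (default 0.3).
#' @param bound Blow-up guard.
#' @return Object of class `long_term_run`: `trajectory` (matrix), `steps`,
#'   `dt`, `transient_cut`, `years`, `completed`.
#' @export
long_term <- function(model, initial_state, steps = 7000L, dt = 1,
                      transient_frac = 0.3, bound = 1e8) {
  tr <- rk4_trajectory(model, initial_state, n_steps = steps, dt = dt,
                       bound = bound)
  structure(list(trajectory = tr$states, steps = as.integer(steps), dt = dt,
                 transient_cut = as.integer(floor(transient_frac * steps)),
                 years = as.integer(steps * dt / 12),
                 completed = tr$completed),
            class = "long_term_run")
}

#' @export
print.long_term_run <- function(x, ...) {
  cat(sprintf("<long_term_run> %d steps of %g month(s) = %d simulated years%s\n",
              x$steps, x$dt, x$years,
              if (x$completed) "" else " [diverged]"))
  invisible(x)
}

#' Estimate the oscillation period of a long-term run
#'
#' Mean spacing of upward mean-crossings of the mean-removed component
#' (default the temperature component, the headline oscillating variable)
#' over the post-transient segment.  Crossing times are refined by linear
#' interpolation.  Fewer than 2 crossings, or a flat signal, yield an
#' undefined period (`NA` with a reason), not an exception.
#'
#' @param run A `long_term_run`, or a numeric vector treated as an already
#'   post-transient signal sampled at `dt` months.
#' @param component Column used when `run` is a `long_term_run` (3 =
#'   temperature).
#' @param dt Sampling interval when `run` is a plain vector.
#' @return List with `period_months` (`NA` when undefined), `n_crossings`,
#'   `reason` (when undefined).
#' @export
estimate_period <- function(run, component = 3L, dt = NULL) {
  if (inherits(run, "long_term_run")) {
    x <- run$trajectory[, component]
    x <- x[(run$transient_cut + 1L):length(x)]
    dt <- run$dt
  } else {
    x <- as.numeric(run)
    if (is.null(dt)) dt <- 1
  }
  x <- x - mean(x)
  if (max(abs(x)) < 1e-12)
    return(list(period_months = NA_real_, n_crossings = 0L,
                reason = "flat signal"))
  up <- which(x[-length(x)] < 0 & x[-1] >= 0)
  if (length(up) < 2L)
    return(list(period_months = NA_real_, n_crossings = length(up),
                reason = "fewer than 2 upward mean-crossings"))
  # linear interpolation of the crossing instants
  tc <- up + x[up] / (x[up] - x[up + 1L])
  list(period_months = mean(diff(tc)) * dt, n_crossings = length(up),
       reason = NULL)
}
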