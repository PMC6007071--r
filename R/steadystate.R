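# Regular barycentric grid over the conservation simplex
# {OO, OP, PO, PP >= 0, sum = tot}, returned in reduced (OO, PP, PO)
# coordinates. step = tot/4 gives 35 points including the four vertices.
simplex_grid <- function(tot, step = tot / 4) {
  k <- round(tot / step)
  pts <- list()
  for (i in 0:k) {
    for (j in 0:(k - i)) {
      for (l in 0:(k - i - j)) {
        pts[[length(pts) + 1]] <- c(OO = i, PP = j, PO = l) * step
      }
    }
  }
  do.call(rbind, pts)
}

# Is the PO coordinate structurally frozen (all reactions that change PO
# inactive)? Then the system is effectively 2-D on the PO = const slice, as
# in the AM topology, and stability must be judged on the (OO, PP) block.
po_frozen <- function(model) {
  all(model$rates[c("p1", "p2", "d1", "d2", "bp1", "bp2", "bd1", "bd2")] == 0)
}

# Damped Newton iteration for f(x) = 0 with analytic Jacobian.
# `dims` selects the active coordinates (1:3, or 1:2 when PO is frozen).
newton_solve <- function(f, J, x0, dims = 1:3, tol = 1e-12, maxit = 100,
                         bound = NULL) {
  x <- x0
  fx <- f(x)[dims]
  for (it in seq_len(maxit)) {
    if (max(abs(fx)) < tol) {
      return(list(x = x, fnorm = max(abs(fx)), converged = TRUE))
    }
    Jx <- J(x)[dims, dims, drop = FALSE]
    dx <- tryCatch(solve(Jx, -fx), error = function(e) NULL)
    if (is.null(dx) || any(!is.finite(dx))) {
      return(list(x = x, fnorm = max(abs(fx)), converged = FALSE))
    }
    lambda <- 1
    improved <- FALSE
    repeat {
      xn <- x
      xn[dims] <- x[dims] + lambda * dx
      fn <- f(xn)[dims]
      if (all(is.finite(fn)) && max(abs(fn)) < max(abs(fx))) {
        improved <- TRUE
        break
      }
      lambda <- lambda / 2
      if (lambda < 1e-4) break
    }
    if (!improved) {
      # stuck (typically a singular Jacobian on an equilibrium continuum)
      return(list(x = x, fnorm = max(abs(fx)), converged = FALSE))
    }
    x[dims] <- x[dims] + lambda * dx
    fx <- f(x)[dims]
    if (!is.null(bound) && max(abs(x)) > bound) {
      return(list(x = x, fnorm = max(abs(fx)), converged = FALSE))
    }
  }
  list(x = x, fnorm = max(abs(fx)), converged = max(abs(fx)) < tol)
}

# Central finite-difference Jacobian of the reduced system (cross-check
# route; the analytic Jacobian is the default).
jacobian_fd <- function(f, x, h) {
  n <- length(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    e <- numeric(n)
    e[j] <- h
    J[, j] <- (f(x + e) - f(x - e)) / (2 * h)
  }
  dimnames(J) <- list(names(x), names(x))
  J
}

#' Locate all steady states on the conservation simplex
#'
#' Runs a damped Newton iteration from a regular barycentric grid over the
#' `(OO, PP, PO)` simplex (step `tot/4`, 35 starts including the vertices),
#' plus any caller-supplied seeds (used for branch continuation). Converged
#' roots are deduplicated, filtered for physicality, and classified by the
#' eigenvalues of the reduced Jacobian. For topologies in which the `PO`
#' coordinate is structurally frozen (the AM case) the root search and the
#' stability analysis run on the two-dimensional `(OO, PP)` slice at
#' `PO = 0`.
#'
#' @param model An `sw_model`.
#' @param nt Optional phosphate-donor override.
#' @param seeds Optional matrix (or list) of additional reduced starting
#'   points `(OO, PP, PO)`.
#' @param grid_step Barycentric grid spacing, default `tot/4`.
#' @param root_tol Newton residual tolerance (max norm), default 1e-12.
#' @param dedup_tol Deduplication radius in max norm, default 1e-6.
#' @param marginal_band Half-width of the marginal band on eigenvalue real
#'   parts, default 1e-6 (wide enough to absorb the near-zero eigenvalues of
#'   roots sitting on an equilibrium continuum, as in the CO/SO topologies).
#' @param jacobian `"analytic"` (default) or `"fd"` (central differences,
#'   step `1e-6 * tot`).
#' @return A tibble of class `sw_steady_states` with columns `OO`, `OP`,
#'   `PO`, `PP`, `residual`, `lead_eig_re` (largest eigenvalue real part) and
#'   `stability` (`"stable"`, `"unstable"` or `"marginal"`). Zero rows (with
#'   a warning) if no root converged.
#' @examples
#' steady_states(sw_model("AM", nt = 4)) # two stable states and a saddle
#' @export
steady_states <- function(model, nt = NULL, seeds = NULL,
                          grid_step = NULL, root_tol = 1e-12,
                          dedup_tol = 1e-6, marginal_band = 1e-6,
                          jacobian = c("analytic", "fd")) {
  stopifnot(inherits(model, "sw_model"))
  jacobian <- match.arg(jacobian)
  tot <- model$tot
  nt_val <- nt %||% model$nt
  f <- build_rhs(model, nt = nt_val)
  Ja <- build_jacobian(model, nt = nt_val)
  J <- if (jacobian == "analytic") Ja else function(x) jacobian_fd(f, x, 1e-6 * tot)
  frozen <- po_frozen(model)
  dims <- if (frozen) 1:2 else 1:3

  starts <- simplex_grid(tot, grid_step %||% (tot / 4))
  if (frozen) starts <- unique(starts[starts[, "PO"] == 0, , drop = FALSE])
  if (!is.null(seeds)) {
    seeds <- if (is.list(seeds)) do.call(rbind, seeds) else rbind(seeds)
    colnames(seeds) <- c("OO", "PP", "PO")
    if (frozen) seeds[, "PO"] <- 0
    starts <- rbind(starts, seeds)
  }

  roots <- list()
  for (i in seq_len(nrow(starts))) {
    res <- newton_solve(f, J, starts[i, ],
      dims = dims, tol = root_tol,
      bound = 10 * tot
    )
    if (!res$converged) next
    x <- res$x
    op <- tot - sum(x)
    if (min(x, op) < -1e-8) next # nonphysical
    roots[[length(roots) + 1]] <- c(x, residual = res$fnorm)
  }
  if (length(roots) == 0) {
    warning("No steady state found from any start (pathological topology?).")
    return(empty_steady_states(model, nt_val))
  }
  R <- do.call(rbind, roots)
  keep <- rep(TRUE, nrow(R))
  for (i in seq_len(nrow(R))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(R))) {
      if (j > i && keep[j] &&
        max(abs(R[j, 1:3] - R[i, 1:3])) <= dedup_tol) {
        keep[j] <- FALSE
      }
    }
  }
  R <- R[keep, , drop = FALSE]
  R <- R[order(R[, "OO"], R[, "PP"], R[, "PO"]), , drop = FALSE]

  eig_re <- numeric(nrow(R))
  flag <- character(nrow(R))
  for (i in seq_len(nrow(R))) {
    ev <- Re(eigen(J(R[i, 1:3])[dims, dims, drop = FALSE],
      only.values = TRUE
    )$values)
    eig_re[i] <- max(ev)
    flag[i] <- stability_flag(ev, marginal_band)
  }
  out <- tibble::tibble(
    OO = R[, "OO"], OP = tot - R[, "OO"] - R[, "PP"] - R[, "PO"],
    PO = R[, "PO"], PP = R[, "PP"],
    residual = R[, "residual"], lead_eig_re = eig_re, stability = flag
  )
  structure(out,
    class = c("sw_steady_states", class(out)),
    model = model$name, nt = nt_val, tot = tot
  )
}

stability_flag <- function(eig_re, band = 1e-6) {
  if (all(eig_re < -band)) "stable" else if (any(eig_re > band)) "unstable" else "marginal"
}

empty_steady_states <- function(model, nt_val) {
  out <- tibble::tibble(
    OO = numeric(), OP = numeric(), PO = numeric(), PP = numeric(),
    residual = numeric(), lead_eig_re = numeric(), stability = character()
  )
  structure(out,
    class = c("sw_steady_states", class(out)),
    model = model$name, nt = nt_val, tot = model$tot
  )
}

#' Linear stability of a steady state
#'
#' Evaluates the Jacobian of the reduced system at a state and classifies it
#' from the eigenvalue real parts: stable if all are below `-band`, unstable
#' if any exceeds `+band`, marginal otherwise.
#'
#' @param model An `sw_model`.
#' @param state Named vector with the four conformations (or the reduced
#'   three); must be a steady state within `check_tol`.
#' @param nt Optional phosphate-donor override.
#' @param band Marginal band half-width, default 1e-6.
#' @param check_tol Maximum allowed derivative norm at `state`, default 1e-8.
#' @param jacobian `"analytic"` or `"fd"`.
#' @return A list with `eig_re` (eigenvalue real parts, decreasing) and
#'   `stability`.
#' @export
stability <- function(model, state, nt = NULL, band = 1e-6, check_tol = 1e-8,
                      jacobian = c("analytic", "fd")) {
  stopifnot(inherits(model, "sw_model"))
  jacobian <- match.arg(jacobian)
  x <- as_reduced(state, model$tot)
  f <- build_rhs(model, nt = nt)
  if (max(abs(f(x))) > check_tol) {
    stop("`state` is not a steady state (|f| = ",
      format(max(abs(f(x)))), " > ", check_tol, ").",
      call. = FALSE
    )
  }
  J <- if (jacobian == "analytic") {
    build_jacobian(model, nt = nt)(x)
  } else {
    jacobian_fd(f, x, 1e-6 * model$tot)
  }
  dims <- if (po_frozen(model)) 1:2 else 1:3
  ev <- sort(Re(eigen(J[dims, dims, drop = FALSE], only.values = TRUE)$values),
    decreasing = TRUE
  )
  list(eig_re = ev, stability = stability_flag(ev, band))
}

# Coerce a 3- or 4-component named state into reduced (OO, PP, PO) coords.
as_reduced <- function(state, tot) {
  if (is.null(names(state))) {
    stopifnot(length(state) == 3)
    return(c(OO = state[[1]], PP = state[[2]], PO = state[[3]]))
  }
  c(
    OO = if ("OO" %in% names(state)) state[["OO"]] else 0,
    PP = if ("PP" %in% names(state)) state[["PP"]] else 0,
    PO = if ("PO" %in% names(state)) state[["PO"]] else 0
  )
}

#' @export
print.sw_steady_states <- function(x, ...) {
  cat("<sw_steady_states> model ", attr(x, "model"),
    ", nt = ", format(attr(x, "nt")), ": ",
    sum(x$stability == "stable"), " stable / ",
    nrow(x), " total\n",
    sep = ""
  )
  NextMethod()
}
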