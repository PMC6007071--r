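#' Classify the dynamical regime at one phosphate-donor level
#'
#' A point is `bistable` when two or more stable steady states coexist;
#' otherwise `oscillatory` when a sustained limit cycle is detected (with a
#' small deterministic multi-start fallback when no stable state exists);
#' otherwise `absorbing` when the unique steady state has one conformation
#' holding essentially the whole conserved pool (within `1e-3` of `tot`);
#' otherwise `monostable`.
#'
#' @param model An `sw_model`.
#' @param nt Phosphate-donor level.
#' @param seeds Optional extra Newton starts (continuation).
#' @param cycle_args List of arguments forwarded to [detect_limit_cycle()].
#' @param ss Optional precomputed [steady_states()] result.
#' @return A list of class `sw_regime_point` with `regime`, `n_stable`,
#'   `n_states`, `absorbing_species`, `ss` (steady-state tibble) and `cycle`.
#' @examples
#' classify_regime(preset("AM"), nt = 4)$regime # "bistable"
#' @export
classify_regime <- function(model, nt, seeds = NULL, cycle_args = list(),
                            ss = NULL) {
  stopifnot(inherits(model, "sw_model"))
  if (is.null(ss)) ss <- steady_states(model, nt = nt, seeds = seeds)
  n_stable <- sum(ss$stability == "stable")
  cycle <- NULL
  regime <- NA_character_
  absorbing_species <- NA_character_
  if (n_stable >= 2) {
    regime <- "bistable"
  } else {
    cycle <- do.call(
      detect_limit_cycle,
      c(list(model = model, nt = nt), cycle_args)
    )
    if (cycle$status == "inconclusive" || (cycle$status == "none" &&
      n_stable == 0 && nrow(ss) > 0)) {
      # fallback: a few deterministic off-grid starts
      for (frac in c(0.25, 0.6, 0.85)) {
        alt_args <- utils::modifyList(cycle_args, list(max_doublings = 1))
        alt <- do.call(detect_limit_cycle, c(
          list(
            model = model, nt = nt,
            init = c(
              OO = frac * model$tot,
              PP = (1 - frac) * 0.7 * model$tot,
              PO = (1 - frac) * 0.2 * model$tot
            )
          ),
          alt_args
        ))
        if (alt$status == "cycle") {
          cycle <- alt
          break
        }
      }
    }
    if (identical(cycle$status, "cycle")) {
      regime <- "oscillatory"
    } else if (n_stable == 1) {
      st <- ss[ss$stability == "stable", ]
      vals <- c(st$OO, st$OP, st$PO, st$PP)
      if (max(vals) >= model$tot - 1e-3) {
        regime <- "absorbing"
        absorbing_species <- CONFORMATIONS[which.max(vals)]
      } else {
        regime <- "monostable"
      }
    } else {
      regime <- if (identical(cycle$status, "inconclusive")) {
        "inconclusive"
      } else {
        "monostable"
      }
    }
  }
  structure(
    list(
      regime = regime, n_stable = n_stable, n_states = nrow(ss),
      absorbing_species = absorbing_species, ss = ss, cycle = cycle,
      nt = nt, model = model$name
    ),
    class = "sw_regime_point"
  )
}

#' @export
print.sw_regime_point <- function(x, ...) {
  cat("<sw_regime_point> model ", x$model, ", nt = ", format(x$nt), ": ",
    x$regime, " (", x$n_stable, " stable / ", x$n_states, " steady states)\n",
    sep = ""
  )
  invisible(x)
}

# Classify every point of an nt grid, with forward and backward steady-state
# continuation (the previous grid point's roots seed the next Newton search)
# so both stable branches are tracked across a hysteresis window.
classify_grid <- function(model, grid, cycle_args = list()) {
  n <- length(grid)
  ss_list <- vector("list", n)
  prev <- NULL
  for (i in seq_len(n)) {
    ss_list[[i]] <- steady_states(model, nt = grid[i], seeds = prev)
    prev <- ss_seeds(ss_list[[i]])
  }
  nxt <- NULL
  for (i in rev(seq_len(n))) {
    if (!is.null(nxt)) {
      extra <- steady_states(model, nt = grid[i], seeds = nxt)
      ss_list[[i]] <- merge_steady_states(ss_list[[i]], extra)
    }
    nxt <- ss_seeds(ss_list[[i]])
  }
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- classify_regime(model, grid[i],
      cycle_args = cycle_args, ss = ss_list[[i]]
    )
  }
  out
}

# Continuation seeds: only isolated (non-marginal) roots are worth tracking
# across nt; marginal roots on an equilibrium continuum (CO/SO) would
# otherwise multiply into ever-growing seed sets.
ss_seeds <- function(ss, max_seeds = 12) {
  ss <- ss[ss$stability != "marginal", ]
  if (nrow(ss) == 0) {
    return(NULL)
  }
  if (nrow(ss) > max_seeds) ss <- ss[seq_len(max_seeds), ]
  cbind(OO = ss$OO, PP = ss$PP, PO = ss$PO)
}

merge_steady_states <- function(a, b, dedup_tol = 1e-6) {
  b <- b[b$stability != "marginal", ] # continuum roots never merge in
  if (nrow(b) == 0) {
    return(a)
  }
  keep <- rep(TRUE, nrow(b))
  for (j in seq_len(nrow(b))) {
    for (i in seq_len(nrow(a))) {
      if (max(abs(c(
        b$OO[j] - a$OO[i], b$PP[j] - a$PP[i],
        b$PO[j] - a$PO[i]
      ))) <= dedup_tol) {
        keep[j] <- FALSE
        break
      }
    }
  }
  out <- dplyr::bind_rows(tibble::as_tibble(a), tibble::as_tibble(b[keep, ]))
  out <- out[order(out$OO, out$PP, out$PO), ]
  structure(out,
    class = c("sw_steady_states", class(tibble::tibble())),
    model = attr(a, "model"), nt = attr(a, "nt"), tot = attr(a, "tot")
  )
}

#' Hysteresis-aware bifurcation sweep over the phosphate-donor level
#'
#' Sweeps `nt` over a grid, locating all steady states at every point (with
#' forward and backward branch continuation) and detecting limit cycles
#' wherever fewer than two stable states exist. The result is the machine
#' form of a bifurcation diagram: stable/unstable branches of `OO` and `PP`
#' against `nt`, plus the oscillation envelope and period where cycles exist.
#'
#' @param model An `sw_model`.
#' @param nt_range Length-2 range; defaults to the preset's standard range,
#'   else `c(0, 10)`.
#' @param step Grid step, default 0.05.
#' @param cycle_args Arguments forwarded to [detect_limit_cycle()].
#' @return An object of class `sw_bifurcation`: a list with `points` (one row
#'   per steady state per `nt`), `cycles` (one row per oscillatory `nt`),
#'   `regimes` (one row per `nt`) and metadata.
#' @examples
#' \donttest{
#' bd <- bifurcation_sweep(preset("AM"), step = 0.25)
#' autoplot(bd)
#' }
#' @export
bifurcation_sweep <- function(model, nt_range = NULL, step = 0.05,
                              cycle_args = list()) {
  stopifnot(inherits(model, "sw_model"), step > 0)
  nt_range <- nt_range %||%
    (if (model$name %in% names(PRESET_NT_RANGE)) {
      PRESET_NT_RANGE[[model$name]]
    } else {
      c(0, 10)
    })
  grid <- seq(nt_range[1], nt_range[2], by = step)
  cls <- classify_grid(model, grid, cycle_args = cycle_args)
  points <- purrr::map2_dfr(cls, grid, function(cl, nt) {
    if (nrow(cl$ss) == 0) {
      return(NULL)
    }
    dplyr::mutate(tibble::as_tibble(cl$ss), nt = nt, .before = 1)
  })
  cycles <- purrr::map_dfr(cls, function(cl) {
    if (is.null(cl$cycle) || cl$cycle$status != "cycle") {
      return(NULL)
    }
    env <- cl$cycle$envelope
    tibble::tibble(
      nt = cl$nt, period = cl$cycle$period,
      regularity = cl$cycle$regularity, asymmetry = cl$cycle$asymmetry,
      OO_min = env$min[env$species == "OO"],
      OO_max = env$max[env$species == "OO"],
      PP_min = env$min[env$species == "PP"],
      PP_max = env$max[env$species == "PP"]
    )
  })
  regimes <- purrr::map_dfr(cls, function(cl) {
    tibble::tibble(
      nt = cl$nt, regime = cl$regime, n_stable = cl$n_stable,
      n_states = cl$n_states, absorbing_species = cl$absorbing_species
    )
  })
  structure(
    list(
      points = points, cycles = cycles, regimes = regimes,
      model = model$name, nt_range = nt_range, step = step, tot = model$tot
    ),
    class = "sw_bifurcation"
  )
}

#' @export
print.sw_bifurcation <- function(x, ...) {
  cat("<sw_bifurcation> model ", x$model, ", nt in [",
    x$nt_range[1], ", ", x$nt_range[2], "] step ", x$step, "\n",
    sep = ""
  )
  print(table(x$regimes$regime))
  invisible(x)
}

#' @describeIn bifurcation_sweep Steady-state branches as a tibble.
#' @param x,object An `sw_bifurcation`.
#' @param ... Unused.
#' @export
tidy.sw_bifurcation <- function(x, ...) x$points

#' @describeIn bifurcation_sweep One row per `nt` with regime and cycle
#'   summary.
#' @export
glance.sw_bifurcation <- function(x, ...) {
  if (nrow(x$cycles) == 0) {
    return(x$regimes)
  }
  dplyr::left_join(x$regimes, x$cycles, by = "nt")
}

#' @describeIn bifurcation_sweep Plot `OO`/`PP` branches and the oscillation
#'   envelope against `nt`.
#' @export
autoplot.sw_bifurcation <- function(object, ...) {
  pts <- tidyr::pivot_longer(object$points,
    cols = c("OO", "PP"),
    names_to = "species", values_to = "concentration"
  )
  p <- ggplot2::ggplot(pts, ggplot2::aes(
    x = .data$nt, y = .data$concentration,
    colour = .data$species, linetype = .data$stability,
    group = interaction(.data$species, .data$stability)
  )) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::labs(
      x = "phosphate donor nt (AU)", y = "steady state (AU)",
      title = paste0(object$model, " bifurcation diagram")
    ) +
    ggplot2::theme_minimal()
  if (nrow(object$cycles) > 0) {
    env <- tidyr::pivot_longer(object$cycles,
      cols = c("OO_min", "OO_max", "PP_min", "PP_max"),
      names_to = c("species", "side"), names_sep = "_",
      values_to = "concentration"
    )
    p <- p + ggplot2::geom_point(
      data = env,
      ggplot2::aes(
        x = .data$nt, y = .data$concentration,
        colour = .data$species,
        group = interaction(.data$species, .data$side)
      ),
      inherit.aes = FALSE, size = 0.3, shape = 3
    )
  }
  p
}

#' Regime boundaries over a phosphate-donor range
#'
#' Classifies the regime on an `nt` grid (step 0.05 by default) and refines
#' every boundary between adjacent grid points of differing classification by
#' bisection to a bracket width of `refine` (0.01 by default, matching
#' two-decimal reporting). When sustained oscillation persists at the top of
#' the scan range, the range is extended by doubling (coarse step, then
#' bisection) until the oscillatory regime closes or `cap` is reached; an
#' interval still open at `cap` is reported with `osc_hi = NA` and
#' `osc_open = TRUE`.
#'
#' @param model An `sw_model`.
#' @param nt_range Length-2 scan range; defaults to the preset's standard
#'   range, else `c(0, 10)`.
#' @param step Grid step, default 0.05.
#' @param refine Bisection bracket width, default 0.01.
#' @param extend Extend the range when oscillation persists at the top,
#'   default TRUE.
#' @param cap Extension cap for `nt`, default 100.
#' @param extend_step Grid step used in the extension region, default 0.5.
#' @param cycle_args Arguments forwarded to [detect_limit_cycle()].
#' @return A one-row tibble of class `sw_regime_row`: `model`,
#'   `bistable_lo`, `bistable_hi`, `osc_lo`, `osc_hi`, `osc_open`,
#'   `overall`, `flagged`, `scan_max`. Boundaries are rounded to 2 decimals.
#' @examples
#' \donttest{
#' regime_boundaries(preset("AM")) # bistable on about [0.50, 8.55]
#' }
#' @export
regime_boundaries <- function(model, nt_range = NULL, step = 0.05,
                              refine = 0.01, extend = TRUE, cap = 100,
                              extend_step = 0.5, cycle_args = list()) {
  stopifnot(inherits(model, "sw_model"))
  nt_range <- nt_range %||%
    (if (model$name %in% names(PRESET_NT_RANGE)) {
      PRESET_NT_RANGE[[model$name]]
    } else {
      c(0, 10)
    })
  grid <- seq(nt_range[1], nt_range[2], by = step)
  cls <- classify_grid(model, grid, cycle_args = cycle_args)
  regime <- vapply(cls, function(cl) cl$regime, "")

  # extend while oscillation persists at the top of the scanned range
  if (extend && regime[length(regime)] == "oscillatory") {
    hi <- nt_range[2]
    while (regime[length(regime)] == "oscillatory" && hi < cap) {
      new_hi <- min(2 * hi, cap)
      ext <- seq(hi + extend_step, new_hi, by = extend_step)
      if (length(ext) == 0) break
      ext_cls <- classify_grid(model, ext, cycle_args = cycle_args)
      grid <- c(grid, ext)
      cls <- c(cls, ext_cls)
      regime <- c(regime, vapply(ext_cls, function(cl) cl$regime, ""))
      hi <- new_hi
    }
  }
  scan_max <- grid[length(grid)]

  classify_fn <- function(nt) {
    classify_regime(model, nt, cycle_args = cycle_args)$regime
  }
  bi <- regime_interval(grid, regime, "bistable", classify_fn, refine)
  osc <- regime_interval(grid, regime, "oscillatory", classify_fn, refine)
  osc_open <- !is.na(osc$lo) && osc$at_scan_max

  out <- tibble::tibble(
    model = model$name,
    bistable_lo = bi$lo, bistable_hi = bi$hi,
    osc_lo = osc$lo, osc_hi = if (osc_open) NA_real_ else osc$hi,
    osc_open = osc_open,
    overall = overall_class(regime, bi, osc),
    flagged = bi$flagged || osc$flagged,
    scan_max = scan_max
  )
  class(out) <- c("sw_regime_row", class(out))
  out
}

# Locate the longest run of `target` classifications on the grid and refine
# its edges by bisection. Returns lo/hi rounded to 2 decimals.
regime_interval <- function(grid, regime, target, classify_fn, refine) {
  none <- list(
    lo = NA_real_, hi = NA_real_, flagged = FALSE,
    at_scan_max = FALSE, n_runs = 0L
  )
  inside <- regime == target
  if (!any(inside)) {
    return(none)
  }
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  longest <- runs[which.max(r$lengths[runs])]
  i0 <- starts[longest]
  i1 <- ends[longest]
  flagged <- FALSE

  refine_edge <- function(out_nt, in_nt, out_class) {
    # bracket (outside, inside); bisect until width <= refine
    while (abs(in_nt - out_nt) > refine) {
      mid <- (out_nt + in_nt) / 2
      cl <- classify_fn(mid)
      if (cl == target) {
        in_nt <- mid
      } else {
        if (cl != out_class) flagged <<- TRUE # classification flip-flop
        out_nt <- mid
      }
    }
    (out_nt + in_nt) / 2
  }

  lo <- if (i0 == 1) {
    grid[1]
  } else {
    refine_edge(grid[i0 - 1], grid[i0], regime[i0 - 1])
  }
  at_scan_max <- i1 == length(grid)
  hi <- if (at_scan_max) {
    grid[i1]
  } else {
    refine_edge(grid[i1 + 1], grid[i1], regime[i1 + 1])
  }
  list(
    lo = round(lo, 2), hi = round(hi, 2), flagged = flagged,
    at_scan_max = at_scan_max, n_runs = length(runs)
  )
}

overall_class <- function(regime, bi, osc) {
  if (!is.na(bi$lo)) {
    return("bistable")
  }
  if (!is.na(osc$lo)) {
    return("oscillatory")
  }
  if (mean(regime == "absorbing") >= 0.5) {
    return("absorbing")
  }
  "monostable"
}

#' Regime table for a set of models
#'
#' Computes [regime_boundaries()] for each preset (or model) and binds the
#' rows: the machine form of a per-model table of bistable and oscillatory
#' phosphate-donor intervals.
#'
#' @param models Character vector of preset names, or a list of `sw_model`
#'   objects. Defaults to all presets.
#' @param ... Forwarded to [regime_boundaries()].
#' @return A tibble with one row per model.
#' @export
regime_table <- function(models = presets(), ...) {
  rows <- lapply(models, function(m) {
    if (is.character(m)) m <- preset(m)
    regime_boundaries(m, ...)
  })
  dplyr::bind_rows(rows)
}
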