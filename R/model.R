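DEFAULT_CATALYTIC <- 1.0
DEFAULT_SPONTANEOUS <- 0.05

# Named preset topologies: which of the 16 reactions are active. Rates follow
# the standard convention: every active catalytic reaction at 1 AU, every
# active spontaneous reaction at 0.05 AU; tot = 4, nd = 2.
PRESET_ACTIVE <- list(
  AM = c("p0", "p3", "d0", "d3", "bp0", "bp3", "bd0", "bd3"),
  TI = c(
    "p0", "p1", "p2", "p3", "d0", "d1", "d2", "d3",
    "bp0", "bp1", "bp2", "bp3", "bd0", "bd1", "bd2", "bd3"
  ),
  BP = c(
    "p0", "p1", "p3", "d1", "d2", "d3",
    "bp0", "bp1", "bp3", "bd1", "bd2", "bd3"
  ),
  BD1 = c(
    "p0", "p1", "p3", "d1", "d2", "d3",
    "bp0", "bp1", "bp3", "bd2", "bd3"
  ),
  CO = c("p0", "p3", "d1", "bd2"),
  SO = c("p0", "d1", "bp3", "bd2")
)

# nt scan range used for each preset's bifurcation analysis
PRESET_NT_RANGE <- list(
  AM = c(0, 10), TI = c(0, 10), BP = c(0, 10),
  BD1 = c(0, 15), CO = c(0, 15), SO = c(0, 15)
)

default_rates <- function(active) {
  rates <- stats::setNames(numeric(length(REACTION_IDS)), REACTION_IDS)
  catalytic <- REACTION_IDS[!startsWith(REACTION_IDS, "b")]
  rates[intersect(active, catalytic)] <- DEFAULT_CATALYTIC
  rates[setdiff(active, catalytic)] <- DEFAULT_SPONTANEOUS
  rates
}

#' Construct a reaction-network model
#'
#' A model is a topology (the subset of the 16 elementary reactions that are
#' active) together with rate constants, modifier levels and the conserved
#' total. An inactive reaction is identical to a reaction with rate zero.
#'
#' @param topology Character vector of active reaction ids, or a preset name
#'   (see [presets()]). Defaults to the full TI catalog.
#' @param rates Optional named numeric vector overriding individual rate
#'   constants (1 AU for active catalytic, 0.05 AU for active spontaneous by
#'   default). Ids not in `topology` must not be given non-zero rates.
#' @param tot Conserved total concentration (AU), default 4.
#' @param nd Phosphate-acceptor level (AU), default 2; multiplies every
#'   dephosphorylation rate.
#' @param nt Phosphate-donor level (AU), default 2; multiplies every
#'   phosphorylation rate. This is the bifurcation parameter and is usually
#'   overridden per analysis.
#' @param name Optional model label used in outputs.
#' @return An object of class `sw_model`.
#' @examples
#' m <- sw_model("TI", nt = 4)
#' m
#' @export
sw_model <- function(topology = "TI", rates = NULL, tot = 4, nd = 2, nt = 2,
                     name = NULL) {
  if (length(topology) == 1 && topology %in% names(PRESET_ACTIVE)) {
    if (is.null(name)) name <- topology
    topology <- PRESET_ACTIVE[[topology]]
  }
  unknown <- setdiff(topology, REACTION_IDS)
  if (length(unknown) > 0) {
    stop("Unknown reaction id(s): ", paste(unknown, collapse = ", "),
      ". Valid ids: ", paste(REACTION_IDS, collapse = ", "),
      call. = FALSE
    )
  }
  topology <- REACTION_IDS[REACTION_IDS %in% topology]
  r <- default_rates(topology)
  if (!is.null(rates)) {
    bad <- setdiff(names(rates), REACTION_IDS)
    if (length(bad) > 0) {
      stop("Unknown rate name(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    off <- setdiff(names(rates)[rates != 0], topology)
    if (length(off) > 0) {
      stop("Non-zero rate for inactive reaction(s): ",
        paste(off, collapse = ", "),
        call. = FALSE
      )
    }
    r[names(rates)] <- rates
  }
  if (any(r < 0)) stop("Rate constants must be non-negative.", call. = FALSE)
  if (!is.numeric(tot) || tot <= 0) stop("`tot` must be > 0.", call. = FALSE)
  if (nd < 0 || nt < 0) stop("`nt` and `nd` must be >= 0.", call. = FALSE)
  structure(
    list(
      active = topology, rates = r,
      tot = as.numeric(tot), nd = as.numeric(nd), nt = as.numeric(nt),
      name = name %||% "custom"
    ),
    class = "sw_model"
  )
}

#' @export
print.sw_model <- function(x, ...) {
  cat("<sw_model> ", x$name, "\n", sep = "")
  cat("  active reactions (", length(x$active), "/16): ",
    paste(x$active, collapse = " "), "\n",
    sep = ""
  )
  cat("  tot = ", x$tot, ", nd = ", x$nd, ", nt = ", x$nt, "\n", sep = "")
  invisible(x)
}

#' Named model presets
#'
#' `presets()` lists the available named topologies; `preset(name)` builds the
#' corresponding model with its standard rates (catalytic 1 AU, spontaneous
#' 0.05 AU, `tot = 4`, `nd = 2`):
#'
#' * `AM` — approximate-majority switch: one phosphorylation and one
#'   dephosphorylation path, `PO` unreachable (effectively three states);
#' * `TI` — two-intermediate network, all 16 reactions active;
#' * `BP` — broken-paths network, TI minus the `PO -> PP` and `OP -> OO` paths;
#' * `BD1` — BP minus the spontaneous `PO -> OO` reaction (`bd1`), a robust
#'   relaxation oscillator;
#' * `CO` — catalytic oscillator, `{p0, p3, d1, bd2}`;
#' * `SO` — spontaneous oscillator, `{p0, d1, bp3, bd2}`.
#'
#' @param name Preset name.
#' @param nt Phosphate-donor level, default 2.
#' @return `preset()` returns an `sw_model`; `presets()` a character vector.
#' @examples
#' preset("CO", nt = 4)
#' @export
preset <- function(name, nt = 2) {
  if (!is.character(name) || length(name) != 1 ||
    !(name %in% names(PRESET_ACTIVE))) {
    stop("Unknown preset. Available presets: ",
      paste(names(PRESET_ACTIVE), collapse = ", "),
      call. = FALSE
    )
  }
  sw_model(name, nt = nt)
}

#' @rdname preset
#' @export
presets <- function() names(PRESET_ACTIVE)

#' Standard nt scan range of a preset
#'
#' @param name Preset name.
#' @return Numeric length-2 vector `c(lo, hi)`.
#' @export
preset_nt_range <- function(name) {
  if (!name %in% names(PRESET_NT_RANGE)) {
    stop("Unknown preset. Available presets: ",
      paste(names(PRESET_NT_RANGE), collapse = ", "),
      call. = FALSE
    )
  }
  PRESET_NT_RANGE[[name]]
}

#' Remove reactions or paths from a model
#'
#' `drop_reactions()` deactivates individual reactions; `drop_paths()`
#' deactivates whole paths (each catalytic reaction together with its
#' spontaneous sibling).
#'
#' @param model An `sw_model`.
#' @param ids Reaction ids (for `drop_reactions`) or path ids `p0..p3`,
#'   `d0..d3` (for `drop_paths`).
#' @return A new `sw_model` with the reactions removed and its rates zeroed.
#' @examples
#' drop_paths(sw_model("TI"), c("p2", "d0")) # the BP topology
#' @export
drop_reactions <- function(model, ids) {
  stopifnot(inherits(model, "sw_model"))
  unknown <- setdiff(ids, REACTION_IDS)
  if (length(unknown) > 0) {
    stop("Unknown reaction id(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  active <- setdiff(model$active, ids)
  rates <- model$rates
  rates[ids] <- 0
  out <- model
  out$active <- active
  out$rates <- rates
  out$name <- paste0(model$name, "-", paste(ids, collapse = "-"))
  out
}

#' @rdname drop_reactions
#' @export
drop_paths <- function(model, ids) {
  path_ids <- reaction_paths()$path
  unknown <- setdiff(ids, path_ids)
  if (length(unknown) > 0) {
    stop("Unknown path id(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  drop_reactions(model, c(ids, paste0("b", ids)))
}

#' Mass-action derivative function of the reduced system
#'
#' The four-species system conserves `OO + OP + PO + PP = tot`, so the `OP`
#' equation is eliminated and the dynamics integrated in the reduced state
#' `(OO, PP, PO)` with `OP = tot - OO - PP - PO` reconstructed algebraically.
#' For the AM topology (all `PO`-path rates zero and `PO(0) = 0`) the reduced
#' system is effectively two-dimensional.
#'
#' `build_rhs()` returns `function(state)` evaluating the time derivative of
#' the reduced state; `build_jacobian()` returns `function(state)` evaluating
#' its exact 3x3 Jacobian (the system is polynomial, so the derivatives are
#' closed-form).
#'
#' @param model An `sw_model`.
#' @param nt Optional phosphate-donor level overriding `model$nt`.
#' @return A function of a numeric length-3 state vector `c(OO, PP, PO)`.
#' @examples
#' rhs <- build_rhs(sw_model("TI", nt = 2))
#' rhs(c(OO = 4, PP = 0, PO = 0))
#' @export
build_rhs <- function(model, nt = NULL) {
  stopifnot(inherits(model, "sw_model"))
  if (any(model$rates < 0)) stop("Rate constants must be non-negative.", call. = FALSE)
  p <- as.list(model$rates)
  nt <- nt %||% model$nt
  nd <- model$nd
  tot <- model$tot
  force(nt)
  function(state) {
    OO <- state[[1]]
    PP <- state[[2]]
    PO <- state[[3]]
    OP <- tot - OO - PP - PO
    dOO <- -(p$p0 + p$p1) * nt * PP * OO +
      p$d0 * nd * OO * OP + p$d1 * nd * OO * PO -
      (p$bp0 + p$bp1) * nt * OO +
      p$bd0 * nd * OP + p$bd1 * nd * PO
    dPP <- p$p3 * nt * PP * OP + p$p2 * nt * PP * PO -
      (p$d2 + p$d3) * nd * OO * PP +
      p$bp3 * nt * OP + p$bp2 * nt * PO -
      (p$bd2 + p$bd3) * nd * PP
    dPO <- p$p1 * nt * PP * OO - p$p2 * nt * PP * PO +
      p$d2 * nd * OO * PP - p$d1 * nd * OO * PO +
      p$bp1 * nt * OO - p$bp2 * nt * PO +
      p$bd2 * nd * PP - p$bd1 * nd * PO
    c(OO = dOO, PP = dPP, PO = dPO)
  }
}

#' @rdname build_rhs
#' @export
build_jacobian <- function(model, nt = NULL) {
  stopifnot(inherits(model, "sw_model"))
  p <- as.list(model$rates)
  nt <- nt %||% model$nt
  nd <- model$nd
  tot <- model$tot
  force(nt)
  function(state) {
    OO <- state[[1]]
    PP <- state[[2]]
    PO <- state[[3]]
    OP <- tot - OO - PP - PO
    # d OP / d (OO, PP, PO) = -1 enters via the chain rule
    matrix(
      c(
        -(p$p0 + p$p1) * nt * PP + p$d0 * nd * (OP - OO) + p$d1 * nd * PO -
          (p$bp0 + p$bp1) * nt - p$bd0 * nd,
        -(p$p0 + p$p1) * nt * OO - p$d0 * nd * OO - p$bd0 * nd,
        (p$d1 - p$d0) * nd * OO + (p$bd1 - p$bd0) * nd,
        -p$p3 * nt * PP - (p$d2 + p$d3) * nd * PP - p$bp3 * nt,
        p$p3 * nt * (OP - PP) + p$p2 * nt * PO - (p$d2 + p$d3) * nd * OO -
          p$bp3 * nt - (p$bd2 + p$bd3) * nd,
        (p$p2 - p$p3) * nt * PP + (p$bp2 - p$bp3) * nt,
        p$p1 * nt * PP + p$d2 * nd * PP - p$d1 * nd * PO + p$bp1 * nt,
        p$p1 * nt * OO - p$p2 * nt * PO + p$d2 * nd * OO + p$bd2 * nd,
        -p$p2 * nt * PP - p$d1 * nd * OO - p$bp2 * nt - p$bd1 * nd
      ),
      nrow = 3, byrow = TRUE,
      dimnames = list(c("OO", "PP", "PO"), c("OO", "PP", "PO"))
    )
  }
}

# Parameter vector layout expected by the compiled derivative routine:
# 16 rates in REACTION_IDS order, then nt, nd, tot, and the coordinate modes
# for OO and PP (0 linear, 1 log, 2 frozen at zero).
model_parms <- function(model, nt = NULL, modes = c(0, 0)) {
  c(model$rates,
    nt = nt %||% model$nt, nd = model$nd, tot = model$tot,
    mode_OO = modes[1], mode_PP = modes[2]
  )
}

# A species is "multiplicative" when its every inflow is proportional to
# itself, so that exact dynamics can drive it through concentrations far
# below any absolute tolerance (and keeps it at zero if started there).
# Such species are integrated in log coordinates, or pinned at zero. The
# test uses the effective inflow coefficients (rate times modifier level):
# e.g. at nt = 0 every spontaneous phosphorylation inflow vanishes.
multiplicative_species <- function(model, nt = NULL) {
  nt <- nt %||% model$nt
  nd <- model$nd
  c(
    OO = all(model$rates[c("bd0", "bd1")] * nd == 0),
    PP = all(model$rates[c("bp2", "bp3")] * nt == 0)
  )
}

# Full reduced state from named components; checks conservation feasibility.
reduced_state <- function(OO = 0, PP = 0, PO = 0, OP = NULL, tot = 4) {
  if (!is.null(OP)) {
    s <- OO + PP + PO + OP
    if (abs(s - tot) > 1e-9 * max(1, tot)) {
      stop("Initial condition violates conservation: OO+OP+PO+PP = ", s,
        " but tot = ", tot,
        call. = FALSE
      )
    }
  } else {
    OP <- tot - OO - PP - PO
    if (OP < -1e-9 * max(1, tot)) {
      stop("Initial condition leaves OP = ", OP, " < 0.", call. = FALSE)
    }
  }
  c(OO = OO, PP = PP, PO = PO)
}
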