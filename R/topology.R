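# Site-swap automorphism on reaction ids: exchanging the two phosphosites
# maps OP<->PO, hence p0<->p1, p2<->p3, d0<->d1, d2<->d3 and likewise for
# the spontaneous siblings. nt and nd are untouched.
SITE_SWAP_MAP <- local({
  swap_idx <- c("0" = "1", "1" = "0", "2" = "3", "3" = "2")
  ids <- REACTION_IDS
  stem <- sub("[0-9]$", "", ids)
  idx <- sub("^[a-z]+", "", ids)
  stats::setNames(paste0(stem, swap_idx[idx]), ids)
})

# Full phospho-swap (O<->P on both sites): OO<->PP, OP<->PO, and each
# phosphorylation maps to the mirror dephosphorylation; nt and nd exchange
# roles.
PHOSPHO_SWAP_MAP <- c(
  p0 = "d2", p1 = "d3", p2 = "d0", p3 = "d1",
  d0 = "p2", d1 = "p3", d2 = "p0", d3 = "p1",
  bp0 = "bd2", bp1 = "bd3", bp2 = "bd0", bp3 = "bd1",
  bd0 = "bp2", bd1 = "bp3", bd2 = "bp0", bd3 = "bp1"
)

#' Symmetry automorphisms of the reaction network
#'
#' `site_swap()` relabels the two phosphosites: conformations `OP` and `PO`
#' exchange, and reaction indices swap 0<->1 and 2<->3 within each family
#' (`p`, `d`, `bp`, `bd`). It is an involution, leaves `nt`/`nd` untouched,
#' and maps trajectories of a model onto trajectories of the swapped model
#' with the swapped initial condition. `phospho_swap()` additionally
#' exchanges `O` and `P` on both sites: `OO <-> PP`, each phosphorylation
#' becomes the mirror dephosphorylation, and the `nt` and `nd` levels swap
#' roles.
#'
#' @param model An `sw_model`.
#' @return The transformed `sw_model`.
#' @examples
#' identical(site_swap(site_swap(preset("BP")))$active, preset("BP")$active)
#' @export
site_swap <- function(model) {
  stopifnot(inherits(model, "sw_model"))
  out <- model
  out$active <- REACTION_IDS[REACTION_IDS %in% unname(SITE_SWAP_MAP[model$active])]
  rates <- model$rates
  names(rates) <- unname(SITE_SWAP_MAP[names(rates)])
  out$rates <- rates[REACTION_IDS]
  out$name <- paste0(model$name, "-siteswap")
  out
}

#' @rdname site_swap
#' @export
phospho_swap <- function(model) {
  stopifnot(inherits(model, "sw_model"))
  out <- model
  out$active <- REACTION_IDS[REACTION_IDS %in% unname(PHOSPHO_SWAP_MAP[model$active])]
  rates <- model$rates
  names(rates) <- unname(PHOSPHO_SWAP_MAP[names(rates)])
  out$rates <- rates[REACTION_IDS]
  out$nt <- model$nd
  out$nd <- model$nt
  out$name <- paste0(model$name, "-phosphoswap")
  out
}

#' Apply the site-swap relabelling to a state or trajectory
#'
#' @param x A named state vector containing `OP`/`PO` entries, or an
#'   `sw_trajectory`.
#' @return The relabelled object (`OP` and `PO` exchanged).
#' @export
site_swap_state <- function(x) {
  if (inherits(x, "sw_trajectory") || is.data.frame(x)) {
    out <- x
    op <- out$OP
    out$OP <- out$PO
    out$PO <- op
    return(out)
  }
  nm <- names(x)
  nm[nm == "OP"] <- ".tmp"
  nm[nm == "PO"] <- "OP"
  nm[nm == ".tmp"] <- "PO"
  names(x) <- nm
  x
}

# Canonical representative of a topology's site-swap orbit: the
# lexicographically smallest sorted active-id set.
canonical_active <- function(active) {
  a <- sort(active)
  b <- sort(unname(SITE_SWAP_MAP[active]))
  key_a <- paste(a, collapse = ",")
  key_b <- paste(b, collapse = ",")
  if (key_a <= key_b) a else b
}

#' Single-path removals from the TI network
#'
#' Removes each of the 8 reaction paths (a catalytic reaction together with
#' its spontaneous sibling) from the full TI network and classifies the
#' resulting topology by a regime-boundary scan over `nt` in `[0, 10]`. All
#' 8 of these reductions preserve the toggle switch.
#'
#' @param step Grid step for the scan, default 0.05.
#' @param nt_range Scan range, default `c(0, 10)`.
#' @param ... Forwarded to [regime_boundaries()].
#' @return A tibble with one row per removal: `removed_path`, `n_active`,
#'   and the [regime_boundaries()] columns.
#' @export
single_path_removals <- function(step = 0.05, nt_range = c(0, 10), ...) {
  paths <- reaction_paths()$path
  rows <- lapply(paths, function(pth) {
    m <- drop_paths(sw_model("TI"), pth)
    rb <- regime_boundaries(m, nt_range = nt_range, step = step, ...)
    dplyr::mutate(rb,
      removed_path = pth, n_active = length(m$active),
      .before = 1
    )
  })
  dplyr::bind_rows(rows)
}

#' Pairwise path removals from the TI network, reduced by symmetry
#'
#' Removes one phosphorylation path and one dephosphorylation path from TI
#' (4 x 4 = 16 combinations), groups the 16 topologies into 8 orbits of size
#' 2 under the site-swap automorphism, classifies one representative per
#' orbit, and copies the classification to the partner (orbit members have
#' exactly identical dynamics up to relabelling). Six of the eight orbits
#' keep the bistable toggle switch; the remaining two are the BP topology
#' (oscillatory) and the AI topology (absorbing: `PO` becomes a sink).
#'
#' @inheritParams single_path_removals
#' @return A tibble with 16 rows: `p_path`, `d_path`, `orbit`,
#'   `representative` and the classification columns.
#' @export
pairwise_path_removals <- function(step = 0.05, nt_range = c(0, 10), ...) {
  pairs <- tidyr::expand_grid(
    p_path = paste0("p", 0:3),
    d_path = paste0("d", 0:3)
  )
  pairs$active_key <- purrr::map2_chr(
    pairs$p_path, pairs$d_path,
    function(p, d) {
      m <- drop_paths(sw_model("TI"), c(p, d))
      paste(canonical_active(m$active), collapse = ",")
    }
  )
  pairs$orbit <- match(pairs$active_key, unique(pairs$active_key))
  pairs <- pairs |>
    dplyr::group_by(.data$orbit) |>
    dplyr::mutate(representative = dplyr::row_number() == 1) |>
    dplyr::ungroup()

  reps <- dplyr::filter(pairs, .data$representative)
  rb <- purrr::map2_dfr(reps$p_path, reps$d_path, function(p, d) {
    m <- drop_paths(sw_model("TI"), c(p, d))
    regime_boundaries(m, nt_range = nt_range, step = step, ...)
  })
  rb$orbit <- reps$orbit
  out <- dplyr::left_join(
    dplyr::select(pairs, -"active_key"),
    dplyr::select(rb, -"model"),
    by = "orbit"
  )
  dplyr::mutate(out, label = paste(
    .data$p_path, .data$d_path,
    paste0("b", .data$p_path), paste0("b", .data$d_path)
  ), .after = "d_path")
}

#' Single-reaction removals from the BD1 oscillator
#'
#' Removes each individual reaction (catalytic or spontaneous separately)
#' from the BD1 network's active set and classifies the result over `nt` in
#' `[0, 15]`. Removing `d1` (catalytic `PO -> OO`) or `p0` (catalytic
#' `OO -> OP`) cuts the only remaining route between the catalytic forms and
#' abolishes oscillation; removing `bd2` (spontaneous `PP -> PO`) leaves
#' only a tiny oscillatory window before the system settles into a
#' `PP`-dominated equilibrium.
#'
#' @param step Grid step, default 0.05.
#' @param nt_range Scan range, default `c(0, 15)`.
#' @param ... Forwarded to [regime_boundaries()]; range extension is off by
#'   default so classifications refer to the standard `[0, 15]` window.
#' @return A tibble with one row per removed reaction.
#' @export
bd1_reaction_removals <- function(step = 0.05, nt_range = c(0, 15), ...) {
  base <- sw_model("BD1")
  rows <- lapply(base$active, function(id) {
    m <- drop_reactions(base, id)
    rb <- regime_boundaries(m,
      nt_range = nt_range, step = step,
      extend = FALSE, ...
    )
    dplyr::mutate(rb, removed = id, .before = 1)
  })
  dplyr::bind_rows(rows)
}
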