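#' The four conformations of the two-site molecule
#'
#' A single molecule carries two phosphosites; each is either unmodified (`O`)
#' or phosphorylated (`P`), giving four conformations `OO`, `OP`, `PO`, `PP`.
#' `OO` and `PP` are the two catalytically active forms: `PP` drives
#' phosphorylation of the other forms (kinase-like), `OO` drives
#' dephosphorylation (phosphatase-like).
#'
#' @format A character vector of length 4.
#' @export
CONFORMATIONS <- c("OO", "OP", "PO", "PP")

# Reaction ids in canonical order; this order also fixes the parameter layout
# passed to the compiled derivative routine.
REACTION_IDS <- c(
  "p0", "p1", "p2", "p3",
  "d0", "d1", "d2", "d3",
  "bp0", "bp1", "bp2", "bp3",
  "bd0", "bd1", "bd2", "bd3"
)

#' The 16-reaction catalog of the two-intermediate network
#'
#' Eight directed conversions connect the four conformations (each changes
#' exactly one phosphosite), and each conversion exists in a catalytic and a
#' spontaneous variant, giving 16 elementary mass-action reactions:
#'
#' * `p0..p3` — catalytic phosphorylations, catalysed by `PP`, scaled by the
#'   phosphate-donor level `nt`;
#' * `d0..d3` — catalytic dephosphorylations, catalysed by `OO`, scaled by the
#'   phosphate-acceptor level `nd`;
#' * `bp0..bp3` / `bd0..bd3` — the corresponding spontaneous
#'   (uncatalysed) reactions, scaled by `nt` / `nd` respectively.
#'
#' The rate of a catalytic reaction is `k * modifier * [catalyst] * [substrate]`
#' and of a spontaneous one `k * modifier * [substrate]`.
#'
#' @return A tibble with one row per reaction and columns `id`, `substrate`,
#'   `product`, `catalyst` (`NA` for spontaneous reactions), `modifier`
#'   (`"nt"` or `"nd"`) and `mechanism` (`"catalytic"` or `"spontaneous"`).
#' @examples
#' reaction_catalog()
#' @export
reaction_catalog <- function() {
  conv <- tibble::tribble(
    ~index, ~phos_sub, ~phos_prod,
    0L, "OO", "OP",
    1L, "OO", "PO",
    2L, "PO", "PP",
    3L, "OP", "PP"
  )
  phos <- dplyr::bind_rows(
    dplyr::mutate(conv,
      id = paste0("p", .data$index), substrate = .data$phos_sub,
      product = .data$phos_prod, catalyst = "PP",
      modifier = "nt", mechanism = "catalytic"
    ),
    dplyr::mutate(conv,
      id = paste0("bp", .data$index), substrate = .data$phos_sub,
      product = .data$phos_prod, catalyst = NA_character_,
      modifier = "nt", mechanism = "spontaneous"
    )
  )
  # dephosphorylations reverse the conversions, catalysed by OO
  dephos <- dplyr::bind_rows(
    dplyr::mutate(conv,
      id = paste0("d", .data$index), substrate = .data$phos_prod,
      product = .data$phos_sub, catalyst = "OO",
      modifier = "nd", mechanism = "catalytic"
    ),
    dplyr::mutate(conv,
      id = paste0("bd", .data$index), substrate = .data$phos_prod,
      product = .data$phos_sub, catalyst = NA_character_,
      modifier = "nd", mechanism = "spontaneous"
    )
  )
  out <- dplyr::bind_rows(phos, dephos)
  out <- dplyr::select(out, "id", "substrate", "product", "catalyst",
                       "modifier", "mechanism")
  out[match(REACTION_IDS, out$id), ]
}

#' The eight reaction paths
#'
#' A *path* is a directed conversion counted together with both of its
#' mechanisms: the catalytic reaction plus its associated spontaneous sibling
#' (`p2` with `bp2`, `d0` with `bd0`, ...). Knockout analyses remove whole
#' paths.
#'
#' @return A tibble with columns `path` (`p0..p3`, `d0..d3`), `catalytic`,
#'   `spontaneous`, `substrate`, `product`.
#' @export
reaction_paths <- function() {
  cat <- reaction_catalog()
  cat |>
    dplyr::filter(.data$mechanism == "catalytic") |>
    dplyr::transmute(
      path = .data$id,
      catalytic = .data$id,
      spontaneous = paste0("b", .data$id),
      substrate = .data$substrate,
      product = .data$product
    )
}

#' Export the reaction catalog as TSV
#'
#' @param path File to write.
#' @return `path`, invisibly.
#' @export
write_catalog_tsv <- function(path) {
  utils::write.table(reaction_catalog(), path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, na = "-"
  )
  invisible(path)
}
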