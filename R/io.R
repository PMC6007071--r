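#' Read a model configuration file
#'
#' Accepts YAML or JSON (by extension) with keys `topology` (preset name or
#' list of active reaction ids), `rates` (map id -> value), `tot`, `nd`,
#' `nt`, `name`. Unknown keys are rejected.
#'
#' @param path Config file path.
#' @return An `sw_model`.
#' @export
read_model_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("Config must be .yaml/.yml or .json, got: ", path, call. = FALSE)
  )
  allowed <- c("topology", "rates", "tot", "nd", "nt", "name")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0) {
    stop("Unknown config key(s): ", paste(unknown, collapse = ", "),
      ". Allowed: ", paste(allowed, collapse = ", "),
      call. = FALSE
    )
  }
  sw_model(
    topology = unlist(cfg$topology) %||% "TI",
    rates = if (!is.null(cfg$rates)) unlist(cfg$rates) else NULL,
    tot = cfg$tot %||% 4, nd = cfg$nd %||% 2, nt = cfg$nt %||% 2,
    name = cfg$name
  )
}

fmt <- function(x) formatC(x, digits = 6, format = "g")

write_tsv_with_header <- function(df, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in meta) writeLines(paste0("# ", m), con)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], fmt)
  utils::write.table(df, con,
    sep = "\t", quote = FALSE, row.names = FALSE,
    na = "NA"
  )
  invisible(path)
}

#' Write a trajectory as TSV
#'
#' Columns `time`, `OO`, `OP`, `PO`, `PP`; metadata in `#` comment lines.
#' Negative undershoots above `-1e-9` (integrator noise) are clamped to 0 in
#' the written output only.
#'
#' @param traj An `sw_trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(traj, path) {
  df <- tibble::as_tibble(traj)
  for (s in CONFORMATIONS) {
    v <- df[[s]]
    df[[s]] <- ifelse(v < 0 & v > -1e-9, 0, v)
  }
  write_tsv_with_header(df, path, meta = c(
    paste0("model: ", attr(traj, "model")),
    paste0("nt: ", attr(traj, "nt")),
    paste0("tot: ", attr(traj, "tot")),
    paste0("rtol: ", attr(traj, "rtol"), " atol: ", attr(traj, "atol"))
  ))
}

#' Write a bifurcation diagram as TSV
#'
#' Steady-state branches (`nt`, `OO`, `OP`, `PO`, `PP`, leading eigenvalue
#' real part, stability) joined with the oscillation envelope and period
#' where present.
#'
#' @param bif An `sw_bifurcation`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bifurcation_tsv <- function(bif, path) {
  pts <- bif$points
  if (nrow(bif$cycles) > 0) {
    pts <- dplyr::left_join(pts, bif$cycles, by = "nt")
  }
  write_tsv_with_header(pts, path, meta = c(
    paste0("model: ", bif$model),
    paste0(
      "nt_range: [", bif$nt_range[1], ", ", bif$nt_range[2],
      "] step ", bif$step
    )
  ))
}

#' Write a regime table as TSV
#'
#' One row per model with bistable and oscillatory intervals (2 decimals) and
#' open-end flags.
#'
#' @param tbl Output of [regime_table()] / [regime_boundaries()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_regime_tsv <- function(tbl, path) {
  df <- tibble::as_tibble(tbl)
  for (col in c("bistable_lo", "bistable_hi", "osc_lo", "osc_hi")) {
    if (col %in% names(df)) df[[col]] <- sprintf("%.2f", df[[col]])
  }
  write_tsv_with_header(df, path)
}
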