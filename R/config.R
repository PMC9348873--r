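#' Read and validate a run configuration
#'
#' Configurations are YAML with four blocks: `model` (name, parameter grids
#' given as `{name, min, max, n_points, spacing}` -- `n_points` rather than
#' `n`, which YAML 1.1 would resolve to a boolean --,
#' contrast, optional structure-factor and smearing corrections), `data`
#' (path, std-fallback flag, optional q-cut range), `solver`
#' ([solver_options()] fields) and `output` (directory). Unknown keys anywhere
#' are rejected before any computation.
#'
#' @param path YAML file path.
#' @return A validated list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

config_schema <- list(
  model = c("name", "grids", "contrast", "structure", "smearing",
            "background"),
  data = c("path", "format", "std_fallback", "q_min", "q_max"),
  solver = c("max_iter", "gtol", "xtol", "ftol_abs", "monitor_every",
             "reduce_tol", "reduce", "polish", "lambda0", "chunk_budget",
             "seed", "verbose"),
  output = c("dir", "formats")
)

validate_config <- function(cfg) {
  if (!is.list(cfg)) stop("config error: top level must be a mapping")
  unknown <- setdiff(names(cfg), names(config_schema))
  if (length(unknown)) {
    stop("config error: unknown top-level key(s): ",
         paste(unknown, collapse = ", "))
  }
  for (blk in names(config_schema)) {
    if (is.null(cfg[[blk]])) next
    bad <- setdiff(names(cfg[[blk]]), config_schema[[blk]])
    if (length(bad)) {
      stop("config error: unknown key(s) in '", blk, "': ",
           paste(bad, collapse = ", "))
    }
  }
  if (is.null(cfg$model$name)) stop("config error: model.name is required")
  if (!cfg$model$name %in% c("sphere", "cylinder")) {
    stop("config error: unsupported model '", cfg$model$name, "'")
  }
  for (g in cfg$model$grids) {
    need <- c("name", "min", "max", "n_points")
    if (!all(need %in% names(g))) {
      stop("config error: each grid needs keys ", paste(need, collapse = ", "))
    }
  }
  structure(cfg, class = "run_config")
}

# Build the grids and Green tensor a config describes, on the data's q grid.
config_green <- function(cfg, q) {
  grids <- lapply(cfg$model$grids, function(g) {
    param_grid_spec(g$name, g$min, g$max, g$n_points, g$spacing %||% "linear",
                    positive = !g$name %in% c("theta", "phi"))
  })
  names(grids) <- vapply(grids, function(g) g$name, character(1))
  contrast <- cfg$model$contrast %||% 1
  G <- if (cfg$model$name == "sphere") {
    sphere_form_green(q, grids[["radius"]], contrast = contrast)
  } else {
    cylinder_form_green_2d(q$axes[[1]], q$axes[[2]], grids[["length"]],
                           grids[["radius"]], grids[["theta"]],
                           grids[["phi"]], contrast = contrast)
  }
  if (!is.null(cfg$model$structure) && is.null(cfg$model$structure$free)) {
    S <- hard_sphere_structure(q, cfg$model$structure$r_eff,
                               cfg$model$structure$V_f)
    G <- apply_structure(G, S)
  }
  if (!is.null(cfg$model$smearing)) {
    W <- smearing_matrix(q, dq = cfg$model$smearing$dq,
                         dq_fraction = cfg$model$smearing$dq_fraction %||% 0.5)
    G <- apply_smearing(G, W)
  }
  G
}

config_solver_options <- function(cfg) {
  so <- cfg$solver %||% list()
  do.call(solver_options, so)
}
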