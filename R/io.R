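#' Read a 1D intensity curve from columnar text
#'
#' Accepts whitespace- or comma-delimited columns `q, I[, sigma][, dq]`, `#`
#' comments and an optional (non-numeric) header line. A missing sigma column
#' triggers the documented `std := mean` fallback with a warning; an optional
#' q-range cut drops points outside `q_range` (e.g. to remove a noisy high-q
#' end).
#'
#' @param path File path.
#' @param q_range Optional `c(min, max)` kept range (inclusive).
#' @param std_fallback Permit the sigma fallback when only two columns exist.
#' @return An [intensity_data()].
#' @export
read_intensity_1d <- function(path, q_range = NULL, std_fallback = TRUE) {
  lines <- readLines(path)
  raw <- sub("#.*$", "", lines)
  keep <- which(trimws(raw) != "")
  if (!length(keep)) stop("parse error: no data rows in ", path)
  toks <- lapply(raw[keep], function(x) {
    strsplit(trimws(x), "[,[:space:]]+")[[1]]
  })
  # optional single header line of non-numeric tokens
  first_numeric <- suppressWarnings(!anyNA(as.numeric(toks[[1]])))
  if (!first_numeric) {
    toks <- toks[-1]
    keep <- keep[-1]
    if (!length(toks)) stop("parse error: header only in ", path)
  }
  ncols <- length(toks[[1]])
  if (!ncols %in% 2:4) {
    stop("parse error at line ", keep[1], ": expected 2-4 columns, got ", ncols)
  }
  for (i in seq_along(toks)) {
    if (length(toks[[i]]) != ncols) {
      stop("parse error at line ", keep[i], ": ragged row (",
           length(toks[[i]]), " fields, expected ", ncols, ")")
    }
  }
  m <- suppressWarnings(
    matrix(as.numeric(unlist(toks)), ncol = ncols, byrow = TRUE))
  bad <- which(apply(m, 1L, anyNA))
  if (length(bad)) stop("parse error at line ", keep[bad[1]],
                        ": non-numeric field")
  if (any(diff(m[, 1]) <= 0)) {
    stop("parse error: q column must be strictly increasing")
  }
  if (!is.null(q_range)) {
    sel <- m[, 1] >= q_range[1] & m[, 1] <= q_range[2]
    if (!any(sel)) stop("q-range cut removed all points")
    m <- m[sel, , drop = FALSE]
  }
  std <- if (ncols >= 3) m[, 3] else NULL
  if (is.null(std)) {
    if (!std_fallback) stop("data error: no sigma column and fallback disabled")
    warning("no sigma column in ", basename(path),
            "; using the mean intensity as its standard deviation")
  } else if (any(std < 0)) {
    stop("parse error: negative sigma at line ",
         keep[which(std < 0)[1]])
  }
  intensity_data(q_grid(q = m[, 1]), m[, 2], std = std,
                 dq = if (ncols >= 4) m[, 4] else NULL,
                 std_fallback = is.null(std))
}

#' Read 2D intensity data from long-format text
#'
#' Expects columns `qx, qy, mean[, std]` (whitespace- or comma-delimited, `#`
#' comments, optional header), one row per pixel, forming a complete
#' rectilinear grid in any row order.
#'
#' @param path File path.
#' @param std_fallback Permit the sigma fallback.
#' @return An [intensity_data()] with M = 2.
#' @export
read_intensity_2d <- function(path, std_fallback = TRUE) {
  df <- utils::read.table(path, header = is_header_line(path),
                          comment.char = "#")
  if (!ncol(df) %in% 3:4) {
    stop("parse error: expected columns qx, qy, mean[, std]")
  }
  qx <- sort(unique(df[[1]]))
  qy <- sort(unique(df[[2]]))
  if (nrow(df) != length(qx) * length(qy)) {
    stop("shape error: rows do not form a complete ",
         length(qx), " x ", length(qy), " grid")
  }
  ix <- match(df[[1]], qx)
  iy <- match(df[[2]], qy)
  mean <- matrix(NA_real_, length(qx), length(qy))
  mean[cbind(ix, iy)] <- df[[3]]
  std <- NULL
  if (ncol(df) == 4) {
    std <- matrix(NA_real_, length(qx), length(qy))
    std[cbind(ix, iy)] <- df[[4]]
  } else if (std_fallback) {
    warning("no std column in ", basename(path), "; using |mean|")
  }
  intensity_data(q_grid(qx = qx, qy = qy), mean, std = std,
                 std_fallback = is.null(std))
}

is_header_line <- function(path) {
  l <- readLines(path, n = 50L)
  l <- l[trimws(sub("#.*$", "", l)) != ""][1]
  anyNA(suppressWarnings(as.numeric(strsplit(trimws(l),
                                             "[,[:space:]]+")[[1]])))
}

#' Write 2D intensity data in the long format read_intensity_2d() accepts
#'
#' @param data An [intensity_data()] with M = 2.
#' @param path Output path.
#' @export
write_intensity_2d <- function(data, path) {
  stopifnot(data$q$M == 2L)
  qx <- data$q$axes[[1]]
  qy <- data$q$axes[[2]]
  df <- data.frame(qx = rep(qx, times = length(qy)),
                   qy = rep(qy, each = length(qx)),
                   mean = as.vector(data$mean), std = as.vector(data$std))
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                     path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a solved state to a directory
#'
#' Emits `solution.json` (scale, background, chi-squared, extras, convergence
#' metadata), one `w_<parameter>.csv` per distribution (columns `value`, `w`
#' and, when supplied, `delta_w`), and the fitted intensity
#' (`fit_intensity.dat`, mirroring the input format).
#'
#' @param solution A `sas_solution`.
#' @param dir Output directory (created if needed).
#' @param data The [intensity_data()] that was fitted (for the q axes of the
#'   fitted-intensity file).
#' @param uncertainty Optional `sas_uncertainty` whose `delta_w` columns are
#'   added to the per-parameter tables.
#' @return The directory path, invisibly.
#' @export
write_solution <- function(solution, dir, data = NULL, uncertainty = NULL) {
  stopifnot(inherits(solution, "sas_solution"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(dir, ".failed")
  file.create(marker)
  d <- solution$mle
  js <- list(
    chi2 = solution$chi2, xi = d$xi,
    background = d$background[c("kind", "b", "A", "B")],
    extras = d$extras, converged = solution$converged,
    message = solution$message, n_iter = solution$n_iter,
    frozen = as.list(solution$frozen),
    scale = list(c_I = solution$scale$c_I, c_G = solution$scale$c_G))
  jsonlite::write_json(js, file.path(dir, "solution.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  nm <- solution$param_names %||% paste0("p", seq_along(d$weights))
  for (k in seq_along(d$weights)) {
    df <- data.frame(value = solution$param_values[[k]], w = d$weights[[k]])
    if (!is.null(uncertainty)) df$delta_w <- uncertainty$delta_w[[k]]
    utils::write.csv(format(df, digits = 17, trim = TRUE),
                     file.path(dir, paste0("w_", nm[k], ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  if (!is.null(data)) {
    if (data$q$M == 1L) {
      df <- data.frame(q = data$q$axes[[1]], I = as.vector(solution$fitted))
      utils::write.table(format(df, digits = 17, trim = TRUE),
                         file.path(dir, "fit_intensity.dat"),
                         quote = FALSE, row.names = FALSE)
    } else {
      fit <- data
      fit$mean <- solution$fitted
      write_intensity_2d(fit, file.path(dir, "fit_intensity.dat"))
    }
  }
  file.remove(marker)
  invisible(dir)
}

#' Read back a solution directory
#'
#' @param dir Directory written by [write_solution()].
#' @return A list with the solution summary (`summary`), the per-parameter
#'   weight tables (`w`, named list of data frames) and the fitted intensity
#'   table if present.
#' @export
read_solution <- function(dir) {
  if (file.exists(file.path(dir, ".failed"))) {
    stop("solution directory ", dir, " is marked failed")
  }
  summary <- jsonlite::read_json(file.path(dir, "solution.json"),
                                 simplifyVector = TRUE)
  wfiles <- list.files(dir, pattern = "^w_.*\\.csv$", full.names = TRUE)
  w <- lapply(wfiles, utils::read.csv)
  names(w) <- sub("^w_(.*)\\.csv$", "\\1", basename(wfiles))
  fit <- NULL
  fp <- file.path(dir, "fit_intensity.dat")
  if (file.exists(fp)) fit <- utils::read.table(fp, header = TRUE)
  list(summary = summary, w = w, fit = fit)
}

# ---- Green-tensor directory store ------------------------------------------
# Plain-text metadata plus raw little-endian double chunks split along the
# first q axis. (A portable stand-in for an HDF5 store, which has no
# R bindings in this stack.)

write_green_meta <- function(dir, model, dims, q_grid, param_grids, contrast,
                             corrections, chunk_rows, chunk_files,
                             volumes = NULL, volume_dims = NULL) {
  meta <- list(model = model, dims = dims, M = q_grid$M,
               contrast = contrast, corrections = corrections,
               chunk_rows = chunk_rows, chunk_files = chunk_files,
               param_names = names(param_grids),
               param_spacing = vapply(param_grids, function(p) p$spacing,
                                      character(1)),
               volume_dims = volume_dims)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in names(q_grid$axes)) {
    utils::write.csv(
      data.frame(value = format(q_grid$axes[[nm]], digits = 17)),
      file.path(dir, paste0("axis_", nm, ".csv")), row.names = FALSE,
      quote = FALSE)
  }
  for (nm in names(param_grids)) {
    utils::write.csv(
      data.frame(value = format(param_grids[[nm]]$values, digits = 17)),
      file.path(dir, paste0("grid_", nm, ".csv")), row.names = FALSE,
      quote = FALSE)
  }
  if (!is.null(volumes)) {
    con <- file(file.path(dir, "volumes.bin"), "wb")
    writeBin(as.vector(volumes), con, size = 8, endian = "little")
    close(con)
  }
  invisible(dir)
}

#' Persist a Green tensor to a directory store
#'
#' Writes `meta.json`, the q axes and parameter grids as CSV, and the tensor
#' data as raw little-endian doubles chunked along the first q axis (each
#' chunk at most a quarter of the memory budget).
#'
#' @param G A `green_tensor`.
#' @param dir Store directory (created if needed).
#' @param mem_budget_bytes Budget controlling the chunk size.
#' @return The directory, invisibly.
#' @export
write_green <- function(G, dir, mem_budget_bytes = 4e9) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(G$data)
  rows_per_chunk <- max(1L, min(d[1],
    floor(mem_budget_bytes / 4 / (8 * prod(d[-1])))))
  splits <- parallel_splits(d[1], ceiling(d[1] / rows_per_chunk))
  chunk_files <- character(0)
  for (ci in seq_along(splits)) {
    blk <- slice_first_axis(G$data, splits[[ci]], d)
    f <- sprintf("data_chunk_%04d.bin", ci)
    con <- file(file.path(dir, f), "wb")
    writeBin(as.vector(blk), con, size = 8, endian = "little")
    close(con)
    chunk_files <- c(chunk_files, f)
  }
  write_green_meta(dir, model = G$meta$model %||% "custom", dims = d,
                   q_grid = G$q_grid, param_grids = G$param_grids,
                   contrast = G$contrast,
                   corrections = G$meta$corrections,
                   chunk_rows = rows_per_chunk, chunk_files = chunk_files,
                   volumes = G$volumes, volume_dims = G$volume_dims)
  invisible(dir)
}

#' Load a Green tensor from a directory store
#'
#' @param dir Store directory written by [write_green()] or the chunked
#'   builder path of [cylinder_form_green_2d()].
#' @return A `green_tensor`.
#' @export
read_green <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  dims <- as.integer(meta$dims)
  M <- as.integer(meta$M)
  axis_files <- list.files(dir, pattern = "^axis_.*\\.csv$")
  axes <- lapply(axis_files, function(f) {
    utils::read.csv(file.path(dir, f))$value
  })
  names(axes) <- sub("^axis_(.*)\\.csv$", "\\1", axis_files)
  axes <- axes[order(match(names(axes), c("q", "qx", "qy")))]
  qg <- q_grid(axes)
  pgrids <- list()
  for (i in seq_along(meta$param_names)) {
    nm <- meta$param_names[i]
    vals <- utils::read.csv(file.path(dir, paste0("grid_", nm, ".csv")))$value
    pgrids[[nm]] <- param_grid(nm, vals, meta$param_spacing[i],
                               positive = all(vals > 0))
  }
  data <- array(0, dims)
  dm <- matrix(data, dims[1], prod(dims[-1]))
  row0 <- 0L
  for (f in meta$chunk_files) {
    con <- file(file.path(dir, f), "rb")
    sz <- file.info(file.path(dir, f))$size / 8
    vals <- readBin(con, "double", n = sz, size = 8, endian = "little")
    close(con)
    nr <- length(vals) / prod(dims[-1])
    dm[row0 + seq_len(nr), ] <- matrix(vals, nr)
    row0 <- row0 + nr
  }
  volumes <- NULL
  if (file.exists(file.path(dir, "volumes.bin"))) {
    con <- file(file.path(dir, "volumes.bin"), "rb")
    sz <- file.info(file.path(dir, "volumes.bin"))$size / 8
    volumes <- readBin(con, "double", n = sz, size = 8, endian = "little")
    close(con)
    vd <- meta$volume_dims
    if (length(vd) > 1L) {
      dim(volumes) <- dims[M + match(vd, meta$param_names)]
    }
  }
  green_tensor(array(dm, dims), qg, pgrids, contrast = meta$contrast,
               volumes = volumes, volume_dims = meta$volume_dims,
               meta = list(model = meta$model,
                           corrections = as.character(meta$corrections)))
}
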