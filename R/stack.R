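#' Environmental raster layers and stacks
#'
#' `env_layer()` wraps a single matrix of cell values on an [env_grid()];
#' `env_stack()` holds an ordered set of named layers sharing one grid and
#' one nodata mask, tagged with the time period / scenario it represents and
#' the climate model (GCM) it came from. Values are stored as plain matrices
#' (`n_rows` x `n_cols`, row 1 = northern edge) with `NA` as nodata.
#'
#' @param grid An [env_grid()].
#' @param values Numeric matrix of dim `n_rows` x `n_cols` (`NA` = nodata).
#' @param name Layer (variable) name.
#' @return An `env_layer` / `env_stack` object.
#' @export
env_layer <- function(grid, values, name = "layer") {
  stopifnot(inherits(grid, "env_grid"))
  values <- as.matrix(values)
  if (!all(dim(values) == c(grid$n_rows, grid$n_cols))) {
    abort(sprintf("values must be a %d x %d matrix", grid$n_rows, grid$n_cols))
  }
  structure(list(grid = grid, values = values, name = name), class = "env_layer")
}

#' @param layers Named list of numeric matrices (or `env_layer`s), one per
#'   variable, identical dimensions and nodata masks.
#' @param period_label Label of the time period / scenario
#'   (e.g. `"present"`, `"LGM"`, `"SSP3-7.0 2021-2030"`).
#' @param gcm_label Source climate model label (e.g. a GCM id), or
#'   `"observed"` for measured present-day layers.
#' @rdname env_layer
#' @export
env_stack <- function(grid, layers, period_label = "present", gcm_label = "observed") {
  stopifnot(inherits(grid, "env_grid"))
  if (length(layers) < 1 || is.null(names(layers)) || any(names(layers) == "")) {
    abort("layers must be a non-empty named list")
  }
  layers <- lapply(layers, function(l) if (inherits(l, "env_layer")) l$values else as.matrix(l))
  for (nm in names(layers)) {
    if (!all(dim(layers[[nm]]) == c(grid$n_rows, grid$n_cols))) {
      abort(sprintf("layer '%s' does not match the grid dimensions", nm))
    }
  }
  mask <- is.na(layers[[1]])
  for (nm in names(layers)) {
    if (!identical(is.na(layers[[nm]]), mask)) {
      abort(sprintf("layer '%s' has a different nodata mask", nm))
    }
  }
  structure(
    list(grid = grid, layers = layers,
         period_label = period_label, gcm_label = gcm_label),
    class = "env_stack"
  )
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("<env_stack> %d variable(s) [%s], period '%s', gcm '%s'\n",
              length(x$layers), paste(names(x$layers), collapse = ", "),
              x$period_label, x$gcm_label))
  print(x$grid)
  invisible(x)
}

#' @export
print.env_layer <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<env_layer> '%s', range [%.4g, %.4g], %d nodata cell(s)\n",
              x$name, min(v), max(v), sum(is.na(x$values))))
  print(x$grid)
  invisible(x)
}

# matrix of cell values (rows = cells in 0-based id order, cols = variables)
stack_values <- function(stack, cells = NULL, variables = names(stack$layers)) {
  m <- vapply(stack$layers[variables], function(v) as.vector(t(v)),
              numeric(n_cells(stack$grid)))
  m <- matrix(m, ncol = length(variables),
              dimnames = list(NULL, variables))
  if (!is.null(cells)) m <- m[cells + 1, , drop = FALSE]
  m
}

# 0-based ids of cells that carry data
valid_cells <- function(stack) {
  which(!is.na(as.vector(t(stack$layers[[1]])))) - 1L
}

# vector (0-based id order) -> matrix on the grid
vector_to_matrix <- function(grid, x) {
  matrix(x, nrow = grid$n_rows, ncol = grid$n_cols, byrow = TRUE)
}

#' Turn a layer or stack into a tidy tibble of cells
#'
#' One row per (cell, variable); nodata cells are dropped. This is the
#' bridge used by the `autoplot()` methods.
#'
#' @param x An `env_layer` or `env_stack`.
#' @return A tibble with `longitude`, `latitude`, `variable`, `value`.
#' @export
as_cell_tibble <- function(x) {
  if (inherits(x, "env_layer")) {
    x <- structure(list(grid = x$grid, layers = stats::setNames(list(x$values), x$name)),
                   class = "env_stack")
  }
  stopifnot(inherits(x, "env_stack"))
  ids <- 0:(n_cells(x$grid) - 1)
  ctr <- cell_center(x$grid, ids)
  out <- purrr::map_dfr(names(x$layers), function(nm) {
    val <- as.vector(t(x$layers[[nm]]))
    tibble(longitude = ctr$longitude, latitude = ctr$latitude,
           variable = nm, value = val)
  })
  out[!is.na(out$value), ]
}

#' Read and write layers as ESRI ASCII grids
#'
#' Plain-text single-band raster exchange. A stack is written as one `.asc`
#' file per variable plus a `stack.json` sidecar recording variable order,
#' period and GCM labels.
#'
#' @param layer An `env_layer`.
#' @param path File path (`.asc`) or, for stacks, a directory.
#' @param nodata Sentinel written for `NA` cells.
#' @return `read_ascii_grid()` returns an `env_layer`; `read_stack_dir()`
#'   an `env_stack`; the writers return the path invisibly.
#' @export
write_ascii_grid <- function(layer, path, nodata = -9999) {
  g <- layer$grid
  hdr <- c(
    sprintf("ncols %d", g$n_cols),
    sprintf("nrows %d", g$n_rows),
    sprintf("xllcorner %.10g", g$west),
    sprintf("yllcorner %.10g", g$south),
    sprintf("cellsize %.12g", g$cell_size),
    sprintf("NODATA_value %g", nodata)
  )
  vals <- layer$values
  vals[is.na(vals)] <- nodata
  body <- apply(vals, 1, function(r) paste(format(r, digits = 12, trim = TRUE), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  kv <- stats::setNames(as.numeric(vapply(hdr, `[`, "", 2)), vapply(hdr, `[`, "", 1))
  g <- env_grid(kv[["nrows"]], kv[["ncols"]],
                west = kv[["xllcorner"]], south = kv[["yllcorner"]],
                east = kv[["xllcorner"]] + kv[["ncols"]] * kv[["cellsize"]],
                north = kv[["yllcorner"]] + kv[["nrows"]] * kv[["cellsize"]])
  vals <- do.call(rbind, lapply(lines[-(1:6)], function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  vals[vals == kv[["nodata_value"]]] <- NA
  env_layer(g, vals, name = sub("\\.asc$", "", basename(path)))
}

#' @param stack An `env_stack` (for `write_stack_dir`).
#' @rdname write_ascii_grid
#' @export
write_stack_dir <- function(stack, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(stack$layers)) {
    write_ascii_grid(env_layer(stack$grid, stack$layers[[nm]], nm),
                     file.path(path, paste0(nm, ".asc")))
  }
  meta <- list(variables = names(stack$layers),
               period_label = stack$period_label, gcm_label = stack$gcm_label)
  jsonlite::write_json(meta, file.path(path, "stack.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_stack_dir <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "stack.json"), simplifyVector = TRUE)
  layers <- lapply(meta$variables, function(nm) {
    read_ascii_grid(file.path(path, paste0(nm, ".asc")))$values
  })
  names(layers) <- meta$variables
  env_stack(read_ascii_grid(file.path(path, paste0(meta$variables[1], ".asc")))$grid,
            layers, period_label = meta$period_label, gcm_label = meta$gcm_label)
}
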