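#' Coarsen a stack by block aggregation
#'
#' Mirrors the usual preprocessing step of adjusting fine-resolution climate
#' and soil layers to the working resolution: each output cell is the mean
#' of the non-nodata source cells in its block; a cell is nodata only when
#' the whole block is. The extent is preserved, so the grid dimensions must
#' divide by the factor.
#'
#' @param stack An [env_stack()].
#' @param factor Integer aggregation factor (>= 1 cells per side).
#' @return The aggregated [env_stack()].
#' @export
aggregate_stack <- function(stack, factor) {
  check_scalar(factor, "factor", 1)
  factor <- as.integer(factor)
  if (factor == 1L) return(stack)
  g <- stack$grid
  if (g$n_rows %% factor != 0 || g$n_cols %% factor != 0) {
    abort(sprintf("aggregation factor %d does not divide the %d x %d grid",
                  factor, g$n_rows, g$n_cols))
  }
  nr <- g$n_rows %/% factor
  nc <- g$n_cols %/% factor
  block_mean <- function(v) {
    ri <- rep(seq_len(nr), each = factor)
    ci <- rep(seq_len(nc), each = factor)
    sums <- rowsum(v, ri, na.rm = TRUE)          # nr x n_cols
    cnts <- rowsum((!is.na(v)) * 1, ri)
    sums <- t(rowsum(t(sums), ci, na.rm = TRUE)) # nr x nc
    cnts <- t(rowsum(t(cnts), ci))
    out <- sums / cnts
    out[cnts == 0] <- NA
    out
  }
  grid2 <- env_grid(nr, nc, g$west, g$south, g$east, g$north)
  env_stack(grid2, lapply(stack$layers, block_mean),
            period_label = stack$period_label, gcm_label = stack$gcm_label)
}

#' @param target_cell_size Target resolution in degrees; must be an integer
#'   multiple of the current cell size (within 1e-9).
#' @rdname aggregate_stack
#' @export
resample_stack <- function(stack, target_cell_size) {
  ratio <- target_cell_size / stack$grid$cell_size
  if (abs(ratio - round(ratio)) > 1e-9 || round(ratio) < 1) {
    abort(sprintf("target cell size %.6g is not an integer multiple of %.6g",
                  target_cell_size, stack$grid$cell_size))
  }
  aggregate_stack(stack, round(ratio))
}

#' Prune collinear variables by Spearman rank correlation
#'
#' Computes pairwise Spearman rho (mid-ranks for ties) over all cells with
#' data, then scans the variables in priority order, keeping a variable iff
#' its |rho| with every already-kept variable is at most `threshold`
#' (inclusive, so a pair at exactly the threshold is tolerated). Distinct
#' variable families (e.g. climate + elevation vs soil composition) can be
#' pruned in separate passes by calling this on sub-stacks.
#'
#' @param stack An [env_stack()].
#' @param threshold Spearman |rho| ceiling between kept variables
#'   (default 0.6).
#' @param priority Character vector: the order in which variables compete
#'   for retention (a permutation of the layer names; default input order).
#' @return Kept variable names in priority order, with the full correlation
#'   matrix as attribute `rho`. Constant variables are excluded with a
#'   warning (their rank correlation is undefined).
#' @export
#' @examples
#' st <- simulate_environment(20, 20, n_vars = 3, seed = 2,
#'   correlated_pairs = list(list("var1", "var2", 0.95)))
#' spearman_select(st) # var2 collides with var1 and is dropped
spearman_select <- function(stack, threshold = 0.6, priority = names(stack$layers)) {
  check_scalar(threshold, "threshold", 0, 1)
  if (!setequal(priority, names(stack$layers))) {
    abort("priority must be a permutation of the stack's variable names")
  }
  m <- stack_values(stack)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  constant <- vapply(priority, function(v) length(unique(m[, v])) < 2, logical(1))
  if (any(constant)) {
    warn(paste0("excluding constant variable(s) with undefined rank correlation: ",
                paste(priority[constant], collapse = ", ")))
    priority <- priority[!constant]
  }
  if (length(priority) == 0) abort("no non-constant variable to select from")
  rho <- cor(m[, priority, drop = FALSE], method = "spearman")
  kept <- character(0)
  for (v in priority) {
    if (all(abs(rho[v, kept]) <= threshold)) kept <- c(kept, v)
  }
  structure(kept, rho = rho)
}
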