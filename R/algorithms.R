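# The five niche-model algorithms behind a single fit/predict interface.
# BIOCLIM and Domain are presence-only and authored here (their scoring
# rules are the classical envelope / Gower-similarity conventions and are
# rank-exact for testing); GLM, SVM and Random Forest are delegated to
# stats::glm, kernlab::ksvm and randomForest::randomForest.

ENM_ALGORITHMS <- c("bioclim", "domain", "glm", "svm", "rf")

#' Fit one niche-model algorithm on presence / pseudoabsence cell values
#'
#' @param algorithm One of `"bioclim"`, `"domain"` (presence-only; the
#'   background matrix is ignored), `"glm"`, `"svm"`, `"rf"`.
#' @param presence Numeric matrix of environmental values at training
#'   presence cells (rows = cells, named columns = variables).
#' @param background Numeric matrix of values at training pseudoabsence
#'   cells (same columns).
#' @param seed Integer seed; fits are deterministic given it.
#' @return An `enm_model` object usable with [predict_cells()] and
#'   [predict_raster()].
#' @export
fit_algorithm <- function(algorithm, presence, background = NULL, seed = 1) {
  algorithm <- match.arg(algorithm, ENM_ALGORITHMS)
  if (nrow(presence) < 1) abort("empty presence training set")
  vars <- colnames(presence)
  if (is.null(vars)) abort("training matrices must have named columns")
  fit <- switch(algorithm,
    bioclim = {
      if (nrow(presence) < 2) abort("bioclim needs >= 2 training presences")
      lapply(stats::setNames(vars, vars), function(v) sort(presence[, v]))
    },
    domain = list(train = presence,
                  range = apply(presence, 2, function(x) diff(range(x)))),
    glm = {
      df <- as.data.frame(rbind(presence, background))
      df$.y <- rep(c(1L, 0L), c(nrow(presence), nrow(background)))
      fml <- stats::as.formula(paste(".y ~", paste(sprintf("`%s`", vars), collapse = " + ")))
      withCallingHandlers(
        glm(fml, family = binomial(), data = df),
        warning = function(w) {
          # complete separation / non-convergence: flag, keep the fit
          if (grepl("fitted probabilities|did not converge", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        }
      )
    },
    svm = {
      x <- rbind(presence, background)
      y <- factor(rep(c("pres", "bg"), c(nrow(presence), nrow(background))),
                  levels = c("bg", "pres"))
      set.seed(seed)
      kernlab::ksvm(x, y, kernel = "rbfdot", C = 1, prob.model = FALSE, scaled = TRUE)
    },
    rf = {
      x <- rbind(presence, background)
      y <- factor(rep(c(1, 0), c(nrow(presence), nrow(background))), levels = c(0, 1))
      set.seed(seed)
      randomForest::randomForest(x, y, ntree = 500)
    }
  )
  flagged <- FALSE
  if (algorithm == "glm") {
    flagged <- !fit$converged || any(fit$fitted.values > 1 - 1e-10) &&
      any(fit$fitted.values < 1e-10)
  }
  structure(list(algorithm = algorithm, fit = fit, variables = vars,
                 seed = seed, flagged = flagged),
            class = "enm_model")
}

# percentile with mid-rank tie handling: (c_less + 0.5 c_equal) / n
bioclim_percentile <- function(sorted_train, q) {
  n <- length(sorted_train)
  c_le <- findInterval(q, sorted_train)
  c_less <- findInterval(q, sorted_train, left.open = TRUE)
  (c_less + 0.5 * (c_le - c_less)) / n
}

score_bioclim <- function(model, newdata) {
  s <- rep(1, nrow(newdata))
  for (v in model$variables) {
    p <- bioclim_percentile(model$fit[[v]], newdata[, v])
    s <- pmin(s, 2 * pmin(p, 1 - p))
  }
  s
}

score_domain <- function(model, newdata) {
  tr <- model$fit$train
  rg <- model$fit$range
  V <- length(model$variables)
  dmin <- rep(Inf, nrow(newdata))
  for (b in seq_len(nrow(tr))) {
    d <- rep(0, nrow(newdata))
    for (v in model$variables) {
      dv <- abs(newdata[, v] - tr[b, v])
      d <- d + if (rg[[v]] == 0) as.numeric(dv != 0) else dv / rg[[v]]
    }
    dmin <- pmin(dmin, d / V)
  }
  pmax(0, 1 - dmin)
}

#' Score cells under a fitted model
#'
#' Returns each algorithm's native continuous score: BIOCLIM envelope score
#' and Domain Gower similarity are already in \[0, 1\]; GLM and Random
#' Forest give probabilities; SVM gives raw decision values, mapped to
#' \[0, 1\] later by range normalization over a whole prediction raster
#' (see [predict_raster()]).
#'
#' @param model An `enm_model` from [fit_algorithm()].
#' @param newdata Numeric matrix with the model's variables as columns.
#' @return Numeric score vector, one per row of `newdata`.
#' @export
predict_cells <- function(model, newdata) {
  missing <- setdiff(model$variables, colnames(newdata))
  if (length(missing)) {
    abort(paste0("newdata is missing variable(s): ", paste(missing, collapse = ", ")))
  }
  newdata <- newdata[, model$variables, drop = FALSE]
  switch(model$algorithm,
    bioclim = score_bioclim(model, newdata),
    domain = score_domain(model, newdata),
    glm = unname(predict(model$fit, as.data.frame(newdata), type = "response")),
    svm = as.vector(kernlab::predict(model$fit, newdata, type = "decision")),
    rf = unname(predict(model$fit, newdata, type = "prob")[, "1"])
  )
}

#' Project a fitted model over an environmental stack
#'
#' Applies the model cell-wise to every non-nodata cell, producing a
#' continuous suitability layer in \[0, 1\]. Nodata propagates. For SVM the
#' raw decision values are range-normalized over the raster's cells, per
#' the package's fixed output contract for margin-based classifiers.
#'
#' @param model An `enm_model`.
#' @param stack An [env_stack()] providing all model variables.
#' @return An [env_layer()] of suitability scores.
#' @export
predict_raster <- function(model, stack) {
  cells <- valid_cells(stack)
  scores <- predict_cells(model, stack_values(stack, cells))
  if (model$algorithm == "svm") {
    rng <- range(scores)
    if (diff(rng) == 0) abort("constant SVM decision values over the raster")
    scores <- (scores - rng[1]) / diff(rng)
  }
  full <- rep(NA_real_, n_cells(stack$grid))
  full[cells + 1] <- scores
  env_layer(stack$grid, vector_to_matrix(stack$grid, full),
            name = paste0(model$algorithm, "_suitability"))
}
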