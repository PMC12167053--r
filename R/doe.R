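#' Define a design factor
#'
#' A named factor with its natural-unit range. Coded level -1 maps to `low`,
#' +1 to `high`, 0 to the midpoint.
#'
#' @param name Factor name.
#' @param low,high Natural-unit bounds, `low < high`.
#' @return A list of class `factor_def`.
#' @export
factor_def <- function(name, low, high) {
  if (!is.finite(low) || !is.finite(high) || low >= high) {
    stop(sprintf("factor '%s': low must be < high", name))
  }
  structure(list(name = as.character(name), low = as.numeric(low),
                 high = as.numeric(high)), class = "factor_def")
}

#' Default lysis-optimization factors
#'
#' The three in-situ lysis factors and their studied ranges: detergent contact
#' time 30-240 min, initial cell density 1e6-1e7 cells/mL, Triton X-100
#' concentration 0.2-1.0%.
#'
#' @return List of three [factor_def()] objects.
#' @export
lysis_factors <- function() {
  list(factor_def("contact_time_min", 30, 240),
       factor_def("cell_density_per_mL", 1e6, 1e7),
       factor_def("triton_pct", 0.2, 1.0))
}

factors_frame <- function(factors) {
  if (inherits(factors, "factor_def")) factors <- list(factors)
  data.frame(name = vapply(factors, `[[`, character(1), "name"),
             low = vapply(factors, `[[`, numeric(1), "low"),
             high = vapply(factors, `[[`, numeric(1), "high"),
             stringsAsFactors = FALSE)
}

decode_design <- function(coded, fdf) {
  center <- (fdf$high + fdf$low) / 2
  half <- (fdf$high - fdf$low) / 2
  sweep(sweep(coded, 2, half, `*`), 2, center, `+`)
}

encode_design <- function(natural, fdf) {
  center <- (fdf$high + fdf$low) / 2
  half <- (fdf$high - fdf$low) / 2
  sweep(sweep(natural, 2, center, `-`), 2, half, `/`)
}

#' Face-centred central composite design
#'
#' Builds the standard face-centred CCD: the full 2^k factorial at coded
#' levels +/-1, 2k axial points on the cube faces (+/-1 on one axis, 0
#' elsewhere), and replicated center points. Natural values follow by linear
#' decoding about each factor's midpoint.
#'
#' @param factors List of [factor_def()] (2 to 6 factors).
#' @param n_center Number of center-point replicates (>= 1, default 3).
#' @return An object of class `ccd_design` with the factor table, coded and
#'   natural matrices, `n_center` and `row_labels`
#'   (factorial/axial/center).
#' @examples
#' d <- ccd_face_centered(lysis_factors(), n_center = 3)
#' nrow(d$coded)  # 8 + 6 + 3 = 17
#' @export
ccd_face_centered <- function(factors, n_center = 3) {
  fdf <- factors_frame(factors)
  k <- nrow(fdf)
  if (k < 2 || k > 6) stop("supported factor count is 2..6")
  if (n_center < 1) stop("n_center must be >= 1")
  factorial <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  axial <- matrix(0, 2 * k, k)
  for (j in seq_len(k)) {
    axial[2 * j - 1, j] <- -1
    axial[2 * j, j] <- 1
  }
  center <- matrix(0, n_center, k)
  coded <- rbind(factorial, axial, center)
  dimnames(coded) <- list(NULL, fdf$name)
  natural <- decode_design(coded, fdf)
  structure(list(
    factors = fdf, coded = coded, natural = natural,
    n_center = as.integer(n_center),
    row_labels = c(rep("factorial", 2^k), rep("axial", 2 * k),
                   rep("center", n_center))
  ), class = "ccd_design")
}

#' @export
print.ccd_design <- function(x, ...) {
  cat(sprintf("Face-centred CCD: %d factors, %d runs (%d factorial + %d axial + %d center)\n",
              nrow(x$factors), nrow(x$coded), 2^nrow(x$factors),
              2 * nrow(x$factors), x$n_center))
  print(x$factors, row.names = FALSE)
  invisible(x)
}

#' Export a design (with optional responses) as a data.frame
#'
#' One row per run: label, coded and natural factor settings, and, when
#' given, the response and per-row dilution factor. Suitable for
#' `write.csv()`.
#'
#' @param design A `ccd_design`.
#' @param responses Optional response vector (length = runs).
#' @param dilution_factors Optional per-row dilution scalars.
#' @return data.frame.
#' @export
design_table <- function(design, responses = NULL, dilution_factors = NULL) {
  out <- data.frame(label = design$row_labels)
  for (j in seq_len(nrow(design$factors))) {
    out[[paste0("coded_", design$factors$name[j])]] <- design$coded[, j]
  }
  for (j in seq_len(nrow(design$factors))) {
    out[[design$factors$name[j]]] <- design$natural[, j]
  }
  if (!is.null(responses)) out$response <- responses
  if (!is.null(dilution_factors)) out$dilution_factor <- dilution_factors
  out
}

# Canonical term order of the full quadratic in k coded factors:
# intercept, k linear, k squares, k(k-1)/2 pairwise interactions.
quadratic_model_matrix <- function(coded) {
  k <- ncol(coded)
  nms <- colnames(coded)
  cols <- list(`(Intercept)` = rep(1, nrow(coded)))
  for (j in seq_len(k)) cols[[nms[j]]] <- coded[, j]
  for (j in seq_len(k)) cols[[paste0(nms[j], "^2")]] <- coded[, j]^2
  if (k >= 2) {
    for (a in seq_len(k - 1)) for (b in seq((a + 1), k)) {
      cols[[paste0(nms[a], ":", nms[b])]] <- coded[, a] * coded[, b]
    }
  }
  mm <- do.call(cbind, cols)
  colnames(mm) <- names(cols)
  mm
}

#' Fit a full-quadratic response surface to a designed experiment
#'
#' Ordinary least squares on the full second-order model (intercept, linear,
#' pure quadratic and pairwise interaction terms) in coded units. Responses
#' are multiplied by their per-row dilution factors before fitting, matching
#' the convention of correcting diluted titer measurements back to the
#' undiluted scale. Model significance is the overall F-test of the full
#' model against intercept-only.
#'
#' @param design A `ccd_design` (or any object with `$coded` and
#'   `$factors`).
#' @param responses Numeric response per design row (e.g. recovered vg/mL).
#' @param dilution_factors Scalar or per-row vector of positive dilution
#'   factors applied multiplicatively to the responses (default 1).
#' @return An object of class `rsm_fit` with `coefficients` (canonical
#'   order), `sigma2` (residual variance), `model_F`, `model_p`,
#'   `r_squared`, the underlying `lm` fit and the design's factor table.
#' @export
fit_quadratic <- function(design, responses, dilution_factors = 1) {
  coded <- design$coded
  n <- nrow(coded)
  if (length(responses) != n) {
    stop("responses length must equal the design row count")
  }
  dil <- rep_len(dilution_factors, n)
  if (any(!is.finite(dil)) || any(dil <= 0)) {
    stop("dilution factors must be > 0")
  }
  y <- responses * dil
  mm <- quadratic_model_matrix(coded)
  p <- ncol(mm)
  if (n < p) {
    qr_mm <- qr(mm)
    keep <- qr_mm$pivot[seq_len(qr_mm$rank)]
    deficient <- setdiff(colnames(mm), colnames(mm)[keep])
    stop("rank-deficient design; cannot estimate terms: ",
         paste(deficient, collapse = ", "))
  }
  df <- as.data.frame(mm[, -1, drop = FALSE])
  names(df) <- paste0("t", seq_len(ncol(df)))  # syntactic term aliases
  df$.y <- y
  fit <- stats::lm(.y ~ ., data = df)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    idx <- as.integer(sub("^t", "", bad))
    stop("rank-deficient design; cannot estimate terms: ",
         paste(colnames(mm)[idx + 1L], collapse = ", "))
  }
  beta <- stats::coef(fit)
  names(beta) <- colnames(mm)
  sm <- suppressWarnings(summary(fit))  # interpolating fits warn harmlessly
  if (stats::var(y) < .Machine$double.eps * max(1, mean(y)^2)) {
    # degenerate constant response: no signal, by convention p = 1, R^2 = 0
    model_F <- 0; model_p <- 1; r2 <- 0
  } else if (is.null(sm$fstatistic)) {
    model_F <- NA_real_; model_p <- NA_real_; r2 <- sm$r.squared
  } else {
    fs <- sm$fstatistic
    model_F <- unname(fs[1])
    model_p <- stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
    r2 <- sm$r.squared
  }
  structure(list(
    coefficients = beta,
    sigma2 = sm$sigma^2,
    model_F = model_F, model_p = model_p, r_squared = r2,
    factors = design$factors,
    dilution_factors = dil,
    lm = fit
  ), class = "rsm_fit")
}

#' @export
coef.rsm_fit <- function(object, ...) object$coefficients

#' @export
print.rsm_fit <- function(x, ...) {
  k <- nrow(x$factors)
  cat(sprintf("Quadratic response surface (%d factors)\n", k))
  cat(sprintf("  R^2 = %.4f, model F = %.3g, p = %.3g\n",
              x$r_squared, x$model_F, x$model_p))
  print(round(x$coefficients, 6))
  invisible(x)
}

#' @export
summary.rsm_fit <- function(object, ...) {
  print(object)
  cat("\nFactor ranges:\n")
  print(object$factors, row.names = FALSE)
  invisible(object)
}

# Split the canonical coefficient vector into (b0, b, A) with A symmetric:
# f(x) = b0 + b'x + x' A x in coded units.
quad_parts <- function(fit) {
  k <- nrow(fit$factors)
  beta <- fit$coefficients
  b0 <- beta[1]
  b <- beta[1 + seq_len(k)]
  A <- diag(beta[1 + k + seq_len(k)], k)
  if (k >= 2) {
    idx <- 1 + 2 * k
    for (a in seq_len(k - 1)) for (bb in seq((a + 1), k)) {
      idx <- idx + 1
      A[a, bb] <- A[bb, a] <- beta[idx] / 2
    }
  }
  list(b0 = unname(b0), b = unname(b), A = A)
}

eval_quad <- function(parts, X) {
  # X: rows are coded points
  drop(parts$b0 + X %*% parts$b + rowSums((X %*% parts$A) * X))
}

#' Predict from a fitted response surface
#'
#' @param object An `rsm_fit`.
#' @param newdata Matrix or data.frame of factor settings (columns in factor
#'   order or named by factor).
#' @param scale `"natural"` (default) if `newdata` is in natural units,
#'   `"coded"` if already coded.
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.rsm_fit <- function(object, newdata, scale = c("natural", "coded"), ...) {
  scale <- match.arg(scale)
  X <- as.matrix(as.data.frame(newdata))
  if (!is.null(colnames(X)) && all(object$factors$name %in% colnames(X))) {
    X <- X[, object$factors$name, drop = FALSE]
  }
  if (scale == "natural") X <- encode_design(X, object$factors)
  eval_quad(quad_parts(object), X)
}

#' Constrained optimum of a fitted quadratic
#'
#' Exact maximizer (or minimizer) of the fitted second-order surface over the
#' closed coded cube \[-1, 1\]^k, optionally with factors pinned to fixed
#' natural-unit values. The optimum of a quadratic over a box lies either at
#' an interior stationary point or on a face; all 3^k face subproblems (each
#' coordinate free or fixed at +/-1) are solved analytically and the best
#' feasible candidate returned, so no iterative search is involved.
#'
#' @param fit An `rsm_fit`.
#' @param fixed Optional named numeric vector pinning factors to natural-unit
#'   values inside their ranges.
#' @param maximize Maximize (default, responses are recovered titers) or
#'   minimize.
#' @return List with `coded` and `natural` optimizer locations and the
#'   `predicted` response there.
#' @export
optimum_within_bounds <- function(fit, fixed = NULL, maximize = TRUE) {
  k <- nrow(fit$factors)
  parts <- quad_parts(fit)
  sgn <- if (maximize) 1 else -1
  pinned <- rep(NA_real_, k)
  if (!is.null(fixed)) {
    for (nm in names(fixed)) {
      j <- match(nm, fit$factors$name)
      if (is.na(j)) stop("unknown factor in 'fixed': ", nm)
      cv <- (fixed[[nm]] - (fit$factors$high[j] + fit$factors$low[j]) / 2) /
        ((fit$factors$high[j] - fit$factors$low[j]) / 2)
      if (cv < -1 - 1e-9 || cv > 1 + 1e-9) {
        stop("pinned level outside bounds for factor: ", nm)
      }
      pinned[j] <- max(-1, min(1, cv))
    }
  }
  free_idx <- which(is.na(pinned))
  kf <- length(free_idx)
  best_val <- -Inf
  best_x <- NULL
  # enumerate face patterns over the free coordinates: -1, +1 or interior
  patterns <- expand.grid(rep(list(c(-1, 1, 0)), kf))
  for (r in seq_len(max(1, nrow(patterns)))) {
    x <- pinned
    if (kf > 0) {
      pat <- as.numeric(patterns[r, ])
      interior <- free_idx[pat == 0]
      x[free_idx[pat != 0]] <- pat[pat != 0]
    } else {
      interior <- integer()
    }
    if (length(interior)) {
      Fi <- interior
      Sx <- x
      Sx[Fi] <- 0
      AFF <- parts$A[Fi, Fi, drop = FALSE]
      rhs <- -(parts$b[Fi] + 2 * (parts$A[Fi, , drop = FALSE] %*% Sx))
      sol <- tryCatch(solve(2 * AFF, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      if (any(abs(sol) > 1 + 1e-9)) next
      x[Fi] <- pmax(-1, pmin(1, sol))
    }
    val <- sgn * eval_quad(parts, matrix(x, 1))
    if (val > best_val + 1e-12) {
      best_val <- val
      best_x <- x
    }
  }
  coded <- best_x
  names(coded) <- fit$factors$name
  natural <- drop(decode_design(matrix(coded, 1), fit$factors))
  names(natural) <- fit$factors$name
  list(coded = coded, natural = natural, predicted = sgn * best_val)
}

#' Prediction grid for contour plotting
#'
#' Evaluates the fitted surface on a rectangular natural-unit grid over two
#' chosen factors, with every other factor pinned, e.g. the response over
#' contact time x detergent concentration at a fixed cell density. The long
#' data.frame exports directly to CSV for external heat-mapping.
#'
#' @param fit An `rsm_fit`.
#' @param axis_pair Character vector of two distinct factor names.
#' @param fixed_levels Named numeric vector of natural-unit levels for all
#'   remaining factors (must lie inside their ranges).
#' @param resolution Points per axis (default 50).
#' @return data.frame with the two axis columns and `response`.
#' @export
contour_grid <- function(fit, axis_pair, fixed_levels = NULL, resolution = 50) {
  if (length(axis_pair) != 2 || axis_pair[1] == axis_pair[2]) {
    stop("axis_pair must name two distinct factors")
  }
  idx <- match(axis_pair, fit$factors$name)
  if (anyNA(idx)) {
    stop("unknown factor name: ", paste(axis_pair[is.na(idx)], collapse = ", "))
  }
  k <- nrow(fit$factors)
  others <- setdiff(seq_len(k), idx)
  lv <- numeric(k)
  for (j in others) {
    nm <- fit$factors$name[j]
    if (is.null(fixed_levels) || !(nm %in% names(fixed_levels))) {
      stop("fixed level required for factor: ", nm)
    }
    v <- fixed_levels[[nm]]
    if (v < fit$factors$low[j] - 1e-9 || v > fit$factors$high[j] + 1e-9) {
      stop("fixed level outside bounds for factor: ", nm)
    }
    lv[j] <- v
  }
  ax1 <- seq(fit$factors$low[idx[1]], fit$factors$high[idx[1]],
             length.out = resolution)
  ax2 <- seq(fit$factors$low[idx[2]], fit$factors$high[idx[2]],
             length.out = resolution)
  grid <- expand.grid(ax1, ax2)
  X <- matrix(rep(lv, each = nrow(grid)), nrow(grid), k)
  X[, idx[1]] <- grid[[1]]
  X[, idx[2]] <- grid[[2]]
  colnames(X) <- fit$factors$name
  out <- data.frame(grid[[1]], grid[[2]],
                    response = predict(fit, X, scale = "natural"))
  names(out)[1:2] <- axis_pair
  out
}
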