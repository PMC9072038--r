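#' Balanced area-by-time panel of direct estimates
#'
#' Container for the inputs of the area-level models: per (area i, period t)
#' a direct survey estimate, its known sampling variance, and covariates.
#' All stacked vectors and matrices in the package use area-major,
#' time-minor order: row index \eqn{(i-1) T + t}.
#'
#' @param area_ids character or numeric vector of m unique area identifiers.
#' @param time_ids vector of T strictly increasing time labels (e.g. survey
#'   years). The models treat periods as equally spaced integers 1..T.
#' @param y m x T matrix of direct estimates.
#' @param D m x T matrix of known, strictly positive sampling variances.
#' @param X (m*T) x p covariate matrix in stacked order (an intercept column
#'   is allowed and typical). Must have full column rank.
#'
#' @return An object of class `area_panel` with fields `area_ids`,
#'   `time_ids`, `y`, `D`, `X`, `m`, `T`, `p`.
#' @export
area_panel <- function(area_ids, time_ids, y, D, X) {
  area_ids <- as.character(area_ids)
  if (anyDuplicated(area_ids)) {
    stfh_stop("duplicated area ids", "stfh_validation_error")
  }
  m <- length(area_ids)
  tt <- length(time_ids)
  if (is.numeric(time_ids) && tt > 1 && any(diff(time_ids) <= 0)) {
    stfh_stop("time_ids must be strictly increasing", "stfh_validation_error")
  }
  if (anyDuplicated(time_ids)) {
    stfh_stop("duplicated time labels", "stfh_validation_error")
  }
  y <- as.matrix(y); D <- as.matrix(D); X <- as.matrix(X)
  if (!all(dim(y) == c(m, tt)) || !all(dim(D) == c(m, tt))) {
    stfh_stop(sprintf("y and D must be %d x %d", m, tt),
              "stfh_validation_error")
  }
  if (nrow(X) != m * tt) {
    stfh_stop(sprintf("X must have %d rows (area-major stacking)", m * tt),
              "stfh_validation_error")
  }
  if (anyNA(y) || anyNA(D) || anyNA(X)) {
    stfh_stop("panel contains missing values", "stfh_validation_error")
  }
  if (any(!is.finite(D)) || any(D <= 0)) {
    bad <- which(D <= 0 | !is.finite(D), arr.ind = TRUE)
    stfh_stop(sprintf(
      "sampling variances must be finite and > 0 (first offender: area %s, period %s)",
      area_ids[bad[1, 1]], time_ids[bad[1, 2]]), "stfh_validation_error")
  }
  p <- ncol(X)
  qrx <- qr(X)
  if (qrx$rank < p) {
    dep <- colnames(X)[qrx$pivot[(qrx$rank + 1):p]] %||%
      qrx$pivot[(qrx$rank + 1):p]
    stfh_stop(paste0("X is rank deficient; dependent column(s): ",
                     paste(dep, collapse = ", ")), "stfh_rank_error")
  }
  if (p >= m * tt) {
    stfh_stop("X must have fewer columns than m*T rows", "stfh_rank_error")
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  rownames(y) <- rownames(D) <- area_ids
  colnames(y) <- colnames(D) <- as.character(time_ids)
  structure(list(area_ids = area_ids, time_ids = time_ids,
                 y = y, D = D, X = X, m = m, T = tt, p = p),
            class = "area_panel")
}

#' @export
print.area_panel <- function(x, ...) {
  cat(sprintf("area_panel: %d areas x %d periods, %d covariate column(s)\n",
              x$m, x$T, x$p))
  cat("periods:", paste(x$time_ids, collapse = ", "), "\n")
  invisible(x)
}

# Stacked (area-major, time-minor) vector of the direct estimates / variances.
panel_yvec <- function(panel) as.vector(t(panel$y))
panel_dvec <- function(panel) as.vector(t(panel$D))

#' Extract a single-period slice of a panel
#'
#' Returns the T = 1 `area_panel` for one period, used e.g. to fit the
#' classical Fay-Herriot or spatial Fay-Herriot model to the latest survey.
#'
#' @param panel an [area_panel()].
#' @param time a time label present in `panel$time_ids`, or an index if
#'   `index = TRUE`.
#' @param index interpret `time` as positional index.
#' @return an `area_panel` with T = 1.
#' @export
panel_slice <- function(panel, time, index = FALSE) {
  t_idx <- if (index) as.integer(time) else match(time, panel$time_ids)
  if (is.na(t_idx) || t_idx < 1 || t_idx > panel$T) {
    stfh_stop("unknown time label", "stfh_validation_error")
  }
  rows <- (seq_len(panel$m) - 1L) * panel$T + t_idx
  area_panel(panel$area_ids, panel$time_ids[t_idx],
             panel$y[, t_idx, drop = FALSE], panel$D[, t_idx, drop = FALSE],
             panel$X[rows, , drop = FALSE])
}
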