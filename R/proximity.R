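#' Row-standardized proximity matrix
#'
#' Wraps an m x m contiguity structure as the row-standardized weight matrix
#' W used by the simultaneous autoregressive (SAR) area effect. The raw
#' adjacency must be symmetric, nonnegative, hollow (zero diagonal) and have
#' no isolated area; rows are scaled to sum to one.
#'
#' The admissible interval for the SAR autocorrelation rho1, i.e. the set
#' where I - rho1 W is nonsingular, is precomputed from the extreme real
#' eigenvalues of W and stored as attribute `rho1_interval`:
#' (max(-0.999, 1/omega_min + 1e-6), 0.999) with omega_min the smallest real
#' eigenvalue. For a row-standardized W the largest eigenvalue is 1, so the
#' upper end 0.999 keeps I - rho1 W away from singularity.
#'
#' @param adjacency m x m symmetric nonnegative matrix (binary contiguity or
#'   any weights); the diagonal must be zero.
#' @param area_ids identifiers aligned with the rows, recycled to row names.
#' @return object of class `proximity_matrix`: the row-standardized matrix
#'   with attributes `area_ids`, `adjacency` and `rho1_interval`.
#' @export
proximity_matrix <- function(adjacency, area_ids = NULL) {
  A <- as.matrix(adjacency)
  m <- nrow(A)
  if (ncol(A) != m) stfh_stop("adjacency must be square", "stfh_validation_error")
  if (is.null(area_ids)) area_ids <- rownames(A) %||% paste0("A", seq_len(m))
  area_ids <- as.character(area_ids)
  if (length(area_ids) != m || anyDuplicated(area_ids)) {
    stfh_stop("area_ids must be m unique labels", "stfh_validation_error")
  }
  if (any(A < 0)) stfh_stop("adjacency must be nonnegative", "stfh_validation_error")
  if (any(diag(A) != 0)) {
    stfh_stop("adjacency diagonal must be zero", "stfh_validation_error")
  }
  if (max(abs(A - t(A))) > 1e-12) {
    stfh_stop("adjacency must be symmetric", "stfh_validation_error")
  }
  rs <- rowSums(A)
  if (any(rs == 0)) {
    stfh_stop(paste0("isolated area(s): ",
                     paste(area_ids[rs == 0], collapse = ", ")),
              "stfh_connectivity_error")
  }
  W <- A / rs
  dimnames(W) <- list(area_ids, area_ids)
  ev <- Re(eigen(W, only.values = TRUE)$values)
  lo <- max(-0.999, 1 / min(ev) + 1e-6)
  structure(W, class = c("proximity_matrix", "matrix"),
            area_ids = area_ids, adjacency = A,
            rho1_interval = c(lo, 0.999))
}

#' @export
as.matrix.proximity_matrix <- function(x, ...) {
  a <- unclass(x)
  attributes(a) <- list(dim = dim(x), dimnames = dimnames(x))
  a
}

#' @export
print.proximity_matrix <- function(x, ...) {
  iv <- attr(x, "rho1_interval")
  cat(sprintf("proximity_matrix: %d areas, rho1 admissible in (%.4f, %.4f)\n",
              nrow(x), iv[1], iv[2]))
  invisible(x)
}

rho1_interval <- function(W) {
  iv <- attr(W, "rho1_interval")
  if (is.null(iv)) {
    ev <- Re(eigen(unclass(as.matrix(W)), only.values = TRUE)$values)
    iv <- c(max(-0.999, 1 / min(ev) + 1e-6), 0.999)
  }
  iv
}

# Reorder a proximity matrix to match the panel's area order.
align_proximity <- function(W, area_ids) {
  ids <- attr(W, "area_ids")
  if (is.null(ids)) return(W)
  if (!setequal(ids, area_ids)) {
    stfh_stop("proximity and panel area ids differ", "stfh_validation_error")
  }
  if (identical(ids, as.character(area_ids))) return(W)
  idx <- match(as.character(area_ids), ids)
  proximity_matrix(attr(W, "adjacency")[idx, idx, drop = FALSE],
                   area_ids = area_ids)
}
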