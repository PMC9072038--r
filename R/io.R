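# Delimited-text I/O. Dialect: comma-separated, UTF-8, "." decimal, header
# mandatory; metadata travels in leading "#" comment lines. The "# created:"
# line is the only nondeterministic output and is excluded from
# byte-identity comparisons.

output_header <- function(seed = NULL, model = NULL, tau = NULL) {
  h <- c(sprintf("# stfh %s", as.character(utils::packageVersion("stfh"))),
         sprintf("# created: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  if (!is.null(seed)) h <- c(h, sprintf("# seed: %d", seed))
  if (!is.null(model)) h <- c(h, sprintf("# model: %s", model))
  if (!is.null(tau)) {
    h <- c(h, sprintf("# tau: sigma1_sq=%.10g rho1=%.10g sigma2_sq=%.10g rho2=%.10g",
                      tau$sigma1_sq, tau$rho1, tau$sigma2_sq, tau$rho2))
  }
  h
}

write_delim_with_header <- function(df, path, header) {
  # %.17g so numeric columns survive a write/read round trip bit-exactly
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
}

#' Read a panel file
#'
#' Expects a comma-separated file with header `area_id,time,y,var_y,x1,...`.
#' Rows may be in any order; the panel is put into canonical area-major /
#' time-minor order with times sorted increasingly. Duplicated or missing
#' (area, time) cells and nonpositive variances are rejected.
#'
#' @param path file path.
#' @return an [area_panel()].
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) {
    stfh_stop(paste0("panel file not found: ", path), "stfh_io_error")
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("area_id", "time", "y", "var_y")
  if (!all(need %in% names(df))) {
    stfh_stop(paste0("panel header must contain ", paste(need, collapse = ", ")),
              "stfh_io_error")
  }
  xcols <- setdiff(names(df), need)
  if (any(df$var_y <= 0 | !is.finite(df$var_y))) {
    bad <- which(df$var_y <= 0 | !is.finite(df$var_y))
    stfh_stop(paste0("var_y must be > 0; offending file row(s): ",
                     paste(bad, collapse = ", ")), "stfh_validation_error")
  }
  areas <- sort(unique(df$area_id))
  times <- sort(unique(df$time))
  key <- paste(df$area_id, df$time, sep = "\r")
  if (anyDuplicated(key)) {
    stfh_stop(paste0("duplicated (area, time) cell(s): ",
                     paste(unique(gsub("\r", ", ", key[duplicated(key)])),
                           collapse = "; ")), "stfh_validation_error")
  }
  full <- as.vector(outer(areas, times, paste, sep = "\r"))
  missing_cells <- setdiff(full, key)
  if (length(missing_cells)) {
    stfh_stop(paste0("panel is unbalanced; missing (area, time) pair(s): ",
                     paste(gsub("\r", ", ", missing_cells), collapse = "; ")),
              "stfh_balance_error")
  }
  idx <- match(full, key)  # canonical order: area-major, time-minor
  m <- length(areas); Tn <- length(times)
  # outer() runs area fastest within each time; rebuild area-major order
  ord <- as.vector(t(matrix(idx, m, Tn)))
  df <- df[ord, , drop = FALSE]
  y <- matrix(df$y, m, Tn, byrow = TRUE)
  D <- matrix(df$var_y, m, Tn, byrow = TRUE)
  X <- as.matrix(df[, xcols, drop = FALSE])
  if (length(xcols) == 0) {
    X <- matrix(1, m * Tn, 1, dimnames = list(NULL, "intercept"))
  }
  area_panel(areas, times, y, D, X)
}

#' Write a panel file
#'
#' @param panel an [area_panel()].
#' @param path destination.
#' @param seed optional seed recorded in the header.
#' @export
write_panel <- function(panel, path, seed = NULL) {
  df <- data.frame(area_id = rep(panel$area_ids, each = panel$T),
                   time = rep(panel$time_ids, panel$m),
                   y = panel_yvec(panel), var_y = panel_dvec(panel))
  df <- cbind(df, as.data.frame(panel$X))
  write_delim_with_header(df, path, output_header(seed = seed))
  invisible(path)
}

#' Read a proximity structure
#'
#' Two dialects, auto-detected from the header: a neighbor list with
#' columns `area_id,neighbor_id` (symmetrized with a warning if a pair is
#' listed one-way), or a dense matrix with area ids as header row and first
#' column. Both are row-standardized on load and aligned to `area_ids`.
#'
#' @param path file path.
#' @param area_ids panel area ids the matrix must cover.
#' @return a [proximity_matrix()].
#' @export
read_proximity <- function(path, area_ids) {
  if (!file.exists(path)) {
    stfh_stop(paste0("proximity file not found: ", path), "stfh_io_error")
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        check.names = FALSE)
  area_ids <- as.character(area_ids)
  m <- length(area_ids)
  if (identical(names(df), c("area_id", "neighbor_id"))) {
    unknown <- setdiff(unique(c(df$area_id, df$neighbor_id)), area_ids)
    if (length(unknown)) {
      stfh_stop(paste0("unknown area id(s) in neighbor list: ",
                       paste(unknown, collapse = ", ")), "stfh_io_error")
    }
    A <- matrix(0, m, m, dimnames = list(area_ids, area_ids))
    A[cbind(match(df$area_id, area_ids), match(df$neighbor_id, area_ids))] <- 1
    if (max(abs(A - t(A))) > 0) {
      stfh_warn("neighbor list not symmetric; symmetrizing",
                "stfh_symmetrize_warning")
      A <- pmax(A, t(A))
    }
  } else {
    first <- names(df)[1]
    ids <- as.character(df[[first]])
    A <- as.matrix(df[, -1, drop = FALSE])
    rownames(A) <- ids
    unknown <- setdiff(c(ids, colnames(A)), area_ids)
    if (length(unknown)) {
      stfh_stop(paste0("unknown area id(s) in proximity matrix: ",
                       paste(unknown, collapse = ", ")), "stfh_io_error")
    }
    if (!setequal(ids, area_ids) || !setequal(colnames(A), area_ids)) {
      stfh_stop("proximity matrix must cover every panel area", "stfh_io_error")
    }
    A <- A[match(area_ids, ids), match(area_ids, colnames(A)), drop = FALSE]
    if (max(abs(A - t(A))) > 1e-12) {
      stfh_warn("dense proximity not symmetric; symmetrizing",
                "stfh_symmetrize_warning")
      A <- pmax(A, t(A))
    }
  }
  proximity_matrix(A[area_ids, area_ids], area_ids)
}

#' Write a proximity structure
#'
#' @param W a [proximity_matrix()].
#' @param path destination.
#' @param format `"neighbor"` (edge list of the raw adjacency) or `"dense"`.
#' @export
write_proximity <- function(W, path, format = c("neighbor", "dense")) {
  format <- match.arg(format)
  ids <- attr(W, "area_ids")
  A <- attr(W, "adjacency")
  if (format == "neighbor") {
    edges <- which(A > 0, arr.ind = TRUE)
    df <- data.frame(area_id = ids[edges[, 1]],
                     neighbor_id = ids[edges[, 2]])
    df <- df[order(df$area_id, df$neighbor_id), ]
    write_delim_with_header(df, path, output_header())
  } else {
    df <- data.frame(area_id = ids, as.data.frame(A))
    names(df) <- c("area_id", ids)
    write_delim_with_header(df, path, output_header())
  }
  invisible(path)
}

#' Write a prediction set
#'
#' One row per (area, time) with the columns of [eblup()]; the header
#' records package version, seed, model tag and fitted tau.
#'
#' @param pred an `stfh_predictions` data frame.
#' @param path destination.
#' @param fit optional `stfh_fit` whose tau goes in the header.
#' @param seed optional seed recorded in the header.
#' @export
write_predictions <- function(pred, path, fit = NULL, seed = NULL) {
  hdr <- output_header(seed = seed %||% attr(pred, "seed"),
                       model = pred$model_tag[1],
                       tau = if (!is.null(fit)) fit$tau_hat)
  write_delim_with_header(as.data.frame(pred), path, hdr)
  invisible(path)
}

write_truth <- function(truth, path, area_ids, time_ids, seed = NULL) {
  m <- nrow(truth$theta); Tn <- ncol(truth$theta)
  df <- data.frame(area_id = rep(area_ids, each = Tn),
                   time = rep(time_ids, m),
                   theta = as.vector(t(truth$theta)),
                   nu1 = rep(truth$nu1, each = Tn),
                   nu2 = as.vector(t(truth$nu2)),
                   eps = as.vector(t(truth$eps)))
  write_delim_with_header(df, path, output_header(seed = seed))
  invisible(path)
}
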