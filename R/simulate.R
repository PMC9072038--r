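# Synthetic zone-by-year panels with the exact stochastic structure of the
# spatio-temporal model, with known truth: a contiguity graph, SAR(1) area
# effects, stationary AR(1) area-time effects, heteroscedastic Gaussian
# sampling errors with known variances, and time-constant covariates
# (emulating census auxiliaries held fixed across surveys).

#' Generate a proximity structure
#'
#' Builds a connected, symmetric contiguity graph and wraps it as a
#' row-standardized [proximity_matrix()]. Kinds: `"chain"` (path graph),
#' `"grid"` (rook contiguity on a rows x cols lattice), `"random_planar"`
#' (seeded random points in the unit square joined to their k nearest
#' neighbours, symmetrized, with components bridged by their closest pair —
#' an approximately planar stand-in for administrative-zone contiguity).
#'
#' @param kind graph kind.
#' @param m number of areas (`chain`, `random_planar`).
#' @param dims `c(rows, cols)` for `"grid"`.
#' @param k neighbours per point for `"random_planar"`, k < m.
#' @param seed integer seed (`random_planar`); the result is a pure function
#'   of `(kind, m/dims, k, seed)`.
#' @param area_ids optional labels (default "A01", "A02", ...).
#' @return a [proximity_matrix()].
#' @export
make_proximity <- function(kind = c("chain", "grid", "random_planar"),
                           m = NULL, dims = NULL, k = 4, seed = 1,
                           area_ids = NULL) {
  kind <- match.arg(kind)
  if (kind == "grid") {
    if (is.null(dims) || length(dims) != 2 || any(dims < 1)) {
      stfh_stop("grid needs dims = c(rows, cols) >= 1", "stfh_validation_error")
    }
    m <- prod(dims)
  }
  if (is.null(m) || m < 2) stfh_stop("need m >= 2 areas", "stfh_validation_error")
  m <- as.integer(m)
  A <- matrix(0, m, m)
  if (kind == "chain") {
    for (i in seq_len(m - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
  } else if (kind == "grid") {
    idx <- function(r, c) (r - 1) * dims[2] + c
    for (r in seq_len(dims[1])) for (c in seq_len(dims[2])) {
      if (c < dims[2]) A[idx(r, c), idx(r, c + 1)] <- A[idx(r, c + 1), idx(r, c)] <- 1
      if (r < dims[1]) A[idx(r, c), idx(r + 1, c)] <- A[idx(r + 1, c), idx(r, c)] <- 1
    }
  } else {
    if (k >= m) stfh_stop("need k < m", "stfh_validation_error")
    pts <- with_seed(mix_seed(seed, "points"),
                     matrix(stats::runif(2 * m), m, 2))
    dmat <- as.matrix(stats::dist(pts))
    for (i in seq_len(m)) {
      nb <- order(dmat[i, ])[2:(k + 1)]
      A[i, nb] <- A[nb, i] <- 1
    }
    # bridge disconnected components through their closest pair
    repeat {
      comp <- graph_components(A)
      if (max(comp) == 1) break
      in1 <- comp == 1
      sub <- dmat[in1, !in1, drop = FALSE]
      ij <- which(sub == min(sub), arr.ind = TRUE)[1, ]
      i <- which(in1)[ij[1]]; j <- which(!in1)[ij[2]]
      A[i, j] <- A[j, i] <- 1
    }
  }
  if (is.null(area_ids)) {
    area_ids <- sprintf(paste0("A%0", nchar(m), "d"), seq_len(m))
  }
  proximity_matrix(A, area_ids)
}

graph_components <- function(A) {
  m <- nrow(A)
  comp <- integer(m)
  cur <- 0L
  for (s in seq_len(m)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(A[v, ] > 0 & comp == 0)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Define a simulation scenario
#'
#' A fully stated data-generating world for [simulate_panel()]. The defaults
#' mirror the shape of a national survey-plus-census application: 83 areas
#' on a random contiguity graph, T = 4 survey rounds, p = 6 covariates
#' (intercept plus five time-constant uniform proportions), z-score-scale
#' sampling variances drawn once per cell from U(0.005, 0.05), and
#' covariance parameters near the strong-spatial / moderate-negative-
#' temporal regime (sigma1^2 small, rho1 large positive, rho2 negative).
#'
#' @param m,T,p panel dimensions (areas, periods, covariate columns
#'   including intercept).
#' @param graph list: `kind` as in [make_proximity()] plus its parameters,
#'   or `list(kind = "supplied")` with `W` passed here.
#' @param beta fixed-effect vector (default `c(-1, 0.5, ...)`, giving
#'   z-score-scale means).
#' @param tau a [variance_components()] object.
#' @param D_spec sampling-variance spec: `list(kind = "uniform", min, max)`,
#'   `list(kind = "constant", value)`, or `list(kind = "supplied")` with `D`.
#' @param X_spec covariate spec: `list(kind = "uniform", min, max)`
#'   (time-constant draws per area, plus intercept) or
#'   `list(kind = "supplied")` with `X`.
#' @param seed mandatory integer root seed.
#' @param W,X,D supplied objects when the corresponding spec is "supplied".
#' @return list of class `simulation_scenario`.
#' @export
simulation_scenario <- function(m = 83, T = 4, p = 6,
                                graph = list(kind = "random_planar",
                                             k = min(4L, m - 1L)),
                                beta = NULL,
                                tau = variance_components(0.001, 0.95,
                                                          0.01, -0.6),
                                D_spec = list(kind = "uniform",
                                              min = 0.005, max = 0.05),
                                X_spec = list(kind = "uniform",
                                              min = 0, max = 1),
                                seed, W = NULL, X = NULL, D = NULL) {
  if (missing(seed)) stfh_stop("seed is mandatory", "stfh_validation_error")
  if (is.null(beta)) beta <- c(-1, rep(0.5, p - 1))
  if (length(beta) != p) stfh_stop("beta must have length p", "stfh_validation_error")
  if (identical(D_spec$kind, "uniform") && D_spec$min <= 0) {
    stfh_stop("sampling variances must be positive: D_spec$min > 0",
              "stfh_validation_error")
  }
  structure(list(m = as.integer(m), T = as.integer(T), p = as.integer(p),
                 graph = graph, beta = beta, tau = tau, D_spec = D_spec,
                 X_spec = X_spec, seed = as.integer(seed),
                 W = W, X = X, D = D),
            class = "simulation_scenario")
}

#' Simulate a panel with known truth
#'
#' Draws one panel from the scenario's data-generating process:
#' nu1 ~ N(0, sigma1^2 Omega1(rho1)) via the symmetric matrix square root,
#' nu2 per area from the stationary AR(1) law (nu2_i1 ~ N(0,
#' sigma2^2/(1-rho2^2)), then the recursion), eps ~ N(0, diag(D)), and
#' y = X beta + nu1 + nu2 + eps. Every component draws from its own
#' sub-stream keyed by (seed, component, area id), so the generator is a
#' pure function of the scenario and toggling one component leaves the
#' others' draws unchanged.
#'
#' @param scenario a [simulation_scenario()].
#' @return list with `panel` ([area_panel()]), `truth` (class `stfh_truth`:
#'   `theta`, `nu1`, `nu2`, `eps`, `beta`, `tau`, `seed`) and `W`.
#' @export
simulate_panel <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  sc <- scenario
  m <- sc$m; Tn <- sc$T; p <- sc$p; seed <- sc$seed
  W <- if (identical(sc$graph$kind, "supplied")) {
    if (is.null(sc$W)) stfh_stop("graph kind 'supplied' needs W",
                                 "stfh_validation_error")
    sc$W
  } else {
    make_proximity(sc$graph$kind, m = m, dims = sc$graph$dims,
                   k = sc$graph$k %||% 4, seed = mix_seed(seed, "graph"))
  }
  ids <- attr(W, "area_ids")
  check_tau(sc$tau, W)

  X <- if (identical(sc$X_spec$kind, "supplied")) {
    as.matrix(sc$X)
  } else {
    lo <- sc$X_spec$min %||% 0; hi <- sc$X_spec$max %||% 1
    Xa <- do.call(rbind, lapply(ids, function(id)
      with_seed(mix_seed(seed, "X", id),
                matrix(stats::runif(p - 1, lo, hi), 1))))
    if (p == 1) Xa <- matrix(0, m, 0)
    Xs <- cbind(1, Xa)[rep(seq_len(m), each = Tn), , drop = FALSE]
    colnames(Xs) <- c("intercept", if (p > 1) paste0("x", seq_len(p - 1)))
    Xs
  }
  D <- switch(sc$D_spec$kind,
    supplied = as.matrix(sc$D),
    constant = matrix(sc$D_spec$value, m, Tn),
    uniform = t(vapply(ids, function(id)
      with_seed(mix_seed(seed, "D", id),
                stats::runif(Tn, sc$D_spec$min, sc$D_spec$max)),
      numeric(Tn))),
    stfh_stop("unknown D_spec kind", "stfh_validation_error"))
  D <- matrix(D, m, Tn)

  tau <- sc$tau
  nu1 <- if (tau$sigma1_sq > 0) {
    z <- vapply(ids, function(id)
      with_seed(mix_seed(seed, "nu1", id), stats::rnorm(1)), 0)
    drop(sym_sqrt(tau$sigma1_sq * build_omega1(tau$rho1, W)) %*% z)
  } else numeric(m)
  nu2 <- matrix(0, m, Tn)
  if (tau$sigma2_sq > 0) {
    sd_stat <- sqrt(tau$sigma2_sq / (1 - tau$rho2^2))
    for (i in seq_len(m)) {
      e <- with_seed(mix_seed(seed, "nu2", ids[i]), stats::rnorm(Tn))
      v <- numeric(Tn)
      v[1] <- sd_stat * e[1]
      if (Tn > 1) for (t in 2:Tn) {
        v[t] <- tau$rho2 * v[t - 1] + sqrt(tau$sigma2_sq) * e[t]
      }
      nu2[i, ] <- v
    }
  }
  eps <- matrix(0, m, Tn)
  for (i in seq_len(m)) {
    eps[i, ] <- with_seed(mix_seed(seed, "eps", ids[i]),
                          stats::rnorm(Tn)) * sqrt(D[i, ])
  }
  theta <- matrix(drop(X %*% sc$beta), m, Tn, byrow = TRUE) + nu1 + nu2
  y <- theta + eps
  panel <- area_panel(ids, seq_len(Tn), y, D, X)
  truth <- structure(list(theta = theta, nu1 = nu1, nu2 = nu2, eps = eps,
                          beta = sc$beta, tau = tau, seed = seed),
                     class = "stfh_truth")
  list(panel = panel, truth = truth, W = W)
}
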