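#' Number of NMF components for a given number of gases
#'
#' The scan matrix always contains two non-gas spectrum families — the sensor
#' baseline and the inter-sensor gap noise — so the factorization rank is the
#' number of gas types plus two: one gas gives rank 3, two gases rank 4.
#'
#' @param n_gas_types Non-negative integer count of distinct gases expected.
#' @return Integer rank `n_gas_types + 2`.
#' @export
choose_rank <- function(n_gas_types) {
  n_gas_types <- as.integer(n_gas_types)
  if (is.na(n_gas_types) || n_gas_types < 0L)
    stop("n_gas_types must be a non-negative integer", call. = FALSE)
  n_gas_types + 2L
}

#' Clip a matrix to non-negative entries
#'
#' NMF requires a non-negative input; baseline-subtracted or noisy scans can
#' dip below zero. Negatives are set to zero and the clipped fraction is
#' attached as attribute `"clipped_fraction"`.
#'
#' @param V Numeric matrix with finite entries.
#' @return The clipped matrix.
#' @export
clip_nonnegative <- function(V) {
  V <- as.matrix(V)
  if (any(is.na(V)) || !all(is.finite(V)))
    stop("matrix entries must be finite (no NaN/NA)", call. = FALSE)
  frac <- mean(V < 0)
  V[V < 0] <- 0
  attr(V, "clipped_fraction") <- frac
  V
}

#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorizes a non-negative scan matrix `V` (n points x m channels) as
#' `V ~ W H` with `W` (n x r) the per-position component concentrations and
#' `H` (r x m) the component feature spectra, by minimizing the Frobenius
#' reconstruction error with the classical multiplicative updates
#' \deqn{H \leftarrow H \odot \frac{W^T V}{W^T W H + \delta}, \qquad
#'       W \leftarrow W \odot \frac{V H^T}{W H H^T + \delta}}
#' with denominator guard `delta = 1e-12`. Factors are initialized from a
#' seeded uniform draw in (0, 1] scaled by `sqrt(mean(V) / r)`, so runs are
#' deterministic given `seed`. Iteration stops when the relative decrease of
#' the objective falls below `tol` or after `max_iter` updates.
#'
#' Because multiplicative updates converge to local optima that depend on the
#' initialization, `n_init > 1` runs the factorization from `n_init`
#' consecutive seeds (`seed`, `seed + 1`, ...) and keeps the solution with the
#' lowest final objective — the usual guard against poorly mixed components.
#'
#' @param V Non-negative numeric matrix, or a [hyperspectral_scan()] (its `V`
#'   is used).
#' @param r Factorization rank, `1 <= r <= min(n, m)`.
#' @param seed RNG seed for the initialization (default 42).
#' @param max_iter Maximum number of update sweeps (default 2000).
#' @param tol Relative objective-change tolerance (default 1e-6).
#' @param n_init Number of seeded restarts; the best (lowest final objective)
#'   factorization is returned (default 1).
#' @return An object of class `unmixing_result` with elements `W`, `H`, `r`,
#'   `objective_trace` (Frobenius error per iteration, non-increasing),
#'   `iterations`, `converged`, `seed` (the winning seed).
#' @export
nmf <- function(V, r, seed = 42L, max_iter = 2000L, tol = 1e-6, n_init = 1L) {
  if (n_init > 1L) {
    runs <- lapply(seq_len(n_init) - 1L, function(k)
      nmf(V, r, seed = seed + k, max_iter = max_iter, tol = tol))
    finals <- vapply(runs, function(x)
      x$objective_trace[length(x$objective_trace)], numeric(1))
    return(runs[[which.min(finals)]])
  }
  if (inherits(V, "hyperspectral_scan")) V <- V$V
  V <- as.matrix(V)
  if (any(is.na(V)) || !all(is.finite(V)))
    stop("V must have finite entries", call. = FALSE)
  if (any(V < 0))
    stop("V must be non-negative; see clip_nonnegative()", call. = FALSE)
  n <- nrow(V); m <- ncol(V)
  r <- as.integer(r)
  if (r < 1L || r > min(n, m))
    stop(sprintf("rank r must satisfy 1 <= r <= min(n, m) = %d", min(n, m)),
         call. = FALSE)
  delta <- 1e-12
  set.seed(seed)
  scale <- sqrt(max(mean(V), delta) / r)
  W <- matrix(stats::runif(n * r, min = .Machine$double.eps, max = 1), n, r) * scale
  H <- matrix(stats::runif(r * m, min = .Machine$double.eps, max = 1), r, m) * scale

  obj <- numeric(max_iter)
  prev <- sqrt(sum((V - W %*% H)^2))
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    H <- H * (crossprod(W, V)) / (crossprod(W, W) %*% H + delta)
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H, H) + delta)
    obj[it] <- sqrt(sum((V - W %*% H)^2))
    if (prev > 0 && (prev - obj[it]) / prev < tol) {
      converged <- TRUE
      break
    }
    prev <- obj[it]
  }
  structure(list(W = W, H = H, r = r, objective_trace = obj[seq_len(it)],
                 iterations = it, converged = converged, seed = seed),
            class = "unmixing_result")
}

#' @export
print.unmixing_result <- function(x, ...) {
  cat(sprintf("<unmixing_result> r = %d, %d x %d, %d iterations%s, final error %.6g\n",
              x$r, nrow(x$W), ncol(x$H), x$iterations,
              if (x$converged) " (converged)" else "",
              x$objective_trace[length(x$objective_trace)]))
  invisible(x)
}

#' Normalize and order NMF components
#'
#' Rescales each feature spectrum (row of `H`) to unit maximum and applies the
#' inverse scale to the matching concentration column of `W`, leaving the
#' product `W H` unchanged, then reorders components by descending total
#' concentration (column sums of `W`) so the dominant gas is component 1.
#' All-zero components are left unscaled and flagged in attribute
#' `"zero_components"`.
#'
#' @param result An `unmixing_result` from [nmf()].
#' @return The normalized, reordered `unmixing_result`.
#' @export
normalize_components <- function(result) {
  stopifnot(inherits(result, "unmixing_result"))
  W <- result$W; H <- result$H
  zero <- integer(0)
  for (i in seq_len(result$r)) {
    s <- max(H[i, ])
    if (s > 0) {
      H[i, ] <- H[i, ] / s
      W[, i] <- W[, i] * s
    } else {
      zero <- c(zero, i)
    }
  }
  ord <- order(colSums(W), decreasing = TRUE)
  result$W <- W[, ord, drop = FALSE]
  result$H <- H[ord, , drop = FALSE]
  attr(result, "zero_components") <- match(zero, ord)
  result
}

#' Assign NMF components to gases by spectral correlation
#'
#' Each feature spectrum (row of `H`) is compared to each reference gas
#' signature by Pearson correlation. Assignment is greedy by decreasing
#' correlation (ties toward the lower component index) and injective over
#' gases: at most one component per gas. Components whose best available
#' correlation falls below `threshold` are labeled `"interference"`.
#'
#' @param H Feature matrix (r x m), or an `unmixing_result`.
#' @param signatures Named list of [gas_signature()] references.
#' @param axis [wavenumber_axis()] matching the columns of `H`.
#' @param threshold Minimum correlation to call a gas (default 0.8).
#' @param lineshape Passed to [signature_spectrum()].
#' @return Character vector, one entry per component: a gas name or
#'   `"interference"`; correlations in attribute `"correlation"`.
#' @export
match_components <- function(H, signatures, axis, threshold = 0.8,
                             lineshape = "lorentzian") {
  if (inherits(H, "unmixing_result")) H <- H$H
  H <- as.matrix(H)
  if (nrow(H) < 1L) stop("empty feature matrix", call. = FALSE)
  if (ncol(H) != length(axis))
    stop("H columns must match the axis length", call. = FALSE)
  refs <- vapply(signatures, signature_spectrum, numeric(length(axis)),
                 axis = axis, lineshape = lineshape)
  cors <- matrix(-Inf, nrow(H), length(signatures),
                 dimnames = list(NULL, names(signatures)))
  for (i in seq_len(nrow(H))) {
    if (stats::sd(H[i, ]) == 0) next
    cors[i, ] <- apply(refs, 2, function(ref) stats::cor(H[i, ], ref))
  }
  assign <- rep("interference", nrow(H))
  cand <- expand.grid(comp = seq_len(nrow(H)), gas = seq_along(signatures))
  cand$cor <- cors[cbind(cand$comp, cand$gas)]
  cand <- cand[is.finite(cand$cor) & cand$cor >= threshold, , drop = FALSE]
  cand <- cand[order(-cand$cor, cand$comp), , drop = FALSE]
  used_gas <- logical(length(signatures))
  for (j in seq_len(nrow(cand))) {
    ci <- cand$comp[j]; gi <- cand$gas[j]
    if (assign[ci] == "interference" && !used_gas[gi]) {
      assign[ci] <- names(signatures)[gi]
      used_gas[gi] <- TRUE
    }
  }
  attr(assign, "correlation") <- cors
  assign
}
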