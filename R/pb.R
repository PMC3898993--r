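#' Parameters of the Peyrard-Bishop chain
#'
#' The promoter is modelled as a 1D lattice of base pairs. Each site `n`
#' carries one degree of freedom `y_n`, the stretching of the hydrogen bonds
#' of that base pair. The potential energy is
#'
#' \deqn{V(y) = \sum_{n=2}^{L} \frac{k}{2}\left(1 + \rho\,
#'   e^{-\alpha (y_n + y_{n-1})}\right) (y_n - y_{n-1})^2 +
#'   \sum_{n=1}^{L} D_n \left(e^{-a_n y_n} - 1\right)^2,}
#'
#' with a Morse on-site term whose depth/width `(D_n, a_n)` depend on the
#' weak (A:T) or strong (C:G) character of the base pair, and an
#' anharmonic stacking interaction between neighbours. The strong Morse
#' depth is 1.5x the weak one (three vs two hydrogen bonds).
#'
#' Defaults are the Campa-Giansanti phenomenological set. Note that the
#' stacking anharmonicity decay `alpha` multiplies terms that vanish in the
#' ground state `y = 0` and therefore never enters the harmonic Hessian; it
#' is kept for evaluating the full potential.
#'
#' @param k stacking stiffness, eV/A^2.
#' @param rho dimensionless stacking anharmonicity amplitude.
#' @param alpha stacking decay constant, 1/A.
#' @param D_W,D_S Morse depths (eV) for weak and strong pairs.
#' @param a_W,a_S Morse inverse widths (1/A).
#' @return list of class `pb_params`.
#' @export
pb_params <- function(k = 0.025, rho = 2, alpha = 0.35,
                      D_W = 0.05, D_S = 0.075, a_W = 4.2, a_S = 6.9) {
  p <- list(k = k, rho = rho, alpha = alpha,
            D_W = D_W, D_S = D_S, a_W = a_W, a_S = a_S)
  if (any(unlist(p) <= 0)) stop("all Peyrard-Bishop parameters must be positive")
  if (abs(D_S - 1.5 * D_W) > 1e-12 * max(D_S, 1))
    warning("D_S is conventionally 1.5 * D_W (got D_S = ", D_S,
            ", D_W = ", D_W, ")")
  class(p) <- "pb_params"
  p
}

.ws_vector <- function(x) {
  x <- toupper(x)
  letters_x <- strsplit(x, "")[[1]]
  if (all(letters_x %in% c("W", "S"))) return(letters_x)
  strsplit(encode_ws(x), "")[[1]]
}

#' Full Peyrard-Bishop potential energy
#'
#' Evaluates the untruncated potential of [pb_params()] at displacement
#' vector `y`. Used chiefly as the independent oracle for the analytic
#' Hessian (finite differences at `y = 0`).
#'
#' @param y numeric displacement vector, length `L`.
#' @param code W/S string (or DNA string, encoded on the fly) of length `L`.
#' @param params [pb_params()] object.
#' @return scalar potential energy (eV).
#' @export
pb_potential <- function(y, code, params = pb_params()) {
  ws <- .ws_vector(code)
  L <- length(ws)
  stopifnot(length(y) == L)
  D <- ifelse(ws == "W", params$D_W, params$D_S)
  a <- ifelse(ws == "W", params$a_W, params$a_S)
  morse <- sum(D * (exp(-a * y) - 1)^2)
  if (L < 2) return(morse)
  dy <- diff(y)
  stack <- sum(params$k / 2 *
                 (1 + params$rho * exp(-params$alpha * (y[-1] + y[-L]))) * dy^2)
  morse + stack
}

#' Harmonic Hessian of the Peyrard-Bishop chain
#'
#' Second derivatives of the potential at the ground state `y = 0`. The
#' result is symmetric tridiagonal: off-diagonal entries are
#' `-k (1 + rho)` for adjacent sites and the diagonal entry at site `n` is
#' `(number of neighbours) * k (1 + rho) + 2 D_n a_n^2`.
#'
#' @inheritParams pb_potential
#' @return `L x L` symmetric matrix.
#' @export
build_hessian <- function(code, params = pb_params()) {
  ws <- .ws_vector(code)
  L <- length(ws)
  if (L < 2) stop("chain must have at least 2 sites")
  D <- ifelse(ws == "W", params$D_W, params$D_S)
  a <- ifelse(ws == "W", params$a_W, params$a_S)
  kp <- params$k * (1 + params$rho)
  nb <- c(1, rep(2, L - 2), 1)
  H <- diag(nb * kp + 2 * D * a^2)
  idx <- seq_len(L - 1)
  H[cbind(idx, idx + 1)] <- -kp
  H[cbind(idx + 1, idx)] <- -kp
  H
}

#' Normal-mode spectrum of a promoter chain
#'
#' Builds the harmonic Hessian for the W/S encoding of `x` and solves the
#' full symmetric eigenproblem. Eigenvalues are returned ascending with
#' orthonormal eigenvectors as columns; each eigenvector is given the
#' deterministic sign that makes its largest-magnitude component positive.
#'
#' @param x DNA string or W/S string.
#' @param params [pb_params()] object.
#' @return object of class `pb_spectrum`: list with elements `values`
#'   (ascending eigenvalues), `vectors` (L x L orthonormal columns), `code`
#'   (W/S string), `sequence` (the DNA string if one was supplied, else
#'   `NA`), `L`, and `params`.
#' @export
pb_spectrum <- function(x, params = pb_params()) {
  is_dna <- !all(strsplit(toupper(x), "")[[1]] %in% c("W", "S"))
  H <- build_hessian(x, params)
  ei <- tryCatch(eigen(H, symmetric = TRUE),
                 error = function(e) stop("eigendecomposition failed for chain of length ",
                                          nrow(H), ": ", conditionMessage(e)))
  L <- nrow(H)
  ord <- L:1  # eigen() returns descending
  vals <- ei$values[ord]
  vecs <- ei$vectors[, ord, drop = FALSE]
  # deterministic sign: largest-magnitude component positive
  for (j in seq_len(L)) {
    i0 <- which.max(abs(vecs[, j]))
    if (vecs[i0, j] < 0) vecs[, j] <- -vecs[, j]
  }
  structure(list(values = vals, vectors = vecs,
                 code = if (is_dna) encode_ws(x) else toupper(x),
                 sequence = if (is_dna) toupper(x) else NA_character_,
                 L = L, params = params),
            class = "pb_spectrum")
}

#' @export
print.pb_spectrum <- function(x, ...) {
  cat("Peyrard-Bishop harmonic spectrum\n")
  cat("  chain length:", x$L, "\n")
  cat("  eigenvalue range: [", format(min(x$values), digits = 6), ", ",
      format(max(x$values), digits = 6), "] eV/A^2\n", sep = "")
  invisible(x)
}

#' Localization indicators of chain eigenvectors
#'
#' For each unit-norm eigenvector `v` the following are computed:
#' * participation number `P = 1 / sum(v^4)` -- the effective number of
#'   sites the mode occupies (1 for a single-site mode, `L` for the uniform
#'   mode);
#' * center of mass `n_cm = sum(n * v_n^2)`;
#' * boundary sites `s`, `e` of the region the mode overlies: `s` is the
#'   largest site with cumulative probability mass at most `eps` from the
#'   left, `e` the smallest site with tail mass at most `eps` from the
#'   right (so the interval includes the crossing site on each side; the
#'   interior `s+1 .. e-1` carries all but at most `2 eps` of the mass);
#' * extension `ext`: distance between the first and last component whose
#'   magnitude exceeds `delta`, plus one. Extension and participation
#'   number are deliberately different measures: a mode with large
#'   components on a few distant sites and tiny components in between has
#'   small `P` but large `ext`.
#'
#' @param spectrum a `pb_spectrum`, or a numeric matrix whose columns are
#'   unit-norm vectors.
#' @param eps tail probability threshold for the boundary sites.
#' @param delta component-magnitude threshold for the extension.
#' @return data.frame with one row per mode: `mode`, `lambda` (NA when a
#'   bare matrix was supplied), `P`, `n_cm`, `s`, `e`, `ext`.
#' @export
eigenvector_indicators <- function(spectrum, eps = 0.01, delta = 1e-4) {
  if (inherits(spectrum, "pb_spectrum")) {
    V <- spectrum$vectors
    lambda <- spectrum$values
  } else {
    V <- as.matrix(spectrum)
    lambda <- rep(NA_real_, ncol(V))
  }
  nrm <- sqrt(colSums(V^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop("eigenvectors must be normalized to unit norm")
  L <- nrow(V)
  v2 <- V^2
  P <- 1 / colSums(V^4)
  n_cm <- colSums(seq_len(L) * v2)
  cs <- apply(v2, 2, cumsum)
  s <- apply(cs, 2, function(x) { w <- which(x <= eps); if (length(w)) max(w) else 1L })
  tl <- apply(v2[L:1, , drop = FALSE], 2, cumsum)[L:1, , drop = FALSE]
  e <- apply(tl, 2, function(x) { w <- which(x <= eps); if (length(w)) min(w) else L })
  big <- abs(V) > delta
  ext <- apply(big, 2, function(b) {
    w <- which(b)
    if (!length(w)) return(0L)
    w[length(w)] - w[1] + 1L
  })
  data.frame(mode = seq_len(ncol(V)), lambda = lambda, P = P, n_cm = n_cm,
             s = s, e = e, ext = ext, row.names = NULL)
}
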