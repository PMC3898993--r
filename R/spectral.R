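#' Threshold a similarity matrix into a weighted adjacency matrix
#'
#' Entries at or below the threshold are zeroed (two promoters are
#' connected only if they align better than the reshuffling null); the
#' diagonal is zeroed; retained weights are rescaled into `(0, 1]`.
#'
#' @param S symmetric similarity matrix (see [similarity_matrix()]).
#' @param theta threshold, typically from [null_threshold()].
#' @param normalization `"max"` (divide by the largest retained
#'   off-diagonal score, the default), `"minself"` (divide by the smallest
#'   self-alignment score) or `"none"`.
#' @return list of class `adjacency`: `W` (weighted adjacency with zero
#'   diagonal), `theta`, `normalization`, `isolated` (ids with no edge).
#' @export
build_adjacency <- function(S, theta,
                            normalization = c("max", "minself", "none")) {
  normalization <- match.arg(normalization)
  if (is.na(theta) || theta == Inf) stop("theta must not be NA or +Inf")
  W <- as.matrix(S)
  diag(W) <- 0
  W[W <= theta] <- 0
  if (all(W == 0)) stop("empty graph: every score is at or below theta")
  scale <- switch(normalization,
                  max = max(W),
                  minself = min(diag(as.matrix(S))),
                  none = 1)
  W <- W / scale
  iso <- rownames(W)[rowSums(W) == 0]
  structure(list(W = W, theta = theta, normalization = normalization,
                 isolated = iso),
            class = "adjacency")
}

#' Spectrum of the symmetric normalized Laplacian
#'
#' Computes the eigendecomposition of `L_sym = I - D^(-1/2) W D^(-1/2)`
#' where `D` is the diagonal degree matrix. Isolated nodes must be removed
#' first (their degree is zero). All eigenvalues lie in `[0, 2]`; the
#' multiplicity of the null eigenvalue equals the number of connected
#' components of the graph.
#'
#' @param adj an `adjacency` object from [build_adjacency()], or a bare
#'   symmetric non-negative matrix.
#' @return list of class `laplacian_spectrum`: ascending `values`,
#'   orthonormal `vectors` (columns, same order), `degree`, `ids`.
#' @export
laplacian_spectrum <- function(adj) {
  W <- if (inherits(adj, "adjacency")) adj$W else as.matrix(adj)
  deg <- rowSums(W)
  if (any(deg == 0))
    stop("zero-degree node(s): remove isolated nodes before the Laplacian ",
         "(", paste(utils::head(rownames(W)[deg == 0], 5), collapse = ", "), ")")
  dinv <- 1 / sqrt(deg)
  Lsym <- diag(nrow(W)) - (dinv %o% dinv) * W
  ei <- eigen(Lsym, symmetric = TRUE)
  n <- nrow(W)
  structure(list(values = ei$values[n:1],
                 vectors = ei$vectors[, n:1, drop = FALSE],
                 degree = deg, ids = rownames(W)),
            class = "laplacian_spectrum")
}

#' Choose the number of clusters by the eigengap heuristic
#'
#' If the graph consisted of `K` well-separated blocks, the first `K`
#' eigenvalues of the normalized Laplacian would sit near zero and the
#' `(K+1)`-th would jump away. `K` is chosen as the position of the largest
#' gap `lambda_(k+1) - lambda_k` among the first `k_max` eigenvalues; ties
#' go to the smaller `K`.
#'
#' @param spectrum a `laplacian_spectrum`, or a numeric vector of ascending
#'   eigenvalues.
#' @param k_max largest number of clusters considered (default 15).
#' @return list: `K`, and `gaps` (the full gap profile for diagnostics).
#' @export
eigengap_k <- function(spectrum, k_max = 15) {
  ev <- if (inherits(spectrum, "laplacian_spectrum")) spectrum$values else
    as.numeric(spectrum)
  k_max <- min(k_max, length(ev) - 1)
  if (k_max < 1) stop("need at least 2 eigenvalues")
  gaps <- diff(ev)[seq_len(k_max)]
  # ties (within numerical noise) break toward the smaller K
  K <- which(gaps >= max(gaps) - 1e-12)[1]
  list(K = as.integer(K), gaps = gaps)
}

# plain Lloyd k-means with centroid-movement tolerance and restarts
.lloyd_kmeans <- function(X, K, tol = 1e-6, max_iter = 200L) {
  n <- nrow(X)
  centers <- X[sample.int(n, K), , drop = FALSE]
  assign <- integer(n)
  for (it in seq_len(max_iter)) {
    d2 <- outer(rowSums(X^2), rowSums(centers^2), "+") - 2 * X %*% t(centers)
    assign <- max.col(-d2, ties.method = "first")
    newc <- centers
    for (k in seq_len(K)) {
      idx <- assign == k
      if (any(idx)) newc[k, ] <- colMeans(X[idx, , drop = FALSE])
      else newc[k, ] <- X[sample.int(n, 1), ]  # re-seed empty cluster
    }
    moved <- max(sqrt(rowSums((newc - centers)^2)))
    centers <- newc
    if (moved <= tol) break
  }
  d2 <- outer(rowSums(X^2), rowSums(centers^2), "+") - 2 * X %*% t(centers)
  inertia <- sum(d2[cbind(seq_len(n), assign)])
  list(assign = assign, centers = centers, inertia = inertia)
}

#' Cluster promoters on the spectral embedding
#'
#' Takes the first `K` eigenvectors of the normalized Laplacian as columns,
#' normalizes each row to unit norm, and runs k-means (Lloyd iterations
#' stopped when the centroids move less than `tol`, with `restarts` random
#' initializations; the solution with the lowest within-cluster inertia is
#' kept). Deterministic for a fixed `seed`.
#'
#' @param spectrum a `laplacian_spectrum`.
#' @param K number of clusters.
#' @param seed integer seed.
#' @param tol centroid-movement stopping tolerance.
#' @param restarts number of random initializations.
#' @return list of class `cluster_assignment`: `K`, `labels` (named integer
#'   vector), `embedding` (the row-normalized matrix `T`), `centroids`,
#'   `inertia`, `unassigned` (ids whose embedding row was zero).
#' @export
spectral_kmeans <- function(spectrum, K, seed = 0L, tol = 1e-6,
                            restarts = 50L) {
  stopifnot(inherits(spectrum, "laplacian_spectrum"), K >= 1)
  U <- spectrum$vectors[, seq_len(K), drop = FALSE]
  nrm <- sqrt(rowSums(U^2))
  zero <- nrm < .Machine$double.eps
  Tm <- U
  Tm[!zero, ] <- U[!zero, , drop = FALSE] / nrm[!zero]
  ids <- if (is.null(spectrum$ids)) as.character(seq_len(nrow(U))) else spectrum$ids
  X <- Tm[!zero, , drop = FALSE]
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- .lloyd_kmeans(X, K, tol = tol)
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  labels <- rep(NA_integer_, nrow(U))
  labels[!zero] <- best$assign
  names(labels) <- ids
  structure(list(K = K, labels = labels, embedding = Tm,
                 centroids = best$centers, inertia = best$inertia,
                 unassigned = ids[zero]),
            class = "cluster_assignment")
}

#' Full spectral clustering of a promoter set
#'
#' Convenience wrapper chaining [similarity_matrix()], [null_threshold()],
#' [build_adjacency()], [laplacian_spectrum()], [eigengap_k()] and
#' [spectral_kmeans()]. Isolated nodes (no edge above the threshold) are
#' excluded from the Laplacian and reported as unassigned (`NA` label).
#'
#' @param records named character vector of promoters.
#' @param scheme a [scoring_scheme()].
#' @param k_max,seed,tol,restarts see the respective steps.
#' @param K fixed number of clusters; `NULL` (default) selects by eigengap.
#' @param normalization passed to [build_adjacency()].
#' @param null_replicates reshuffle replicates for the threshold.
#' @param verbose progress messages.
#' @return list of class `promoter_clustering`: `labels` (named vector over
#'   all input promoters, `NA` for isolated ones), `K`, `theta`,
#'   `eigenvalues`, `gaps`, `assignment` (the `cluster_assignment`),
#'   `adjacency`, `similarity`.
#' @export
cluster_promoters <- function(records, scheme = scoring_scheme(),
                              k_max = 15, seed = 0L, tol = 1e-6,
                              restarts = 50L, K = NULL,
                              normalization = "max", null_replicates = 1L,
                              verbose = FALSE) {
  records <- as_promoters(records, allow_n = FALSE)
  if (verbose) message("aligning ", length(records), " promoters all-vs-all")
  S <- similarity_matrix(records, scheme, verbose = verbose)
  theta <- null_threshold(records, scheme, seed = seed + 1000L,
                          replicates = null_replicates)
  if (verbose) message("null threshold theta = ", format(theta, digits = 5))
  adj <- build_adjacency(S, theta, normalization = normalization)
  keep <- setdiff(rownames(adj$W), adj$isolated)
  Wk <- adj$W[keep, keep, drop = FALSE]
  spec <- laplacian_spectrum(Wk)
  eg <- eigengap_k(spec, k_max = k_max)
  if (is.null(K)) K <- eg$K
  asg <- spectral_kmeans(spec, K, seed = seed, tol = tol, restarts = restarts)
  labels <- rep(NA_integer_, length(records))
  names(labels) <- names(records)
  labels[names(asg$labels)] <- asg$labels
  structure(list(labels = labels, K = K, theta = theta,
                 eigenvalues = spec$values, gaps = eg$gaps,
                 assignment = asg, adjacency = adj, similarity = S),
            class = "promoter_clustering")
}

#' @export
print.promoter_clustering <- function(x, ...) {
  cat("promoter clustering: K =", x$K, "\n")
  cat("  theta =", format(x$theta, digits = 5),
      "; isolated:", sum(is.na(x$labels)), "\n")
  print(table(x$labels, useNA = "ifany"))
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement of two labelings; 1 for identical partitions
#' (up to relabeling), ~0 for independent ones. Pairs with `NA` in either
#' labeling are dropped.
#'
#' @param a,b label vectors of equal length.
#' @return scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  keep <- !(is.na(a) | is.na(b))
  a <- a[keep]; b <- b[keep]
  tab <- table(a, b)
  comb2 <- function(x) sum(choose(x, 2))
  sij <- comb2(c(tab))
  si <- comb2(rowSums(tab))
  sj <- comb2(colSums(tab))
  n2 <- choose(sum(tab), 2)
  expected <- si * sj / n2
  denom <- (si + sj) / 2 - expected
  if (denom == 0) return(1)
  (sij - expected) / denom
}
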