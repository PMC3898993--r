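# Independent oracles. These deliberately avoid the package's own code
# paths: alignment scores come from exhaustive enumeration of alignment
# paths, Hessians from finite differences of the full potential, uniform
# chain eigenvalues from the closed-form dispersion relation.

rand_dna <- function(L, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = prob),
        collapse = "")
}

# --- exhaustive alignment enumeration ------------------------------------

# all monotone edit paths from (0,0) to (la,lb); ops: D diag, U gap-in-b
# (consumes a), L gap-in-a (consumes b)
.enum_paths <- function(la, lb) {
  rec <- function(i, j) {
    if (i == la && j == lb) return(list(character(0)))
    out <- list()
    if (i < la && j < lb)
      for (p in rec(i + 1, j + 1)) out[[length(out) + 1]] <- c("D", p)
    if (i < la)
      for (p in rec(i + 1, j)) out[[length(out) + 1]] <- c("U", p)
    if (j < lb)
      for (p in rec(i, j + 1)) out[[length(out) + 1]] <- c("L", p)
    out
  }
  rec(0, 0)
}

.score_path <- function(ops, av, bv, match, mismatch, gap_open, gap_extend,
                        end_free) {
  score <- 0
  i <- 0L; j <- 0L
  t <- 1L
  n <- length(ops)
  while (t <= n) {
    if (ops[t] == "D") {
      i <- i + 1L; j <- j + 1L
      score <- score + if (av[i] == bv[j]) match else mismatch
      t <- t + 1L
    } else {
      op <- ops[t]
      t0 <- t
      while (t <= n && ops[t] == op) t <- t + 1L
      len <- t - t0
      if (op == "U") i <- i + len else j <- j + len
      # semiglobal free end gaps: only the runs lying on the border of the
      # DP matrix (the very first and very last run of the path) are free
      terminal <- (t0 == 1L) || (t - 1L == n)
      if (!(end_free && terminal))
        score <- score - (gap_open + len * gap_extend)
    }
  }
  score
}

# maximum alignment score by enumeration; mode "global" (optionally with
# free end gaps) or "local" (best substring pair, clamped at 0)
enum_align <- function(a, b, mode = "global", gap_open = 20,
                       gap_extend = 0.5, end_free = TRUE,
                       match = 5, mismatch = -4) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  if (mode == "global") {
    paths <- .enum_paths(length(av), length(bv))
    return(max(vapply(paths, .score_path, numeric(1), av = av, bv = bv,
                      match = match, mismatch = mismatch,
                      gap_open = gap_open, gap_extend = gap_extend,
                      end_free = end_free)))
  }
  # local: best global (no free ends) over all non-empty substring pairs
  best <- 0
  la <- length(av); lb <- length(bv)
  for (i1 in 1:la) for (i2 in i1:la) for (j1 in 1:lb) for (j2 in j1:lb) {
    s <- enum_align(paste(av[i1:i2], collapse = ""),
                    paste(bv[j1:j2], collapse = ""),
                    mode = "global", gap_open = gap_open,
                    gap_extend = gap_extend, end_free = FALSE,
                    match = match, mismatch = mismatch)
    if (s > best) best <- s
  }
  best
}

# --- finite-difference Hessian of the full potential ---------------------

fd_hessian_h <- function(code, params, h) {
  L <- nchar(code)
  H <- matrix(0, L, L)
  ei <- function(i) { y <- numeric(L); y[i] <- h; y }
  for (i in 1:L) for (j in i:L) {
    vpp <- pb_potential(ei(i) + ei(j), code, params)
    vpm <- pb_potential(ei(i) - ei(j), code, params)
    vmp <- pb_potential(-ei(i) + ei(j), code, params)
    vmm <- pb_potential(-ei(i) - ei(j), code, params)
    H[i, j] <- H[j, i] <- (vpp - vpm - vmp + vmm) / (4 * h^2)
  }
  H
}

# central differences with one Richardson extrapolation step (the O(h^2)
# truncation term cancels, leaving O(h^4))
fd_hessian <- function(code, params = pb_params(), h = 1e-4) {
  (4 * fd_hessian_h(code, params, h / 2) - fd_hessian_h(code, params, h)) / 3
}

# --- uniform free-ended chain: closed-form dispersion --------------------

uniform_chain_eigenvalues <- function(L, letter = "W", params = pb_params()) {
  D <- if (letter == "W") params$D_W else params$D_S
  a <- if (letter == "W") params$a_W else params$a_S
  kp <- params$k * (1 + params$rho)
  m <- 0:(L - 1)
  sort(2 * D * a^2 + 2 * kp * (1 - cos(m * pi / L)))
}
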