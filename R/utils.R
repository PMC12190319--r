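# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministic 31-bit hash of a master seed plus arbitrary labels, so that
# per-subject / per-recording seeds are reproducible piecewise: regenerating
# one subject of a cohort gives bit-identical data to generating the whole
# cohort. Plain polynomial rolling hash over the label characters.
derive_seed <- function(master_seed, ...) {
  m <- 2147483647
  h <- as.numeric(master_seed) %% m
  labels <- paste(vapply(list(...), function(x) paste(format(x), collapse = "|"),
                         character(1)), collapse = "/")
  for (code in utf8ToInt(labels)) h <- (h * 31 + code) %% m
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) < 1 || any(!is.finite(x)) || any(x <= 0))
    stopf("`%s` must be positive and finite", name)
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || length(x) < 1 || any(!is.finite(x)) || any(x < 0))
    stopf("`%s` must be non-negative and finite", name)
  invisible(x)
}

# Dense 1-D Gaussian smoothing operator of size n with edge renormalisation
# (kernel truncated at the borders and re-scaled so constants are preserved).
gauss_operator <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(-r:r, sd = sigma)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- pmax(1L, i - r):pmin(n, i + r)
    w <- k[j - i + r + 1L]
    K[i, j] <- w / sum(w)
  }
  K
}

# Separable Gaussian smoothing of a 2-D or 3-D array (spatial axes only).
gauss_smooth_array <- function(a, sigma) {
  if (sigma <= 0) return(a)
  d <- dim(a)
  nd <- length(d)
  for (ax in seq_len(nd)) {
    K <- gauss_operator(d[ax], sigma)
    a <- aperm(a, c(ax, setdiff(seq_len(nd), ax)))
    dp <- dim(a)
    a <- K %*% matrix(a, nrow = d[ax])
    dim(a) <- dp
    a <- aperm(a, order(c(ax, setdiff(seq_len(nd), ax))))
  }
  a
}

# Connected components among a set of voxels in a 3-D grid.
# `idx`: linear indices of the voxels; `dim`: grid dimensions;
# connectivity 26 (face/edge/corner) or 6 (face only).
# Returns integer labels (1..n_components) aligned with `idx`.
label_components <- function(idx, dim, connectivity = 26) {
  m <- length(idx)
  if (m == 0L) return(integer(0))
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  # keep one of each +/- pair; edges are undirected
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
                 (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), , drop = FALSE]
  co <- arrayInd(idx, dim)
  edges <- NULL
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(co, 2, offs[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dim[1] & nb[, 2] >= 1 & nb[, 2] <= dim[2] &
      nb[, 3] >= 1 & nb[, 3] <= dim[3]
    if (!any(ok)) next
    lin <- (nb[ok, 3] - 1L) * dim[1] * dim[2] + (nb[ok, 2] - 1L) * dim[1] + nb[ok, 1]
    hit <- match(lin, idx)
    found <- !is.na(hit)
    if (any(found)) edges <- rbind(edges, cbind(which(ok)[found], hit[found]))
  }
  if (is.null(edges)) return(seq_len(m))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, m - igraph::vcount(g)))
  as.integer(igraph::components(g)$membership)
}

# Topographic prominence of peaks at indices `at` in series `x`: for each
# peak, the drop from the peak to the highest of the two key saddles (the
# minimum on each side before reaching a strictly higher sample or the
# series boundary).
peak_prominence <- function(x, at) {
  vapply(at, function(i) {
    v <- x[i]
    left <- if (i > 1) x[seq_len(i - 1)] else numeric(0)
    right <- if (i < length(x)) x[(i + 1):length(x)] else numeric(0)
    higher_l <- which(rev(left) > v)[1]
    lmin <- if (length(left) == 0) v
            else min(rev(left)[seq_len(if (is.na(higher_l)) length(left) else higher_l)])
    higher_r <- which(right > v)[1]
    rmin <- if (length(right) == 0) v
            else min(right[seq_len(if (is.na(higher_r)) length(right) else higher_r)])
    v - max(lmin, rmin)
  }, numeric(1))
}

# Linear detrend of a numeric vector (least-squares line removed).
detrend_linear <- function(x) {
  n <- length(x)
  t <- seq_len(n)
  stats::residuals(stats::lm.fit(cbind(1, t), x))
}
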