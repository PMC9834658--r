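# Shared fixtures and independent oracle implementations. The oracles are
# deliberately naive (loops, exhaustive enumeration) and share no code with
# the package internals they check.

make_geno <- function(calls, samples = sprintf("s%03d", seq_len(nrow(calls)))) {
  L <- ncol(calls)
  geno(
    calls = calls,
    markers = tibble::tibble(
      name = sprintf("m%04d", seq_len(L)),
      chromosome = as.character(rep_len(1:26, L)),
      position_bp = seq_len(L) * 1000L,
      allele_a = "A", allele_b = "G"
    ),
    samples = samples
  )
}

random_geno <- function(n, L, q = NULL, missing_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(q)) q <- runif(L, 0.1, 0.5)
  calls <- matrix(rbinom(n * L, 2L, rep(q, each = n)), n)
  if (missing_rate > 0) {
    calls[runif(length(calls)) < missing_rate] <- NA_integer_
  }
  make_geno(calls)
}

# IBS-matrix-shaped object from an arbitrary symmetric weight matrix, for
# driving the network code with hand-built topologies.
fake_ibs <- function(w, ids = sprintf("n%02d", seq_len(nrow(w)))) {
  diag(w) <- 1
  dimnames(w) <- list(ids, ids)
  structure(list(samples = ids, ibs = w,
                 n_used = matrix(1L, nrow(w), ncol(w), dimnames = dimnames(w))),
            class = "ibs_matrix")
}

# adjacency matrix (0/1) -> fake IBS where edges weigh 1
adj_ibs <- function(adj, ids = sprintf("n%02d", seq_len(nrow(adj)))) {
  fake_ibs(adj * 1.0, ids)
}

random_adjacency <- function(n, p_edge) {
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- as.numeric(runif(n * (n - 1) / 2) < p_edge)
  a + t(a)
}

# --- exhaustive betweenness / diameter oracle (graphs up to ~8 nodes) ------

# all simple paths from s to t, as lists of vertex indices
all_simple_paths_bf <- function(adj, s, t) {
  n <- nrow(adj)
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      out[[length(out) + 1]] <<- path
      return(invisible())
    }
    for (w in seq_len(n)) {
      if (adj[v, w] > 0 && !(w %in% path)) walk(c(path, w))
    }
  }
  walk(s)
  out
}

# normalized betweenness (endpoints excluded, unweighted shortest paths)
bf_betweenness <- function(adj) {
  n <- nrow(adj)
  b <- numeric(n)
  if (n < 3) return(b)
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      paths <- all_simple_paths_bf(adj, s, t)
      if (length(paths) == 0) next
      lens <- vapply(paths, length, integer(1))
      short <- paths[lens == min(lens)]
      sigma <- length(short)
      inner <- unlist(lapply(short, function(p) p[-c(1, length(p))]))
      if (length(inner) > 0) {
        cnt <- table(inner)
        idx <- as.integer(names(cnt))
        b[idx] <- b[idx] + as.numeric(cnt) / sigma
      }
    }
  }
  b / ((n - 1) * (n - 2) / 2)
}

# diameter of the largest component, unweighted (Floyd-Warshall)
bf_diameter <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj > 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  # largest component = most members with finite distance rows
  comp_sizes <- rowSums(is.finite(d))
  members <- which(comp_sizes == max(comp_sizes))
  dm <- d[members, members, drop = FALSE]
  if (length(members) < 2) NA_real_ else max(dm[is.finite(dm)])
}

# --- Weir-Cockerham (1984) textbook two-population theta, per-locus loop ---

wc_theta_oracle <- function(g, grp) {
  cl <- g$calls
  A <- 0; D <- 0
  for (j in seq_len(ncol(cl))) {
    x1 <- cl[grp == 1, j]; x2 <- cl[grp == 2, j]
    x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
    n1 <- length(x1); n2 <- length(x2)
    if (n1 < 2 || n2 < 2) next
    p1 <- sum(x1) / (2 * n1); p2 <- sum(x2) / (2 * n2)
    h1 <- mean(x1 == 1); h2 <- mean(x2 == 1)
    nbar <- (n1 + n2) / 2
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    if (pbar <= 0 || pbar >= 1) next
    nc <- n1 + n2 - (n1^2 + n2^2) / (n1 + n2)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
    hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
    a <- nbar / nc *
      (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    A <- A + a
    D <- D + a + b + cc
  }
  A / D
}

# --- misc -------------------------------------------------------------------

ols_scan_pvals <- function(y, calls) {
  vapply(seq_len(ncol(calls)), function(j) {
    d <- calls[, j]
    if (stats::var(d) == 0) return(NA_real_)
    stats::summary.lm(stats::lm(y ~ d))$coefficients["d", 4]
  }, numeric(1))
}

published_diversity <- function() {
  readr::read_tsv(
    system.file("extdata", "merino_diversity_published.tsv",
                package = "flocknet"),
    show_col_types = FALSE
  )
}
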