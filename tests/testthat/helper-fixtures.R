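# Shared fixtures, built in code at test time.

tiny_reference <- function(seed = 11, n_types = 3, n_genes = 60,
                           n_cells = 120) {
  generate_reference(n_types = n_types, n_genes = n_genes, n_cells = n_cells,
                     marker_genes_per_type = 5, marker_logfc = 2, seed = seed)
}

tiny_slice <- function(n = 30, g = 8, seed = 12) {
  set.seed(seed)
  counts <- matrix(rpois(n * g, 5), n, g,
                   dimnames = list(paste0("s", 1:n), paste0("g", 1:g)))
  slice_data(counts, cbind(runif(n, 0, 100), runif(n, 0, 100)))
}

# Brute-force MMD^2 by explicit double loops (independent of the package's
# vectorized path).
mmd2_brute <- function(U, V, sigma) {
  k <- function(a, b) exp(-sum((a - b)^2) / sigma)
  n <- nrow(U); m <- nrow(V)
  s1 <- 0; for (i in 1:n) for (j in 1:n) s1 <- s1 + k(U[i, ], U[j, ])
  s2 <- 0; for (i in 1:n) for (j in 1:m) s2 <- s2 + k(U[i, ], V[j, ])
  s3 <- 0; for (i in 1:m) for (j in 1:m) s3 <- s3 + k(V[i, ], V[j, ])
  s1 / n^2 - 2 * s2 / (n * m) + s3 / m^2
}

# Brute-force mutual k-nearest-neighbour overlap (O(n^2) loops).
overlap_brute <- function(S, T, k, max_dist) {
  d <- as.matrix(stats::dist(rbind(S, T)))[seq_len(nrow(S)),
                                           nrow(S) + seq_len(nrow(T)),
                                           drop = FALSE]
  kn_s <- lapply(seq_len(nrow(S)), function(i)
    order(d[i, ])[seq_len(min(k, ncol(d)))])
  kn_t <- lapply(seq_len(nrow(T)), function(j)
    order(d[, j])[seq_len(min(k, nrow(d)))])
  lapply(seq_len(nrow(S)), function(i) {
    cand <- kn_s[[i]]
    mut <- cand[vapply(cand, function(j) i %in% kn_t[[j]], logical(1))]
    sort(mut[d[i, mut] <= max_dist])
  })
}

# Direct AOF evaluation from its definition, built on overlap_brute.
aof_brute <- function(S, sdom, T, tdom, k, p, max_dist) {
  nb <- overlap_brute(S, T, k, max_dist)
  ov <- which(lengths(nb) > 0)
  agree <- if (length(ov)) {
    mean(vapply(ov, function(i) mean(tdom[nb[[i]]] == sdom[i]), numeric(1)))
  } else 0
  agree - abs(length(ov) / nrow(S) - 1)^p
}
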