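## Shared fixtures (memoized across test files) and independent brute-force
## oracles used to freeze expected values.

.cache <- new.env(parent = emptyenv())

## canonical C7O2 isomer family used throughout the suite
fixture_family <- function(count = 50, seed = 3) {
  key <- sprintf("fam_%d_%d", count, seed)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- generate_fixture_family(9, c(C = 7, O = 2), count, seed)
  .cache[[key]]
}

fixture_crystals <- function(count = 500, seed = 9) {
  key <- sprintf("cry_%d_%d", count, seed)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- generate_crystal_fixtures(count = count, seed = seed)
  .cache[[key]]
}

## permute the atoms of a molgraph (graph only)
permute_graph <- function(g, p) {
  molecular_graph(g$nuclear_charges[p], g$bond_order_matrix[p, p])
}

## brute-force shortest-path oracle: exhaustive enumeration of all simple
## paths (hops and covalent-radius-weighted length) -- independent of igraph
brute_path_metrics <- function(g) {
  heavy <- g$heavy_indices
  B <- g$bond_order_matrix[heavy, heavy, drop = FALSE]
  r <- covalent_radius(g$nuclear_charges[heavy])
  n <- nrow(B)
  W <- outer(r, r, `+`)
  hop <- matrix(Inf, n, n); diag(hop) <- 0
  len <- matrix(Inf, n, n); diag(len) <- 0
  for (i in seq_len(n)) {
    rec <- function(v, visited, hops, lensum) {
      if (hops < hop[i, v]) hop[i, v] <<- hops
      if (lensum < len[i, v]) len[i, v] <<- lensum
      for (u in which(B[v, ] > 0L)) if (!(u %in% visited))
        rec(u, c(visited, u), hops + 1, lensum + W[v, u])
    }
    rec(i, i, 0, 0)
  }
  list(hop = hop, len = len)
}

## all permutations of a small vector (for exhaustive tie-case checks)
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(all_perms(v[-i]), function(p) c(v[i], p))))
}
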