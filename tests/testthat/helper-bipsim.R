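# shared test helpers: small compositions and quick states

tiny_mixed_state <- function(N = 12, L = 16, lx = 9, seed = 1) {
  build_initial_configuration(system_composition(N = N, L = L, lx = lx,
                                                 seed = seed))
}

# pure-R union-find for cluster oracle tests
uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      a <- find(edges[k, 1]); b <- find(edges[k, 2])
      if (a != b) parent[a] <- b
    }
  }
  vapply(seq_len(n), find, 0L)
}

canon_partition <- function(memb) match(memb, unique(memb))
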