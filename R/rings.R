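# Ring perception on the heavy-atom skeleton (simple graph; bond multiplicity
# does not create rings).

# logical vector over bonds: is the bond part of some cycle?
bonds_in_ring <- function(m) {
  nb <- nrow(m$bonds)
  if (nb == 0L) return(logical(0))
  g <- mol_graph(m)
  br <- igraph::bridges(g)
  in_ring <- rep(TRUE, nb)
  # edges in mol_graph keep the insertion order of m$bonds
  if (length(br)) in_ring[as.integer(br)] <- FALSE
  in_ring
}

# number of independent rings (cyclomatic number of the simple skeleton)
ring_count <- function(m) {
  n <- length(m$element)
  comp <- if (n == 1L) 1L else igraph::count_components(mol_graph(m))
  max(0L, as.integer(nrow(m$bonds) - n + comp))
}

# smallest ring through each atom (Inf when the atom is in no ring)
smallest_ring_per_atom <- function(m) {
  n <- length(m$element)
  out <- rep(Inf, n)
  nb <- nrow(m$bonds)
  if (nb == 0L) return(out)
  in_ring <- bonds_in_ring(m)
  if (!any(in_ring)) return(out)
  g <- mol_graph(m)
  for (k in which(in_ring)) {
    f <- m$bonds$from[k]; t <- m$bonds$to[k]
    g2 <- igraph::delete_edges(g, k)
    d <- igraph::distances(g2, v = f, to = t)[1L, 1L]
    if (is.finite(d)) {
      size <- d + 1
      out[f] <- min(out[f], size)
      out[t] <- min(out[t], size)
    }
  }
  out
}

# smallest ring containing each bond (Inf for acyclic bonds)
smallest_ring_per_bond <- function(m) {
  nb <- nrow(m$bonds)
  out <- rep(Inf, nb)
  if (nb == 0L) return(out)
  in_ring <- bonds_in_ring(m)
  g <- mol_graph(m)
  for (k in which(in_ring)) {
    g2 <- igraph::delete_edges(g, k)
    d <- igraph::distances(g2, v = m$bonds$from[k], to = m$bonds$to[k])[1L, 1L]
    if (is.finite(d)) out[k] <- d + 1
  }
  out
}
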