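# Independent brute-force oracles for the isomer enumerator.
#
# Deliberately naive and igraph-free: labeled bond-order matrices are
# enumerated exhaustively (no symmetry pruning) and reduced with a
# backtracking isomorphism matcher, so agreement with the package's
# canonical-form orderly generation is a genuine two-route check.

# element/charge/hcount-preserving graph isomorphism by backtracking
oracle_isomorphic <- function(a, b) {
  n <- length(a$element)
  if (n != length(b$element) || nrow(a$bonds) != nrow(b$bonds)) return(FALSE)
  keyA <- paste(a$element, a$charge, a$hcount)
  keyB <- paste(b$element, b$charge, b$hcount)
  if (!identical(sort(keyA), sort(keyB))) return(FALSE)
  A <- matrix(0L, n, n); B <- matrix(0L, n, n)
  for (k in seq_len(nrow(a$bonds))) {
    A[a$bonds$from[k], a$bonds$to[k]] <- a$bonds$order[k]
    A[a$bonds$to[k], a$bonds$from[k]] <- a$bonds$order[k]
  }
  for (k in seq_len(nrow(b$bonds))) {
    B[b$bonds$from[k], b$bonds$to[k]] <- b$bonds$order[k]
    B[b$bonds$to[k], b$bonds$from[k]] <- b$bonds$order[k]
  }
  degA <- rowSums(A); degB <- rowSums(B)
  map <- integer(n)
  used <- logical(n)
  extend <- function(i) {
    if (i > n) return(TRUE)
    for (j in seq_len(n)) {
      if (used[j] || keyB[j] != keyA[i] || degB[j] != degA[i]) next
      ok <- TRUE
      if (i > 1L) {
        prev <- seq_len(i - 1L)
        if (!all(A[i, prev] == B[j, map[prev]])) ok <- FALSE
      }
      if (ok) {
        map[i] <<- j; used[j] <<- TRUE
        if (extend(i + 1L)) return(TRUE)
        used[j] <<- FALSE
      }
    }
    FALSE
  }
  extend(1L)
}

# exhaustive enumeration over all labeled upper-triangular bond-order
# matrices, reduced by oracle_isomorphic; returns the molecule list
oracle_enumerate <- function(formula, max_order = 3L) {
  counts <- decoybench::parse_formula(formula)
  h_total <- if ("H" %in% names(counts)) counts[["H"]] else 0L
  heavy <- counts[setdiff(names(counts), "H")]
  elements <- rep(names(heavy), heavy)
  val <- unname(vapply(elements, function(e) decoybench::default_valence(e),
                       integer(1L)))
  n <- length(elements)
  twoB <- sum(val) - h_total
  if (twoB < 0L || twoB %% 2L != 0L) return(list())
  B <- twoB %/% 2L
  if (n == 1L) {
    if (B != 0L) return(list())
    return(list(decoybench::molecule(elements, hcount = h_total)))
  }
  pairs <- which(upper.tri(matrix(0L, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  P <- nrow(pairs)
  reps <- list()
  res <- val
  orders <- integer(P)

  connected <- function(bonds) {
    if (!nrow(bonds)) return(n == 1L)
    seen <- logical(n); seen[1L] <- TRUE; frontier <- 1L
    while (length(frontier)) {
      nxt <- unique(c(bonds$to[bonds$from %in% frontier],
                      bonds$from[bonds$to %in% frontier]))
      nxt <- nxt[!seen[nxt]]
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    all(seen)
  }

  recurse <- function(p, b_rem) {
    if (p > P) {
      if (b_rem != 0L) return(invisible())
      keep <- orders > 0L
      bonds <- data.frame(from = pairs[keep, 1L], to = pairs[keep, 2L],
                          order = orders[keep])
      if (!connected(bonds)) return(invisible())
      m <- decoybench::molecule(elements, bonds = bonds, hcount = res,
                                validate = FALSE)
      for (r in reps) if (oracle_isomorphic(m, r)) return(invisible())
      reps[[length(reps) + 1L]] <<- m
      return(invisible())
    }
    i <- pairs[p, 1L]; j <- pairs[p, 2L]
    for (o in 0L:min(max_order, res[i], res[j], b_rem)) {
      orders[p] <<- o
      res[i] <<- res[i] - o; res[j] <<- res[j] - o
      if (b_rem - o <= 3L * (P - p)) recurse(p + 1L, b_rem - o)
      res[i] <<- res[i] + o; res[j] <<- res[j] + o
      orders[p] <<- 0L
    }
    invisible()
  }
  recurse(1L, B)
  reps
}

oracle_count <- function(formula) length(oracle_enumerate(formula))
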