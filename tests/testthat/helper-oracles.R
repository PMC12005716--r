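## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths (no phyper, no Fitch pass) so agreement is
## informative.

# Exact upper-tail hypergeometric probability P(X >= shared) for `shared`
# overlaps between a set of size nA and a set of size nB drawn from N items.
# For small problems this is literal enumeration of all C(N, nA) subsets;
# otherwise the exact combinatorial sum (still phyper-free).
exactUpperTail <- function(shared, nA, nB, N) {
  if (nA == 0L || nB == 0L) return(if (shared <= 0L) 1 else 0)
  if (choose(N, nA) <= 2e5) {
    sets <- utils::combn(N, nA)
    mean(colSums(sets <= nB) >= shared)
  } else {
    ks <- max(shared, 0L):min(nA, nB)
    sum(choose(nB, ks) * choose(N - nB, nA - ks)) / choose(N, nA)
  }
}

# Minimum number of state changes over all labelings of the internal nodes
# of a rooted binary-character tree (brute force over 2^Nnode labelings).
bruteMinChanges <- function(tree, tipStates) {
  nint <- tree$Nnode
  ntip <- ape::Ntip(tree)
  best <- Inf
  for (mask in seq_len(2^nint) - 1L) {
    lab <- c(tipStates,
             as.integer(intToBits(mask))[seq_len(nint)])
    ch <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
    best <- min(best, ch)
  }
  as.integer(best)
}

# Changes implied by a full node labeling (tips + internals, indices 1..nn).
labelingChanges <- function(tree, labeling) {
  sum(labeling[tree$edge[, 1]] != labeling[tree$edge[, 2]])
}
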