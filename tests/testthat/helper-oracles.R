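# Independent oracles used by multiple test files.

# Brute-force Mk likelihood: enumerate all internal-node state assignments
# with closed-form 2-state transition probabilities and an equal root prior.
brute_force_loglik <- function(tree, states, q01, q10) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  internal <- (ntip + 1L):nn
  total <- 0
  for (mask in 0:(2^length(internal) - 1)) {
    st <- integer(nn)
    st[seq_len(ntip)] <- states
    st[internal] <- as.integer(intToBits(mask))[seq_along(internal)]
    p <- 0.5
    for (k in seq_len(nrow(tree$edge))) {
      P <- mk_pmat(q01, q10, tree$edge.length[k])
      p <- p * P[st[tree$edge[k, 1]] + 1L, st[tree$edge[k, 2]] + 1L]
    }
    total <- total + p
  }
  log(total)
}
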