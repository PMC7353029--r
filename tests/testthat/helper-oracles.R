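# Independent oracles.
#
# Saturation: the package enumerates biopsy subsets explicitly; the oracle
# for avg_unique/avg_ptv is a per-variant combinatorial closed form (a
# variant present in m of b biopsies lies in all k chosen biopsies for
# C(m,k) of the C(b,k) subsets, and in none of them for C(b-m,k)), and the
# oracle for avg_ppv is a bitmask re-enumeration sharing no code with the
# implementation.

oracle_unique_ptv <- function(pm, k) {
  b <- ncol(pm$presence)
  m <- rowSums(pm$presence)
  denom <- choose(b, k)
  list(unique = sum(1 - choose(b - m, k) / denom),
       ptv = sum(choose(m, k) / denom))
}

oracle_ppv <- function(pm, k) {
  b <- ncol(pm$presence)
  vmask <- as.integer(pm$presence %*% 2^(seq_len(b) - 1))
  full <- sum(2^(seq_len(b) - 1))
  C <- sum(vmask == full)
  terms <- c()
  n_excluded <- 0L
  for (S in seq_len(2^b) - 1L) {
    if (sum(bitwAnd(S, 2^(seq_len(b) - 1)) > 0) != k) next
    ptv <- sum(bitwAnd(vmask, S) == S)
    if (ptv > 0) terms <- c(terms, C / ptv) else n_excluded <- n_excluded + 1L
  }
  list(ppv = if (length(terms)) mean(terms) else NA_real_,
       n_excluded = n_excluded)
}

# Fitch parsimony score of a given tree via phangorn (independent
# implementation); the germline taxon GL is an all-absent row, so the
# unrooted score equals the germline-rooted score.
oracle_parsimony <- function(newick, pm) {
  states <- rbind(t(ifelse(pm$presence, "1", "0")),
                  GL = rep("0", nrow(pm$presence)))
  dat <- phangorn::phyDat(states, type = "USER", levels = c("0", "1"))
  tree <- ape::read.tree(text = newick)
  as.integer(phangorn::parsimony(tree, dat, method = "fitch"))
}

# Minimum parsimony score over all topologies, via phangorn's exhaustive
# tree set.
oracle_min_parsimony <- function(pm) {
  states <- rbind(t(ifelse(pm$presence, "1", "0")),
                  GL = rep("0", nrow(pm$presence)))
  dat <- phangorn::phyDat(states, type = "USER", levels = c("0", "1"))
  trees <- phangorn::allTrees(nrow(states), rooted = FALSE,
                              tip.label = rownames(states))
  min(vapply(trees, function(tr) {
    phangorn::parsimony(tr, dat, method = "fitch")
  }, numeric(1)))
}
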