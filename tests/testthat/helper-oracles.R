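# exact CRP (infinite-alleles) enumeration: walk every seating sequence of
# j customers and sum the probability of outcomes with a single table
crp_monoallelic <- function(theta, j) {
  recurse <- function(tables, prob) {
    k <- sum(tables)
    if (k == j) return(if (length(tables) == 1L) prob else 0)
    tot <- theta + k
    p <- sum(vapply(seq_along(tables), function(i)
      recurse(`[<-`(tables, i, tables[i] + 1L), prob * tables[i] / tot),
      1.0))
    p + recurse(c(tables, 1L), prob * theta / tot)
  }
  recurse(1L, 1)
}
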