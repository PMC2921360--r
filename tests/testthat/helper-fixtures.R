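# Shared fixtures: the two worked-example substrates, residue alphabet,
# random parents/matrices for property tests.

RES20 <- names(residue_masses()$residue_masses)

sf_29_35 <- function() {
  tagged_substrate("SF 29-35", "LERMFLSQ", "Abz", "EDDnp", parent_offset = 29)
}

sf_57_67 <- function() {
  tagged_substrate("SF 57-67", "GHGAKVAAALTQQ", "Abz", "EDDnp",
                   parent_offset = 57)
}

random_sequence <- function(n, seed) {
  set.seed(seed)
  paste(sample(RES20, n, replace = TRUE), collapse = "")
}

random_matrix <- function(subsites, seed, threshold = 0.5) {
  set.seed(seed)
  w <- lapply(subsites, function(s) setNames(runif(20, 0.05, 1), RES20))
  names(w) <- subsites
  specificity_matrix(w, threshold = threshold)
}

uniform_matrix <- function(subsites, threshold = 0.5) {
  w <- lapply(subsites, function(s) setNames(rep(1, 20), RES20))
  names(w) <- subsites
  specificity_matrix(w, threshold = threshold)
}

# map a synthetic digest's observed intervals back to cleavage sites
digest_sites <- function(dig, parent_seq, chain = "c1") {
  pp <- parent_proteins(setNames(parent_seq, chain))
  iv <- map_peptides(
    data.frame(chain = chain, start = dig$intervals$start,
               end = dig$intervals$end, stringsAsFactors = FALSE), pp)
  extract_sites(iv, pp)
}
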