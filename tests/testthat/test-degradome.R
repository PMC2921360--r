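# Peptide-to-parent mapping, cleavage-site extraction, subsite statistics
# and hemocidin annotation.

hb <- bovine_hemoglobin()

test_that("packaged hemoglobin chains carry the expected landmarks", {
  expect_equal(hb$length, c(141, 145))
  expect_equal(substr(hb$sequence[1], 29, 35), "LERMFLS")
  expect_equal(substr(hb$sequence[1], 57, 67), "GHGAKVAAALT")
  expect_equal(substr(hb$sequence[1], 60, 62), "AKV")  # Ala at P2 of Lys61/Val62
})

test_that("peptides map by exact substring search with occurrence flags", {
  iv <- map_peptides(c("LERMFLS", "GHGAKVAAALT", "WWWWW"), hb)
  expect_equal(iv$start, c(29, 57))
  expect_equal(iv$end, c(35, 67))
  expect_equal(iv$chain_id, c("alpha", "alpha"))
  expect_false(any(iv$ambiguous))
  expect_equal(attr(iv, "unmapped"), "WWWWW")

  # multi-occurrence peptides are reported at every locus, flagged
  pp <- parent_proteins(c(c1 = "AAGWAAGW"))
  iv2 <- map_peptides("AAGW", pp)
  expect_equal(nrow(iv2), 2)
  expect_true(all(iv2$ambiguous))
})

test_that("coordinate rows are verified against the parent", {
  rows <- data.frame(
    chain = c("alpha", "alpha", "alpha"),
    start = c(29, 29, 300), end = c(35, 35, 310),
    sequence = c("LERMFLS", "WRONGSEQ", NA),
    stringsAsFactors = FALSE)
  iv <- map_peptides(rows, hb)
  expect_equal(nrow(iv), 1)            # only the verified row survives
  err <- attr(iv, "errors")
  expect_equal(err$row, c(2, 3))
  expect_match(err$reason[1], "WRONGSEQ")
  # mapping soundness holds on every output
  expect_equal(substr(hb$sequence[1], iv$start, iv$end), iv$sequence)
})

test_that("internal peptide termini become cleavage sites with support", {
  rows <- data.frame(chain = "alpha", start = c(1, 33), end = c(32, 43),
                     stringsAsFactors = FALSE)
  s <- extract_sites(map_peptides(rows, hb), hb)
  bond32 <- s[s$position == 32, ]
  expect_equal(bond32$support, 2)       # end of 1-32 and start of 33-43
  expect_equal(bond32$site, "Met32/Phe33")
  expect_equal(bond32$P1, "M")
  expect_equal(bond32$`P1'`, "F")

  # a full-chain peptide has no internal termini
  full <- map_peptides(data.frame(chain = "alpha", start = 1, end = 141), hb)
  expect_equal(nrow(extract_sites(full, hb)), 0)

  # duality: summed support equals the number of internal termini
  rows2 <- data.frame(chain = "alpha",
                      start = c(1, 10, 33, 48), end = c(9, 32, 47, 141),
                      stringsAsFactors = FALSE)
  s2 <- extract_sites(map_peptides(rows2, hb), hb)
  n_termini <- sum(rows2$start > 1) + sum(rows2$end < 141)
  expect_equal(sum(s2$support), n_termini)

  # min_support filters
  s3 <- extract_sites(map_peptides(rows, hb), hb, min_support = 2)
  expect_equal(s3$position, 32)
})

test_that("subsite columns conserve site counts and track truncation", {
  rows <- data.frame(chain = "alpha", start = c(1, 33, 3), end = c(32, 43, 60),
                     stringsAsFactors = FALSE)
  s <- extract_sites(map_peptides(rows, hb), hb)
  tab <- subsite_table(s)
  n <- attr(tab, "n_sites")
  expect_equal(n, nrow(s))
  trunc <- attr(tab, "truncated")
  expect_true(all(rowSums(tab) + trunc == n))
  # site at bond 2 (peptide starting at 3) truncates P4..P3
  expect_gte(trunc[["P4"]], 1)
  expect_error(subsite_table(s[0, ]), "no cleavage sites")
})

test_that("class percentages follow the declared residue partition", {
  rows <- data.frame(chain = "alpha", start = c(1, 33), end = c(32, 43),
                     stringsAsFactors = FALSE)
  tab <- subsite_table(extract_sites(map_peptides(rows, hb), hb))
  summ <- classify_summary(tab)
  # P1 residues are Met and Phe: both non-polar
  expect_equal(summ$class_percent["P1", "nonpolar"], 100)
  expect_equal(summ$class_percent["P1", "polar"], 0)
  # combined Leu+Phe share at P1 is 50% (Met32 + Phe43)
  summ2 <- classify_summary(tab, share_residues = c("L", "F"))
  expect_equal(unname(summ2$share["P1"]), 50)
  # a non-partition is rejected
  expect_error(classify_summary(tab, classes = list(a = "A", b = "C")),
               "partition")
})

test_that("hemocidin annotation distinguishes exact and overlapping hits", {
  ref <- hemocidin_reference()
  rows <- data.frame(chain = "alpha", start = c(1, 33, 100),
                     end = c(32, 43, 110), stringsAsFactors = FALSE)
  iv <- annotate_hemocidins(map_peptides(rows, hb), ref, min_jaccard = 0.5)
  expect_equal(iv$annotation,
               c("known_antimicrobial", "potential_antimicrobial",
                 "unannotated"))
  expect_equal(iv$matched_name[1], "Hb alpha 1-32")
  expect_equal(iv$matched_name[2], "Hb alpha 34-46")  # overlap 10/14 = 0.71
  expect_equal(interval_jaccard(c(33, 43), c(34, 46)), 10 / 14)
  # empty reference leaves everything unannotated
  iv0 <- annotate_hemocidins(map_peptides(rows, hb), ref[0, ])
  expect_true(all(iv0$annotation == "unannotated"))
})

test_that("a P2 Leu-biased generator is recovered as the P2 argmax", {
  w <- setNames(rep(0.25, 20), RES20); w["L"] <- 1
  mat <- specificity_matrix(list(P2 = w))
  par <- random_sequence(1500, 21)
  dig <- gen_digest(par, mat, seed = 3, score_rule = "product")
  s <- digest_sites(dig, par)
  expect_gte(nrow(s), 200)
  tab <- subsite_table(s)
  expect_equal(names(which.max(tab["P2", ])), "L")
})

test_that("a generator with 81% non-polar P1 is recovered within 3 points", {
  nonpolar <- residue_classes()$nonpolar
  # weight ratio 5.21 puts 81% of cut probability on non-polar P1 residues
  # under a uniform residue background
  w <- setNames(rep(0.192, 20), RES20); w[nonpolar] <- 1
  mat <- specificity_matrix(list(P1 = w))
  par <- random_sequence(4000, 1)
  dig <- gen_digest(par, mat, seed = 1, score_rule = "product")
  s <- digest_sites(dig, par)
  expect_gte(nrow(s), 500)
  pct <- classify_summary(subsite_table(s))$class_percent["P1", "nonpolar"]
  expect_lte(abs(pct - 81), 3)
})
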