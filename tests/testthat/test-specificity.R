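# PS-SCL normalization, specificity matrices, in-silico digestion,
# concordance.

test_that("normalize_psscl rescales each subsite to percent of maximum", {
  d <- data.frame(subsite = "P1", residue = c("R", "K", "A"),
                  rate = c(8, 4, 2))
  expect_equal(normalize_psscl(d)$percent, c(100, 50, 25))
  # all residues equal -> all 100
  d2 <- data.frame(subsite = "P2", residue = c("A", "V"), rate = c(3, 3))
  expect_equal(normalize_psscl(d2)$percent, c(100, 100))
  # all-zero subsite rejected by name
  d3 <- data.frame(subsite = c("P1", "P2"), residue = "A", rate = c(1, 0))
  expect_error(normalize_psscl(d3), "P2")
})

test_that("normalization is idempotent and scale-invariant", {
  d <- gen_psscl(random_matrix(c("P2", "P1"), 4), noise_sigma = 0.1, seed = 9)
  n1 <- normalize_psscl(d)
  n2 <- normalize_psscl(transform(n1, rate = percent))
  expect_equal(n1$percent, n2$percent)
  d2 <- d
  d2$rate[d2$subsite == "P1"] <- d2$rate[d2$subsite == "P1"] * 37.5
  expect_equal(normalize_psscl(d2)$percent, n1$percent)
})

test_that("build_matrix max-normalizes and preserves argmax", {
  d <- data.frame(subsite = "P1", residue = c("R", "K", "A"),
                  rate = c(8, 4, 2))
  m <- build_matrix(normalize_psscl(d))
  expect_equal(m$weights["P1", "R"], 1)
  expect_equal(m$weights["P1", "K"], 0.5)
  expect_true(is.na(m$weights["P1", "W"]))  # absent from panel: no info

  # degradome-derived: single site gives one-hot weights
  hbp <- bovine_hemoglobin()
  s <- extract_sites(map_peptides(
    data.frame(chain = "alpha", start = c(1, 33), end = c(32, 43)), hbp), hbp)
  tab <- subsite_table(s[1, ])
  m2 <- build_matrix(tab)
  expect_equal(m2$weights["P1", "M"], 1)
  expect_equal(sum(m2$weights["P1", ] > 0, na.rm = TRUE), 1)
})

test_that("matrix -> gen_psscl -> normalize -> build_matrix round trips", {
  m <- random_matrix(c("P4", "P3", "P2", "P1"), 11)
  d <- gen_psscl(m, noise_sigma = 0, seed = 5)
  m2 <- build_matrix(normalize_psscl(d))
  expect_equal(m2$weights, m$weights, tolerance = 1e-9)
  # noisy round trip keeps the true top residue at the top of the profile
  # (5% noise can swap near-tied leaders, so assert near-maximal weight
  # rather than an exact argmax)
  d3 <- gen_psscl(m, noise_sigma = 0.05, seed = 6)
  m3 <- build_matrix(normalize_psscl(d3))
  for (s in rownames(m$weights)) {
    true_top <- names(which.max(m$weights[s, ]))
    expect_gte(m3$weights[s, true_top], 0.85)
  }
})

test_that("a zero weight at P2 vetoes cleavage under the min rule", {
  hbp <- bovine_hemoglobin()
  m <- specificity_matrix(list(
    P2 = c(A = 0, V = 1, L = 0.8, F = 0.6, Y = 0.5),
    P1 = c(R = 1, K = 0.6, Q = 0.5, M = 0.4)))
  pred <- predict_cleavage(hbp[1, ], m, score_rule = "min")
  # alpha-chain bond Lys61/Val62 has Ala at P2 -> score 0, never predicted
  b61 <- pred$bonds[pred$bonds$position == 61, ]
  expect_equal(b61$p1, "K")
  expect_equal(b61$score, 0)
  expect_false(b61$predicted)
})

test_that("an all-ones matrix predicts the full single-residue digest", {
  m <- uniform_matrix("P1")
  seq <- random_sequence(30, 8)
  pred <- predict_cleavage(seq, m, threshold = 0.5)
  expect_equal(length(pred$predicted_sites), 29)
  expect_equal(nrow(pred$peptides), 30)
  expect_true(all(nchar(pred$peptides$sequence) == 1))
  # the peptide partition always tiles the parent
  expect_equal(paste(pred$peptides$sequence, collapse = ""), seq)
})

test_that("raising a weight never removes a predicted site (min rule)", {
  m <- random_matrix(c("P2", "P1", "P1'"), 13, threshold = 0.4)
  seq <- random_sequence(60, 14)
  before <- predict_cleavage(seq, m, "min")$predicted_sites
  w <- m$weights
  w["P1", "A"] <- 1
  m2 <- specificity_matrix(w, threshold = 0.4)
  after <- predict_cleavage(seq, m2, "min")$predicted_sites
  expect_true(all(before %in% after))
})

test_that("bond scores equal a naive per-bond recomputation", {
  offs <- c("P4" = -3, "P3" = -2, "P2" = -1, "P1" = 0, "P1'" = 1, "P2'" = 2)
  for (seed in 1:6) {
    m <- random_matrix(sample(names(offs), 3), seed + 40)
    seq <- random_sequence(30, seed + 60)
    chars <- strsplit(seq, "")[[1]]
    pred <- predict_cleavage(seq, m, "min")
    for (i in c(1, 2, 15, 28, 29)) {
      vals <- c()
      for (s in m$subsites) {
        pos <- i + offs[[s]]
        if (pos < 1 || pos > 30) next
        wv <- m$weights[s, chars[pos]]
        if (!is.na(wv)) vals <- c(vals, wv)
      }
      expected <- if (length(vals)) min(vals) else NA_real_
      expect_equal(pred$bonds$score[i], expected)
    }
  }
})

test_that("near-terminal bonds skip out-of-range subsites", {
  m <- specificity_matrix(list(P4 = setNames(rep(0.9, 20), RES20),
                               P1 = setNames(rep(0.9, 20), RES20)))
  pred <- predict_cleavage(random_sequence(10, 3), m, "min")
  # bond 1 has no P4 position; it is scored from P1 alone, not zeroed
  expect_equal(pred$bonds$score[1], 0.9 / 0.9 * 1)  # max-normalized to 1
})

test_that("concordance is 1 for identical sources and high for same-matrix sites", {
  m <- random_matrix(c("P2", "P1"), 17)
  par <- random_sequence(3000, 18)
  dig <- gen_digest(par, m, seed = 19, score_rule = "product")
  s <- digest_sites(dig, par)
  expect_gte(nrow(s), 200)
  cc <- concordance(m, s)
  expect_true(all(cc$spearman >= 0.8))
  expect_gte(attr(cc, "mean_spearman"), 0.8)

  # self-concordance of a degradome-derived matrix is exactly 1
  tab <- subsite_table(s)
  cc2 <- concordance(build_matrix(tab), s)
  expect_equal(cc2$spearman, rep(1, nrow(cc2)))

  expect_error(concordance(m, s[1:4, ]), "at least 5")
})

test_that("concordance with an unrelated uniform generator is near zero", {
  m <- random_matrix(c("P2", "P1", "P1'", "P2'"), 23)
  unif <- uniform_matrix(c("P2", "P1", "P1'", "P2'"))
  means <- c(); per <- c()
  for (seed in 1:40) {
    par <- random_sequence(450, seed + 300)
    dig <- gen_digest(par, unif, cut_probability_scale = 0.45, seed = seed,
                      score_rule = "product")
    s <- digest_sites(dig, par)
    cc <- concordance(m, s)
    means <- c(means, attr(cc, "mean_spearman"))
    per <- c(per, cc$spearman)
  }
  # mean across subsites concentrates near zero; single subsites are noisy
  # (spearman over a 20-residue panel has null SD ~ 0.23)
  expect_gte(mean(abs(means) < 0.3), 0.9)
  expect_gte(mean(abs(per) < 0.3), 0.7)
  expect_lt(abs(mean(per)), 0.1)
})
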