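# Fragment enumeration and ion matching for tagged fluorogenic substrates.

test_that("enumerate_fragments yields 2(n-1) single-cut fragments", {
  fr <- enumerate_fragments(sf_29_35(), max_cuts = 1)
  expect_equal(nrow(fr), 14)  # n = 8
  # tag retention is tied to the substrate ends
  expect_true(all(fr$retains_n_mod == (fr$start == 1)))
  expect_true(all(fr$retains_c_mod == (fr$end == 8)))
  # max_cuts = 2 adds one internal fragment per cut pair
  fr2 <- enumerate_fragments(sf_29_35(), max_cuts = 2)
  expect_equal(nrow(fr2), 14 + choose(7, 2))
  expect_error(enumerate_fragments(tagged_substrate("x", "A"), 1),
               "at least 2")
  expect_error(enumerate_fragments(sf_29_35(), max_cuts = 3), "1 or 2")
})

test_that("tagged fragment masses reproduce the printed theoretical m/z", {
  fr <- enumerate_fragments(sf_29_35(), max_cuts = 1)
  flsq <- fr[fr$sequence == "FLSQ" & fr$retains_c_mod, ]
  expect_equal(flsq$cut1, 4)
  expect_equal(flsq$mz, 702.4, tolerance = 0.3 / 702.4)
  lermfl <- fr[fr$sequence == "LERMFL" & fr$retains_n_mod, ]
  expect_equal(lermfl$mz, 927.5, tolerance = 0.3 / 927.5)
  # internal double-cut fragment, average mode
  fr2 <- enumerate_fragments(sf_57_67(), max_cuts = 2, mode = "average")
  aalt <- fr2[!is.na(fr2$cut2) & fr2$cut1 == 7 & fr2$cut2 == 11, ]
  expect_equal(aalt$sequence, "AALT")
  expect_false(aalt$retains_n_mod || aalt$retains_c_mod)
  expect_equal(aalt$mz, 375.4, tolerance = 0.3 / 375.4)
})

test_that("single-cut fragments conserve the intact substrate mass", {
  water <- residue_masses("monoisotopic")$water_mass
  for (seed in 1:8) {
    n <- sample(3:12, 1)
    sub <- tagged_substrate("rnd", random_sequence(n, seed), "Abz", "EDDnp")
    intact <- peptide_mass(sub$sequence, "Abz", "EDDnp")
    fr <- enumerate_fragments(sub, max_cuts = 1)
    for (i in seq_len(n - 1)) {
      pair <- fr[fr$cut1 == i, ]
      expect_equal(sum(pair$neutral_mass), intact + water, tolerance = 1e-6)
    }
  }
})

test_that("worked-example ion lists infer the expected scissile bonds", {
  r1 <- match_ions(sf_29_35(), c(702.3, 927.7), tolerance = 0.5)
  expect_setequal(r1$sites, c("Met32/Phe33", "Leu34/Ser35"))
  expect_true(all(abs(r1$matches$mass_error) <= 0.5))

  r2 <- match_ions(sf_57_67(), c(839.5, 483.2, 374.5), tolerance = 0.5,
                   max_cuts = 2)
  expect_setequal(r2$sites, c("Ala63/Ala64", "Thr67/Gln68"))

  r0 <- match_ions(sf_29_35(), numeric())
  expect_equal(nrow(r0$matches), 0)
  expect_length(r0$sites, 0)
})

test_that("internal fragments confirm but never introduce sites", {
  # 374.24 is the theoretical [M+H]+ of the internal fragment GAKV of
  # SF 57-67; alone it is compatible with cuts that no tagged fragment
  # supports and must stay unassigned
  r <- match_ions(sf_57_67(), 374.24, tolerance = 0.5, max_cuts = 2)
  expect_length(r$sites, 0)
  expect_equal(nrow(r$unassigned), 1)
  # once the flanking tagged fragments evidence cuts 7 and 11, an ion near
  # the internal AALT mass is accepted as confirmatory
  r2 <- match_ions(sf_57_67(), c(839.5, 483.2, 375.2), tolerance = 0.5,
                   max_cuts = 2)
  conf <- r2$matches[r2$matches$confirmatory, ]
  expect_equal(conf$sequence, "AALT")
  expect_setequal(r2$sites, c("Ala63/Ala64", "Thr67/Gln68"))
})

test_that("enlarging the tolerance never removes a matched ion", {
  sub <- sf_57_67()
  obs <- c(839.5, 483.2, 374.5, 600.0, 1114.8)
  prev <- character()
  for (tol in c(0.1, 0.3, 0.5, 1, 2)) {
    r <- match_ions(sub, obs, tolerance = tol, max_cuts = 2)
    got <- unique(r$matches$observed_mz)
    expect_true(all(prev %in% got))
    prev <- got
  }
})

test_that("matching agrees with a brute-force matcher on random substrates", {
  # independent oracle: recompute fragment masses from the raw residue
  # table and assign each ion to the closest fragment within tolerance
  tab <- residue_masses("monoisotopic")
  abz <- get_modification("Abz"); edd <- get_modification("EDDnp")
  brute <- function(sub, obs, tol) {
    chars <- strsplit(sub$sequence, "")[[1]]
    n <- length(chars)
    mz <- c(); cut <- c()
    for (i in seq_len(n - 1)) {
      mN <- sum(tab$residue_masses[chars[1:i]]) + tab$water_mass +
        abz$delta_mono
      mC <- sum(tab$residue_masses[chars[(i + 1):n]]) + tab$water_mass +
        edd$delta_mono
      mz <- c(mz, mN + tab$proton_mass, mC + tab$proton_mass)
      cut <- c(cut, i, i)
    }
    sort(unique(unlist(lapply(obs, function(o) {
      d <- abs(mz - o)
      if (min(d) > tol) return(integer())
      cut[which.min(d)]
    }))))
  }
  for (seed in 1:12) {
    n <- sample(4:12, 1)
    sub <- tagged_substrate("rnd", random_sequence(n, seed + 500),
                            "Abz", "EDDnp")
    fr <- enumerate_fragments(sub, 1)
    set.seed(seed)
    obs <- sample(fr$mz, min(4, nrow(fr))) + runif(4, -0.3, 0.3)
    got <- match_ions(sub, obs, tolerance = 0.4)
    expect_equal(got$cut_set, brute(sub, obs, 0.4))
  }
})

test_that("ions generated from a known cut set match back to it", {
  sub <- sf_29_35()
  # zero mass error: exact recovery
  obs <- gen_ions(sub, list(4, 6), mass_error_sigma = 0, seed = 1)
  r <- match_ions(sub, obs, tolerance = 0.5)
  expect_equal(r$cut_set, c(4L, 6L))
  # gaussian mass error well inside tolerance: recovery across seeds
  ok <- 0
  for (seed in 1:50) {
    obs <- gen_ions(sub, list(4, 6), mass_error_sigma = 0.1, seed = seed)
    r <- match_ions(sub, obs, tolerance = 0.5)
    if (identical(r$cut_set, c(4L, 6L))) ok <- ok + 1
  }
  expect_gte(ok, 49)
})
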