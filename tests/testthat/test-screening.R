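test_that("the activity filter is a conjunction over both confidences", {
  lib <- data.frame(compound_id = c("a", "b", "c"),
                    conf_voting = c(0.85, 0.85, 0.79),
                    conf_stacking = c(0.85, 0.79, 0.9))
  out <- activity_filter(lib, threshold = 0.8)
  expect_identical(out$compound_id, "a")
  expect_equal(unname(attr(out, "counts")), c(3, 1))
  lib$conf_stacking[2] <- NA
  expect_error(activity_filter(lib), "conf_stacking")
})

test_that("planted dual-high compounds are recovered exactly", {
  lib <- synth_screening_library(n = 400, fraction_dual_high = 0.1,
                                 admet_pass_fraction = 0.3, seed = 6)
  out <- activity_filter(lib$records)
  expect_identical(nrow(out), 40L)
  expect_setequal(out$compound_id,
                  lib$manifest$compound_id[lib$manifest$dual_high])
})

test_that("drug-likeness rules fire individually with named reasons", {
  good <- passing_admet_record()
  expect_identical(nrow(druglikeness_filter(good)), 1L)

  logs_bad <- good; logs_bad$logs <- -5
  out <- druglikeness_filter(logs_bad)
  expect_identical(nrow(out), 0L)
  expect_equal(attr(out, "tally")[["LogS"]], 1)

  heavy <- good; heavy$mw <- 600
  out <- druglikeness_filter(heavy)
  expect_identical(nrow(out), 0L)
  expect_equal(attr(out, "tally")[["Lipinski"]], 1)
  # ... unless violations are explicitly allowed
  expect_identical(nrow(druglikeness_filter(heavy, lipinski_max_violations = 1)), 1L)

  toxic <- good; toxic$tox_hepatotoxicity <- TRUE
  expect_equal(attr(druglikeness_filter(toxic), "tally")[["Toxicity"]], 1)

  incomplete <- good; incomplete$mce18 <- NULL
  expect_error(druglikeness_filter(incomplete), "mce18")
})

test_that("activity and drug-likeness filters commute as set operations", {
  lib <- synth_screening_library(n = 500, fraction_dual_high = 0.3,
                                 admet_pass_fraction = 0.5, seed = 2)$records
  ab <- druglikeness_filter(activity_filter(lib))
  ba <- activity_filter(druglikeness_filter(lib))
  expect_setequal(ab$compound_id, ba$compound_id)
})

test_that("Tanimoto similarity is 1 for identical structures and 0 for disjoint bits", {
  pair <- data.frame(compound_id = c("x", "y", "z"),
                     smiles = c("c1ccccc1CCO", "OCCc1ccccc1", "CCCC"))
  res <- similarity_cluster(pair)
  expect_equal(unname(res$similarity["x", "y"]), 1)
  expect_true(all(diag(res$similarity) == 1))
  expect_equal(res$similarity, t(res$similarity))

  disjoint_fp <- function(records) {
    m <- matrix(0, 2, 8, dimnames = list(records$compound_id, NULL))
    m[1, 1:4] <- 1; m[2, 5:8] <- 1
    m
  }
  two <- data.frame(compound_id = c("p", "q"), smiles = c("CC", "OO"))
  res2 <- similarity_cluster(two, fp_provider = disjoint_fp)
  expect_equal(unname(res2$similarity["p", "q"]), 0)
  expect_error(similarity_cluster(two[1, , drop = FALSE]), "at least 2")
})

test_that("hierarchical clustering recovers two planted structural families", {
  family_fp <- function(records) {
    n <- nrow(records)
    fam <- rep(1:2, each = n / 2)
    core <- matrix(0, n, 64, dimnames = list(records$compound_id, NULL))
    set.seed(8)
    for (i in seq_len(n)) {
      base_bits <- if (fam[i] == 1) 1:20 else 33:52
      core[i, c(base_bits, sample(53:64, 3))] <- 1
    }
    core
  }
  records <- data.frame(compound_id = sprintf("m%02d", 1:12),
                        smiles = synth_smiles_pool(12))
  res <- similarity_cluster(records, fp_provider = family_fp)
  groups <- cutree(res$tree, k = 2)
  expect_identical(length(unique(groups[1:6])), 1L)
  expect_identical(length(unique(groups[7:12])), 1L)
  expect_false(groups[1] == groups[7])
})

test_that("consensus scores follow their closed forms and bounds", {
  sc <- consensus_score(0.830, 0.836, -9.007)
  expect_equal(sc$s_ml, 0.833)
  expect_equal(sc$s_dock, 9.007 / 10.6)
  expect_equal(sc$s_total, (sc$s_ml + sc$s_dock) / 2)

  expect_equal(consensus_score(0.5, 0.5, -10.6)$s_dock, 1)       # at reference
  expect_equal(consensus_score(0.5, 0.5, -12)$s_dock, 1)         # capped
  expect_warning(sc0 <- consensus_score(0.5, 0.5, 2), "positive")
  expect_equal(sc0$s_dock, 0)
  expect_error(consensus_score(0.5, 0.5, -9, reference_energy_kcal = 0), "nonzero")
  expect_error(consensus_score(0.5, 0.5, -9, reference_energy_kcal = 5), "negative")
  expect_error(consensus_score(0.5, NA, -9), "complete")
})

test_that("the total score is monotone in confidence and docking favourability", {
  set.seed(12)
  for (i in 1:20) {
    cv <- runif(1); cs <- runif(1); e <- runif(1, -10, -1)
    base <- consensus_score(cv, cs, e)$s_total
    expect_gte(consensus_score(min(1, cv + 0.05), cs, e)$s_total, base)
    expect_gte(consensus_score(cv, min(1, cs + 0.05), e)$s_total, base)
    expect_gte(consensus_score(cv, cs, e - 0.5)$s_total, base)
  }
})

test_that("ranking reproduces the published top-five order from printed inputs", {
  hits <- top5_hits()
  ranked <- rank_candidates(score_library(hits, reference_energy_kcal = -10.6))
  expect_identical(ranked$compound_id, hits$compound_id)
  expect_identical(ranked$rank, 1:5)
})

test_that("ranking breaks ties by id and selects by strict inequality", {
  tied <- data.frame(compound_id = c("a", "b", "c"),
                     s_total = c(0.5, 0.5, 0.5))
  expect_identical(rank_candidates(tied)$compound_id, c("a", "b", "c"))

  edge <- data.frame(compound_id = c("p", "q", "r"),
                     s_total = c(0.81, 0.80, 0.79))
  out <- rank_candidates(edge, select_threshold = 0.8)
  expect_identical(sum(out$selected), 1L)
  expect_identical(out$compound_id[out$selected], "p")
  expect_error(rank_candidates(data.frame(compound_id = "x")), "scored")
})
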