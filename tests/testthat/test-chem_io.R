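make_records <- function(n = 5) {
  as_tbl <- data.frame(
    compound_id = paste0("cpd", seq_len(n)),
    smiles = synth_smiles_pool(n),
    name = paste0("name", seq_len(n)),
    cas_number = sprintf("%d-00-%d", seq_len(n), seq_len(n)),
    ic50_um = c(0.2, 0.5, 1.0, 5, 40)[seq_len(n)],
    label = c("active", "active", "inactive", "inactive", "inactive")[seq_len(n)],
    stringsAsFactors = FALSE
  )
  as_tbl
}

test_that("write-then-read round trips preserve ids, structures and activity", {
  records <- make_records()
  for (fmt in c("csv", "sdf")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_compounds(records, path, fmt)
    back <- read_compounds(path, fmt)
    expect_identical(back$compound_id, records$compound_id)
    expect_equal(back$ic50_um, records$ic50_um)
    expect_identical(back$label, records$label)
    expect_identical(canonical_smiles(back$smiles), canonical_smiles(records$smiles))
    expect_identical(nrow(attr(back, "rejects")), 0L)
  }
  # .smi carries structures and ids only
  path <- withr::local_tempfile(fileext = ".smi")
  write_compounds(records, path, "smi")
  back <- read_compounds(path, "smi")
  expect_identical(back$compound_id, records$compound_id)
  expect_identical(canonical_smiles(back$smiles), canonical_smiles(records$smiles))
})

test_that("malformed structures are rejected with their row, not silently dropped", {
  df <- data.frame(compound_id = c("a", "b", "c"),
                   smiles = c("CCO", "C1CC", "c1ccccc1"),
                   ic50_um = c(0.5, 0.5, 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  expect_warning(records <- read_compounds(path, "csv"), "rejected")
  expect_identical(records$compound_id, c("a", "c"))
  rejects <- attr(records, "rejects")
  expect_identical(rejects$compound_id, "b")
  expect_identical(rejects$row, 2L)
  expect_match(rejects$reason, "SMILES")
})

test_that("missing file errors", {
  expect_error(read_compounds("no/such/file.csv"), "not found")
})

test_that("curation labels by strict inequality at the threshold", {
  records <- data.frame(
    compound_id = c("a", "b", "c"),
    smiles = c("CCO", "CCCO", "CCCCO"),
    ic50_um = c(0.5, 1.0, 1.5))
  cur <- curate_dataset(records, threshold_um = 1.0)
  expect_identical(cur$label, c("active", "inactive", "inactive"))
})

test_that("duplicate structures collapse to the geometric mean IC50", {
  # same molecule written two ways
  records <- data.frame(
    compound_id = c("a", "b", "c"),
    smiles = c("OCC", "CCO", "CCCCO"),
    ic50_um = c(0.4, 0.9, 2))
  cur <- curate_dataset(records)
  expect_identical(nrow(cur), 2L)
  expect_equal(cur$ic50_um[cur$compound_id == "a"], sqrt(0.4 * 0.9))
  expect_identical(attr(cur, "report")$duplicates_collapsed, 1L)
})

test_that("curation removes missing-activity and invalid records and is idempotent", {
  records <- data.frame(
    compound_id = c("a", "b", "c", "d"),
    smiles = c("CCO", "CCCO", "C1CC", "CCCCO"),
    ic50_um = c(0.5, NA, 0.7, 3))
  cur <- curate_dataset(records)
  rep <- attr(cur, "report")
  expect_identical(rep$removed_no_activity, 1L)
  expect_identical(rep$removed_invalid_structure, 1L)
  expect_identical(cur$compound_id, c("a", "d"))
  again <- curate_dataset(cur)
  strip <- function(x) { attributes(x) <- attributes(x)[c("names", "class", "row.names")]; x }
  expect_identical(strip(again), strip(cur))
})

test_that("curation that removes everything errors with the dominant reason", {
  records <- data.frame(
    compound_id = c("a", "b"), smiles = c("CCO", "CCC"),
    ic50_um = c(NA_real_, NA_real_))
  expect_error(curate_dataset(records), "missing activity")
})

test_that("splits honour the ratio, the seed and the partition property", {
  records <- data.frame(compound_id = paste0("c", 1:10),
                        label = rep(c("active", "inactive"), 5))
  sp <- split_dataset(records, ratio = c(4, 1), seed = 3)
  expect_identical(length(sp$train_ids), 8L)
  expect_identical(length(sp$test_ids), 2L)
  sp2 <- split_dataset(records, ratio = c(4, 1), seed = 3)
  expect_identical(sp, sp2)
  for (seed in c(1, 2, 99)) {
    s <- split_dataset(records, seed = seed)
    expect_setequal(c(s$train_ids, s$test_ids), records$compound_id)
    expect_length(intersect(s$train_ids, s$test_ids), 0)
  }
})

test_that("stratified splitting preserves the class balance of an imbalanced set", {
  n_active <- 1138; n_inactive <- 285
  records <- data.frame(
    compound_id = paste0("c", seq_len(n_active + n_inactive)),
    label = rep(c("active", "inactive"), c(n_active, n_inactive)))
  sp <- split_dataset(records, ratio = c(4, 1), seed = 7, stratify = TRUE)
  frac <- function(ids) mean(records$label[match(ids, records$compound_id)] == "active")
  expect_lt(abs(frac(sp$train_ids) - frac(sp$test_ids)), 0.01)
})

test_that("one-class data cannot be stratified", {
  records <- data.frame(compound_id = paste0("c", 1:8),
                        label = rep("active", 8))
  expect_error(split_dataset(records, stratify = TRUE), "both classes")
  expect_silent(split_dataset(records, stratify = FALSE))
})
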