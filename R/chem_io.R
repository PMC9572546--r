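#' Read a compound table
#'
#' Reads compounds from CSV (canonical schema: `compound_id, smiles, name,
#' cas_number, ic50_um, label`), SMILES (`.smi`, one `SMILES<TAB>id` per
#' line) or SDF (activity carried in named data fields). Structures that the
#' chemistry backend cannot parse are not silently dropped: they are collected
#' into a rejects table attached as `attr(x, "rejects")` with the offending
#' row/line and a reason.
#'
#' @param path Path to the input file.
#' @param format One of `"csv"`, `"smi"`, `"sdf"`. Defaults to the file
#'   extension.
#' @return A compound `data.frame` in the canonical schema with a
#'   `rejects` attribute (`data.frame` with columns `row`, `compound_id`,
#'   `smiles`, `reason`).
#' @export
read_compounds <- function(path, format = c("csv", "smi", "sdf")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (missing(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("csv", "smi", "sdf")) ext else "csv"
  }
  format <- match.arg(format)
  raw <- switch(format,
    csv = read_compounds_csv(path),
    smi = read_compounds_smi(path),
    sdf = read_compounds_sdf(path)
  )
  check_compound_table(raw)
  canon <- canonical_smiles(raw$smiles)
  bad <- is.na(canon)
  rejects <- data.frame(
    row = which(bad),
    compound_id = raw$compound_id[bad],
    smiles = raw$smiles[bad],
    reason = rep("unparseable SMILES", sum(bad)),
    stringsAsFactors = FALSE
  )
  records <- raw[!bad, , drop = FALSE]
  rownames(records) <- NULL
  if (nrow(rejects)) {
    warning(sprintf("%d record(s) rejected while reading %s (see attr(x, 'rejects'))",
                    nrow(rejects), basename(path)), call. = FALSE)
  }
  attr(records, "rejects") <- rejects
  records
}

read_compounds_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("compound_id", "smiles") %in% names(df))) {
    stop("CSV must carry at least compound_id and smiles columns", call. = FALSE)
  }
  as_compound_table(df)
}

read_compounds_smi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  smiles <- vapply(parts, `[`, character(1), 1)
  ids <- vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_, character(1))
  ids[is.na(ids)] <- paste0("line", which(is.na(ids)))
  as_compound_table(data.frame(compound_id = ids, smiles = smiles,
                               stringsAsFactors = FALSE))
}

read_compounds_sdf <- function(path) {
  sdf <- ChemmineR::read.SDFset(path)
  valid <- ChemmineR::validSDF(sdf)
  sdf <- sdf[valid]
  db <- ChemmineR::datablock2ma(ChemmineR::datablock(sdf))
  get_field <- function(field) {
    if (is.matrix(db) && field %in% colnames(db)) as.character(db[, field]) else rep(NA_character_, length(sdf))
  }
  ids <- get_field("compound_id")
  if (all(is.na(ids))) ids <- ChemmineR::sdfid(sdf)
  smiles <- as.character(ChemmineR::sdf2smiles(sdf))
  df <- data.frame(
    compound_id = ids, smiles = smiles, name = get_field("name"),
    cas_number = get_field("cas_number"), ic50_um = get_field("ic50_um"),
    label = get_field("label"), stringsAsFactors = FALSE
  )
  df$ic50_um[df$ic50_um %in% c("NA", "")] <- NA
  df$label[df$label %in% c("NA", "")] <- NA
  df$name[df$name %in% c("NA", "")] <- NA
  df$cas_number[df$cas_number %in% c("NA", "")] <- NA
  as_compound_table(df)
}

#' Write a compound table
#'
#' Inverse of [read_compounds()]; round-tripping through any supported format
#' preserves ids, SMILES and activity fields.
#'
#' @param records Compound table (canonical schema).
#' @param path Output file path.
#' @param format One of `"csv"`, `"smi"`, `"sdf"`.
#' @return `path`, invisibly.
#' @export
write_compounds <- function(records, path, format = c("csv", "smi", "sdf")) {
  if (missing(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("csv", "smi", "sdf")) ext else "csv"
  }
  format <- match.arg(format)
  records <- as_compound_table(records)
  switch(format,
    csv = utils::write.csv(records, path, row.names = FALSE, na = ""),
    smi = writeLines(paste(records$smiles, records$compound_id, sep = "\t"), path),
    sdf = {
      sdf <- records_to_sdfset(records)
      ChemmineR::datablock(sdf) <- data.frame(
        compound_id = records$compound_id,
        name = ifelse(is.na(records$name), "", records$name),
        cas_number = ifelse(is.na(records$cas_number), "", records$cas_number),
        ic50_um = ifelse(is.na(records$ic50_um), "", format(records$ic50_um, trim = TRUE)),
        label = ifelse(is.na(records$label), "", records$label),
        stringsAsFactors = FALSE
      )
      ChemmineR::write.SDF(sdf, path, cid = TRUE)
    }
  )
  invisible(path)
}

#' Curate a bioactivity dataset
#'
#' Applies the standard curation rules for building a binary activity dataset
#' from an IC50 table: records with unparseable structures or no measured
#' activity are removed, duplicates (same canonical structure) are collapsed
#' to a single record whose IC50 is the geometric mean of the duplicates, and
#' labels are assigned by strict inequality `ic50_um < threshold_um`
#' (an IC50 exactly at the threshold is inactive).
#'
#' @param records Compound table with `ic50_um`.
#' @param threshold_um Activity threshold in micromolar; default 1.
#' @return The curated compound table with a `report` attribute (class
#'   `curation_report`) counting removals by reason. Curation is idempotent.
#' @export
curate_dataset <- function(records, threshold_um = 1.0) {
  check_compound_table(records)
  if (!nrow(records)) stop("records must be non-empty", call. = FALSE)
  if (!is.numeric(threshold_um) || threshold_um <= 0) {
    stop("threshold_um must be a positive real", call. = FALSE)
  }
  n_input <- nrow(records)
  records$ic50_um <- suppressWarnings(as.numeric(records$ic50_um))

  canon <- canonical_smiles(records$smiles)
  invalid <- is.na(canon)
  no_activity <- !invalid & (is.na(records$ic50_um) | records$ic50_um <= 0)
  keep <- !invalid & !no_activity
  kept <- records[keep, , drop = FALSE]
  key <- canon[keep]

  # collapse duplicates by canonical structure: geometric mean IC50,
  # identifiers from the first occurrence
  n_dup <- 0L
  if (nrow(kept) && anyDuplicated(key)) {
    groups <- split(seq_len(nrow(kept)), factor(key, levels = unique(key)))
    n_dup <- nrow(kept) - length(groups)
    first <- vapply(groups, `[`, integer(1), 1)
    agg_ic50 <- vapply(groups, function(ix) exp(mean(log(kept$ic50_um[ix]))), numeric(1))
    kept <- kept[first, , drop = FALSE]
    kept$ic50_um <- unname(agg_ic50)
  }
  kept$label <- ifelse(kept$ic50_um < threshold_um, "active", "inactive")
  rownames(kept) <- NULL

  report <- structure(list(
    n_input = n_input,
    removed_invalid_structure = sum(invalid),
    removed_no_activity = sum(no_activity),
    duplicates_collapsed = n_dup,
    n_output = nrow(kept),
    threshold_um = threshold_um,
    n_active = sum(kept$label == "active"),
    n_inactive = sum(kept$label == "inactive")
  ), class = "curation_report")

  if (!nrow(kept)) {
    reason <- if (sum(invalid) >= sum(no_activity)) "invalid structures" else "missing activity"
    stop("curation removed every record (dominant reason: ", reason, ")", call. = FALSE)
  }
  attr(kept, "report") <- report
  kept
}

#' @export
print.curation_report <- function(x, ...) {
  cat("Curation report\n")
  cat(sprintf("  input records:              %d\n", x$n_input))
  cat(sprintf("  removed, invalid structure: %d\n", x$removed_invalid_structure))
  cat(sprintf("  removed, no activity:       %d\n", x$removed_no_activity))
  cat(sprintf("  duplicates collapsed:       %d\n", x$duplicates_collapsed))
  cat(sprintf("  curated records:            %d (%d active / %d inactive at < %g uM)\n",
              x$n_output, x$n_active, x$n_inactive, x$threshold_um))
  invisible(x)
}

#' Split a curated dataset into training and test sets
#'
#' Random, by default label-stratified, partition at a given ratio (4:1 by
#' default). Deterministic for a given seed.
#'
#' @param records Curated compound table with a `label` column.
#' @param ratio Integer pair `c(train, test)`; default `c(4, 1)`.
#' @param seed Integer RNG seed.
#' @param stratify Preserve class proportions (within one compound per class)?
#' @return An object of class `dataset_split`: list with `train_ids`,
#'   `test_ids`, `ratio`, `seed`, `stratified`.
#' @export
split_dataset <- function(records, ratio = c(4, 1), seed = 1, stratify = TRUE) {
  check_compound_table(records, require = c("compound_id"))
  if (nrow(records) < 5) stop("need at least 5 records to split", call. = FALSE)
  stopifnot(length(ratio) == 2, all(ratio > 0))
  test_frac <- ratio[2] / sum(ratio)
  ids <- records$compound_id
  if (stratify) {
    if (!"label" %in% names(records) || length(unique(records$label)) < 2) {
      stop("stratified split requires both classes present; ",
           "use stratify = FALSE for a plain random split", call. = FALSE)
    }
    classes <- split(ids, records$label)
  } else {
    classes <- list(all = ids)
  }
  set.seed(as.integer(seed))
  test_ids <- unlist(lapply(classes, function(cl) {
    n_test <- round(length(cl) * test_frac)
    n_test <- max(min(n_test, length(cl) - 1L), if (length(cl) > 1) 1L else 0L)
    sample(cl, n_test)
  }), use.names = FALSE)
  structure(list(
    train_ids = setdiff(ids, test_ids),
    test_ids = test_ids,
    ratio = ratio, seed = as.integer(seed), stratified = stratify
  ), class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("Dataset split %d:%d (seed %d%s): %d train / %d test\n",
              x$ratio[1], x$ratio[2], x$seed,
              if (x$stratified) ", stratified" else "",
              length(x$train_ids), length(x$test_ids)))
  invisible(x)
}
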