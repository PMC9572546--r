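#' Canonicalize SMILES strings
#'
#' Converts SMILES to Open Babel canonical SMILES. Unparseable strings map to
#' `NA_character_`, which is how every downstream curation and descriptor step
#' recognizes an invalid structure.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES, `NA` where parsing failed.
#' @export
canonical_smiles <- function(smiles) {
  smiles <- as.character(smiles)
  out <- rep(NA_character_, length(smiles))
  ok <- !is.na(smiles) & nzchar(trimws(smiles))
  if (!any(ok)) return(out)
  # Batch conversion with tagged lines. Open Babel aborts a batch at the
  # first invalid entry, so on partial output the offending entry is marked
  # invalid and conversion resumes with the remainder; the number of batch
  # calls is one more than the number of invalid structures.
  ids <- paste0("q", seq_along(smiles))
  queue <- which(ok)
  while (length(queue)) {
    input <- paste0(paste0(smiles[queue], " ", ids[queue], collapse = "\n"), "\n")
    res <- suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", input))
    lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
    matched <- logical(length(queue))
    for (ln in lines[nzchar(trimws(lines))]) {
      parts <- strsplit(trimws(ln), "[ \t]+")[[1]]
      if (length(parts) < 2) next
      pos <- match(match(parts[length(parts)], ids), queue)
      if (!is.na(pos)) {
        out[queue[pos]] <- parts[1]
        matched[pos] <- TRUE
      }
    }
    unresolved <- which(!matched)
    if (!length(unresolved)) break
    # the first unresolved entry stopped the batch: it stays NA (invalid);
    # everything after it goes back on the queue
    queue <- queue[unresolved[-1]]
  }
  out
}

#' Convert compound records to an SDF set
#'
#' @param records Compound table with `compound_id` and `smiles` columns.
#' @return A `ChemmineR::SDFset` with molecule CMP ids set to `compound_id`.
#' @keywords internal
records_to_sdfset <- function(records) {
  smi <- records$smiles
  names(smi) <- records$compound_id
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smi))
  ChemmineR::cid(sdf) <- records$compound_id
  sdf
}

# Shared validation of the compound-table schema.
check_compound_table <- function(records, require = c("compound_id", "smiles")) {
  if (!is.data.frame(records)) {
    stop("records must be a data.frame (see compound table schema)", call. = FALSE)
  }
  missing <- setdiff(require, names(records))
  if (length(missing)) {
    stop("compound table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(records$compound_id)) {
    stop("compound_id values must be unique within a dataset", call. = FALSE)
  }
  invisible(records)
}

# Empty compound table in the canonical column order.
empty_compound_table <- function() {
  data.frame(
    compound_id = character(), smiles = character(), name = character(),
    cas_number = character(), ic50_um = numeric(), label = character(),
    stringsAsFactors = FALSE
  )
}

# Coerce an arbitrary data.frame to the canonical compound schema, filling
# optional columns with NA.
as_compound_table <- function(df) {
  n <- nrow(df)
  grab <- function(col, numeric = FALSE) {
    if (col %in% names(df)) {
      if (numeric) suppressWarnings(as.numeric(df[[col]])) else as.character(df[[col]])
    } else {
      if (numeric) rep(NA_real_, n) else rep(NA_character_, n)
    }
  }
  out <- data.frame(
    compound_id = grab("compound_id"),
    smiles = grab("smiles"),
    name = grab("name"),
    cas_number = grab("cas_number"),
    ic50_um = grab("ic50_um", numeric = TRUE),
    label = grab("label"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
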