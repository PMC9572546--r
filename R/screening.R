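admet_numeric_cols <- c("mw", "logp", "hbd", "hba", "logs", "hia_percent", "mce18")
admet_flag_cols <- c("bbb_permeant", "tox_mutagenicity", "tox_carcinogenicity",
                     "tox_hepatotoxicity", "tox_oral_acute_toxicity")

check_admet <- function(records) {
  needed <- c(admet_numeric_cols, admet_flag_cols)
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    stop("ADMET annotation incomplete; missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in needed) {
    if (anyNA(records[[col]])) {
      stop("ADMET field contains missing values: ", col, call. = FALSE)
    }
  }
  if (any(records$hia_percent < 0 | records$hia_percent > 100)) {
    stop("hia_percent must lie in [0, 100]", call. = FALSE)
  }
  invisible(records)
}

#' Dual-confidence activity filter
#'
#' A library compound passes only when both fused-model confidences reach the
#' screening threshold: `conf_voting >= threshold` AND
#' `conf_stacking >= threshold` (0.8 by default).
#'
#' @param records Screening table with `conf_voting` and `conf_stacking`.
#' @param threshold Confidence threshold; default 0.8.
#' @return The passing records, with a `counts` attribute
#'   (`n_input`, `n_pass`).
#' @export
activity_filter <- function(records, threshold = 0.8) {
  for (col in c("conf_voting", "conf_stacking")) {
    if (!col %in% names(records) || anyNA(records[[col]])) {
      stop("missing confidence column or values: ", col, call. = FALSE)
    }
  }
  pass <- records$conf_voting >= threshold & records$conf_stacking >= threshold
  out <- records[pass, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "counts") <- c(n_input = nrow(records), n_pass = sum(pass))
  out
}

#' Rule-based drug-likeness / ADMET filter
#'
#' A compound passes only if it satisfies every rule: Lipinski's Rule of
#' Five (MW <= 500 Da, logP <= 5, H-bond donors <= 5, acceptors <= 10; at
#' most `lipinski_max_violations` violations, zero by default), aqueous
#' solubility −4 <= LogS <= 0.5 (log10 mol/L), human intestinal absorption
#' > 30%, MCE-18 structural-evolution score > 45, blood-brain-barrier
#' permeant, and no toxicity flag (mutagenicity, carcinogenicity,
#' hepatotoxicity, oral acute toxicity). All annotations are upstream
#' predictions consumed as inputs; this filter never predicts properties
#' itself.
#'
#' @param records Screening table with the ADMET annotation columns
#'   (`mw, logp, hbd, hba, logs, hia_percent, mce18, bbb_permeant, tox_*`).
#' @param lipinski_max_violations Allowed Rule-of-Five violations; default 0.
#' @return The passing records, with a `tally` attribute counting failures
#'   per rule.
#' @export
druglikeness_filter <- function(records, lipinski_max_violations = 0) {
  check_admet(records)
  violations <- (records$mw > 500) + (records$logp > 5) +
    (records$hbd > 5) + (records$hba > 10)
  rules <- cbind(
    Lipinski = violations <= lipinski_max_violations,
    LogS = records$logs >= -4 & records$logs <= 0.5,
    HIA = records$hia_percent > 30,
    MCE18 = records$mce18 > 45,
    BBB = as.logical(records$bbb_permeant),
    Toxicity = !(as.logical(records$tox_mutagenicity) |
                 as.logical(records$tox_carcinogenicity) |
                 as.logical(records$tox_hepatotoxicity) |
                 as.logical(records$tox_oral_acute_toxicity))
  )
  pass <- rowSums(rules) == ncol(rules)
  out <- records[pass, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tally") <- colSums(!rules)
  attr(out, "counts") <- c(n_input = nrow(records), n_pass = sum(pass))
  out
}

#' Fingerprint provider backed by Open Babel FP2
#'
#' @return Function mapping a compound table to a binary fingerprint matrix
#'   (rows = compounds, 1024 FP2 bits).
#' @export
ob_fingerprint_provider <- function() {
  function(records) {
    canon <- canonical_smiles(records$smiles)
    if (anyNA(canon)) {
      stop("unparseable structure(s): ",
           paste(utils::head(records$compound_id[is.na(canon)], 5), collapse = ", "),
           call. = FALSE)
    }
    fp <- ChemmineR::fingerprintOB(records_to_sdfset(records), "FP2")@fpma
    if (is.null(dim(fp))) fp <- matrix(fp, nrow = 1)
    rownames(fp) <- records$compound_id
    fp
  }
}

#' Tanimoto similarity matrix and hierarchical clustering
#'
#' Pairwise Tanimoto similarity over binary fingerprints with an
#' average-linkage tree over `1 - similarity`, the standard view of the
#' structural diversity of a screened hit list.
#'
#' @param records Compound table (>= 2 rows).
#' @param fp_provider Function `records -> binary matrix`; default the
#'   Open Babel FP2 provider.
#' @return List with `similarity` (symmetric, unit diagonal) and `tree`
#'   (an `hclust` object, average linkage).
#' @export
similarity_cluster <- function(records, fp_provider = ob_fingerprint_provider()) {
  if (nrow(records) < 2) stop("need at least 2 records to cluster", call. = FALSE)
  fp <- fp_provider(records)
  fp <- (fp > 0) * 1
  counts <- fp %*% t(fp)
  n_bits <- rowSums(fp)
  union <- outer(n_bits, n_bits, "+") - counts
  sim <- ifelse(union > 0, counts / union, 0)
  diag(sim) <- 1
  dimnames(sim) <- list(rownames(fp), rownames(fp))
  tree <- stats::hclust(stats::as.dist(1 - sim), method = "average")
  list(similarity = sim, tree = tree)
}

#' Consensus score of ensemble confidence and docking affinity
#'
#' The machine-learning sub-score is the mean of the two fused-model
#' confidences; the docking sub-score is the ratio of the compound's binding
#' free energy to the reference (co-crystallized ligand) affinity, capped at
#' 1 for compounds that out-dock the reference; an unfavourable (positive)
#' energy scores 0 with a warning. The total score is the mean of the two
#' sub-scores; all three lie in \[0, 1\].
#'
#' @param conf_voting,conf_stacking Fused-model confidences in \[0, 1\].
#' @param docking_energy_kcal Binding free energies in kcal/mol (negative =
#'   favourable).
#' @param reference_energy_kcal Reference affinity; must be negative.
#'   Default −10.6 kcal/mol.
#' @return Data frame `s_ml, s_dock, s_total` (vectorized over the inputs).
#' @export
consensus_score <- function(conf_voting, conf_stacking, docking_energy_kcal,
                            reference_energy_kcal = -10.6) {
  if (!is.finite(reference_energy_kcal) || reference_energy_kcal == 0) {
    stop("reference energy must be a nonzero negative value", call. = FALSE)
  }
  if (reference_energy_kcal > 0) {
    stop("reference energy must be negative (favourable binding)", call. = FALSE)
  }
  stopifnot(length(conf_voting) == length(conf_stacking),
            length(conf_voting) == length(docking_energy_kcal))
  if (anyNA(conf_voting) || anyNA(conf_stacking) || anyNA(docking_energy_kcal)) {
    stop("confidences and docking energies must be complete", call. = FALSE)
  }
  s_ml <- (conf_voting + conf_stacking) / 2
  s_dock <- pmin(1, docking_energy_kcal / reference_energy_kcal)
  if (any(docking_energy_kcal > 0)) {
    warning("positive (unfavourable) docking energy; docking sub-score set to 0",
            call. = FALSE)
    s_dock[docking_energy_kcal > 0] <- 0
  }
  data.frame(s_ml = s_ml, s_dock = s_dock, s_total = (s_ml + s_dock) / 2)
}

#' Score a screening library
#'
#' Adds `s_ml`, `s_dock`, `s_total` columns via [consensus_score()].
#'
#' @param records Screening table with `conf_voting`, `conf_stacking`,
#'   `docking_energy_kcal`.
#' @param reference_energy_kcal Reference affinity; default −10.6.
#' @return `records` with the three score columns appended.
#' @export
score_library <- function(records, reference_energy_kcal = -10.6) {
  scores <- consensus_score(records$conf_voting, records$conf_stacking,
                            records$docking_energy_kcal,
                            reference_energy_kcal = reference_energy_kcal)
  cbind(records, scores)
}

#' Rank scored candidates and select the high-consensus subset
#'
#' Sorts descending by total score with a stable tie-break on `compound_id`,
#' and flags compounds whose total score strictly exceeds the selection
#' threshold.
#'
#' @param records Scored screening table (with `s_total`).
#' @param select_threshold Selection cut on `s_total` (strict >); default 0.8.
#' @return The table sorted by rank with `rank` and `selected` columns.
#' @export
rank_candidates <- function(records, select_threshold = 0.8) {
  if (!"s_total" %in% names(records)) {
    stop("records must be scored first (see score_library)", call. = FALSE)
  }
  ord <- order(-records$s_total, records$compound_id)
  out <- records[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$selected <- out$s_total > select_threshold
  rownames(out) <- NULL
  out
}
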