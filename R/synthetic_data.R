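#' Pool of valid synthetic SMILES
#'
#' Enumerated substitutions (side chain and alkyl tail) on a small set of
#' aromatic/aliphatic scaffolds. The structures are chemically valid and
#' mutually distinct so parser- and fingerprint-dependent code paths run;
#' chemical realism is not attempted.
#'
#' @param n Number of distinct SMILES required.
#' @return Character vector of `n` distinct SMILES.
#' @export
synth_smiles_pool <- function(n) {
  scaffolds <- c("c1ccccc1", "c1ccncc1", "c1ccoc1", "c1ccsc1", "C1CCCCC1",
                 "C1CCNCC1", "c1ccc2ccccc2c1", "c1ccc2[nH]ccc2c1",
                 "C1CCOC1", "c1cncnc1")
  # a unique side chain per index: the binary digits of i become a linear
  # C (0) / N (1) chain, so no two entries can collapse to the same
  # canonical structure
  chain <- vapply(seq_len(n), function(i) {
    bits <- as.integer(intToBits(i))
    bits <- bits[seq_len(max(which(bits == 1)))]
    paste(c("C", "N")[bits + 1], collapse = "")
  }, character(1))
  paste0(scaffolds[((seq_len(n) - 1) %% length(scaffolds)) + 1], chain)
}

#' Synthetic QSAR dataset with planted feature pathologies
#'
#' Generates a descriptor/label dataset with known ground truth emulating a
#' curated kinase bioactivity set: class-conditional Gaussian informative
#' features (class means separated by `effect_size` standard deviations),
#' plus exactly `n_constant` constant columns, `n_duplicated` exact copies of
#' informative columns and `n_independent` label-free noise columns. A small
#' fraction of labels is flipped (`label_noise`) so classifiers cannot
#' saturate; IC50 values are drawn consistently with the final label
#' (actives below 1 uM, inactives above). Deterministic given the seed.
#'
#' @param n_active,n_inactive Class sizes; defaults 1138 and 285.
#' @param n_features Total descriptor count; default 208.
#' @param n_constant,n_duplicated,n_independent Planted pathology counts
#'   (defaults 12, 20, 40); the remainder are informative.
#' @param effect_size Standardized class-mean shift of each informative
#'   feature; default 0.6.
#' @param label_noise Label flip probability; default 0.05.
#' @param seed Integer seed.
#' @return List with `records` (compound table incl. `ic50_um`, `label`),
#'   `descriptors` (a raw `descriptor_matrix`), `labels` (character vector
#'   aligned with rows) and `manifest` (feature roles and per-compound truth).
#' @export
synth_qsar_dataset <- function(n_active = 1138, n_inactive = 285,
                               n_features = 208, n_constant = 12,
                               n_duplicated = 20, n_independent = 40,
                               effect_size = 0.6, label_noise = 0.05,
                               seed = 1) {
  n_informative <- n_features - n_constant - n_duplicated - n_independent
  if (n_informative < 1) {
    stop("pathology counts must sum to less than n_features", call. = FALSE)
  }
  if (effect_size < 0) stop("effect_size must be non-negative", call. = FALSE)
  set.seed(as.integer(seed))
  n <- n_active + n_inactive
  true_class <- sample(rep(c(1L, 0L), c(n_active, n_inactive)))
  flip <- stats::runif(n) < label_noise
  y <- ifelse(flip, 1L - true_class, true_class)

  informative <- sapply(seq_len(n_informative), function(j) {
    stats::rnorm(n, mean = effect_size * true_class)
  })
  colnames(informative) <- sprintf("inf_%03d", seq_len(n_informative))
  independent <- if (n_independent) {
    ind <- sapply(seq_len(n_independent), function(j) stats::rnorm(n))
    colnames(ind) <- sprintf("noise_%03d", seq_len(n_independent))
    ind
  } else NULL
  constant <- if (n_constant) {
    cm <- sapply(seq_len(n_constant), function(j) rep(j * 1.5, n))
    colnames(cm) <- sprintf("const_%03d", seq_len(n_constant))
    cm
  } else NULL
  dup_src <- if (n_duplicated) {
    sample(n_informative, n_duplicated, replace = n_duplicated > n_informative)
  } else integer(0)
  duplicated_m <- if (n_duplicated) {
    dm <- informative[, dup_src, drop = FALSE]
    colnames(dm) <- sprintf("dup_%03d", seq_len(n_duplicated))
    dm
  } else NULL

  values <- cbind(informative, independent, constant, duplicated_m)
  ids <- sprintf("syn%05d", seq_len(n))
  rownames(values) <- ids
  labels <- ifelse(y == 1, "active", "inactive")
  ic50 <- ifelse(y == 1, 10^stats::runif(n, -2, -0.05), 10^stats::runif(n, 0.05, 2))
  records <- as_compound_table(data.frame(
    compound_id = ids, smiles = synth_smiles_pool(n),
    ic50_um = ic50, label = labels, stringsAsFactors = FALSE
  ))
  roles <- data.frame(
    descriptor = colnames(values),
    role = rep(c("informative", "independent", "constant", "duplicated"),
               c(n_informative, n_independent, n_constant, n_duplicated)),
    copy_of = c(rep(NA_character_, n_features - n_duplicated),
                sprintf("inf_%03d", dup_src)),
    stringsAsFactors = FALSE
  )
  list(records = records,
       descriptors = descriptor_matrix(values, provenance = "raw"),
       labels = labels,
       manifest = list(feature_roles = roles, true_class = true_class,
                       flipped = flip, effect_size = effect_size,
                       label_noise = label_noise, seed = as.integer(seed)))
}

#' Synthetic annotated screening library
#'
#' Emulates a natural-product screening library with precomputed ensemble
#' confidences, ADMET annotations and docking energies, with the planted
#' truth (which compounds pass the dual-confidence filter, which pass every
#' drug-likeness rule and which rules the others break) recorded in the
#' manifest.
#'
#' @param n Library size; default 4112.
#' @param fraction_dual_high Fraction with both fused-model confidences at or
#'   above 0.8; default 343/4112.
#' @param admet_pass_fraction Fraction passing every drug-likeness rule;
#'   default 22/343.
#' @param energy_range_kcal Docking energy range (kcal/mol); default
#'   `c(-11, -5)`.
#' @param seed Integer seed.
#' @return List with `records` (screening table in the `library.csv` schema)
#'   and `manifest` (data frame of per-compound planted truth).
#' @export
synth_screening_library <- function(n = 4112, fraction_dual_high = 343 / 4112,
                                    admet_pass_fraction = 22 / 343,
                                    energy_range_kcal = c(-11, -5), seed = 1) {
  stopifnot(fraction_dual_high >= 0, fraction_dual_high <= 1,
            admet_pass_fraction >= 0, admet_pass_fraction <= 1)
  set.seed(as.integer(seed))
  ids <- sprintf("lib%05d", seq_len(n))
  n_dual <- round(n * fraction_dual_high)
  dual <- seq_len(n) %in% sample(n, n_dual)
  conf_voting <- stats::runif(n)
  conf_stacking <- stats::runif(n)
  conf_voting[dual] <- stats::runif(n_dual, 0.8, 1)
  conf_stacking[dual] <- stats::runif(n_dual, 0.8, 1)
  both_high <- !dual & conf_voting >= 0.8 & conf_stacking >= 0.8
  conf_stacking[both_high] <- stats::runif(sum(both_high), 0, 0.799)

  n_pass <- round(n * admet_pass_fraction)
  admet_pass <- seq_len(n) %in% sample(n, n_pass)
  ann <- data.frame(
    mw = stats::runif(n, 200, 480), logp = stats::runif(n, -1, 4.5),
    hbd = sample(0:4, n, replace = TRUE), hba = sample(2:9, n, replace = TRUE),
    logs = stats::runif(n, -3.8, 0.4), hia_percent = stats::runif(n, 35, 100),
    mce18 = stats::runif(n, 50, 120), bbb_permeant = TRUE,
    tox_mutagenicity = FALSE, tox_carcinogenicity = FALSE,
    tox_hepatotoxicity = FALSE, tox_oral_acute_toxicity = FALSE
  )
  rule_breakers <- list(
    Lipinski = function(df, i) { df$mw[i] <- stats::runif(length(i), 520, 700); df },
    LogS = function(df, i) { df$logs[i] <- stats::runif(length(i), -6, -4.2); df },
    HIA = function(df, i) { df$hia_percent[i] <- stats::runif(length(i), 0, 28); df },
    MCE18 = function(df, i) { df$mce18[i] <- stats::runif(length(i), 20, 44); df },
    BBB = function(df, i) { df$bbb_permeant[i] <- FALSE; df },
    Toxicity = function(df, i) { df$tox_hepatotoxicity[i] <- TRUE; df }
  )
  broken <- rep("", n)
  fail_ix <- which(!admet_pass)
  if (length(fail_ix)) {
    which_rule <- sample(names(rule_breakers), length(fail_ix), replace = TRUE)
    for (rule in names(rule_breakers)) {
      ix <- fail_ix[which_rule == rule]
      if (length(ix)) ann <- rule_breakers[[rule]](ann, ix)
    }
    broken[fail_ix] <- which_rule
  }
  energy <- stats::runif(n, energy_range_kcal[1], energy_range_kcal[2])
  records <- cbind(
    data.frame(compound_id = ids, smiles = synth_smiles_pool(n) [sample(n)],
               conf_voting = conf_voting, conf_stacking = conf_stacking,
               stringsAsFactors = FALSE),
    ann,
    data.frame(docking_energy_kcal = energy)
  )
  manifest <- data.frame(compound_id = ids, dual_high = dual,
                         admet_pass = admet_pass, broken_rule = broken,
                         docking_energy_kcal = energy,
                         stringsAsFactors = FALSE)
  list(records = records, manifest = manifest)
}

#' Synthetic dose-response plate readings
#'
#' Back-computes plate signal ratios from a four-parameter logistic
#' inhibition curve so that [percent_inhibition()] recovers the planted curve
#' exactly at zero noise: sample ratio
#' `R = R_noCompound - inh/100 * (R_noCompound - R_noKinase)`, with both
#' control roles included. Multiplicative Gaussian noise of relative
#' standard deviation `ratio_noise_sd` is applied to every well.
#'
#' @param ic50_um Planted IC50 (relative midpoint), micromolar.
#' @param hill Hill slope; default 1.
#' @param top,bottom Curve asymptotes (%); defaults 100 and 0.
#' @param concentrations Tested concentrations; default the 50 uM two-fold
#'   ten-point series.
#' @param ratio_noise_sd Relative noise SD on signal ratios; default 0.
#' @param seed Integer seed.
#' @param r_no_compound,r_no_kinase Control signal ratios (assay window);
#'   defaults 2.0 and 0.5.
#' @param control_replicates,sample_replicates Wells per control role /
#'   concentration; defaults 2 and 1.
#' @return Plate data frame (`well, role, concentration_um, signal_ratio`)
#'   with the planted curve in `attr(x, "truth")`.
#' @export
synth_dose_response <- function(ic50_um = 10, hill = 1, top = 100, bottom = 0,
                                concentrations = dilution_series(),
                                ratio_noise_sd = 0, seed = 1,
                                r_no_compound = 2.0, r_no_kinase = 0.5,
                                control_replicates = 2, sample_replicates = 1) {
  stopifnot(ic50_um > 0, all(concentrations > 0))
  set.seed(as.integer(seed))
  conc <- rep(sort(concentrations, decreasing = TRUE), each = sample_replicates)
  inh <- fourpl(log10(conc), bottom, top, log10(ic50_um), hill)
  ratios <- r_no_compound - inh / 100 * (r_no_compound - r_no_kinase)
  plate <- rbind(
    data.frame(role = "no_compound_control", concentration_um = 0,
               signal_ratio = rep(r_no_compound, control_replicates)),
    data.frame(role = "no_kinase_control", concentration_um = 0,
               signal_ratio = rep(r_no_kinase, control_replicates)),
    data.frame(role = "sample", concentration_um = conc, signal_ratio = ratios)
  )
  if (ratio_noise_sd > 0) {
    plate$signal_ratio <- plate$signal_ratio *
      (1 + stats::rnorm(nrow(plate), sd = ratio_noise_sd))
  }
  plate <- cbind(well = sprintf("W%02d", seq_len(nrow(plate))), plate)
  attr(plate, "truth") <- list(ic50_um = ic50_um, hill = hill, top = top,
                               bottom = bottom, seed = as.integer(seed))
  plate
}
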