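#' Construct a descriptor matrix
#'
#' A descriptor matrix is a numeric matrix with compounds as rows
#' (`rownames` = compound ids) and named descriptors as columns, plus a
#' `provenance` attribute (`"raw"`, `"standardized"` or `"selected"`).
#'
#' @param values Numeric matrix with dimnames.
#' @param provenance Free-text provenance tag.
#' @return The matrix with class `descriptor_matrix`.
#' @export
descriptor_matrix <- function(values, provenance = "raw") {
  values <- as.matrix(values)
  if (is.null(colnames(values))) stop("descriptor columns must be named", call. = FALSE)
  if (anyDuplicated(colnames(values))) stop("descriptor names must be unique", call. = FALSE)
  if (nrow(values) && anyNA(values)) {
    stop("descriptor matrix must not contain missing values", call. = FALSE)
  }
  structure(values, provenance = provenance,
            class = c("descriptor_matrix", class(values)))
}

provenance <- function(x) attr(x, "provenance")

# Preserve the class/provenance through column subsetting.
set_provenance <- function(x, provenance) {
  attr(x, "provenance") <- provenance
  if (!inherits(x, "descriptor_matrix")) class(x) <- c("descriptor_matrix", class(x))
  x
}

#' The built-in 208-descriptor panel backed by Open Babel
#'
#' A descriptor provider computing a fixed, ordered panel of 208 named
#' numeric descriptors per molecule: 8 global physicochemical properties
#' (hydrogen-bond acceptor counts under two definitions, donor count, logP,
#' molar refractivity, molecular weight, fluorine count, topological polar
#' surface area), 10 heavy-element counts, and 190 hashed structural-fragment
#' counts obtained by folding the 1024-bit FP2 path fingerprint into 190
#' buckets. Deterministic: repeated calls on the same structure give
#' bit-identical rows.
#'
#' @return A `descriptor_provider` object with fields `name`,
#'   `descriptor_names` (length 208) and `compute(records)`.
#' @export
ob_descriptor_provider <- function() {
  prop_names <- c("HBA1", "HBA2", "HBD", "logP", "MR", "MW", "nF", "TPSA")
  elements <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B")
  n_fp <- 190L
  panel <- c(paste0("ob_", prop_names), paste0("elem_", elements),
             sprintf("fp2_b%03d", seq_len(n_fp)))
  compute <- function(records) {
    check_compound_table(records)
    if (!nrow(records)) {
      return(list(values = matrix(numeric(0), 0, length(panel),
                                  dimnames = list(NULL, panel)),
                  rejects = data.frame(compound_id = character(),
                                       reason = character(),
                                       stringsAsFactors = FALSE)))
    }
    canon <- canonical_smiles(records$smiles)
    bad <- is.na(canon)
    rejects <- data.frame(compound_id = records$compound_id[bad],
                          reason = rep("unparseable SMILES", sum(bad)),
                          stringsAsFactors = FALSE)
    ok <- records[!bad, , drop = FALSE]
    if (!nrow(ok)) {
      return(list(values = matrix(numeric(0), 0, length(panel),
                                  dimnames = list(NULL, panel)),
                  rejects = rejects))
    }
    sdf <- records_to_sdfset(ok)
    props <- ChemmineR::propOB(sdf)
    pm <- as.matrix(props[, prop_names, drop = FALSE])
    ac <- ChemmineR::atomcountMA(sdf, addH = FALSE)
    if (is.null(dim(ac))) ac <- matrix(ac, nrow = 1, dimnames = list(NULL, names(ac)))
    em <- matrix(0, nrow(ok), length(elements),
                 dimnames = list(NULL, elements))
    shared <- intersect(colnames(ac), elements)
    em[, shared] <- ac[, shared, drop = FALSE]
    fp <- ChemmineR::fingerprintOB(sdf, "FP2")@fpma
    if (is.null(dim(fp))) fp <- matrix(fp, nrow = 1)
    bucket <- ((seq_len(ncol(fp)) - 1L) %% n_fp) + 1L
    fold <- vapply(seq_len(n_fp), function(j) as.numeric(bucket == j),
                   numeric(ncol(fp)))
    fm <- fp %*% fold
    values <- cbind(pm, em, fm)
    colnames(values) <- panel
    rownames(values) <- ok$compound_id
    nan_rows <- apply(values, 1, function(r) any(!is.finite(r)))
    if (any(nan_rows)) {
      for (i in which(nan_rows)) {
        dname <- panel[which(!is.finite(values[i, ]))[1]]
        rejects <- rbind(rejects, data.frame(
          compound_id = rownames(values)[i],
          reason = paste0("non-finite descriptor: ", dname),
          stringsAsFactors = FALSE))
      }
      values <- values[!nan_rows, , drop = FALSE]
    }
    list(values = values, rejects = rejects)
  }
  structure(list(name = "openbabel-208", descriptor_names = panel,
                 compute = compute),
            class = "descriptor_provider")
}

#' A file-backed descriptor provider
#'
#' Reads a precomputed descriptor matrix (CSV with first column
#' `compound_id`, remaining columns named descriptors) and serves rows on
#' demand, so the pipeline's numerics can run without a chemistry toolkit.
#'
#' @param path CSV file of precomputed descriptors.
#' @return A `descriptor_provider`.
#' @export
file_descriptor_provider <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "compound_id") {
    stop("descriptor CSV must have compound_id as its first column", call. = FALSE)
  }
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$compound_id
  panel <- colnames(values)
  compute <- function(records) {
    check_compound_table(records, require = "compound_id")
    found <- records$compound_id %in% rownames(values)
    rejects <- data.frame(compound_id = records$compound_id[!found],
                          reason = rep("not present in descriptor file", sum(!found)),
                          stringsAsFactors = FALSE)
    list(values = values[records$compound_id[found], , drop = FALSE],
         rejects = rejects)
  }
  structure(list(name = paste0("file:", basename(path)),
                 descriptor_names = panel, compute = compute),
            class = "descriptor_provider")
}

#' Compute molecular descriptors for a set of compounds
#'
#' @param records Compound table.
#' @param provider A `descriptor_provider`; default the built-in 208-panel
#'   Open Babel provider.
#' @return A `descriptor_matrix` (provenance `"raw"`) with one row per
#'   successfully processed record, a `rejects` attribute for failures, and a
#'   `panel` attribute recording the provider's name list.
#' @export
compute_descriptors <- function(records, provider = ob_descriptor_provider()) {
  stopifnot(inherits(provider, "descriptor_provider"))
  res <- provider$compute(records)
  m <- descriptor_matrix(res$values, provenance = "raw")
  attr(m, "rejects") <- res$rejects
  attr(m, "panel") <- list(name = provider$name,
                           descriptor_names = provider$descriptor_names)
  if (nrow(res$rejects)) {
    warning(sprintf("%d record(s) rejected during descriptor computation",
                    nrow(res$rejects)), call. = FALSE)
  }
  m
}

#' Fit a feature standardizer on a training matrix
#'
#' Column means and standard deviations fitted on the training rows only.
#' Constant columns get scale 1 so they map to exactly 0 rather than dividing
#' by zero. Test matrices are transformed with the training parameters,
#' never refitted.
#'
#' @param matrix Descriptor matrix (training rows).
#' @return An object of class `standardizer`.
#' @export
fit_standardizer <- function(matrix) {
  m <- as.matrix(matrix)
  center <- colMeans(m)
  scale <- apply(m, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  structure(list(center = center, scale = scale,
                 descriptor_names = colnames(m)),
            class = "standardizer")
}

#' Apply a fitted standardizer
#'
#' @param std A `standardizer` from [fit_standardizer()].
#' @param matrix Descriptor matrix whose columns must exactly match the
#'   standardizer's descriptor names.
#' @return Standardized `descriptor_matrix` (provenance `"standardized"`).
#' @export
apply_standardizer <- function(std, matrix) {
  stopifnot(inherits(std, "standardizer"))
  m <- as.matrix(matrix)
  if (!identical(colnames(m), std$descriptor_names)) {
    extra <- setdiff(colnames(m), std$descriptor_names)
    missing <- setdiff(std$descriptor_names, colnames(m))
    stop("descriptor names do not match the fitted standardizer",
         if (length(missing)) paste0("; missing: ", paste(utils::head(missing, 5), collapse = ", ")),
         if (length(extra)) paste0("; unseen: ", paste(utils::head(extra, 5), collapse = ", ")),
         call. = FALSE)
  }
  out <- sweep(sweep(m, 2, std$center, "-"), 2, std$scale, "/")
  descriptor_matrix(out, provenance = "standardized")
}

#' Fit a principal-component chemical-space model
#'
#' PCA on a standardized descriptor matrix, retaining the requested number of
#' components together with the training score ranges per component (used by
#' the applicability domain).
#'
#' @param matrix Standardized descriptor matrix.
#' @param n_components Number of components to retain (2 or 3 typical).
#' @return An object of class `chemspace_model` with orthonormal loadings,
#'   non-increasing explained-variance ratios and per-component training
#'   min/max ranges.
#' @export
fit_chemspace <- function(matrix, n_components = 2) {
  m <- as.matrix(matrix)
  if (n_components > ncol(m)) {
    stop("n_components exceeds the number of descriptors", call. = FALSE)
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  ev_ratio <- pc$sdev^2 / sum(pc$sdev^2)
  k <- n_components
  scores <- pc$x[, seq_len(k), drop = FALSE]
  structure(list(
    center = pc$center,
    loadings = pc$rotation[, seq_len(k), drop = FALSE],
    ev_ratio = ev_ratio[seq_len(k)],
    ranges = apply(scores, 2, range),
    n_components = k
  ), class = "chemspace_model")
}

#' Project compounds into a fitted chemical space
#'
#' @param model A `chemspace_model`.
#' @param matrix Standardized descriptor matrix with the same columns the
#'   model was fitted on.
#' @return Data frame `compound_id, pc1..pcN`.
#' @export
project_chemspace <- function(model, matrix) {
  stopifnot(inherits(model, "chemspace_model"))
  m <- as.matrix(matrix)
  if (!identical(colnames(m), rownames(model$loadings))) {
    stop("descriptor names do not match the chemical-space model", call. = FALSE)
  }
  scores <- sweep(m, 2, model$center, "-") %*% model$loadings
  out <- data.frame(compound_id = rownames(m) %||% seq_len(nrow(m)),
                    scores, stringsAsFactors = FALSE)
  names(out) <- c("compound_id", paste0("pc", seq_len(model$n_components)))
  rownames(out) <- NULL
  out
}

#' Applicability-domain check by chemical-space coverage
#'
#' A compound is in-domain iff each of its first two principal-component
#' coordinates lies within the training range, optionally widened by
#' `margin` times the training range on each side.
#'
#' @param model A `chemspace_model`.
#' @param matrix Standardized descriptor matrix of the compounds to check.
#' @param margin Fractional widening of the training box; default 0.
#' @return List with `flags` (data frame `compound_id, pc1, pc2, in_domain`)
#'   and `overlap_fraction` (share of compounds in-domain).
#' @export
applicability_domain <- function(model, matrix, margin = 0) {
  coords <- project_chemspace(model, matrix)
  k <- min(2L, model$n_components)
  inside <- rep(TRUE, nrow(coords))
  for (j in seq_len(k)) {
    rng <- model$ranges[, j]
    width <- diff(rng)
    lo <- rng[1] - margin * width
    hi <- rng[2] + margin * width
    v <- coords[[paste0("pc", j)]]
    inside <- inside & v >= lo & v <= hi
  }
  flags <- cbind(coords[, seq_len(k + 1), drop = FALSE], in_domain = inside)
  list(flags = flags,
       overlap_fraction = if (nrow(flags)) mean(inside) else NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
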