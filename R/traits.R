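#' Derive growth rates from mass, head width and development time
#'
#' Appends the two growth-rate traits: `grm` = mass / dev_time (mg/day) and
#' `grh` = head_width / dev_time (mm/day).
#'
#' @param pheno a `phenotype_table` with trait columns.
#' @return the table with `grm` and `grh` appended.
#' @export
derive_growth_rates <- function(pheno) {
  for (col in c("mass", "head_width", "dev_time"))
    if (!col %in% names(pheno)) stopf("missing trait column '%s'", col)
  if (any(pheno$dev_time == 0)) stopf("dev_time of 0 day; growth rate undefined")
  pheno$grm <- pheno$mass / pheno$dev_time
  pheno$grh <- pheno$head_width / pheno$dev_time
  pheno
}

#' Default trait transformation map
#'
#' Head width and wing pad length are log-transformed; the growth rates are
#' arcsine-transformed (plain `asin(x)`, domain \[0, 1\]); mass and
#' development time enter untransformed.
#'
#' @return named character vector trait -> one of `"log"`, `"arcsin"`, `"none"`.
#' @export
default_transforms <- function() {
  c(mass = "none", head_width = "log", wing_pad = "log",
    dev_time = "none", grm = "arcsin", grh = "arcsin")
}

#' Build the transformed trait matrix for canonical analysis
#'
#' @param pheno a `phenotype_table` including derived growth rates.
#' @param transforms named vector as from [default_transforms()]; names select
#'   which traits enter the matrix.
#' @return numeric matrix (individuals x traits) with `rownames` the
#'   individual ids; transformed columns keep their trait names.
#' @export
transform_traits <- function(pheno, transforms = default_transforms()) {
  out <- matrix(NA_real_, nrow(pheno), length(transforms),
                dimnames = list(pheno$individual_id, names(transforms)))
  for (trait in names(transforms)) {
    if (!trait %in% names(pheno)) stopf("trait '%s' not in phenotype table", trait)
    v <- as.numeric(pheno[[trait]])
    out[, trait] <- switch(transforms[[trait]],
      none = v,
      log = {
        bad <- which(v <= 0)
        if (length(bad))
          stopf("log transform of non-positive %s at row %d", trait, bad[1])
        log(v)
      },
      arcsin = {
        bad <- which(v < 0 | v > 1)
        if (length(bad))
          stopf("arcsin input for %s outside [0, 1] at row %d (value %.4g); rescale the trait to a proportion first",
                trait, bad[1], v[bad[1]])
        asin(v)
      },
      stopf("unknown transform '%s' for trait '%s'", transforms[[trait]], trait))
  }
  if (any(!is.finite(out))) stopf("non-finite transformed trait value")
  out
}

#' Screen collinear traits by Spearman rank correlation
#'
#' Computes all pairwise Spearman correlations; while any pair exceeds the
#' threshold in absolute value, the member of a violating pair with the
#' largest mean absolute correlation against all remaining variables is
#' dropped (ties broken alphabetically), then correlations are re-examined.
#' The comparison is strict (`|r| > threshold`) except at a threshold of
#' exactly 1, where `|r| >= 1` is used so duplicate columns are still
#' removable.
#'
#' @param tm numeric trait matrix (individuals x traits).
#' @param threshold absolute Spearman correlation above which a trait is
#'   considered redundant; default 0.9.
#' @return list with `retained` (filtered matrix), `dropped` (character),
#'   and `correlations` (the full initial Spearman matrix).
#' @export
collinearity_screen <- function(tm, threshold = 0.9) {
  stopifnot(is.matrix(tm), ncol(tm) >= 2, nrow(tm) >= 3,
            threshold > 0, threshold <= 1)
  if (any(apply(tm, 2, stats::sd) == 0))
    stopf("constant trait column '%s': rank correlation undefined",
          colnames(tm)[which(apply(tm, 2, stats::sd) == 0)[1]])
  rho_full <- stats::cor(tm, method = "spearman")
  over <- function(r) if (threshold == 1) abs(r) >= 1 else abs(r) > threshold
  keep <- sort(colnames(tm))
  dropped <- character(0)
  repeat {
    r <- rho_full[keep, keep, drop = FALSE]
    diag(r) <- 0
    if (!any(over(r))) break
    offenders <- keep[apply(over(r), 1, any)]
    mean_abs <- (rowSums(abs(r)) / (length(keep) - 1))[offenders]
    victim <- offenders[order(-mean_abs)][1]  # order() is stable: ties fall back to name order
    dropped <- c(dropped, victim)
    keep <- setdiff(keep, victim)
    if (length(keep) < 2) break
  }
  retained <- tm[, intersect(colnames(tm), keep), drop = FALSE]
  list(retained = retained, dropped = dropped, correlations = rho_full)
}
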