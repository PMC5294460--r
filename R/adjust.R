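#' Adjust a phenotype for fixed effects and structure PCs
#'
#' Fits an ordinary least squares model of the trait on an intercept,
#' dummy-coded categorical covariates (year, farm, gender), continuous
#' covariates (fattening days, entering weight), and the structure PC
#' scores, and returns the residuals. The residuals are the "corrected
#' phenotype" used by the gene-based scan.
#'
#' Rows with missing covariates or trait values are dropped listwise; the
#' count is reported in the model summary. Categorical covariates are
#' dummy-coded against their first level (residuals do not depend on the
#' coding). A rank-deficient design raises an error naming the aliased
#' columns.
#'
#' @param pheno data.frame with columns `id`, the trait, and any covariates
#'   named in `covariates`.
#' @param trait name of the trait column.
#' @param pcs optional [structure_pcs()] object (or a numeric matrix with
#'   rownames) whose scores enter the design, aligned by individual id.
#' @param covariates character vector of covariate column names present in
#'   `pheno`; character/factor columns are treated as categorical.
#' @return object of class `AdjustedPhenotype`: `id`, `residuals` (named
#'   by id), and `model` (n used, n dropped, R-squared, coefficient names).
#' @export
adjust_phenotype <- function(pheno, trait, pcs = NULL,
                             covariates = intersect(
                               c("year", "farm", "gender",
                                 "fattening_days", "entering_weight"),
                               names(pheno))) {
  stopifnot(is.data.frame(pheno), "id" %in% names(pheno),
            trait %in% names(pheno))
  df <- pheno[, c("id", trait, covariates), drop = FALSE]
  if (!is.null(pcs)) {
    scores <- if (inherits(pcs, "StructurePCs")) pcs$scores else as.matrix(pcs)
    if (is.null(rownames(scores)))
      stop("PC scores must carry individual ids as rownames")
    idx <- match(df$id, rownames(scores))
    if (anyNA(idx))
      stop("PC scores missing for individual(s): ",
           paste(utils::head(df$id[is.na(idx)], 5), collapse = ", "))
    pc_df <- as.data.frame(scores[idx, , drop = FALSE])
    names(pc_df) <- colnames(scores)
    df <- cbind(df, pc_df)
  }
  complete <- stats::complete.cases(df)
  n_dropped <- sum(!complete)
  if (n_dropped > 0)
    message("adjust_phenotype: dropped ", n_dropped,
            " row(s) with incomplete trait/covariates")
  df <- df[complete, , drop = FALSE]
  if (nrow(df) == 0) stop("no complete rows to fit")

  for (v in covariates)
    if (is.character(df[[v]])) df[[v]] <- factor(df[[v]])
  rhs <- setdiff(names(df), c("id", trait))
  form <- stats::reformulate(if (length(rhs)) rhs else "1",
                             response = as.name(trait))
  fit <- stats::lm(form, data = df)
  aliased <- is.na(stats::coef(fit))
  if (any(aliased))
    stop("rank-deficient design; aliased column(s): ",
         paste(names(stats::coef(fit))[aliased], collapse = ", "))
  res <- stats::residuals(fit)
  names(res) <- df$id
  structure(list(
    id = df$id,
    residuals = res,
    model = list(trait = trait, n = nrow(df), n_dropped = n_dropped,
                 r_squared = summary(fit)$r.squared,
                 terms = names(stats::coef(fit)))
  ), class = "AdjustedPhenotype")
}

#' @export
print.AdjustedPhenotype <- function(x, ...) {
  cat(sprintf("AdjustedPhenotype '%s': n = %d (%d dropped), R^2 = %.3f\n",
              x$model$trait, x$model$n, x$model$n_dropped, x$model$r_squared))
  invisible(x)
}

#' Write adjusted phenotypes as TSV
#' @param x an `AdjustedPhenotype`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_adjusted <- function(x, path) {
  utils::write.table(data.frame(id = x$id, residual = unname(x$residuals)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
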