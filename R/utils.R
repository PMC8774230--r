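#' Derive a stage seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its own seed from the master
#' seed through this function, so a stage can be re-run in isolation and
#' reproduce exactly what it did inside the full pipeline. The scheme is a
#' small deterministic hash: the stage label is folded into the master seed
#' with a fixed multiplier, modulo 2^31 - 2 (R seeds are 32-bit integers).
#'
#' @param master integer master seed.
#' @param label character stage label (e.g. `"iter17"`, `"genes"`).
#' @return an integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(label))
  m <- 2147483646 # 2^31 - 2
  h <- as.double(master) %% m
  for (k in utf8ToInt(label)) h <- (h * 69069 + k) %% m
  as.integer(h + 1)
}

# histology levels accepted throughout the package
.histologies <- c("chRCC", "RO", "N", "other")

#' Validate an expression matrix
#'
#' @param x numeric matrix, genes/probes in rows, samples in columns.
#' @param what label used in error messages.
#' @return `x`, invisibly, after checks.
#' @keywords internal
validate_expression <- function(x, what = "expression matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(what, " must have row and column names", call. = FALSE)
  dup <- rownames(x)[duplicated(rownames(x))]
  if (length(dup))
    stop(what, " has duplicated row ids: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  dup <- colnames(x)[duplicated(colnames(x))]
  if (length(dup))
    stop(what, " has duplicated sample ids: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(x)))
    stop(what, " contains non-finite values; impute or drop them explicitly",
         call. = FALSE)
  invisible(x)
}

#' Validate a phenotype table
#'
#' @param pheno data.frame with columns `sample`, `histology`, `batch`.
#' @param expr optional expression matrix whose columns must all be covered.
#' @return `pheno`, invisibly.
#' @keywords internal
validate_phenotype <- function(pheno, expr = NULL) {
  need <- c("sample", "histology", "batch")
  if (!is.data.frame(pheno) || !all(need %in% names(pheno)))
    stop("phenotype table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(pheno$sample))
    stop("phenotype sample ids are not unique", call. = FALSE)
  bad <- setdiff(unique(as.character(pheno$histology)), .histologies)
  if (length(bad))
    stop("unknown histology label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.null(expr)) {
    missing <- setdiff(colnames(expr), pheno$sample)
    if (length(missing))
      stop("samples absent from phenotype table: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(pheno)
}

# row-wise means/vars without heavy dependencies
.row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2) return(rep(NA_real_, nrow(x)))
  rowSums((x - rowMeans(x))^2) / (n - 1)
}
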