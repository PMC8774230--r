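#' Read an expression table
#'
#' Parses the plain TSV dialect used throughout the package: a header row of
#' sample ids, first column of row ids, tab-separated numeric cells. Lines
#' starting with `!` (series-matrix style metadata) are skipped. The matrix
#' is normalized to genes/probes in rows; pass `orientation = "samples"` when
#' the file stores samples in rows.
#'
#' @param path file path.
#' @param orientation `"genes"` (default, rows are genes/probes) or
#'   `"samples"` (rows are samples; the matrix is transposed after reading).
#' @return numeric matrix, genes/probes x samples.
#' @export
read_expression <- function(path, orientation = c("genes", "samples")) {
  orientation <- match.arg(orientation)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "!")]
  if (length(lines) < 2) stop("expression file has no data rows: ", path)
  con <- textConnection(lines)
  on.exit(close(con))
  df <- utils::read.table(con, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = "character")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicated row id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(m), dim(m), dimnames(m)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(m), arr.ind = TRUE)
    if (nrow(bad) == 0) bad <- which(is.na(num), arr.ind = TRUE)
    stop("non-numeric or missing cell in ", path, " at row '",
         ids[bad[1, 1]], "', column '", colnames(m)[bad[1, 2]], "'")
  }
  rownames(num) <- ids
  if (orientation == "samples") num <- t(num)
  validate_expression(num)
  num
}

#' Write an expression table
#'
#' Inverse of [read_expression()]; values are written with full double
#' precision so write-then-read round-trips are lossless.
#'
#' @param x numeric matrix, genes/probes x samples.
#' @param path destination file.
#' @param id_name header of the id column.
#' @export
write_expression <- function(x, path, id_name = "id") {
  validate_expression(x)
  header <- paste(c(id_name, colnames(x)), collapse = "\t")
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], format(x[i, ], digits = 17, trim = TRUE,
                                   scientific = FALSE)), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read / write a phenotype table
#'
#' CSV with columns `sample`, `histology` (one of chRCC, RO, N, other) and
#' `batch`.
#'
#' @param path file path.
#' @return data.frame with character columns `sample`, `histology`, `batch`.
#' @export
read_phenotype <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  validate_phenotype(df)
  df
}

#' @rdname read_phenotype
#' @param pheno phenotype data.frame.
#' @export
write_phenotype <- function(pheno, path) {
  validate_phenotype(pheno)
  utils::write.csv(pheno, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write probe annotation
#'
#' Two-column TSV mapping probe ids to gene symbols; probes mapping several
#' genes occupy several rows.
#'
#' @param path file path.
#' @return data.frame with columns `probe`, `gene`.
#' @export
read_annotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character")
  if (!all(c("probe", "gene") %in% names(df)))
    stop("annotation needs columns 'probe' and 'gene'")
  df
}

#' @rdname read_annotation
#' @param ann annotation data.frame.
#' @export
write_annotation <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then members. Duplicate members within a set are dropped; empty sets and
#' duplicated set names are errors.
#'
#' @param path file path.
#' @return named list of character vectors; each carries a `description`
#'   attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("malformed GMT line ", i, " in ", path,
           " (need name, description, >=1 member)")
    name <- f[1]
    if (name %in% names(sets))
      stop("duplicated set name '", name, "' at GMT line ", i)
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0) stop("empty set '", name, "' at GMT line ", i)
    attr(members, "description") <- f[2]
    sets[[name]] <- members
  }
  if (length(sets) == 0) stop("no gene sets in ", path)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors (optional `description`
#'   attributes).
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description")
    if (is.null(desc)) desc <- ""
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a signature table as JSON
#'
#' @param signature data.frame as returned by [run_cascade()].
#' @param path destination.
#' @export
write_signature <- function(signature, path) {
  jsonlite::write_json(signature, path, dataframe = "rows", digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  df <- jsonlite::fromJSON(path)
  stopifnot(is.data.frame(df), "gene" %in% names(df))
  df
}

#' Write a consensus result as JSON (+ iteration matrix TSV)
#'
#' @param consensus a `dbu_consensus` object from [run_ensemble()].
#' @param path JSON destination; the iteration-by-sample assignment matrix is
#'   written next to it with suffix `.iterations.tsv`.
#' @export
write_consensus <- function(consensus, path) {
  stopifnot(inherits(consensus, "dbu_consensus"))
  out <- list(
    samples = names(consensus$assignment),
    group = unname(consensus$assignment),
    support = unname(consensus$support),
    threshold = consensus$threshold,
    n_iterations = consensus$n_iterations
  )
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  it <- consensus$iterations
  utils::write.table(it, paste0(path, ".iterations.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}
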