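# File-format adapters. TSV dialect: tab-delimited, UTF-8, mandatory header
# row, "." for missing values. All coordinates in files are 1-based
# inclusive. FASTA goes through Biostrings (CRLF and line wrapping handled
# there); JSON through jsonlite.

#' Read parent protein sequences from FASTA
#'
#' @param path Path to a single- or multi-record amino-acid FASTA file.
#' @return A [parent_proteins()] table; record descriptions are preserved
#'   in the `description` column, the first whitespace-delimited token
#'   becomes the `chain_id`.
#' @export
read_parent_fasta <- function(path) {
  parent_proteins(Biostrings::readAAStringSet(path))
}

#' Packaged bovine hemoglobin chains
#'
#' Mature alpha (141 aa) and beta (145 aa) chains of bovine hemoglobin,
#' the parent proteins of the worked examples.
#'
#' @return A [parent_proteins()] table with chains `alpha` and `beta`.
#' @export
bovine_hemoglobin <- function() {
  read_parent_fasta(system.file("extdata", "bovine_hemoglobin.fasta",
                                package = "scissile", mustWork = TRUE))
}

read_tsv_checked <- function(path, required, numeric_cols = character()) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          na.strings = ".", stringsAsFactors = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s: missing required column(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  for (col in intersect(numeric_cols, names(df))) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) & is.na(vals))
    if (length(bad))
      stop(sprintf("%s: non-numeric value '%s' in column '%s', row %d",
                   path, df[[col]][bad[1]], col, bad[1]), call. = FALSE)
    df[[col]] <- vals
  }
  df
}

#' Read an observed-ion list
#'
#' @param path TSV with required column `mz` (optional `intensity`, ignored
#'   by matching). Non-numeric values are rejected naming the row.
#' @return A data frame with numeric `mz` (and `intensity` if present).
#' @export
read_ion_tsv <- function(path) {
  read_tsv_checked(path, "mz", c("mz", "intensity"))
}

#' Read a product-peptide list
#'
#' @param path TSV with columns among `enzyme`, `chain`, `start`, `end`,
#'   `sequence` (`start`/`end` optional when `sequence` is given).
#' @return A data frame ready for [map_peptides()].
#' @export
read_peptide_tsv <- function(path) {
  df <- read_tsv_checked(path, character(), c("start", "end"))
  if (!any(c("sequence", "start") %in% names(df)))
    stop(path, ": need a sequence column or start/end coordinates",
         call. = FALSE)
  df
}

#' Read PS-SCL sublibrary hydrolysis rates
#'
#' @param path TSV with columns `subsite`, `residue`, `rate` (optional
#'   `sem`).
#' @return A data frame for [normalize_psscl()].
#' @export
read_psscl_tsv <- function(path) {
  read_tsv_checked(path, c("subsite", "residue", "rate"), c("rate", "sem"))
}

#' Read an activity series
#'
#' @param path TSV with columns `time_min`, `value` (optional
#'   `temperature`, `ph`).
#' @return A data frame.
#' @export
read_activity_tsv <- function(path) {
  read_tsv_checked(path, c("time_min", "value"),
                   c("time_min", "value", "temperature", "ph"))
}

#' Write a data frame in the canonical TSV dialect
#'
#' Tab-delimited, UTF-8, header row, `"."` for missing values; writing and
#' re-reading a canonical table is the identity.
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_canonical <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = ".",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read tagged-substrate definitions from JSON
#'
#' Each record carries `id`, `sequence`, `n_mod`, `c_mod` (modification
#' names or null) and `parent_offset`.
#'
#' @param path Path to a JSON array.
#' @param registry Optional modification registry ([read_modifications()]).
#' @return A named list of [tagged_substrate()] objects.
#' @export
read_substrates_json <- function(path, registry = NULL) {
  recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  subs <- lapply(recs, function(r) {
    tagged_substrate(
      id = r$id, sequence = r$sequence,
      n_mod = if (!is.null(r$n_mod)) get_modification(r$n_mod, registry),
      c_mod = if (!is.null(r$c_mod)) get_modification(r$c_mod, registry),
      parent_offset = if (!is.null(r$parent_offset)) r$parent_offset else 1L)
  })
  names(subs) <- vapply(subs, `[[`, "", "id")
  subs
}

#' Read / write a specificity matrix as JSON
#'
#' The JSON form is `{"threshold": x, "weights": {subsite: {residue: w}}}`;
#' `NA` (no-information) weights are simply absent.
#'
#' @param path File path.
#' @return `read_matrix_json()`: a [specificity_matrix()];
#'   `write_matrix_json()`: `path`, invisibly.
#' @export
read_matrix_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  w <- lapply(obj$weights, function(x) unlist(x))
  specificity_matrix(w, threshold = if (!is.null(obj$threshold))
    obj$threshold else 0.5)
}

#' @rdname read_matrix_json
#' @param matrix A [specificity_matrix()].
#' @export
write_matrix_json <- function(matrix, path) {
  w <- apply(matrix$weights, 1, function(row) {
    as.list(row[!is.na(row)])
  }, simplify = FALSE)
  jsonlite::write_json(list(threshold = matrix$threshold, weights = w),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
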