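# PS-SCL profile normalization, specificity matrices, in-silico digestion
# and concordance between library-derived and degradome-derived specificity.
#
# A specificity matrix holds per-subsite residue preference weights in
# [0, 1], max-normalized per subsite. Subsites P4..P1 sit N-terminal of the
# scissile bond, P1'..P2' C-terminal. Residues absent from a panel (PS-SCL
# libraries commonly omit Cys) carry NA weight -- "no information" -- which
# is distinct from a measured weight of zero ("forbidden").

.MATRIX_SUBSITES <- c("P4", "P3", "P2", "P1", "P1'", "P2'")

#' Normalize a PS-SCL rate profile
#'
#' Rescales each subsite's hydrolysis rates to percent of that subsite's
#' maximum, the conventional presentation of positional-scanning library
#' data.
#'
#' @param rates A data frame with columns `subsite`, `residue`, `rate`
#'   (RFU/min, >= 0), e.g. from [read_psscl_tsv()] or [gen_psscl()].
#' @return The same data frame with a `percent` column added (per-subsite
#'   % of maximum; zero rates map to 0).
#' @examples
#' d <- data.frame(subsite = "P1", residue = c("R", "K", "A"),
#'                 rate = c(8, 4, 2))
#' normalize_psscl(d)$percent  # 100, 50, 25
#' @export
normalize_psscl <- function(rates) {
  stopifnot(all(c("subsite", "residue", "rate") %in% names(rates)))
  if (any(rates$rate < 0)) stop("rates must be >= 0", call. = FALSE)
  rates$percent <- NA_real_
  for (s in unique(rates$subsite)) {
    i <- rates$subsite == s
    mx <- max(rates$rate[i])
    if (mx <= 0)
      stop("all rates are zero at subsite ", s, call. = FALSE)
    rates$percent[i] <- 100 * rates$rate[i] / mx
  }
  rates
}

#' Construct a specificity matrix
#'
#' @param weights A numeric matrix (subsites x residues) or a named list of
#'   named residue-weight vectors. Weights are max-normalized to `[0, 1]`
#'   per subsite; residues not present get `NA` (no information).
#' @param threshold Cut-score threshold in `[0, 1]` used by
#'   [predict_cleavage()] (default 0.5).
#' @return An object of class `specificity_matrix`: list with `weights`
#'   (matrix, subsites x 20 residues), `subsites`, `threshold`.
#' @export
specificity_matrix <- function(weights, threshold = 0.5) {
  if (threshold < 0 || threshold > 1)
    stop("threshold must be in [0, 1]", call. = FALSE)
  if (is.list(weights) && !is.data.frame(weights)) {
    subs <- names(weights)
    m <- matrix(NA_real_, length(subs), 20,
                dimnames = list(subs, names(.MONO_RESIDUE)))
    for (s in subs) {
      w <- weights[[s]]
      stopifnot(!is.null(names(w)), all(names(w) %in% colnames(m)))
      m[s, names(w)] <- w
    }
    weights <- m
  }
  stopifnot(is.matrix(weights), !is.null(rownames(weights)))
  if (!all(rownames(weights) %in% .SUBSITES))
    stop("subsite names must be among ", paste(.SUBSITES, collapse = ", "),
         call. = FALSE)
  full <- matrix(NA_real_, nrow(weights), 20,
                 dimnames = list(rownames(weights), names(.MONO_RESIDUE)))
  full[, colnames(weights)] <- weights
  for (s in rownames(full)) {
    mx <- max(full[s, ], na.rm = TRUE)
    if (!is.finite(mx) || mx <= 0)
      stop("subsite ", s, " has no positive weight", call. = FALSE)
    full[s, ] <- full[s, ] / mx
  }
  if (any(full < 0, na.rm = TRUE))
    stop("weights must be >= 0", call. = FALSE)
  structure(list(weights = full, subsites = rownames(full),
                 threshold = threshold),
            class = "specificity_matrix")
}

#' @export
print.specificity_matrix <- function(x, ...) {
  cat(sprintf("<specificity matrix> subsites %s, threshold %.2f\n",
              paste(x$subsites, collapse = ", "), x$threshold))
  top <- apply(x$weights, 1, function(w) {
    w <- w[!is.na(w)]
    paste(names(sort(w, decreasing = TRUE))[1:3], collapse = ",")
  })
  cat("  top residues:",
      paste(sprintf("%s:{%s}", names(top), top), collapse = "  "), "\n")
  invisible(x)
}

#' Build a specificity matrix from profile or degradome data
#'
#' From a normalized PS-SCL profile, weights are `percent / 100`; from a
#' [subsite_table()], weights are per-subsite frequency over maximum
#' frequency. Both end max-normalized to 1 per subsite.
#'
#' @param source A data frame with `subsite`, `residue`, `percent` (output
#'   of [normalize_psscl()]) or a `subsite_table`.
#' @param threshold Threshold stored in the matrix (default 0.5).
#' @return A [specificity_matrix()].
#' @export
build_matrix <- function(source, threshold = 0.5) {
  if (inherits(source, "subsite_table")) {
    m <- unclass(source)
    attr(m, "n_sites") <- NULL; attr(m, "truncated") <- NULL
    return(specificity_matrix(m / pmax(apply(m, 1, max), 1), threshold))
  }
  stopifnot(is.data.frame(source),
            all(c("subsite", "residue") %in% names(source)))
  if (is.null(source$percent)) source <- normalize_psscl(source)
  if (!nrow(source)) stop("empty source", call. = FALSE)
  subs <- unique(source$subsite)
  w <- lapply(subs, function(s) {
    i <- source$subsite == s
    setNames(source$percent[i] / 100, source$residue[i])
  })
  names(w) <- subs
  specificity_matrix(w, threshold)
}

# Score every internal bond of a sequence under a specificity matrix.
# Subsite k maps to sequence position: P1 -> i, P2 -> i-1, ..., P1' -> i+1.
# Out-of-range subsites and NA-weight (no-information) residues are skipped;
# a bond with no scorable subsite gets NA.
score_bonds <- function(sequence, matrix,
                        score_rule = c("min", "product", "mean")) {
  score_rule <- match.arg(score_rule)
  chars <- check_sequence(sequence)
  n <- length(chars)
  if (!length(matrix$subsites)) stop("matrix has no subsites", call. = FALSE)
  offsets <- c("P4" = -3L, "P3" = -2L, "P2" = -1L, "P1" = 0L,
               "P1'" = 1L, "P2'" = 2L, "P3'" = 3L, "P4'" = 4L)
  vapply(seq_len(n - 1L), function(i) {
    vals <- c()
    for (s in matrix$subsites) {
      pos <- i + offsets[[s]]
      if (pos < 1L || pos > n) next
      w <- matrix$weights[s, chars[pos]]
      if (is.na(w)) next
      vals <- c(vals, w)
    }
    if (!length(vals)) return(NA_real_)
    switch(score_rule,
           min = min(vals),
           product = prod(vals),
           mean = mean(vals))
  }, numeric(1))
}

#' Predict cleavage of a parent protein in silico
#'
#' Scores every internal peptide bond under a specificity matrix and
#' reports the bonds at or above the matrix threshold together with the
#' peptide partition induced by cutting all of them (a full digest).
#'
#' The default combination rule is `min`: a single forbidden residue at any
#' covered subsite vetoes cleavage of that bond, which reproduces the
#' behaviour of papain-family proteinases whose S2 pocket rejects
#' particular residues. `product` and `mean` are available for graded
#' scoring. Subsites falling off a chain end, and residues the matrix has
#' no information for, are skipped rather than scored zero, so terminal
#' bonds are not forbidden by construction.
#'
#' @param parent A sequence string, or one row of a [parent_proteins()]
#'   table.
#' @param matrix A [specificity_matrix()].
#' @param score_rule `"min"` (default), `"product"` or `"mean"`.
#' @param threshold Override of the matrix threshold.
#' @return A list of class `cleavage_prediction`: `bonds` (data frame
#'   `position`, `p1`, `p1p`, `score`, `predicted`), `predicted_sites`
#'   (bond positions), `peptides` (data frame `start`, `end`, `sequence`
#'   of the full-digest partition), `score_rule`, `threshold`.
#' @export
predict_cleavage <- function(parent, matrix,
                             score_rule = c("min", "product", "mean"),
                             threshold = NULL) {
  score_rule <- match.arg(score_rule)
  if (inherits(parent, "parent_proteins") || is.data.frame(parent)) {
    stopifnot(nrow(parent) == 1L)
    sequence <- parent$sequence
  } else sequence <- parent
  if (is.null(threshold)) threshold <- matrix$threshold
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  if (n <= length(matrix$subsites))
    stop("parent shorter than the matrix span", call. = FALSE)

  score <- score_bonds(sequence, matrix, score_rule)
  predicted <- !is.na(score) & score >= threshold
  bonds <- data.frame(position = seq_len(n - 1L),
                      p1 = chars[-n], p1p = chars[-1],
                      score = score, predicted = predicted,
                      stringsAsFactors = FALSE)
  cuts <- bonds$position[predicted]
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  peptides <- data.frame(start = starts, end = ends,
                         sequence = substring(sequence, starts, ends),
                         stringsAsFactors = FALSE)
  structure(list(bonds = bonds, predicted_sites = cuts, peptides = peptides,
                 score_rule = score_rule, threshold = threshold),
            class = "cleavage_prediction")
}

#' @export
print.cleavage_prediction <- function(x, ...) {
  cat(sprintf("<cleavage prediction> %d/%d bonds >= %.2f (%s rule) -> %d peptides\n",
              length(x$predicted_sites), nrow(x$bonds), x$threshold,
              x$score_rule, nrow(x$peptides)))
  invisible(x)
}

#' Concordance between a specificity matrix and observed cleavage sites
#'
#' For each subsite shared between the matrix and the site contexts,
#' computes the Spearman rank correlation between the matrix weights and
#' the observed residue frequencies at that subsite, plus the overlap of
#' the top-`top_n` residue sets. Requires at least 5 sites.
#'
#' @param matrix A [specificity_matrix()].
#' @param sites A `cleavage_sites` data frame ([extract_sites()]).
#' @param top_n Size of the top-residue sets compared (default 3).
#' @return A data frame per shared subsite: `subsite`, `spearman`,
#'   `top_overlap` (0..`top_n`), `top_matrix`, `top_observed`; attribute
#'   `mean_spearman`.
#' @export
concordance <- function(matrix, sites, top_n = 3L) {
  if (nrow(sites) < 5L)
    stop("need at least 5 cleavage sites for concordance", call. = FALSE)
  shared <- intersect(matrix$subsites, .SUBSITES[.SUBSITES %in% names(sites)])
  if (!length(shared)) stop("no shared subsites", call. = FALSE)
  rows <- lapply(shared, function(s) {
    res <- sites[[s]]
    res <- res[!is.na(res)]
    freq <- table(factor(res, levels = names(.MONO_RESIDUE)))
    w <- matrix$weights[s, ]
    use <- !is.na(w)
    rho <- stats::cor(w[use], as.numeric(freq)[use], method = "spearman")
    topm <- names(sort(w[use], decreasing = TRUE))[seq_len(top_n)]
    topo <- names(sort(freq, decreasing = TRUE))[seq_len(top_n)]
    data.frame(subsite = s, spearman = rho,
               top_overlap = length(intersect(topm, topo)),
               top_matrix = paste(topm, collapse = ","),
               top_observed = paste(topo, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "mean_spearman") <- mean(out$spearman)
  out
}
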