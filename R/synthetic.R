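# Seeded generators emulating every input the analysis stages consume:
# partial digests under a specificity matrix with detection dropout, PS-SCL
# rate data with multiplicative noise, first-order activity decay, and ion
# lists with Gaussian mass error. All are bit-reproducible given a seed;
# each generator scopes its RNG use so callers' RNG state is untouched.

with_seed <- function(seed, code) {
  if (is.null(seed)) stop("a seed is mandatory for generators", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a partial digest of a parent protein
#'
#' Each internal bond of the parent is cut independently with probability
#' `cut_probability_scale * score`, where the score comes from the
#' specificity matrix under `score_rule`. The resulting peptides (segments
#' between consecutive cuts, including the chain ends) are then thinned:
#' dropped with probability `detection_dropout` or when shorter than
#' `min_peptide_length`, emulating MS detection loss. The true cut set is
#' returned alongside the observed intervals.
#'
#' @param parent One row of a [parent_proteins()] table, or a sequence
#'   string (then labelled chain `"chain1"`).
#' @param matrix A [specificity_matrix()].
#' @param cut_probability_scale Scale on bond scores, in `[0, 1]`.
#' @param detection_dropout Per-peptide drop probability, in `[0, 1]`.
#' @param min_peptide_length Shorter peptides are never detected.
#' @param seed Mandatory integer seed.
#' @param score_rule Bond-score combination rule (see
#'   [predict_cleavage()]); `"product"` makes observed subsite frequencies
#'   proportional to matrix weights on a uniform background, which is the
#'   regime recovery tests use.
#' @return A list: `intervals` (data frame `chain`, `start`, `end`,
#'   `sequence`, `enzyme`), `true_cuts` (integer bond positions),
#'   `bond_probabilities`.
#' @export
gen_digest <- function(parent, matrix, cut_probability_scale = 1,
                       detection_dropout = 0, min_peptide_length = 1L,
                       seed, score_rule = "min") {
  if (is.character(parent) && length(parent) == 1L)
    parent <- parent_proteins(c(chain1 = parent))
  stopifnot(nrow(parent) == 1L,
            cut_probability_scale >= 0, cut_probability_scale <= 1,
            detection_dropout >= 0, detection_dropout <= 1)
  sequence <- parent$sequence
  chain <- parent$chain_id
  score <- score_bonds(sequence, matrix, score_rule)
  p <- cut_probability_scale * ifelse(is.na(score), 0, score)
  if (all(p == 0)) warning("degenerate matrix: no bond has positive cut probability")

  with_seed(seed, {
    cuts <- which(stats::runif(length(p)) < p)
    n <- nchar(sequence)
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, n)
    keep <- (ends - starts + 1L) >= min_peptide_length
    keep <- keep & (stats::runif(length(starts)) >= detection_dropout)
    intervals <- data.frame(
      enzyme = "synthetic", chain = chain,
      start = starts[keep], end = ends[keep],
      sequence = substring(sequence, starts[keep], ends[keep]),
      stringsAsFactors = FALSE)
    list(intervals = intervals, true_cuts = as.integer(cuts),
         bond_probabilities = p)
  })
}

#' Simulate PS-SCL rate data from a known specificity matrix
#'
#' Rates are proportional to the matrix weights with multiplicative
#' Gaussian noise (`rate = w * (1 + N(0, noise_sigma))`, truncated at 0).
#' Residues with `NA` weight (outside the panel) are omitted from the
#' dataset, as a real sublibrary panel would omit them.
#'
#' @param matrix A [specificity_matrix()].
#' @param noise_sigma Relative noise SD (>= 0).
#' @param seed Mandatory integer seed.
#' @param ph pH label attached to the dataset (default 4.5, the acidic
#'   assay condition).
#' @param max_rate Rate corresponding to weight 1, in RFU/min.
#' @return A data frame `subsite`, `residue`, `rate` with attribute `ph`.
#' @export
gen_psscl <- function(matrix, noise_sigma = 0, seed, ph = 4.5,
                      max_rate = 100) {
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  w <- matrix$weights
  with_seed(seed, {
    rows <- list()
    for (s in rownames(w)) {
      res <- colnames(w)[!is.na(w[s, ])]
      base <- max_rate * w[s, res]
      noisy <- pmax(0, base * (1 + stats::rnorm(length(base), 0, noise_sigma)))
      rows[[s]] <- data.frame(subsite = s, residue = res, rate = unname(noisy),
                              stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "ph") <- ph
    out
  })
}

#' Simulate an exponential activity-decay series
#'
#' `activity = a0 * exp(-k1 * t) * (1 + N(0, noise_sigma))`, truncated at 0.
#'
#' @param k1 Inactivation constant per minute (>= 0).
#' @param times Time points in minutes.
#' @param noise_sigma Relative noise SD (>= 0).
#' @param seed Mandatory integer seed.
#' @param a0 Initial activity (default 100, i.e. percent remaining).
#' @return A data frame `time_min`, `activity`.
#' @examples
#' gen_decay(log(2) / 8, seq(0, 14, 2), 0, seed = 1)
#' @export
gen_decay <- function(k1, times, noise_sigma = 0, seed, a0 = 100) {
  if (k1 < 0) stop("k1 must be >= 0", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  with_seed(seed, {
    mu <- a0 * exp(-k1 * times)
    data.frame(
      time_min = times,
      activity = pmax(0, mu * (1 + stats::rnorm(length(times), 0, noise_sigma))))
  })
}

#' Simulate an observed ion list from known cut sets
#'
#' Each cut set (a vector of substrate-internal cut positions) partitions
#' the tagged substrate into pieces: the first retains the N-terminal tag,
#' the last the C-terminal tag, middles are untagged. The theoretical
#' singly protonated m/z of every piece across all cut sets is perturbed
#' by Gaussian mass error.
#'
#' @param substrate A [tagged_substrate()].
#' @param cut_sets A list of integer vectors (or a single vector) of cut
#'   positions; each set represents one co-occurring combination of cuts.
#' @param mass_error_sigma Mass error SD in Da (>= 0).
#' @param seed Mandatory integer seed.
#' @param mode Mass mode (default monoisotopic).
#' @return A numeric vector of observed m/z values (one per distinct
#'   fragment, deduplicated before noise).
#' @export
gen_ions <- function(substrate, cut_sets, mass_error_sigma = 0, seed,
                     mode = "monoisotopic") {
  if (mass_error_sigma < 0)
    stop("mass_error_sigma must be >= 0", call. = FALSE)
  if (!is.list(cut_sets)) cut_sets <- list(cut_sets)
  n <- nchar(substrate$sequence)
  frags <- list()
  for (cs in cut_sets) {
    cs <- sort(unique(as.integer(cs)))
    stopifnot(all(cs >= 1L), all(cs < n))
    starts <- c(1L, cs + 1L)
    ends <- c(cs, n)
    for (k in seq_along(starts)) {
      key <- paste(starts[k], ends[k])
      if (!is.null(frags[[key]])) next
      mass <- peptide_mass(
        substr(substrate$sequence, starts[k], ends[k]),
        n_mod = if (starts[k] == 1L) substrate$n_mod,
        c_mod = if (ends[k] == n) substrate$c_mod,
        mode = mode)
      frags[[key]] <- to_mz(mass, 1L)
    }
  }
  mz <- unname(unlist(frags))
  with_seed(seed, mz + stats::rnorm(length(mz), 0, mass_error_sigma))
}
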