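# Degradome mapping: locate identified product peptides on parent chains,
# extract scissile bonds from peptide termini, tabulate Schechter-Berger
# subsite occupancies (P4..P4'), and annotate hemocidins -- antimicrobial
# hemoglobin fragments -- by interval comparison against a reference list.
#
# Coordinates are 1-based inclusive on the mature chain; a scissile bond is
# indexed by its N-side residue (the bond between residues i and i+1).

.SUBSITES <- c("P4", "P3", "P2", "P1", "P1'", "P2'", "P3'", "P4'")

#' Assemble a parent-protein table
#'
#' @param x A named character vector of sequences (names are chain ids), a
#'   data frame with columns `chain_id` and `sequence`, or a
#'   `Biostrings::AAStringSet` (e.g. from [read_parent_fasta()]).
#' @return A data frame with columns `chain_id`, `sequence`, `length`,
#'   `description`, of class `parent_proteins`.
#' @examples
#' parent_proteins(c(alpha = "VLSAADK", beta = "MLTAEEK"))
#' @export
parent_proteins <- function(x) {
  if (inherits(x, "parent_proteins")) return(x)
  if (inherits(x, "AAStringSet")) {
    ids <- sub("\\s.*$", "", names(x))
    desc <- sub("^\\S+\\s*", "", names(x))
    x <- data.frame(chain_id = ids, sequence = as.character(x),
                    description = desc, stringsAsFactors = FALSE)
  } else if (is.character(x)) {
    if (is.null(names(x))) stop("sequences must be named by chain id",
                                call. = FALSE)
    x <- data.frame(chain_id = names(x), sequence = unname(x),
                    description = "", stringsAsFactors = FALSE)
  }
  if (!all(c("chain_id", "sequence") %in% names(x)))
    stop("need columns chain_id and sequence", call. = FALSE)
  if (anyDuplicated(x$chain_id))
    stop("duplicated chain_id in parent table", call. = FALSE)
  for (i in seq_len(nrow(x)))
    check_sequence(x$sequence[i], paste0("chain '", x$chain_id[i], "'"))
  x$length <- nchar(x$sequence)
  if (is.null(x$description)) x$description <- ""
  out <- x[, c("chain_id", "sequence", "length", "description")]
  class(out) <- c("parent_proteins", "data.frame")
  out
}

parent_seq <- function(parents, chain) {
  i <- match(chain, parents$chain_id)
  if (is.na(i)) stop("unknown chain '", chain, "'", call. = FALSE)
  parents$sequence[i]
}

#' Map product peptides onto parent chains
#'
#' Peptides given by sequence are located by exact substring search against
#' every parent chain; every occurrence is reported, and peptides occurring
#' more than once (across or within chains) are flagged `ambiguous`.
#' Peptides given by coordinates are verified: a row whose stated sequence
#' does not equal the parent subsequence becomes a per-row error record
#' rather than a global failure.
#'
#' @param peptides A character vector of peptide sequences, or a data frame
#'   with any of the columns `enzyme`, `chain`, `start`, `end`, `sequence`
#'   (coordinates optional when a sequence is given, and vice versa).
#' @param parents A [parent_proteins()] table (or anything coercible).
#' @return A data frame of located intervals (`chain_id`, `start`, `end`,
#'   `sequence`, `enzyme_label`, `ambiguous`, `annotation`) with attributes
#'   `unmapped` (peptides found nowhere) and `errors` (coordinate rows that
#'   failed verification).
#' @examples
#' hb <- parent_proteins(c(alpha = "VLSAADKGNVKAAW"))
#' map_peptides("SAADK", hb)
#' @export
map_peptides <- function(peptides, parents) {
  parents <- parent_proteins(parents)
  if (is.character(peptides))
    peptides <- data.frame(sequence = peptides, stringsAsFactors = FALSE)
  if (!nrow(peptides)) {
    out <- empty_intervals()
    attr(out, "unmapped") <- character()
    attr(out, "errors") <- data.frame()
    return(out)
  }
  enzyme <- if (!is.null(peptides$enzyme)) peptides$enzyme else
    rep(NA_character_, nrow(peptides))

  rows <- list(); unmapped <- character(); errors <- list()
  for (r in seq_len(nrow(peptides))) {
    pep <- peptides[r, , drop = FALSE]
    has_coords <- !is.null(pep$chain) && !is.null(pep$start) &&
      !is.null(pep$end) && !is.na(pep$start) && !is.na(pep$end)
    if (has_coords) {
      seq <- parent_seq(parents, pep$chain)
      if (pep$start < 1 || pep$end > nchar(seq) || pep$start > pep$end) {
        errors[[length(errors) + 1L]] <- data.frame(
          row = r, reason = "coordinates out of range",
          stringsAsFactors = FALSE)
        next
      }
      found <- substr(seq, pep$start, pep$end)
      stated <- pep$sequence
      if (!is.null(stated) && !is.na(stated) && nzchar(stated) &&
          !identical(found, stated)) {
        errors[[length(errors) + 1L]] <- data.frame(
          row = r,
          reason = sprintf("stated sequence '%s' != parent %s[%d..%d] = '%s'",
                           stated, pep$chain, pep$start, pep$end, found),
          stringsAsFactors = FALSE)
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chain_id = pep$chain, start = as.integer(pep$start),
        end = as.integer(pep$end), sequence = found,
        enzyme_label = enzyme[r], ambiguous = FALSE,
        stringsAsFactors = FALSE)
    } else {
      if (is.null(pep$sequence) || is.na(pep$sequence)) {
        errors[[length(errors) + 1L]] <- data.frame(
          row = r, reason = "neither coordinates nor sequence given",
          stringsAsFactors = FALSE)
        next
      }
      check_sequence(pep$sequence, sprintf("peptide row %d", r))
      occ <- list()
      for (ci in seq_len(nrow(parents))) {
        starts <- gregexpr(pep$sequence, parents$sequence[ci],
                           fixed = TRUE)[[1]]
        if (starts[1] == -1) next
        for (s in as.integer(starts)) {
          occ[[length(occ) + 1L]] <- data.frame(
            chain_id = parents$chain_id[ci], start = s,
            end = s + nchar(pep$sequence) - 1L, sequence = pep$sequence,
            enzyme_label = enzyme[r], stringsAsFactors = FALSE)
        }
      }
      if (!length(occ)) {
        unmapped <- c(unmapped, pep$sequence)
        next
      }
      occ <- do.call(rbind, occ)
      occ$ambiguous <- nrow(occ) > 1L
      rows[[length(rows) + 1L]] <- occ
    }
  }

  out <- if (length(rows)) do.call(rbind, rows) else empty_intervals()
  out$annotation <- rep("unannotated", nrow(out))
  rownames(out) <- NULL
  # mapping soundness: every output interval must reproduce its sequence
  for (i in seq_len(nrow(out))) {
    stopifnot(identical(
      substr(parent_seq(parents, out$chain_id[i]), out$start[i], out$end[i]),
      out$sequence[i]))
  }
  attr(out, "unmapped") <- unmapped
  attr(out, "errors") <- if (length(errors)) do.call(rbind, errors)
    else data.frame()
  out
}

empty_intervals <- function() {
  data.frame(chain_id = character(), start = integer(), end = integer(),
             sequence = character(), enzyme_label = character(),
             ambiguous = logical(), annotation = character(),
             stringsAsFactors = FALSE)
}

#' Extract cleavage sites from mapped peptide intervals
#'
#' Each internal peptide terminus evidences one scissile bond: the bond
#' before the peptide's start and the bond after its end. Termini that
#' coincide with a chain end evidence nothing. Sites are deduplicated per
#' (chain, bond) with support summed over contributing termini, and the
#' P4..P1 / P1'..P4' residue context is read off the parent (NA where the
#' context runs off a chain end).
#'
#' @param intervals Output of [map_peptides()] (or a compatible data frame).
#' @param parents The [parent_proteins()] table the intervals refer to.
#' @param min_support Drop sites evidenced by fewer termini (default 1,
#'   i.e. single-peptide evidence counts).
#' @param strict Exclude intervals flagged `ambiguous` (default `TRUE`);
#'   with `FALSE`, ambiguous placements contribute from every occurrence.
#' @return A data frame of class `cleavage_sites`: `chain_id`, `position`
#'   (bond index), `support`, one column per subsite `P4..P4'`, and `site`
#'   (display label).
#' @examples
#' hb <- parent_proteins(c(alpha = "VLSAADKGNVKAAW"))
#' iv <- map_peptides(c("VLSAA", "DKGNV"), hb)
#' extract_sites(iv, hb)
#' @export
extract_sites <- function(intervals, parents, min_support = 1L,
                          strict = TRUE) {
  parents <- parent_proteins(parents)
  if (strict && nrow(intervals))
    intervals <- intervals[!intervals$ambiguous, , drop = FALSE]

  bonds <- list()
  for (i in seq_len(nrow(intervals))) {
    iv <- intervals[i, ]
    len <- nchar(parent_seq(parents, iv$chain_id))
    if (iv$start > 1L)
      bonds[[length(bonds) + 1L]] <- c(iv$chain_id, iv$start - 1L)
    if (iv$end < len)
      bonds[[length(bonds) + 1L]] <- c(iv$chain_id, iv$end)
  }
  if (!length(bonds)) return(empty_sites())

  b <- data.frame(chain_id = vapply(bonds, `[`, "", 1),
                  position = as.integer(vapply(bonds, `[`, "", 2)),
                  stringsAsFactors = FALSE)
  key <- paste(b$chain_id, b$position)
  agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
  parts <- strsplit(agg$key, " ")
  out <- data.frame(
    chain_id = vapply(parts, function(p) paste(p[-length(p)], collapse = " "),
                      ""),
    position = as.integer(vapply(parts, function(p) p[length(p)], "")),
    support = agg$Freq, stringsAsFactors = FALSE)
  out <- out[out$support >= min_support, , drop = FALSE]
  out <- out[order(out$chain_id, out$position), , drop = FALSE]

  # subsite context: P4..P1 at positions i-3..i, P1'..P4' at i+1..i+4
  ctx <- matrix(NA_character_, nrow(out), 8,
                dimnames = list(NULL, .SUBSITES))
  lab <- character(nrow(out))
  for (i in seq_len(nrow(out))) {
    seq <- parent_seq(parents, out$chain_id[i])
    pos <- out$position[i]
    idx <- c(pos - 3L, pos - 2L, pos - 1L, pos,
             pos + 1L, pos + 2L, pos + 3L, pos + 4L)
    ok <- idx >= 1L & idx <= nchar(seq)
    ctx[i, ok] <- substring(seq, idx[ok], idx[ok])
    lab[i] <- sprintf("%s%d/%s%d", .AA3[[ctx[i, "P1"]]], pos,
                      .AA3[[ctx[i, "P1'"]]], pos + 1L)
  }
  out <- cbind(out, as.data.frame(ctx, stringsAsFactors = FALSE))
  out$site <- lab
  rownames(out) <- NULL
  class(out) <- c("cleavage_sites", "data.frame")
  out
}

empty_sites <- function() {
  ctx <- as.data.frame(matrix(character(), 0, 8,
                              dimnames = list(NULL, .SUBSITES)),
                       stringsAsFactors = FALSE)
  out <- cbind(data.frame(chain_id = character(), position = integer(),
                          support = integer(), stringsAsFactors = FALSE),
               ctx, data.frame(site = character(), stringsAsFactors = FALSE))
  class(out) <- c("cleavage_sites", "data.frame")
  out
}

#' Subsite occupancy table
#'
#' Counts, for each Schechter-Berger subsite across a set of cleavage
#' sites, how often each residue occupies it. Sites whose context is
#' truncated by a chain end contribute nothing to the truncated subsites;
#' the per-subsite truncation counts are kept so percentages can be taken
#' over the residues actually observed.
#'
#' @param sites A `cleavage_sites` data frame from [extract_sites()] (sites
#'   may also be weighted by their `support` via `weight_by_support`).
#' @param span Integer pair: number of non-primed and primed subsites to
#'   tabulate, up to `c(4, 4)` = P4..P4' (the default).
#' @param weight_by_support Count each site once (`FALSE`, default) or
#'   `support` times (`TRUE`).
#' @return A matrix of class `subsite_table` (subsites x 20 residues) with
#'   attributes `n_sites` and `truncated` (per-subsite missing contexts).
#' @export
subsite_table <- function(sites, span = c(4, 4), weight_by_support = FALSE) {
  if (!nrow(sites)) stop("no cleavage sites to tabulate", call. = FALSE)
  stopifnot(length(span) == 2, span[1] >= 0, span[2] >= 0,
            span[1] <= 4, span[2] <= 4, span[1] + span[2] > 0)
  keep <- c(rev(paste0("P", seq_len(span[1]))),
            paste0("P", seq_len(span[2]), "'"))
  keep <- .SUBSITES[.SUBSITES %in% keep]
  w <- if (weight_by_support) sites$support else rep(1L, nrow(sites))

  counts <- matrix(0L, length(keep), 20,
                   dimnames = list(keep, names(.MONO_RESIDUE)))
  truncated <- setNames(integer(length(keep)), keep)
  for (s in keep) {
    res <- sites[[s]]
    miss <- is.na(res)
    truncated[s] <- sum(w[miss])
    tab <- tapply(w[!miss], factor(res[!miss],
                                   levels = names(.MONO_RESIDUE)), sum)
    tab[is.na(tab)] <- 0
    counts[s, ] <- as.integer(tab)
  }
  structure(counts, n_sites = sum(w), truncated = truncated,
            class = c("subsite_table", class(counts)))
}

#' Default residue polarity classes
#'
#' The partition used for class percentages. The non-polar/hydrophobic set
#' is \{A, V, L, I, M, F, W, P, G\}; polar is the complement. The
#' convention is configurable because published percentages depend on it.
#'
#' @return A named list of residue vectors partitioning the 20-letter
#'   alphabet.
#' @export
residue_classes <- function() {
  nonpolar <- c("A", "V", "L", "I", "M", "F", "W", "P", "G")
  list(nonpolar = nonpolar,
       polar = setdiff(names(.MONO_RESIDUE), nonpolar))
}

#' Per-subsite class percentages and residue shares
#'
#' Summarizes a [subsite_table()] as the percentage of (non-truncated)
#' sites whose subsite residue falls in each class, plus optionally the
#' combined share of a named residue subset (e.g. the share of Leu+Phe at
#' P1).
#'
#' @param table A `subsite_table`.
#' @param classes A named list of residue vectors that partitions the
#'   20-residue alphabet (default [residue_classes()]).
#' @param share_residues Optional character vector of residues whose
#'   combined per-subsite share is reported.
#' @return A list with `class_percent` (data frame subsite x class, integer
#'   percent), `share` (per-subsite percent of `share_residues`, or `NULL`),
#'   `n_sites`, and the class definition used.
#' @export
classify_summary <- function(table, classes = residue_classes(),
                             share_residues = NULL) {
  all_res <- sort(unlist(classes, use.names = FALSE))
  if (length(all_res) != 20 || anyDuplicated(all_res) ||
      !identical(all_res, sort(names(.MONO_RESIDUE))))
    stop("classes must partition the 20-residue alphabet", call. = FALSE)

  totals <- rowSums(table)
  pct <- sapply(names(classes), function(cl) {
    round(100 * rowSums(table[, classes[[cl]], drop = FALSE]) /
            pmax(totals, 1))
  })
  pct <- as.data.frame(pct)
  pct$n_observed <- as.integer(totals)

  share <- NULL
  if (!is.null(share_residues)) {
    stopifnot(all(share_residues %in% names(.MONO_RESIDUE)))
    share <- round(100 * rowSums(table[, share_residues, drop = FALSE]) /
                     pmax(totals, 1))
  }
  list(class_percent = pct, share = share,
       n_sites = attr(table, "n_sites"), classes = classes)
}

#' Annotate intervals against a reference of known antimicrobials
#'
#' Exact interval identity marks a peptide `known_antimicrobial`; a
#' positional Jaccard overlap (intersection over union of residue
#' positions) of at least `min_jaccard` with any reference entry on the
#' same chain marks it `potential_antimicrobial`; otherwise it stays
#' `unannotated`.
#'
#' @param intervals A peptide-interval data frame ([map_peptides()]).
#' @param reference A data frame with `chain_id`, `start`, `end`, `name`
#'   (and optionally `source`), e.g. [hemocidin_reference()].
#' @param min_jaccard Overlap threshold in (0, 1] (default 0.5).
#' @return `intervals` with `annotation` filled in and a `matched_name`
#'   column naming the best reference hit (NA when unannotated).
#' @export
annotate_hemocidins <- function(intervals, reference, min_jaccard = 0.5) {
  stopifnot(min_jaccard > 0, min_jaccard <= 1)
  intervals$matched_name <- rep(NA_character_, nrow(intervals))
  if (!nrow(intervals) || is.null(reference) || !nrow(reference)) {
    intervals$annotation <- rep("unannotated", nrow(intervals))
    return(intervals)
  }
  for (i in seq_len(nrow(intervals))) {
    iv <- intervals[i, ]
    ref <- reference[reference$chain_id == iv$chain_id, , drop = FALSE]
    ann <- "unannotated"; best_j <- 0; best_name <- NA_character_
    for (r in seq_len(nrow(ref))) {
      if (ref$start[r] == iv$start && ref$end[r] == iv$end) {
        ann <- "known_antimicrobial"; best_name <- ref$name[r]
        break
      }
      inter <- max(0L, min(iv$end, ref$end[r]) - max(iv$start, ref$start[r]) + 1L)
      uni <- (iv$end - iv$start + 1L) + (ref$end[r] - ref$start[r] + 1L) - inter
      j <- inter / uni
      if (j >= min_jaccard && j > best_j) {
        ann <- "potential_antimicrobial"; best_j <- j; best_name <- ref$name[r]
      }
    }
    intervals$annotation[i] <- ann
    intervals$matched_name[i] <- best_name
  }
  intervals
}

#' Positional Jaccard overlap of two intervals
#'
#' @param a,b Length-2 integer vectors `c(start, end)`, 1-based inclusive.
#' @return Intersection size over union size, in `[0, 1]`.
#' @examples
#' interval_jaccard(c(33, 43), c(34, 46))  # 10/14
#' @export
interval_jaccard <- function(a, b) {
  inter <- max(0L, min(a[2], b[2]) - max(a[1], b[1]) + 1L)
  uni <- (a[2] - a[1] + 1L) + (b[2] - b[1] + 1L) - inter
  inter / uni
}

#' Packaged reference list of hemoglobin-derived antimicrobials
#'
#' Loads the packaged JSON of bovine hemoglobin fragments reported as
#' antimicrobial (hemocidins), identified by chain and 1-based interval.
#'
#' @param path Optional path to an alternative JSON reference.
#' @return A data frame with `chain_id`, `start`, `end`, `name`, `source`.
#' @export
hemocidin_reference <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "hemocidins_reference.json",
                        package = "scissile", mustWork = TRUE)
  ref <- jsonlite::fromJSON(path)
  stopifnot(all(c("chain_id", "start", "end", "name") %in% names(ref)),
            !anyDuplicated(ref$name), all(ref$start <= ref$end))
  ref
}
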