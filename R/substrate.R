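# Cleavage-site inference for internally quenched fluorogenic substrates.
#
# A tagged substrate Abz-X1..Xn-EDDnp cut once yields a fluorophore-retaining
# N-side fragment and a quencher-retaining C-side fragment; cut twice it
# additionally yields untagged internal fragments. Observed LC/MS ions are
# matched against the enumerated theoretical fragments, and the matched
# fragments identify the scissile bonds in parent-chain numbering.

#' Define a tagged fluorogenic substrate
#'
#' @param id Substrate identifier (e.g. `"SF 29-35"`).
#' @param sequence Residue string, uppercase standard alphabet. For
#'   Abz/EDDnp substrates this includes any linker residues (the C-terminal
#'   Gln carrying EDDnp).
#' @param n_mod,c_mod Terminal modifications ([get_modification()] names or
#'   objects), or `NULL` for free termini.
#' @param parent_offset Parent-chain residue number of the substrate's first
#'   residue; used only for naming inferred sites (e.g. Met32/Phe33).
#' @return An object of class `tagged_substrate`.
#' @examples
#' tagged_substrate("SF 29-35", "LERMFLSQ", "Abz", "EDDnp", parent_offset = 29)
#' @export
tagged_substrate <- function(id, sequence, n_mod = NULL, c_mod = NULL,
                             parent_offset = 1L) {
  check_sequence(sequence, "substrate sequence")
  if (parent_offset < 1)
    stop("parent_offset must be >= 1", call. = FALSE)
  structure(
    list(id = id, sequence = sequence,
         n_mod = get_modification(n_mod), c_mod = get_modification(c_mod),
         parent_offset = as.integer(parent_offset)),
    class = "tagged_substrate"
  )
}

#' @export
print.tagged_substrate <- function(x, ...) {
  tag <- function(m) if (is.null(m)) "" else paste0(m$name, "-")
  ctag <- function(m) if (is.null(m)) "" else paste0("-", m$name)
  cat(sprintf("<tagged substrate> %s: %s%s%s (parent offset %d)\n",
              x$id, tag(x$n_mod), x$sequence, ctag(x$c_mod), x$parent_offset))
  invisible(x)
}

# Scissile-bond label in parent numbering: cut after substrate position i
# between residues i and i+1, rendered "Met32/Phe33".
site_label <- function(substrate, cut_after) {
  s <- strsplit(substrate$sequence, "")[[1]]
  off <- substrate$parent_offset
  vapply(cut_after, function(i) {
    sprintf("%s%d/%s%d", .AA3[[s[i]]], off + i - 1L, .AA3[[s[i + 1L]]], off + i)
  }, character(1))
}

#' Enumerate candidate cleavage fragments of a tagged substrate
#'
#' For `max_cuts = 1`, both fragments of every single cut (2(n-1) in total
#' for an n-residue substrate); the N-side fragment retains the N-terminal
#' tag, the C-side fragment the C-terminal tag. For `max_cuts = 2`, all
#' untagged internal fragments (one per ordered cut pair) are added.
#'
#' @param substrate A [tagged_substrate()].
#' @param max_cuts 1 or 2.
#' @param mode Mass mode for fragment masses (default monoisotopic, the
#'   convention for MS fragment matching).
#' @param charge Charge state for the reported m/z (default 1; singly
#'   protonated ions).
#' @return A data frame with one row per fragment: `substrate_id`, `cut1`,
#'   `cut2` (`NA` for single cuts), `start`, `end`, `sequence`,
#'   `retains_n_mod`, `retains_c_mod`, `neutral_mass`, `mz`.
#' @examples
#' sf <- tagged_substrate("SF 29-35", "LERMFLSQ", "Abz", "EDDnp", 29)
#' nrow(enumerate_fragments(sf))  # 14
#' @export
enumerate_fragments <- function(substrate, max_cuts = 1L,
                                mode = c("monoisotopic", "average"),
                                charge = 1L) {
  mode <- match.arg(mode)
  if (!max_cuts %in% c(1L, 2L))
    stop("max_cuts must be 1 or 2", call. = FALSE)
  n <- nchar(substrate$sequence)
  if (n < 2)
    stop("substrate must have at least 2 residues", call. = FALSE)

  rows <- list()
  sub <- function(i, j) substr(substrate$sequence, i, j)
  add <- function(cut1, cut2, start, end, ret_n, ret_c) {
    seq <- sub(start, end)
    mass <- peptide_mass(seq,
                         n_mod = if (ret_n) substrate$n_mod,
                         c_mod = if (ret_c) substrate$c_mod,
                         mode = mode)
    rows[[length(rows) + 1L]] <<- data.frame(
      substrate_id = substrate$id, cut1 = cut1, cut2 = cut2,
      start = start, end = end, sequence = seq,
      retains_n_mod = ret_n, retains_c_mod = ret_c,
      neutral_mass = mass, mz = to_mz(mass, charge),
      stringsAsFactors = FALSE
    )
  }
  for (i in seq_len(n - 1L)) {
    add(i, NA_integer_, 1L, i, TRUE, FALSE)      # N-side, keeps fluorophore
    add(i, NA_integer_, i + 1L, n, FALSE, TRUE)  # C-side, keeps quencher
  }
  if (max_cuts == 2L && n >= 3L) {
    for (i in seq_len(n - 2L)) {
      for (j in seq(i + 1L, n - 1L)) {
        add(i, j, i + 1L, j, FALSE, FALSE)       # internal, untagged
      }
    }
  }
  do.call(rbind, rows)
}

# Fragment-level site labels (one or two bonds per fragment).
fragment_sites <- function(substrate, cut1, cut2) {
  mapply(function(a, b) {
    cuts <- c(a, b)
    paste(site_label(substrate, cuts[!is.na(cuts)]), collapse = " + ")
  }, cut1, cut2)
}

# Match one set of ions against one fragment table: best |error| within
# tolerance, exact ties flagged ambiguous (all tied rows returned).
match_against <- function(observed, frags, tolerance) {
  hits <- list(); unassigned <- list()
  for (mz in observed) {
    err <- frags$mz - mz
    ok <- which(abs(err) <= tolerance)
    if (!length(ok)) {
      nearest <- which.min(abs(err))
      unassigned[[length(unassigned) + 1L]] <- data.frame(
        observed_mz = mz,
        nearest_sequence = frags$sequence[nearest],
        nearest_error = err[nearest], stringsAsFactors = FALSE)
      next
    }
    best <- min(abs(err[ok]))
    tied <- ok[abs(abs(err[ok]) - best) < 1e-9]
    h <- frags[tied, , drop = FALSE]
    h$observed_mz <- mz
    h$mass_error <- err[tied]
    h$ambiguous <- length(tied) > 1L
    hits[[length(hits) + 1L]] <- h
  }
  list(
    matches = if (length(hits)) do.call(rbind, hits) else NULL,
    unassigned = if (length(unassigned)) do.call(rbind, unassigned) else NULL
  )
}

#' Infer scissile bonds from an observed ion list
#'
#' Two-stage matching. Tag-retaining fragments (single cuts) are matched
#' first: each observed ion is assigned to the fragment minimizing the
#' absolute mass error within `tolerance` (exact ties are reported and
#' flagged ambiguous), and the matched cuts form the evidenced cut set.
#' When `max_cuts = 2`, untagged internal fragments are then considered
#' confirmatory only: still-unassigned ions are matched against internal
#' fragments both of whose cuts are already evidenced. An internal fragment
#' alone cannot introduce a new site -- a deliberate conservatism, since a
#' short untagged fragment mass is compatible with many substring placements
#' while tagged fragments anchor the cut unambiguously at one terminus.
#'
#' @param substrate A [tagged_substrate()].
#' @param observed Numeric vector of observed m/z values (may be empty).
#' @param tolerance Matching tolerance in Da (default 0.5, wide enough for
#'   unit-resolution ion-trap data).
#' @param max_cuts 1 (default) or 2 (also consider internal fragments).
#' @param mode Mass mode (default monoisotopic).
#' @param charge Assumed charge state of the observed ions.
#' @return A list of class `ion_match_result`: `matches` (data frame of
#'   assigned ions with fragment, mass error, sites, ambiguity and
#'   `confirmatory` flag), `unassigned` (ions with no acceptable fragment),
#'   `sites` (consolidated site labels, ordered along the chain) and
#'   `cut_set` (substrate-internal cut positions).
#' @examples
#' sf <- tagged_substrate("SF 29-35", "LERMFLSQ", "Abz", "EDDnp", 29)
#' match_ions(sf, c(702.3, 927.7))$sites
#' @export
match_ions <- function(substrate, observed, tolerance = 0.5, max_cuts = 1L,
                       mode = c("monoisotopic", "average"), charge = 1L) {
  mode <- match.arg(mode)
  if (tolerance <= 0) stop("tolerance must be > 0", call. = FALSE)
  observed <- as.numeric(observed)

  frags1 <- enumerate_fragments(substrate, 1L, mode, charge)
  empty <- function() {
    data.frame(observed_mz = numeric(), sequence = character(),
               stringsAsFactors = FALSE)
  }
  if (!length(observed)) {
    out <- list(matches = empty(), unassigned = empty(),
                sites = character(), cut_set = integer())
    class(out) <- "ion_match_result"
    return(out)
  }

  pass1 <- match_against(observed, frags1, tolerance)
  matches <- pass1$matches
  cut_set <- sort(unique(matches$cut1))
  if (!is.null(matches)) matches$confirmatory <- FALSE

  leftover_mz <- if (is.null(pass1$unassigned)) numeric() else
    pass1$unassigned$observed_mz
  unassigned <- pass1$unassigned

  if (max_cuts == 2L && length(leftover_mz) && length(cut_set) >= 2L) {
    frags2 <- enumerate_fragments(substrate, 2L, mode, charge)
    internal <- frags2[!is.na(frags2$cut2) &
                         frags2$cut1 %in% cut_set &
                         frags2$cut2 %in% cut_set, , drop = FALSE]
    if (nrow(internal)) {
      pass2 <- match_against(leftover_mz, internal, tolerance)
      if (!is.null(pass2$matches)) {
        pass2$matches$confirmatory <- TRUE
        matches <- rbind(matches, pass2$matches)
      }
      unassigned <- pass2$unassigned
    }
  }

  if (is.null(matches)) matches <- empty() else {
    matches$sites <- fragment_sites(substrate, matches$cut1, matches$cut2)
    rownames(matches) <- NULL
  }
  if (is.null(unassigned)) unassigned <- empty() else rownames(unassigned) <- NULL

  cuts <- if (nrow(matches) && "cut1" %in% names(matches)) {
    sort(unique(c(matches$cut1[!matches$ambiguous],
                  matches$cut2[!is.na(matches$cut2)])))
  } else integer()
  out <- list(
    matches = matches,
    unassigned = unassigned,
    sites = if (length(cuts)) site_label(substrate, cuts) else character(),
    cut_set = as.integer(cuts)
  )
  class(out) <- "ion_match_result"
  out
}

#' @export
print.ion_match_result <- function(x, ...) {
  cat("<ion match result>\n")
  if (nrow(x$matches)) {
    for (i in seq_len(nrow(x$matches))) {
      m <- x$matches[i, ]
      cat(sprintf("  m/z %8.2f -> %s (theor. %8.2f, err %+0.3f Da)%s -> %s\n",
                  m$observed_mz, m$sequence, m$mz, m$mass_error,
                  if (isTRUE(m$ambiguous)) " [ambiguous]" else "",
                  m$sites))
    }
  }
  if (nrow(x$unassigned)) {
    cat(sprintf("  %d unassigned ion(s): %s\n", nrow(x$unassigned),
                paste(format(x$unassigned$observed_mz), collapse = ", ")))
  }
  cat("  sites:", if (length(x$sites)) paste(x$sites, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}
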