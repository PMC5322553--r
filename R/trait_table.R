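#' Construct a trait table
#'
#' The analysis-ready table joining, per organism, the binary gene state
#' (`present` / `absent` / `unknown`), genome completeness, a free habitat
#' label, and the ordinal iron level (0 = low/scarce, 1 = medium, 2 = high).
#' `absent` may only be recorded for completely sequenced genomes: a draft
#' genome with no hit is `unknown`, never `absent`, to avoid false negatives.
#'
#' @param organism_id Character vector of unique organism identifiers.
#' @param fld_state One of `"present"`, `"absent"`, `"unknown"` per organism.
#' @param genome_complete Logical vector.
#' @param habitat Free-text habitat label (optional, `NA` allowed).
#' @param iron_level Ordinal iron availability in `0:2` (`NA` allowed).
#' @param provenance Named list of processing metadata (thresholds used,
#'   whether dedup was applied); stored as an attribute.
#' @return A `data.frame` of class `"trait_table"`.
#' @export
trait_table <- function(organism_id, fld_state,
                        genome_complete = TRUE,
                        habitat = NA_character_,
                        iron_level = NA_integer_,
                        provenance = list()) {
  df <- data.frame(organism_id = as.character(organism_id),
                   fld_state = as.character(fld_state),
                   genome_complete = rep_len(as.logical(genome_complete),
                                             length(organism_id)),
                   habitat = rep_len(as.character(habitat),
                                     length(organism_id)),
                   iron_level = rep_len(as.integer(iron_level),
                                        length(organism_id)),
                   stringsAsFactors = FALSE)
  validate_trait_table(df)
  attr(df, "provenance") <- provenance
  class(df) <- c("trait_table", "data.frame")
  df
}

validate_trait_table <- function(df) {
  needed <- c("organism_id", "fld_state", "genome_complete",
              "habitat", "iron_level")
  miss <- setdiff(needed, names(df))
  if (length(miss)) stop("trait table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$organism_id))
    stop("duplicate organism_id in trait table")
  bad <- !df$fld_state %in% c("present", "absent", "unknown")
  if (any(bad)) stop("invalid fld_state value(s): ",
                     paste(unique(df$fld_state[bad]), collapse = ", "))
  if (any(df$fld_state == "absent" & !df$genome_complete))
    stop("fld_state 'absent' recorded for an incomplete genome")
  ok_iron <- is.na(df$iron_level) | df$iron_level %in% 0:2
  if (!all(ok_iron)) stop("iron_level must be in {0, 1, 2} or NA")
  invisible(df)
}

# Standard 12-column tabular homology hit format (BLAST outfmt 6).
hit_columns <- c("query_id", "subject_id", "percent_identity",
                 "alignment_length", "mismatches", "gap_openings",
                 "q_start", "q_end", "s_start", "s_end",
                 "evalue", "bitscore")

#' Read a 12-column tabular homology hit file
#'
#' Tab-separated, no header, the column order emitted by standard search
#' tools: query, subject, percent identity, alignment length, mismatches,
#' gap openings, query start/end, subject start/end, e-value, bit score.
#'
#' @param path File path.
#' @return A `data.frame` with named columns; e-values and identities are
#'   validated (`evalue >= 0`, identity in `[0, 100]`).
#' @export
read_hits <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 12L)
    stop("hit file has ", ncol(df), " columns; 12 expected")
  names(df)[1:12] <- hit_columns
  validate_hits(df)
}

validate_hits <- function(df) {
  if (any(df$evalue < 0)) stop("negative e-value in hit table")
  if (any(df$percent_identity < 0 | df$percent_identity > 100))
    stop("percent_identity outside [0, 100]")
  df
}

#' Call gene presence/absence from homology hits
#'
#' An organism is `present` iff it has at least one hit with e-value at or
#' below the threshold (default `1e-5`, the calling threshold used for
#' database searches).  Organisms with no qualifying hit are `absent` only
#' when their genome is completely sequenced; otherwise the state is
#' `unknown` and the organism is excluded from downstream analyses.
#'
#' @param hits Hit `data.frame` (see [read_hits()]) carrying an
#'   `organism_id` column assigning each hit to an organism; an error is
#'   raised if an organism in `hits` is not covered by `genome_complete`.
#' @param genome_complete Named logical vector over *all* organisms under
#'   study (the calling universe; organisms without hits must appear here to
#'   receive an `absent`/`unknown` call).
#' @param evalue_threshold Positive e-value cutoff, default `1e-5`.
#' @return A `"trait_table"` with `fld_state` filled in and habitat/iron
#'   left `NA`, rows in the order of `names(genome_complete)`.
#' @examples
#' hits <- data.frame(organism_id = "org1", query_id = "fld", subject_id = "g1",
#'                    percent_identity = 45, alignment_length = 160,
#'                    evalue = 1e-12, bitscore = 150)
#' call_presence(hits, c(org1 = TRUE, org2 = TRUE, org3 = FALSE))
#' @export
call_presence <- function(hits, genome_complete, evalue_threshold = 1e-5) {
  stopifnot(evalue_threshold > 0)
  if (is.null(names(genome_complete)) || anyNA(names(genome_complete)))
    stop("genome_complete must be a named logical vector")
  orgs <- names(genome_complete)
  if (nrow(hits) > 0) {
    if (!"organism_id" %in% names(hits))
      stop("hits must carry an organism_id column")
    unknown_org <- setdiff(unique(hits$organism_id), orgs)
    if (length(unknown_org))
      stop("organism(s) in hits missing from genome_complete: ",
           paste(unknown_org, collapse = ", "))
    qualifying <- hits$organism_id[hits$evalue <= evalue_threshold]
  } else {
    qualifying <- character(0)
  }
  state <- ifelse(orgs %in% qualifying, "present",
                  ifelse(genome_complete, "absent", "unknown"))
  trait_table(orgs, state, genome_complete = unname(genome_complete),
              provenance = list(evalue_threshold = evalue_threshold))
}

#' Greedy identity-threshold clustering of sequences
#'
#' Reduces redundancy in a sequence set from a pairwise percent-identity
#' matrix, emulating greedy incremental clustering: labels are visited in
#' `tie_order` (default: sorted), each label joins the first existing
#' cluster whose *representative* has identity at or above the threshold,
#' otherwise it founds a new cluster.  Only representatives are returned.
#'
#' @param identity Symmetric matrix of percent identities in `[0, 100]` with
#'   diagonal 100 and identical row/column names.
#' @param threshold Percent identity cutoff (e.g. 70, 80 or 90).
#' @param tie_order Character vector giving the visiting order; defaults to
#'   lexicographic label order for reproducibility.
#' @return Character vector of representative labels, in founding order.
#' @export
cluster_representatives <- function(identity, threshold, tie_order = NULL) {
  stopifnot(is.matrix(identity), nrow(identity) == ncol(identity))
  if (!isTRUE(all.equal(identity, t(identity), tolerance = 1e-8,
                        check.attributes = FALSE)))
    stop("identity matrix is not symmetric")
  labs <- rownames(identity)
  if (is.null(labs)) stop("identity matrix must be labeled")
  if (is.null(tie_order)) tie_order <- sort(labs)
  if (!setequal(tie_order, labs)) stop("tie_order must permute the labels")
  reps <- character(0)
  for (lab in tie_order) {
    hit <- which(identity[lab, reps] >= threshold)
    if (length(hit) == 0L) reps <- c(reps, lab)
  }
  reps
}

#' Remove near-duplicate tips before fitting
#'
#' Over-represented, nearly identical isolates bias an association test
#' toward whatever pattern they share.  This filter groups organisms by
#' single linkage over pairs whose sequence divergence is below the
#' threshold (default 0.005, i.e. 0.5%) *and* that share the same
#' (`fld_state`, `iron_level`) pattern; within each group only the
#' lexicographically first `organism_id` is retained.  Groups are only
#' formed within identical patterns, so two close tips with different
#' states are both kept.
#'
#' @param distances Labeled symmetric divergence matrix on the proportion
#'   scale (0.005 = 0.5%), covering every organism in `traits`.
#' @param traits A `"trait_table"`.
#' @param divergence_threshold Proportion below which two organisms are
#'   considered redundant; default 0.005.
#' @return The reduced `"trait_table"`, survivors in input order, with the
#'   filter recorded in the provenance attribute.
#' @export
dedup_tips <- function(distances, traits, divergence_threshold = 0.005) {
  validate_trait_table(traits)
  ids <- traits$organism_id
  miss <- setdiff(ids, rownames(distances))
  if (length(miss))
    stop("organism(s) missing from distance matrix: ",
         paste(miss, collapse = ", "))
  D <- distances[ids, ids, drop = FALSE]
  if (anyNA(D)) stop("missing distance entry")
  pattern <- paste(traits$fld_state, traits$iron_level, sep = "|")
  # union-find over edges: close pair + identical pattern
  parent <- seq_along(ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  n <- length(ids)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (D[i, j] < divergence_threshold && pattern[i] == pattern[j]) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  keep <- logical(n)
  for (g in unique(comp)) {
    members <- which(comp == g)
    keep[members[order(ids[members])[1L]]] <- TRUE
  }
  out <- traits[keep, , drop = FALSE]
  rownames(out) <- NULL
  prov <- attr(traits, "provenance")
  if (is.null(prov)) prov <- list()
  prov$dedup <- list(divergence_threshold = divergence_threshold,
                     linkage = "single",
                     survivor_rule = "lexicographic",
                     n_in = n, n_out = sum(keep))
  attr(out, "provenance") <- prov
  class(out) <- c("trait_table", "data.frame")
  out
}

#' Per-habitat-class presence frequencies
#'
#' Tallies, for each habitat class, how many organisms carry the gene out of
#' how many scored (unknown states are excluded), and the percentage
#' `100 * n_present / n_total`, also rounded to integer precision for
#' reporting.
#'
#' @param traits A `"trait_table"`; rows with `fld_state == "unknown"` or a
#'   missing habitat are dropped.
#' @param habitat_grouping Optional named character vector mapping habitat
#'   labels to coarser classes; habitats without a mapping are dropped with
#'   a warning.  Default: each habitat label is its own class.
#' @return `data.frame` with columns `class`, `n_present`, `n_total`,
#'   `percent` (exact) and `percent_rounded`; empty classes are omitted with
#'   a warning.
#' @examples
#' tt <- trait_table(sprintf("o%02d", 1:10),
#'                   rep(c("present", "absent"), 5),
#'                   habitat = rep(c("lake", "ocean"), each = 5))
#' habitat_frequency(tt)
#' @export
habitat_frequency <- function(traits, habitat_grouping = NULL) {
  validate_trait_table(traits)
  use <- traits$fld_state != "unknown" & !is.na(traits$habitat)
  tt <- traits[use, , drop = FALSE]
  if (is.null(habitat_grouping)) {
    cls <- tt$habitat
    classes <- unique(traits$habitat[!is.na(traits$habitat)])
  } else {
    cls <- unname(habitat_grouping[tt$habitat])
    unmapped <- unique(tt$habitat[is.na(cls)])
    if (length(unmapped))
      warning("habitat(s) without class mapping dropped: ",
              paste(unmapped, collapse = ", "))
    tt <- tt[!is.na(cls), , drop = FALSE]
    cls <- cls[!is.na(cls)]
    classes <- unique(unname(habitat_grouping))
  }
  empty <- setdiff(classes, unique(cls))
  if (length(empty))
    warning("empty habitat class(es) omitted: ",
            paste(empty, collapse = ", "))
  out <- do.call(rbind, lapply(unique(cls), function(k) {
    sel <- cls == k
    np <- sum(tt$fld_state[sel] == "present")
    nt <- sum(sel)
    data.frame(class = k, n_present = np, n_total = nt,
               percent = 100 * np / nt,
               percent_rounded = round(100 * np / nt),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Read / write trait tables as TSV
#'
#' Header columns: `organism_id`, `fld_state`, `genome_complete`,
#' `habitat`, `iron_level`.
#'
#' @param path File path.
#' @export
read_trait_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$genome_complete <- as.logical(df$genome_complete)
  trait_table(df$organism_id, df$fld_state, df$genome_complete,
              df$habitat, df$iron_level)
}

#' @rdname read_trait_table
#' @param traits A `"trait_table"`.
#' @export
write_trait_table <- function(traits, path) {
  validate_trait_table(traits)
  utils::write.table(as.data.frame(traits), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
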